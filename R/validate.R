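#' Detection and quantification limits from method blanks
#'
#' Currie-style limits from the spread of blank-equivalent concentrations:
#' `LoD = k_d * sd(blanks)` and `LoQ = k_q * sd(blanks)`, by default with
#' multipliers 3 and 10 so that LoQ/LoD = 10/3. Blanks should be the signed
#' blank-corrected concentrations from the full method (30 blanks over
#' different analytical sessions is the reference design); negative values
#' are informative and must be retained.
#'
#' @param blanks numeric blank-equivalent concentrations, length >= 2.
#' @param k_d,k_q LoD and LoQ multipliers (defaults 3 and 10).
#' @return List with `lod`, `loq`, `sd_blank`, `n`.
#' @export
lod_loq <- function(blanks, k_d = 3, k_q = 10) {
  if (length(blanks) < 2) stop("need >= 2 blank measurements")
  s <- stats::sd(blanks)
  list(lod = k_d * s, loq = k_q * s, sd_blank = s, n = length(blanks))
}

#' Coefficient of variation of replicate measurements
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; the standard
#' precision measure for both repeatability (same session) and intermediate
#' precision (across sessions).
#'
#' @param replicates numeric concentrations, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
precision_cv <- function(replicates) {
  if (length(replicates) < 2) stop("need >= 2 replicates")
  m <- mean(replicates)
  if (m == 0) stop("undefined CV: replicate mean is zero")
  100 * stats::sd(replicates) / m
}

#' Horwitz predicted relative standard deviation
#'
#' The Horwitz function predicts the acceptable between-laboratory RSD as a
#' function of analyte mass fraction `c` (dimensionless, e.g. 1 mg/kg =
#' 1e-6): `PRSD = 2^(1 - 0.5 * log10(c))` percent. Below c = 1.2e-7 (120
#' ug/kg) the Thompson modification caps the prediction at a constant 22%,
#' reflecting the empirical flattening of the curve at trace levels; it is
#' applied by default.
#'
#' @param conc concentration in ug/kg (> 0).
#' @param thompson apply the low-level 22% floor (default TRUE).
#' @return Predicted RSD, percent.
#' @export
horwitz_prsd <- function(conc, thompson = TRUE) {
  if (any(conc <= 0)) stop("concentration must be > 0")
  c_frac <- conc * 1e-9          # ug/kg -> mass fraction
  prsd <- 2^(1 - 0.5 * log10(c_frac))
  if (thompson) prsd[c_frac < 1.2e-7] <- 22
  prsd
}

#' Check a measured CV against the Horwitz acceptance band
#'
#' @param cv measured CV, percent.
#' @param conc concentration at which precision was measured, ug/kg.
#' @param thompson see [horwitz_prsd()].
#' @return List with `ok` (CV <= predicted RSD), `prsd`, `horrat` (the
#'   CV/PRSD ratio).
#' @export
horwitz_check <- function(cv, conc, thompson = TRUE) {
  prsd <- horwitz_prsd(conc, thompson = thompson)
  list(ok = cv <= prsd, prsd = prsd, horrat = cv / prsd)
}

#' Spike-recovery trueness assessment
#'
#' Aliquots of a sample are spiked with increasing known amounts of
#' standard; per-aliquot recovery is `100 * (found - base) / added`. The
#' mean recovery is tested against 100% with a two-tailed one-sample t-test
#' (df = n - 1): a significant deficit is an underestimation bias, a
#' significant excess an overestimation bias, otherwise the recovery is
#' quantitative. Acceptability is additionally screened against a
#' concentration-banded recovery range (AOAC-style), configurable via
#' `bands`.
#'
#' @param base unspiked (base) concentration of the sample, ug/kg.
#' @param spiked data frame or list of `(added, found)` pairs, ug/kg;
#'   >= 2 aliquots, all `added > 0`.
#' @param alpha significance level (default 0.05).
#' @param bands acceptance table: data frame with columns `max_conc`
#'   (upper bound of the band, ug/kg, `Inf` for the last), `lo`, `hi`
#'   (acceptable recovery %, inclusive). The band is chosen by the mean
#'   spiked concentration `base + mean(added)`.
#' @return List with `recovery_mean`, `recovery_sd`, `recoveries`, `t`,
#'   `df`, `p`, `bias_verdict` (`"quantitative"`, `"under"`, `"over"`),
#'   `aoac_ok`.
#' @export
recovery_test <- function(base, spiked, alpha = 0.05,
                          bands = default_recovery_bands()) {
  if (is.data.frame(spiked)) {
    added <- spiked$added; found <- spiked$found
  } else {
    added <- vapply(spiked, `[[`, numeric(1), "added")
    found <- vapply(spiked, `[[`, numeric(1), "found")
  }
  if (any(added <= 0)) stop("spike additions must be > 0")
  if (length(added) < 2) stop("need >= 2 spiked aliquots")
  rec <- 100 * (found - base) / added
  m <- mean(rec); s <- stats::sd(rec); n <- length(rec)
  if (s == 0) {
    t <- if (m == 100) 0 else Inf * sign(m - 100)
    p <- if (m == 100) 1 else 0
  } else {
    t <- (m - 100) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  verdict <- if (p > alpha) "quantitative" else if (t < 0) "under" else "over"
  conc <- base + mean(added)
  band <- bands[which(conc <= bands$max_conc)[1], ]
  list(recovery_mean = m, recovery_sd = s, recoveries = rec,
       t = t, df = n - 1L, p = p, bias_verdict = verdict,
       aoac_ok = m >= band$lo && m <= band$hi)
}

#' Default concentration-banded recovery acceptance table
#'
#' Editable AOAC-style acceptance ranges: 80--110% recovery at or below
#' 100 ug/kg, 85--110% above.
#'
#' @return Data frame with columns `max_conc`, `lo`, `hi`.
#' @export
default_recovery_bands <- function() {
  data.frame(max_conc = c(100, Inf), lo = c(80, 85), hi = c(110, 110))
}

#' Efficiency of organic matter decomposition
#'
#' `EOMD% = 100 * (TOC - DOC) / TOC`, where TOC is the total organic carbon
#' of the honey and DOC the dissolved organic carbon remaining in the
#' digested solution, both in mg/kg. Complete decomposition gives 100%; a
#' successful honey digestion is typically above 94%.
#'
#' @param toc total organic carbon, mg/kg (> 0).
#' @param doc dissolved organic carbon, mg/kg (0 <= doc <= toc).
#' @return EOMD in percent.
#' @export
eomd <- function(toc, doc) {
  if (any(toc <= 0)) stop("TOC must be > 0")
  if (any(doc < 0)) stop("DOC must be >= 0")
  if (any(doc > toc))
    stop("DOC exceeds TOC: over-unity decomposition efficiency is impossible")
  100 * (toc - doc) / toc
}

#' Assemble a per-element validation report
#'
#' Combines blank-based limits, precision CVs with Horwitz acceptance, and
#' spike-recovery bias tests into one row per element, the layout of a
#' method-validation table.
#'
#' @param elements character vector of element symbols.
#' @param blanks named list of blank-concentration vectors per element.
#' @param repeatability,intermediate named lists of replicate concentration
#'   vectors per element.
#' @param spikes named list per element: list with `base` and `spiked` as in
#'   [recovery_test()].
#' @param alpha significance level for bias tests.
#' @return A `validation_report` data frame: `element`, `lod`, `loq`,
#'   `cv_repeatability`, `cv_intermediate`, `horwitz_ok_rep`,
#'   `horwitz_ok_int`, `recovery_mean`, `recovery_sd`, `bias_verdict`,
#'   `aoac_ok`.
#' @export
validation_report <- function(elements, blanks, repeatability, intermediate,
                              spikes, alpha = 0.05) {
  rows <- lapply(elements, function(el) {
    ll <- lod_loq(blanks[[el]])
    cv_r <- precision_cv(repeatability[[el]])
    cv_i <- precision_cv(intermediate[[el]])
    rec <- recovery_test(spikes[[el]]$base, spikes[[el]]$spiked, alpha = alpha)
    m_r <- mean(repeatability[[el]]); m_i <- mean(intermediate[[el]])
    data.frame(element = el, lod = ll$lod, loq = ll$loq,
               cv_repeatability = cv_r, cv_intermediate = cv_i,
               horwitz_ok_rep = horwitz_check(cv_r, m_r)$ok,
               horwitz_ok_int = horwitz_check(cv_i, m_i)$ok,
               recovery_mean = rec$recovery_mean,
               recovery_sd = rec$recovery_sd,
               bias_verdict = rec$bias_verdict,
               aoac_ok = rec$aoac_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Format a validation report with table-style rounding
#'
#' Rounds a validation report (or the equivalent columns of an element
#' panel) the way validation tables are printed: LoD/LoQ to 2 significant
#' figures, CV% to the nearest integer, recovery as integer +/- integer sd.
#'
#' @param report a `validation_report` or any data frame with columns
#'   `lod`, `loq`, `cv_repeatability`, `cv_intermediate`, `recovery_mean`,
#'   `recovery_sd`.
#' @return Data frame of formatted character columns.
#' @export
format_validation_report <- function(report) {
  fmt_sig2 <- function(x) format(signif(x, 2), trim = TRUE, scientific = FALSE)
  data.frame(element = report$element,
             lod = fmt_sig2(report$lod),
             loq = fmt_sig2(report$loq),
             cv_repeatability = as.character(round(report$cv_repeatability)),
             cv_intermediate = as.character(round(report$cv_intermediate)),
             recovery = paste0(round(report$recovery_mean), " ± ",
                               round(report$recovery_sd)),
             stringsAsFactors = FALSE)
}
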