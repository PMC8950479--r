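#' Internal-standard drift correction and blank subtraction
#'
#' Raw analyte counts are first divided by the measured-to-reference
#' response ratio of the internal standard (Rh at 10 ug/dm^3), compensating
#' instrumental drift, then the blank signal is subtracted. The result may
#' be negative: signed blank-corrected signals are needed downstream for
#' detection-limit statistics and must not be clipped here.
#'
#' @param raw raw signal counts.
#' @param blank blank signal counts (already drift-corrected).
#' @param istd_ratio measured/reference internal-standard response ratio;
#'   must be > 0.
#' @return Corrected signal, `raw / istd_ratio - blank`.
#' @export
correct_signal <- function(raw, blank, istd_ratio = 1) {
  if (any(istd_ratio <= 0))
    stop("internal-standard drift failure: istd_ratio must be > 0")
  raw / istd_ratio - blank
}

#' Fit an instrumental calibration line
#'
#' Ordinary least squares of signal on concentration over all replicate
#' points. The standard design replicates the two extreme points of the
#' calibration range three times each (six standards per analyte); any
#' level/replicate layout with at least two distinct concentrations is
#' accepted.
#'
#' @param levels a list of `(conc, signals)` pairs: each element is a list
#'   or data frame with `conc` (ug/dm^3, scalar) and `signals` (numeric
#'   replicate signals). Alternatively a data frame with columns `conc` and
#'   `signal`, one row per replicate point.
#' @param element optional element symbol carried into the fit.
#' @return A `calibration_fit`: list with `element`, `slope`, `intercept`,
#'   `r2`, `slope_se`, `df`, `n`, `data` (the point-level data) and the
#'   underlying `lm` fit.
#' @export
fit_calibration <- function(levels, element = NA_character_) {
  if (is.data.frame(levels)) {
    pts <- data.frame(conc = levels$conc, signal = levels$signal)
  } else {
    pts <- do.call(rbind, lapply(levels, function(l)
      data.frame(conc = l$conc, signal = as.numeric(l$signals))))
  }
  if (length(unique(pts$conc)) < 2)
    stop("singular calibration design: need >= 2 distinct concentrations")
  fit <- stats::lm(signal ~ conc, data = pts)
  # noise-free replicated lines are a legitimate input here (r2 must be 1),
  # so muffle summary.lm's perfect-fit advisory only
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(element = element,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 slope_se = sm$coefficients["conc", "Std. Error"],
                 df = fit$df.residual,
                 n = nrow(pts),
                 data = pts, lm = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration %s: signal = %.6g + %.6g x conc, R2 = %.4f (n = %d)\n",
              ifelse(is.na(x$element), "", x$element),
              x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}

#' Verify linearity of a calibration function at its central point
#'
#' Replicate standards at the centre of the calibration range are compared
#' with the line's prediction by a two-tailed one-sample t-test; the
#' calibration is declared linear only if the difference is not significant
#' at `alpha` *and* the coefficient of determination reaches `r2_min`.
#'
#' @param fit a `calibration_fit`.
#' @param center list/data frame with `conc` (central concentration) and
#'   `signals` (>= 2 replicate signals).
#' @param alpha significance level of the t-test (default 0.05).
#' @param r2_min minimum acceptable R^2 (default 0.999).
#' @return List with `verdict` (`"linear"` / `"nonlinear"`), `t`, `df`, `p`,
#'   `predicted`, `r2_ok`.
#' @export
check_linearity <- function(fit, center, alpha = 0.05, r2_min = 0.999) {
  sig <- as.numeric(center$signals)
  if (length(sig) < 2) stop("need >= 2 center replicates")
  pred <- fit$intercept + fit$slope * center$conc
  if (stats::sd(sig) == 0) {
    if (isTRUE(all.equal(mean(sig), pred))) {
      t <- 0; p <- 1
    } else {
      # zero replicate variance with nonzero bias: certain lack of fit
      t <- Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(sig, mu = pred)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  r2_ok <- fit$r2 >= r2_min
  verdict <- if (p > alpha && r2_ok) "linear" else "nonlinear"
  list(verdict = verdict, t = t, df = length(sig) - 1L, p = p,
       predicted = pred, r2_ok = r2_ok)
}

#' Digest description for concentration scaling
#'
#' @param sample_mass mass of honey digested, g (typically ~0.7 g).
#' @param final_volume final digest volume, cm^3 (typically 15 cm^3).
#' @param dilution_factor post-digestion blank-dilution factor, >= 1.
#' @return A `digest_info` list.
#' @export
digest_info <- function(sample_mass, final_volume, dilution_factor = 1) {
  if (sample_mass <= 0) stop("sample_mass must be > 0")
  if (final_volume <= 0) stop("final_volume must be > 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  structure(list(sample_mass = sample_mass, final_volume = final_volume,
                 dilution_factor = dilution_factor), class = "digest_info")
}

#' Solution concentration to honey concentration
#'
#' Scales an instrumental solution concentration (ug/dm^3) to a
#' concentration in the original honey (ug/kg):
#' `conc * V(dm^3) * dilution / mass(kg)`. With the standard digest
#' (0.7 g to 15 cm^3, no dilution) 1 ug/dm^3 corresponds to ~21.4 ug/kg.
#' Negative solution concentrations (possible after blank correction) clamp
#' to 0 and are flagged censored.
#'
#' @param solution_conc concentration in the measured solution, ug/dm^3.
#' @param digest a [digest_info()].
#' @return Numeric vector of honey concentrations, ug/kg, with attribute
#'   `censored` (logical: clamped negatives).
#' @export
quantify_concentration <- function(solution_conc, digest) {
  stopifnot(inherits(digest, "digest_info"), all(is.finite(solution_conc)))
  censored <- solution_conc < 0
  conc <- pmax(solution_conc, 0) *
    (digest$final_volume / 1000) * digest$dilution_factor /
    (digest$sample_mass / 1000)
  attr(conc, "censored") <- censored
  conc
}

#' Test for a matrix effect by comparing calibration slopes
#'
#' The slopes of a calibration fitted in plain acid solution and one fitted
#' in digested-matrix solution are compared with a Welch-style t-test: the
#' statistic is the slope difference over the root-sum-square of the two
#' regression slope standard errors, with Welch--Satterthwaite degrees of
#' freedom. A non-significant difference at `alpha` means external (aqueous)
#' calibration is adequate.
#'
#' @param fit_aqueous,fit_matrix `calibration_fit`s with >= 3 points each.
#' @param alpha significance level (default 0.05).
#' @return List with `verdict` (`"absent"` / `"present"`), `t`, `df`, `p`,
#'   `slope_ratio` (matrix/aqueous).
#' @export
matrix_effect_test <- function(fit_aqueous, fit_matrix, alpha = 0.05) {
  for (f in list(fit_aqueous, fit_matrix))
    if (f$n < 3) stop("insufficient data: each calibration needs >= 3 points")
  d <- fit_matrix$slope - fit_aqueous$slope
  se2a <- fit_aqueous$slope_se^2
  se2m <- fit_matrix$slope_se^2
  if (se2a + se2m == 0) {
    t <- if (d == 0) 0 else Inf
    df <- fit_aqueous$df + fit_matrix$df
    p <- if (d == 0) 1 else 0
  } else {
    t <- d / sqrt(se2a + se2m)
    df <- (se2a + se2m)^2 /
      (se2a^2 / fit_aqueous$df + se2m^2 / fit_matrix$df)
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(verdict = if (p > alpha) "absent" else "present",
       t = t, df = df, p = p,
       slope_ratio = fit_matrix$slope / fit_aqueous$slope)
}

#' Average duplicate sample analyses
#'
#' Each honey sample is analyzed in duplicate; replicate rows sharing a
#' `sample_id` are averaged (quantified values) before table assembly.
#' Censoring is resolved afterwards against the panel, so a pair
#' (quantified, below-LoQ) averages over the recorded values.
#'
#' @param conc data frame with columns `sample_id`, `element`, `conc`
#'   (ug/kg; `NA` for non-detects).
#' @return Data frame `sample_id`, `element`, `conc` with one row per pair,
#'   `conc` the mean of the non-missing replicate values (NA if none).
#' @export
average_duplicates <- function(conc) {
  stopifnot(all(c("sample_id", "element", "conc") %in% names(conc)))
  agg <- stats::aggregate(conc ~ sample_id + element, data = conc,
                          FUN = mean, na.action = stats::na.pass,
                          na.rm = TRUE)
  agg$conc[is.nan(agg$conc)] <- NA_real_
  agg[order(agg$sample_id, agg$element), , drop = FALSE]
}
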