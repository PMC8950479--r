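# Synthetic honey elemental datasets: per-class log-normal profiles with
# block-correlated covariance, multiplicative measurement noise and
# LoD/LoQ censoring, so every pipeline stage is testable without the
# original (undistributed) sample set.

#' Default per-class element profiles
#'
#' Ships four botanical-class profiles on the log10 concentration scale.
#' For each class x element the profile stores a location (log10 of a
#' geometric center chosen inside the published concentration range of
#' that honey type) and a spread (log10 sd sized so that +/- 2 sd roughly
#' spans the published range), plus the printed range bounds where these
#' were uncensored (NA where the table printed a censored bound). Censoring
#' is not parameterized directly: it emerges from the location/spread
#' relative to the panel LoD/LoQ, so rarely-quantified elements (Ag, Be,
#' Hg, Sb, Te) sit well below their limits in every class.
#'
#' Correlated element blocks (Fe-Mn-V, Cu-Ni-Zn, Ba-Sr-Li, Cd-Co) share a
#' common within-class correlation, 0.7 by default.
#'
#' @param rho within-block correlation on the log scale (default 0.7).
#' @return List with `profiles` (data frame: `class`, `element`,
#'   `log10_loc`, `log10_sd`, `range_low`, `range_high`) and `blocks`
#'   (list of `list(elements, rho)`).
#' @export
default_profiles <- function(rho = 0.7) {
  el <- c("Ag", "As", "Ba", "Be", "Bi", "Cd", "Co", "Cr", "Cu", "Fe",
          "Hg", "Li", "Mn", "Mo", "Ni", "Pb", "Sb", "Sn", "Sr", "Te",
          "Tl", "V", "Zn")
  g <- list(
    asphodel        = c(1.5, 3, 120, 0.05, 0.15, 0.5, 2, 15, 80, 150,
                        1, 1.5, 170, 1.2, 14, 15, 0.5, 30, 30, 0.5,
                        0.09, 0.35, 450),
    eucalyptus      = c(1.5, 6, 300, 0.05, 0.15, 1.5, 6, 15, 160, 500,
                        1, 9, 2000, 1.8, 18, 12, 0.5, 25, 160, 0.5,
                        0.25, 3.5, 600),
    strawberry_tree = c(1.5, 1.5, 450, 0.05, 0.15, 0.25, 1.5, 15, 80, 160,
                        1, 100, 300, 1.6, 10, 7, 0.5, 30, 120, 0.5,
                        0.1, 0.5, 350),
    thistle         = c(1.5, 4, 250, 0.05, 0.3, 1.2, 4, 15, 160, 320,
                        1, 3.5, 300, 1.5, 20, 6, 0.5, 35, 90, 0.5,
                        0.16, 1.2, 700))
  s <- list(
    asphodel        = c(0.3, 0.3, 0.45, 0.25, 0.35, 0.35, 0.35, 0.25, 0.3,
                        0.3, 0.3, 0.4, 0.3, 0.25, 0.4, 0.45, 0.3, 0.4,
                        0.4, 0.3, 0.35, 0.25, 0.3),
    eucalyptus      = c(0.3, 0.3, 0.25, 0.25, 0.35, 0.35, 0.45, 0.25, 0.3,
                        0.3, 0.3, 0.35, 0.35, 0.25, 0.35, 0.4, 0.3, 0.4,
                        0.2, 0.3, 0.35, 0.3, 0.2),
    strawberry_tree = c(0.3, 0.3, 0.4, 0.25, 0.35, 0.35, 0.4, 0.25, 0.3,
                        0.3, 0.3, 0.7, 0.5, 0.25, 0.3, 0.4, 0.3, 0.4,
                        0.25, 0.3, 0.35, 0.3, 0.35),
    thistle         = c(0.3, 0.3, 0.35, 0.25, 0.35, 0.35, 0.3, 0.25, 0.35,
                        0.25, 0.3, 0.4, 0.4, 0.25, 0.35, 0.35, 0.3, 0.4,
                        0.3, 0.3, 0.35, 0.3, 0.25))
  lo <- list(
    asphodel        = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                        NA, NA, 40, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    eucalyptus      = c(NA, NA, 80, NA, NA, NA, NA, NA, NA, NA,
                        NA, NA, 140, NA, NA, NA, NA, NA, 20, NA, NA, NA, 330),
    strawberry_tree = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                        NA, NA, NA, NA, NA, NA, NA, NA, 22, NA, NA, NA, NA),
    thistle         = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 120,
                        NA, NA, 40, NA, NA, NA, NA, NA, 18, NA, NA, NA, 300))
  hi <- list(
    asphodel        = c(NA, 9, 1600, NA, 1.6, 2.5, 10.2, 24, 250, 660,
                        NA, 14, 770, 3.6, 170, 400, NA, 210, 174, 6.8,
                        0.4, NA, 1400),
    eucalyptus      = c(NA, 19, 690, NA, 1.2, 9.2, 109, 26, 630, 1600,
                        NA, 30, 5100, 3.9, 122, 95, 4.7, 110, 290, NA,
                        2.2, 12.8, 1400),
    strawberry_tree = c(NA, NA, 2600, NA, 0.8, NA, 9.7, 24, 250, 630,
                        NA, 8500, 4900, 3.8, 33, 90, NA, 200, 350, NA,
                        1.4, 1.8, 1200),
    thistle         = c(NA, NA, 1800, NA, 10.7, 5.2, 15.5, 24, 1030, 820,
                        NA, 22, 3300, 3.7, 220, 30, 2.8, 240, 420, NA,
                        1.3, 5.6, 2000))
  profiles <- do.call(rbind, lapply(botanical_classes(), function(cl)
    data.frame(class = cl, element = el,
               log10_loc = log10(g[[cl]]), log10_sd = s[[cl]],
               range_low = lo[[cl]], range_high = hi[[cl]],
               stringsAsFactors = FALSE)))
  blocks <- list(list(elements = c("Fe", "Mn", "V"), rho = rho),
                 list(elements = c("Cu", "Ni", "Zn"), rho = rho),
                 list(elements = c("Ba", "Sr", "Li"), rho = rho),
                 list(elements = c("Cd", "Co"), rho = rho))
  list(profiles = profiles, blocks = blocks)
}

block_correlation <- function(elements, blocks) {
  p <- length(elements)
  R <- diag(p)
  dimnames(R) <- list(elements, elements)
  for (b in blocks) {
    i <- match(b$elements, elements)
    if (anyNA(i)) next
    R[i, i] <- b$rho
    diag(R)[i] <- 1
  }
  R
}

#' Generate a synthetic honey sample table
#'
#' Per botanical class, log10 concentrations are drawn from a multivariate
#' normal with the class profile's locations/spreads and a block-correlated
#' correlation matrix, exponentiated, perturbed by multiplicative
#' measurement noise, and censored at the panel LoD/LoQ. Deterministic for
#' a fixed seed.
#'
#' @param n_per_class samples per class (scalar or named vector over the
#'   four classes; default 30).
#' @param seed integer seed (mandatory).
#' @param panel the [element_panel()] providing LoD/LoQ and (when present)
#'   intermediate-precision CV% used as measurement noise.
#' @param profiles output of [default_profiles()].
#' @param noise_cv per-element measurement noise CV%, recycled; defaults to
#'   the panel's `cv_intermediate` column, else 5%.
#' @return A [sample_table()].
#' @export
generate_samples <- function(n_per_class = 30, seed,
                             panel = default_panel(),
                             profiles = default_profiles(),
                             noise_cv = NULL) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  classes <- botanical_classes()
  if (length(n_per_class) == 1L)
    n_per_class <- stats::setNames(rep(n_per_class, 4), classes)
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1")
  if (is.null(noise_cv))
    noise_cv <- if ("cv_intermediate" %in% names(panel))
      panel$cv_intermediate else rep(5, nrow(panel))
  noise_cv <- rep_len(noise_cv, nrow(panel))
  elements <- panel$element
  R <- block_correlation(elements, profiles$blocks)
  U <- tryCatch(chol(R), error = function(e) {
    stop("block correlation matrix not positive-definite (blocks: ",
         paste(vapply(profiles$blocks,
                      function(b) paste(b$elements, collapse = "-"), ""),
               collapse = ", "), ")")
  })
  sd_noise <- sqrt(log(1 + (noise_cv / 100)^2))   # lognormal sigma
  with_seed(seed, {
    vals <- list(); cls <- character(0)
    for (cl in classes) {
      n <- n_per_class[[cl]]
      prof <- profiles$profiles[profiles$profiles$class == cl, ]
      prof <- prof[match(elements, prof$element), ]
      z <- matrix(stats::rnorm(n * length(elements)), n) %*% U
      x <- sweep(sweep(z, 2, prof$log10_sd, `*`), 2, prof$log10_loc, `+`)
      conc <- 10^x * exp(sweep(
        matrix(stats::rnorm(n * length(elements)), n), 2, sd_noise, `*`))
      vals[[cl]] <- conc
      cls <- c(cls, rep(cl, n))
    }
    conc <- do.call(rbind, vals)
    colnames(conc) <- elements
    lodm <- matrix(panel$lod, nrow(conc), ncol(conc), byrow = TRUE)
    loqm <- matrix(panel$loq, nrow(conc), ncol(conc), byrow = TRUE)
    censor <- matrix("quantified", nrow(conc), ncol(conc),
                     dimnames = dimnames(conc))
    censor[conc < loqm] <- "below_loq"
    censor[conc < lodm] <- "below_lod"
    conc[censor == "below_lod"] <- NA_real_
    sample_table(conc, censor, cls, panel)
  })
}

#' Generate validation-study inputs with known truth
#'
#' Fixtures for exercising the quantification and validation operations
#' against analytically known answers: method blanks with a chosen sd (so
#' LoD/LoQ are known), calibration lines with a chosen slope and intercept,
#' spike-recovery sets with a dialable bias, and factorial-design responses
#' from a chosen coefficient vector plus pure error.
#'
#' @param seed integer seed (mandatory).
#' @param n_blanks number of blank measurements (default 30).
#' @param blank_sd true blank sd, concentration units (default 1).
#' @param cal_slope,cal_intercept true calibration line (default 100, 0).
#' @param cal_levels concentrations of the calibration standards (default
#'   three replicates at each extreme of a 0.1--50 range).
#' @param cal_noise_sd sd of the signal noise (default 0.5).
#' @param spike_base base concentration of the spiked sample (default 50).
#' @param spike_added spike additions (default `c(25, 50, 75)`).
#' @param spike_bias_pct recovery bias in percent (e.g. -8 for 92%
#'   recovery; default 0).
#' @param spike_cv_pct CV% of the found concentrations (default 1).
#' @param doe_coef true factorial coefficients `c(b0, b1, b2, b12)`.
#' @param doe_sd pure-error sd added to every run (default 0; 0 keeps the
#'   responses exactly on the model).
#' @return List with `blanks`, `calibration` (data frame `conc`, `signal`),
#'   `spikes` (`base`, `spiked` data frame), and `doe` (a
#'   [factorial_study()] with response `y`).
#' @export
generate_validation_inputs <- function(seed, n_blanks = 30, blank_sd = 1,
                                       cal_slope = 100, cal_intercept = 0,
                                       cal_levels = rep(c(0.1, 50), each = 3),
                                       cal_noise_sd = 0.5,
                                       spike_base = 50,
                                       spike_added = c(25, 50, 75),
                                       spike_bias_pct = 0,
                                       spike_cv_pct = 1,
                                       doe_coef = c(96, -2.8, 2.5, 3.5),
                                       doe_sd = 0) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  with_seed(seed, {
    blanks <- stats::rnorm(n_blanks, 0, blank_sd)
    calibration <- data.frame(
      conc = cal_levels,
      signal = cal_intercept + cal_slope * cal_levels +
        stats::rnorm(length(cal_levels), 0, cal_noise_sd))
    true_rec <- 100 + spike_bias_pct
    found <- spike_base + spike_added * true_rec / 100 *
      exp(stats::rnorm(length(spike_added), 0,
                       sqrt(log(1 + (spike_cv_pct / 100)^2))))
    spikes <- list(base = spike_base,
                   spiked = data.frame(added = spike_added, found = found))
    x1 <- c(-1, 1, -1, 1, 0, 0); x2 <- c(-1, -1, 1, 1, 0, 0)
    y <- doe_coef[1] + doe_coef[2] * x1 + doe_coef[3] * x2 +
      doe_coef[4] * x1 * x2
    if (doe_sd > 0) y <- y + stats::rnorm(length(y), 0, doe_sd)
    doe <- factorial_study(list(factor_def("f1", 0, 1),
                                factor_def("f2", 0, 1)),
                           x1, x2, data.frame(y = y))
    list(blanks = blanks, calibration = calibration, spikes = spikes,
         doe = doe)
  })
}
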