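#' Design factors and coded levels
#'
#' A factor of a two-level design is described by its physical low and high
#' levels; `code_levels()` maps physical values affinely so that
#' `(low, high) -> (-1, +1)` and the midpoint maps to 0, and
#' `decode_levels()` inverts the map.
#'
#' @param name factor name.
#' @param low,high physical levels, `low < high`.
#' @return `factor_def()` returns a `factor_def` list.
#' @export
factor_def <- function(name, low, high) {
  if (low >= high) stop("factor '", name, "' needs low < high")
  structure(list(name = name, low = low, high = high), class = "factor_def")
}

#' @rdname factor_def
#' @param factor a `factor_def`.
#' @param physical physical value(s).
#' @export
code_levels <- function(factor, physical) {
  (physical - (factor$low + factor$high) / 2) / ((factor$high - factor$low) / 2)
}

#' @rdname factor_def
#' @param coded coded value(s).
#' @export
decode_levels <- function(factor, coded) {
  coded * (factor$high - factor$low) / 2 + (factor$low + factor$high) / 2
}

#' Two-level full factorial study with center points
#'
#' Container for a 2^2 design: two factors, the four factorial corners run
#' once per response, and at least two replicated center points providing
#' the pure-error estimate.
#'
#' @param factors list of two [factor_def()]s.
#' @param x1,x2 coded levels of the runs, each in \{-1, 0, +1\}.
#' @param responses data frame (or named list) of response values per run,
#'   one column per response.
#' @return A `factorial_study`.
#' @export
factorial_study <- function(factors, x1, x2, responses) {
  stopifnot(length(factors) == 2)
  responses <- as.data.frame(responses)
  if (!all(c(x1, x2) %in% c(-1, 0, 1)))
    stop("coded levels must be in {-1, 0, +1}")
  corners <- paste(x1, x2)[x1 != 0 & x2 != 0]
  want <- c("-1 -1", "1 -1", "-1 1", "1 1")
  if (!setequal(corners, want) || anyDuplicated(corners))
    stop("design must contain all 4 factorial corners exactly once")
  if (sum(x1 == 0 & x2 == 0) < 2)
    stop("design needs >= 2 center replicates for pure error")
  structure(list(factors = factors, x1 = x1, x2 = x2,
                 responses = responses), class = "factorial_study")
}

#' The digestion-optimization design
#'
#' The built-in 2^2 + 2 center-point study that optimized the acid
#' microwave digestion of honey: X1 is the sample amount (0.5--1.0 g), X2
#' the HNO3/H2O2 volume ratio (0.5/3 to 2/1.5 cm^3, i.e. ~0.167--1.333),
#' with responses Y1 = residual acidity (mol/dm^3, by titration) and Y2 =
#' EOMD% (efficiency of organic matter decomposition).
#'
#' @return A `factorial_study` with 6 runs.
#' @export
digestion_doe <- function() {
  factorial_study(
    factors = list(factor_def("sample_amount_g", 0.5, 1.0),
                   factor_def("ratio_HNO3_H2O2", 0.5 / 3, 2 / 1.5)),
    x1 = c(-1, 1, -1, 1, 0, 0),
    x2 = c(-1, -1, 1, 1, 0, 0),
    responses = data.frame(
      residual_acidity = c(0.39, 0.06, 1.41, 0.16, 0.48, 0.39),
      eomd = c(99.7, 87.2, 97.7, 99.1, 95.8, 96.4))
  )
}

#' Pure-error standard deviation from center replicates
#'
#' @param center_responses numeric vector of >= 2 center-point responses.
#' @return Sample (n-1) standard deviation.
#' @export
pure_error_sd <- function(center_responses) {
  if (length(center_responses) < 2) stop("need >= 2 center replicates")
  stats::sd(center_responses)
}

#' Fit the multilinear factorial model
#'
#' Least-squares fit of `Y = b0 + b1*X1 + b2*X2 + b12*X1*X2` over all runs,
#' center points included. On this orthogonal design the least-squares
#' coefficients coincide with the classical contrast averages over the four
#' corners (and b0 with the grand mean). Each coefficient is tested against
#' the pure error from the center replicates: `t = |b| / (s_pe / 2)` (the
#' contrast variance of a 4-corner average), df = n_center - 1, and banded
#' `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001).
#'
#' @param study a [factorial_study()].
#' @param response name of the response column to fit.
#' @return An `mlr_fit`: list with `coef` (b0, b1, b2, b12),
#'   `pure_error_sd`, `n_center`, `t`, `p`, `significance` (star bands),
#'   `coef_corners` (b0 recomputed from the corners only), `response`,
#'   `factors`, `lm`.
#' @export
fit_factorial <- function(study, response = names(study$responses)[1]) {
  y <- study$responses[[response]]
  if (is.null(y)) stop("unknown response: ", response)
  dat <- data.frame(y = y, x1 = study$x1, x2 = study$x2)
  fit <- stats::lm(y ~ x1 * x2, data = dat)
  if (fit$rank < 4) stop("rank-deficient design: missing factorial corner")
  b <- stats::coef(fit)
  names(b) <- c("b0", "b1", "b2", "b12")
  center <- study$x1 == 0 & study$x2 == 0
  s_pe <- pure_error_sd(y[center])
  n_c <- sum(center)
  se <- s_pe / 2                       # contrast average of 4 corner runs
  t <- if (se == 0) ifelse(b == 0, 0, Inf) else abs(b) / se
  p <- 2 * stats::pt(-t, df = n_c - 1)
  corner_b0 <- mean(y[!center])
  structure(list(coef = b, pure_error_sd = s_pe, n_center = n_c,
                 se_coef = se, t = t, p = p,
                 significance = stats::setNames(significance_band(p), names(b)),
                 coef_corners = c(b0 = corner_b0, b[-1]),
                 response = response, factors = study$factors, lm = fit),
            class = "mlr_fit")
}

significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = FALSE) |> as.character()
}

#' @export
print.mlr_fit <- function(x, digits = 3, ...) {
  cat("factorial fit of", x$response, "\n")
  out <- data.frame(coefficient = names(x$coef),
                    value = round(x$coef, digits),
                    p = signif(x$p, 2), significance = x$significance)
  print(out, row.names = FALSE)
  cat(sprintf("pure error sd = %.3g (%d center replicates)\n",
              x$pure_error_sd, x$n_center))
  invisible(x)
}

#' Predict a factorial response at coded levels
#'
#' Evaluates `b0 + b1*x1 + b2*x2 + b12*x1*x2`. Coded levels outside
#' `[-1, 1]` are extrapolation beyond the design region and raise a
#' warning. The standard error attached to the prediction derives from the
#' pure-error sd of the fit.
#'
#' @param fit an `mlr_fit`.
#' @param x1,x2 coded factor levels.
#' @return List with `value`, `se` (pure-error based standard error of the
#'   fitted value at the center of the design).
#' @export
predict_response <- function(fit, x1, x2) {
  if (any(abs(c(x1, x2)) > 1 + 1e-8))
    warning("prediction outside the coded design region [-1, 1]")
  b <- fit$coef
  value <- b["b0"] + b["b1"] * x1 + b["b2"] * x2 + b["b12"] * x1 * x2
  n <- length(stats::resid(fit$lm))
  list(value = unname(value), se = fit$pure_error_sd / sqrt(n))
}

#' Model adequacy from the center points
#'
#' Tests the model's prediction at the coded center (0,0) against the mean
#' of the replicated center runs with a one-sample t-test on the pure
#' error: `t = (mean(center) - predicted) / (s_pe / sqrt(n_center))`,
#' df = n_center - 1. A non-significant difference means no detectable lack
#' of fit and the first-order model is accepted.
#'
#' @param fit an `mlr_fit`.
#' @param center_responses center-point responses (>= 2).
#' @param alpha significance level (default 0.05).
#' @return List with `verdict` (`"accepted"` / `"lack_of_fit"`), `t`, `df`,
#'   `p`, `predicted`, `center_mean`.
#' @export
model_adequacy <- function(fit, center_responses, alpha = 0.05) {
  if (length(center_responses) < 2) stop("need >= 2 center replicates")
  pred <- predict_response(fit, 0, 0)$value
  m <- mean(center_responses)
  n_c <- length(center_responses)
  s <- fit$pure_error_sd
  if (s == 0) {
    t <- if (m == pred) 0 else Inf * sign(m - pred)
  } else {
    t <- (m - pred) / (s / sqrt(n_c))
  }
  p <- 2 * stats::pt(-abs(t), df = n_c - 1)
  list(verdict = if (p > alpha) "accepted" else "lack_of_fit",
       t = t, df = n_c - 1L, p = p, predicted = pred, center_mean = m)
}

#' Contour grid of predicted response over the physical factor space
#'
#' Dense evaluation of the fitted model over a physical-level grid,
#' suitable for contour plotting of the design region.
#'
#' @param fit an `mlr_fit`.
#' @param factors list of two [factor_def()]s (defaults to the fit's).
#' @param resolution grid points per axis (>= 2).
#' @return Data frame with physical levels `f1`, `f2`, coded `x1`, `x2`,
#'   and `predicted`.
#' @export
contour_grid <- function(fit, factors = fit$factors, resolution = 25) {
  if (resolution < 2) stop("resolution must be >= 2")
  g1 <- seq(factors[[1]]$low, factors[[1]]$high, length.out = resolution)
  g2 <- seq(factors[[2]]$low, factors[[2]]$high, length.out = resolution)
  grid <- expand.grid(f1 = g1, f2 = g2)
  grid$x1 <- code_levels(factors[[1]], grid$f1)
  grid$x2 <- code_levels(factors[[2]], grid$f2)
  grid$predicted <- predict_response(fit, grid$x1, grid$x2)$value
  names(grid)[1:2] <- c(factors[[1]]$name, factors[[2]]$name)
  grid
}

#' Read a DoE study from CSV
#'
#' Expected columns: `x1`, `x2` (coded levels) and one column per response.
#' Physical-level columns, if present, are ignored for fitting (coded
#' levels are authoritative).
#'
#' @param path file path.
#' @param factors list of two [factor_def()]s.
#' @return A `factorial_study`.
#' @export
read_doe <- function(path, factors) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x1", "x2") %in% names(d)))
    stop("DoE file needs coded-level columns 'x1' and 'x2'")
  resp <- d[, setdiff(names(d), c("run", "x1", "x2",
                                  vapply(factors, `[[`, "", "name"))),
            drop = FALSE]
  factorial_study(factors, d$x1, d$x2, resp)
}
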