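test_that("coding maps physical levels affinely onto [-1, 1]", {
  mass <- factor_def("sample_amount_g", 0.5, 1.0)
  expect_equal(code_levels(mass, 0.75), 0)
  expect_equal(code_levels(mass, 0.5), -1)
  expect_equal(code_levels(mass, 1.0), 1)
  set.seed(2)
  x <- stats::runif(25, 0.2, 1.5)
  expect_equal(decode_levels(mass, code_levels(mass, x)), x)
  expect_error(factor_def("bad", 1, 1), "low < high")
})

test_that("the digestion study fit reproduces the published coefficients", {
  s <- digestion_doe()
  eomd_fit <- fit_factorial(s, "eomd")
  expect_equal(unname(eomd_fit$coef[c("b1", "b2", "b12")]),
               c(-2.8, 2.5, 3.5), tolerance = 0.05 / 2.5)
  acid_fit <- fit_factorial(s, "residual_acidity")
  expect_equal(unname(acid_fit$coef[c("b1", "b2", "b12")]),
               c(-0.41, 0.27, -0.25), tolerance = 0.03 / 0.25)
  # b0 ambiguity: grand mean vs corner mean are both reported
  expect_equal(unname(acid_fit$coef["b0"]), 0.48, tolerance = 0.005)
  expect_equal(unname(acid_fit$coef_corners["b0"]), 0.505)
  expect_equal(unname(eomd_fit$coef_corners["b0"]), 95.925)
})

test_that("least-squares coefficients equal contrast averages exactly", {
  set.seed(6)
  for (i in 1:10) {
    y <- stats::rnorm(6, 50, 10)
    s <- factorial_study(list(factor_def("a", 0, 1), factor_def("b", 0, 1)),
                         x1 = c(-1, 1, -1, 1, 0, 0),
                         x2 = c(-1, -1, 1, 1, 0, 0),
                         responses = data.frame(y = y))
    fit <- fit_factorial(s, "y")
    expect_equal(fit$coef, contrast_oracle(s$x1, s$x2, y), tolerance = 1e-10)
  }
})

test_that("a constant response yields b0 = c and zero effects", {
  s <- factorial_study(list(factor_def("a", 0, 1), factor_def("b", 0, 1)),
                       x1 = c(-1, 1, -1, 1, 0, 0),
                       x2 = c(-1, -1, 1, 1, 0, 0),
                       responses = data.frame(y = rep(7.5, 6)))
  fit <- fit_factorial(s, "y")
  expect_equal(unname(fit$coef), c(7.5, 0, 0, 0), tolerance = 1e-12)
})

test_that("design validation rejects malformed studies", {
  f <- list(factor_def("a", 0, 1), factor_def("b", 0, 1))
  expect_error(factorial_study(f, c(-1, 1, -1, 0, 0), c(-1, -1, 1, 0, 0),
                               data.frame(y = 1:5)), "corners")
  expect_error(factorial_study(f, c(-1, 1, -1, 1, 0), c(-1, -1, 1, 1, 0),
                               data.frame(y = 1:5)), "center")
  expect_error(factorial_study(f, c(-1, 1, -1, 2, 0, 0),
                               c(-1, -1, 1, 1, 0, 0),
                               data.frame(y = 1:6)), "coded")
})

test_that("pure error matches the published center-point spreads", {
  expect_equal(round(pure_error_sd(c(0.48, 0.39)), 2), 0.06)
  expect_equal(round(pure_error_sd(c(95.8, 96.4)), 2), 0.42)
  expect_equal(pure_error_sd(c(3, 3, 3)), 0)
  expect_error(pure_error_sd(5), ">= 2")
})

test_that("center predictions and adequacy match the published verdicts", {
  s <- digestion_doe()
  acid <- fit_factorial(s, "residual_acidity")
  eomd_ <- fit_factorial(s, "eomd")
  expect_equal(round(predict_response(acid, 0, 0)$value, 1), 0.5)
  expect_equal(round(predict_response(eomd_, 0, 0)$value), 96)
  centers <- s$x1 == 0 & s$x2 == 0
  expect_equal(model_adequacy(acid, s$responses$residual_acidity[centers])$verdict,
               "accepted")
  expect_equal(model_adequacy(eomd_, s$responses$eomd[centers])$verdict,
               "accepted")
  # shifting the center responses by many pure-error sds forces lack of fit
  shifted <- s$responses$eomd[centers] + 10 * eomd_$pure_error_sd
  expect_equal(model_adequacy(eomd_, shifted)$verdict, "lack_of_fit")
  # exact agreement gives t = 0
  b0 <- predict_response(eomd_, 0, 0)$value
  exact <- model_adequacy(eomd_, c(b0, b0))
  expect_equal(exact$t, 0)
  expect_equal(exact$verdict, "accepted")
})

test_that("trivial model evaluation follows the coded polynomial", {
  fit <- structure(list(coef = c(b0 = 1, b1 = 1, b2 = 1, b12 = 1),
                        pure_error_sd = 0,
                        lm = stats::lm(y ~ 1, data.frame(y = 1:4))),
                   class = "mlr_fit")
  expect_equal(predict_response(fit, 1, 1)$value, 4)
  expect_equal(predict_response(fit, -1, 1)$value, 0)
  expect_warning(predict_response(fit, 2, 0), "outside")
})

test_that("contour grids agree with corner predictions and monotonicity", {
  s <- digestion_doe()
  fit <- fit_factorial(s, "eomd")
  g <- contour_grid(fit, resolution = 5)
  expect_equal(nrow(g), 25)
  corners <- g[abs(abs(g$x1) - 1) < 1e-9 & abs(abs(g$x2) - 1) < 1e-9, ]
  for (i in seq_len(nrow(corners)))
    expect_equal(corners$predicted[i],
                 predict_response(fit, corners$x1[i], corners$x2[i])$value)
  # constant fit -> constant grid
  sc <- factorial_study(s$factors, s$x1, s$x2, data.frame(y = rep(2, 6)))
  gc <- contour_grid(fit_factorial(sc, "y"), resolution = 4)
  expect_equal(unique(round(gc$predicted, 12)), 2)
  # pure main effect: monotone along x1 within every x2 row
  sm <- factorial_study(s$factors, s$x1, s$x2,
                        data.frame(y = c(10, 20, 10, 20, 15, 15)))
  gm <- contour_grid(fit_factorial(sm, "y"), resolution = 6)
  for (x2v in unique(gm$x2))
    expect_true(all(diff(gm$predicted[gm$x2 == x2v][order(gm$x1[gm$x2 == x2v])]) > 0))
  expect_error(contour_grid(fit, resolution = 1), "resolution")
})

test_that("significance bands follow the pure-error t-test thresholds", {
  # synthetic design built so the p-values straddle the band boundaries
  x1 <- c(-1, 1, -1, 1, 0, 0); x2 <- c(-1, -1, 1, 1, 0, 0)
  s_pe <- 0.1                           # centers 0.05 apart around 10
  crit <- stats::qt(c(0.975, 0.995, 0.9995), df = 1) * s_pe / 2
  b <- c(b1 = crit[1] * 1.2, b2 = crit[2] * 1.2, b12 = crit[3] * 1.2)
  y <- 10 + b["b1"] * x1 + b["b2"] * x2 + b["b12"] * x1 * x2
  y[5:6] <- 10 + c(-1, 1) * s_pe / sqrt(2)
  st <- factorial_study(list(factor_def("a", 0, 1), factor_def("b", 0, 1)),
                        x1, x2, data.frame(y = y))
  fit <- fit_factorial(st, "y")
  expect_equal(unname(fit$significance[c("b1", "b2", "b12")]),
               c("*", "**", "***"))
  # p monotone decreasing in |coefficient| under a common pure error
  expect_true(all(diff(fit$p[c("b1", "b2", "b12")]) < 0))
})

test_that("DoE CSV round trip preserves the study", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- digestion_doe()
  utils::write.csv(data.frame(run = 1:6, x1 = s$x1, x2 = s$x2, s$responses),
                   f, row.names = FALSE)
  back <- read_doe(f, s$factors)
  expect_equal(back$responses, s$responses)
  expect_equal(fit_factorial(back, "eomd")$coef,
               fit_factorial(s, "eomd")$coef)
})
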