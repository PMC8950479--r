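make_censored_table <- function() {
  p <- toy_panel()   # Mn (8/27), Hg (6/20), Cd (0.3/1.0)
  vals <- rbind(c(190, NA, 2),
                c(40, NA, NA),
                c(15, NA, 0.5))
  cen <- rbind(c("quantified", "below_lod", "quantified"),
               c("quantified", "below_lod", "below_lod"),
               c("below_loq", "below_loq", "below_loq"))
  colnames(vals) <- colnames(cen) <- p$element
  sample_table(vals, cen, c("asphodel", "thistle", "thistle"), p)
}

test_that("censored substitution fills only censored cells", {
  tab <- make_censored_table()
  x <- substitute_censored(tab)
  expect_false(anyNA(x))
  expect_equal(unname(x[1, "Mn"]), 190)              # quantified untouched
  expect_equal(unname(x[1, "Hg"]), 3)                # lod/2 = 6/2
  expect_equal(unname(x[2, "Cd"]), 0.15)             # lod/2
  expect_equal(unname(x[3, "Mn"]), 15)               # recorded below_loq kept
  expect_equal(unname(x[3, "Hg"]), (6 + 20) / 2)     # unrecorded below_loq
  # strategy swap changes exactly the below-LoD cells
  x2 <- substitute_censored(tab, "lod_sqrt2")
  diff <- which(x != x2, arr.ind = TRUE)
  expect_true(all(tab$censor[diff] == "below_lod"))
  expect_equal(unname(x2[1, "Hg"]), 6 / sqrt(2))
  # custom strategy
  x3 <- substitute_censored(tab, "custom", custom = function(lod, loq) lod)
  expect_equal(unname(x3[1, "Hg"]), 6)
  expect_error(substitute_censored(tab, "custom"), "custom")
})

test_that("log10 transform is monotone and reduces log-normal skewness", {
  m <- matrix(c(100, 10, 1000, 1), 2)
  expect_equal(log_transform(m), log10(m))
  set.seed(12)
  x <- matrix(10^stats::rnorm(500, 2, 0.5), ncol = 1)
  expect_gt(skewness_oracle(x[, 1]), skewness_oracle(log_transform(x)[, 1]))
  expect_equal(order(x[, 1]), order(log_transform(x)[, 1]))
  bad <- matrix(c(1, -2), 1, dimnames = list(NULL, c("a", "b")))
  expect_error(log_transform(bad), "column b")
})

test_that("screening drops rarely quantified elements", {
  tab <- make_censored_table()
  frac <- colMeans(tab$censor == "quantified")  # Mn 2/3, Hg 0, Cd 1/3
  expect_equal(screen_variables(tab, 0.1), c("Mn", "Cd"))
  expect_equal(screen_variables(tab, 0.5), "Mn")
  expect_error(screen_variables(tab, 0.99), "all elements dropped")
})

test_that("stratified splits are reproducible, disjoint and exhaustive", {
  tab <- generate_samples(c(asphodel = 33, eucalyptus = 30,
                            strawberry_tree = 31, thistle = 39), seed = 3)
  sp <- split_train_validation(tab, 85, seed = 10)
  expect_equal(length(sp$train_idx), 85)
  expect_equal(length(sp$validation_idx), 48)
  expect_length(intersect(sp$train_idx, sp$validation_idx), 0)
  expect_setequal(c(sp$train_idx, sp$validation_idx), 1:133)
  # proportional allocation by class
  expect_equal(as.integer(table(sp$train$class)), c(21L, 19L, 20L, 25L))
  sp2 <- split_train_validation(tab, 85, seed = 10)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_validation(tab, 85, seed = 11)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  expect_error(split_train_validation(tab, 200, seed = 1), "smaller")
})

test_that("PCA matches eigen structure, a reconstruction oracle and prcomp", {
  set.seed(18)
  x <- matrix(stats::rnorm(80), 10, 8)
  x[, 2] <- x[, 1] + stats::rnorm(10, 0, 0.3)
  m <- pca_fit(x, "autoscale")
  # orthonormal loadings
  expect_equal(crossprod(m$loadings), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  # explained fractions non-increasing and summing to 1
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_equal(sum(m$explained), 1)
  # back-projection reconstructs the data
  rec <- sweep(m$scores %*% t(m$loadings), 2, m$scale, `*`)
  rec <- sweep(rec, 2, m$center, `+`)
  expect_equal(rec, x, tolerance = 1e-10, ignore_attr = TRUE)
  # agreement with prcomp up to sign
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(abs(unname(m$loadings)), abs(unname(pr$rotation)),
               tolerance = 1e-8)
  expect_equal(m$sdev^2 / sum(m$sdev^2),
               pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-8)
  # sign convention: dominant loading positive
  expect_true(all(apply(m$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  # projection of the training data equals the stored scores
  expect_equal(pca_project(m, x), m$scores)
})

test_that("perfectly correlated variables load on a single component", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 5)
  m <- pca_fit(x, "autoscale")
  expect_equal(m$explained[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(cbind(a = 1:5, b = rep(1, 5)), "autoscale"),
               "zero-variance")
})

test_that("LDA scores agree with a brute-force Mahalanobis oracle", {
  set.seed(25)
  x <- matrix(stats::rnorm(50), 10, 5)
  y <- rep(c("p", "q"), each = 5)
  m <- lda_fit(x, y, ridge = 0)
  sc <- predict(m, x)$scores
  oracle <- lda_oracle_scores(x, m$means, m$sigma, m$priors)
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-10)
})

test_that("LDA assignments match MASS::lda on separable toy data", {
  skip_if_not_installed("MASS")
  set.seed(26)
  n <- 20
  x <- rbind(matrix(stats::rnorm(2 * n, 0), ncol = 2),
             matrix(stats::rnorm(2 * n, 3), ncol = 2),
             matrix(stats::rnorm(2 * n, c(0, 6)), ncol = 2))
  y <- rep(c("a", "b", "c"), each = n)
  ours <- predict(lda_fit(x, y, ridge = 0), x)$class
  ref <- predict(MASS::lda(x, grouping = y,
                           prior = rep(1 / 3, 3)))$class
  expect_equal(as.character(ours), as.character(ref))
})

test_that("well-separated classes classify perfectly, identical ones at chance", {
  set.seed(30)
  x <- rbind(matrix(stats::rnorm(40, 0, 0.2), ncol = 2),
             matrix(stats::rnorm(40, 5, 0.2), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  m <- lda_fit(x, y)
  expect_equal(mean(predict(m, x)$class == y), 1)
  # four identical class distributions: accuracy near 25%
  set.seed(31)
  acc <- replicate(30, {
    xn <- matrix(stats::rnorm(400), 100, 4)
    yn <- rep(letters[1:4], each = 25)
    mean(predict(lda_fit(xn, yn), xn)$class == yn) * 100
  })
  expect_gt(mean(acc), 20)
  expect_lt(mean(acc), 45)
  expect_error(lda_fit(x, rep("a", 40)), ">= 2 classes")
  expect_error(lda_fit(x[1:3, ], c("a", "a", "b")), ">= 2 samples")
})

test_that("LDA decisions are invariant to common affine feature rescaling", {
  set.seed(40)
  x <- matrix(stats::rnorm(60), 20, 3)
  x[11:20, ] <- x[11:20, ] + 1.5
  y <- rep(c("a", "b"), each = 10)
  base <- predict(lda_fit(x, y), x)$class
  xr <- sweep(sweep(x, 2, c(10, 0.01, 3), `*`), 2, c(5, -2, 0), `+`)
  expect_equal(as.character(predict(lda_fit(xr, y), xr)$class),
               as.character(base))
})

test_that("singular covariance errors advise the ridge and ridge rescues it", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))   # collinear
  y <- c("p", "p", "q", "q")
  expect_error(lda_fit(x, y, ridge = 0), "ridge")
  expect_s3_class(lda_fit(x, y, ridge = 1e-8), "lda_model")
})

test_that("cross-validation refits per fold and stays below training accuracy", {
  set.seed(50)
  x <- rbind(matrix(stats::rnorm(60, 0), ncol = 3),
             matrix(stats::rnorm(60, 4), ncol = 3))
  y <- rep(c("a", "b"), each = 20)
  cv <- cross_validate(x, y)
  expect_equal(sum(cv$confusion), 40)            # one prediction per sample
  expect_equal(unname(rowSums(cv$confusion)), c(20, 20))
  expect_equal(cv$total_accuracy, 100)
  # k-fold is deterministic under a fixed seed
  k1 <- cross_validate(x, y, scheme = 5, seed = 2)
  k2 <- cross_validate(x, y, scheme = 5, seed = 2)
  expect_identical(k1$assigned, k2$assigned)
  # on average CV does not beat training accuracy
  set.seed(51)
  gap <- replicate(20, {
    xn <- matrix(stats::rnorm(30 * 3), 30, 3)
    xn[16:30, 1] <- xn[16:30, 1] + 1
    yn <- rep(c("a", "b"), each = 15)
    train <- mean(predict(lda_fit(xn, yn), xn)$class == yn) * 100
    train - cross_validate(xn, yn)$total_accuracy
  })
  expect_gt(mean(gap), 0)
})

test_that("permutation test is seeded, valid and detects real structure", {
  set.seed(60)
  x <- rbind(matrix(stats::rnorm(40, 0), ncol = 2),
             matrix(stats::rnorm(40, 4), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  pt1 <- permutation_test(x, y, n_permutations = 30, seed = 9)
  pt2 <- permutation_test(x, y, n_permutations = 30, seed = 9)
  expect_identical(pt1$null, pt2$null)
  expect_equal(pt1$observed, 100)
  expect_true(all(pt1$null < pt1$observed))
  expect_equal(pt1$p, 1 / 31)
  # labels without structure: p stays away from 0 over repeats
  set.seed(61)
  ps <- replicate(10, {
    xn <- matrix(stats::rnorm(40), 20, 2)
    yn <- sample(rep(c("a", "b"), each = 10))
    permutation_test(xn, yn, n_permutations = 19,
                     seed = sample.int(1e6, 1))$p
  })
  expect_gt(stats::median(ps), 0.2)
  expect_error(permutation_test(x, y, n_permutations = 0), ">= 1")
})

test_that("confusion statistics match a naive loop oracle", {
  m <- matrix(c(11, 0, 0, 1,
                1, 9, 0, 1,
                1, 0, 9, 2,
                0, 0, 0, 13), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  st <- confusion_stats(m)
  for (i in 1:4) expect_equal(unname(st$per_class[i]),
                              100 * m[i, i] / sum(m[i, ]))
  expect_equal(st$total, 100 * sum(diag(m)) / sum(m))
  expect_equal(unname(confusion_stats(diag(5))$per_class), rep(100, 5))
  expect_warning(st0 <- confusion_stats(rbind(c(2, 0), c(0, 0))), "zero")
  expect_true(is.na(st0$per_class[2]))
  expect_error(confusion_stats(matrix(1:6, 2)), "square")
  expect_error(confusion_stats(matrix(c(1, -1, 0, 2), 2)), "non-negative")
})

test_that("the full pipeline recovers class structure on synthetic data", {
  tab <- generate_samples(30, seed = 17)
  res <- classify_pipeline(tab, seed = 17, n_permutations = 25)
  expect_setequal(res$retained,
                  c("As", "Ba", "Bi", "Cd", "Co", "Cr", "Cu", "Fe", "Li",
                    "Mn", "Mo", "Ni", "Pb", "Sn", "Sr", "Tl", "V", "Zn"))
  expect_gte(res$cv$total_accuracy, 70)
  val_classes <- tab$class[res$split$validation_idx]
  expect_equal(unname(rowSums(res$prediction$confusion)),
               unname(as.integer(table(val_classes))))
  expect_lte(res$permutation$p, 1 / 26 + 1e-12)
  # rerun with the same seed is identical
  res2 <- classify_pipeline(tab, seed = 17, n_permutations = 25)
  expect_equal(res$cv$total_accuracy, res2$cv$total_accuracy)
  expect_identical(res$permutation$null, res2$permutation$null)
})
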