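# Classification pipeline: censored-value substitution, log10 transform,
# variable screening, train/validation split, PCA, LDA, cross-validation,
# permutation testing and confusion statistics.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    })
  }
  force(code)
}

#' Replace censored cells by numeric surrogates
#'
#' Multivariate analysis needs a complete positive matrix, so censored
#' cells are substituted: below-LoD cells by a fixed fraction of the
#' element's LoD (`half_lod`: LoD/2, the conventional choice;
#' `lod_sqrt2`: LoD/sqrt(2)), below-LoQ cells by their recorded value when
#' one exists, otherwise by the interval midpoint `(LoD + LoQ)/2`.
#' Quantified cells are untouched.
#'
#' @param table a [sample_table()].
#' @param strategy `"half_lod"`, `"lod_sqrt2"` or `"custom"`.
#' @param custom for `strategy = "custom"`: `function(lod, loq)` returning
#'   the surrogate for below-LoD cells.
#' @return Numeric matrix (samples x elements) with no missing entries,
#'   rownames the sample ids.
#' @export
substitute_censored <- function(table,
                                strategy = c("half_lod", "lod_sqrt2", "custom"),
                                custom = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(table, "sample_table"))
  sub_lod <- switch(strategy,
                    half_lod = function(lod, loq) lod / 2,
                    lod_sqrt2 = function(lod, loq) lod / sqrt(2),
                    custom = custom)
  if (is.null(sub_lod)) stop("strategy 'custom' needs a `custom` function")
  x <- table$values
  for (el in colnames(x)) {
    i <- match(el, table$panel$element)
    lod <- table$panel$lod[i]; loq <- table$panel$loq[i]
    cen <- table$censor[, el]
    x[cen == "below_lod", el] <- sub_lod(lod, loq)
    miss_loq <- cen == "below_loq" & is.na(x[, el])
    x[miss_loq, el] <- (lod + loq) / 2
  }
  rownames(x) <- table$sample_id
  x
}

#' Element-wise log10 transform
#'
#' Reduces the right skew of trace-element concentration distributions
#' before multivariate analysis. All entries must be strictly positive
#' (guaranteed after [substitute_censored()]).
#'
#' @param x numeric matrix.
#' @return `log10(x)`.
#' @export
log_transform <- function(x) {
  bad <- which(!(x > 0), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop("non-positive entry at row ", bad[1, 1], ", column ",
         colnames(x)[bad[1, 2]])
  log10(x)
}

#' Screen out rarely quantified elements
#'
#' Elements almost never quantified carry no usable variance and are
#' dropped before modelling: an element is retained iff the fraction of
#' samples in which it is quantified (censor flag `quantified`) reaches
#' `min_quantified_fraction`.
#'
#' @param table a [sample_table()].
#' @param min_quantified_fraction retention threshold (default 0.1).
#' @return Character vector of retained element symbols, in panel order.
#' @export
screen_variables <- function(table, min_quantified_fraction = 0.1) {
  stopifnot(inherits(table, "sample_table"))
  frac <- colMeans(table$censor == "quantified")
  keep <- names(frac)[frac >= min_quantified_fraction]
  if (!length(keep)) stop("all elements dropped by screening")
  keep
}

#' Stratified train/validation split
#'
#' Randomly divides the samples into a training and a validation set,
#' reproducibly for a fixed seed. Under stratification (default) training
#' slots are allocated to classes proportionally (largest-remainder
#' rounding), so class balance carries over to both sets.
#'
#' @param table a [sample_table()].
#' @param train_n number of training samples.
#' @param seed integer seed.
#' @param stratify stratify by botanical class (default TRUE).
#' @return List with `train` and `validation` (both `sample_table`s) and
#'   the index vectors `train_idx`, `validation_idx`.
#' @export
split_train_validation <- function(table, train_n, seed, stratify = TRUE) {
  n <- nrow(table$values)
  if (train_n >= n) stop("train_n must be smaller than the number of samples")
  idx <- with_seed(seed, {
    if (stratify) {
      counts <- table(table$class)
      counts <- counts[counts > 0]
      if (any(counts < 2))
        stop("stratified split needs >= 2 samples per class")
      quota <- train_n * as.numeric(counts) / n
      alloc <- floor(quota)
      rem <- train_n - sum(alloc)
      if (rem > 0) {
        extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
      }
      unlist(lapply(seq_along(counts), function(k) {
        pool <- which(table$class == names(counts)[k])
        sample(pool, alloc[k])
      }), use.names = FALSE)
    } else {
      sample(n, train_n)
    }
  })
  idx <- sort(idx)
  list(train = table[idx], validation = table[-idx],
       train_idx = idx, validation_idx = setdiff(seq_len(n), idx))
}

#' Principal component analysis
#'
#' Eigen-decomposition of the covariance (under `center_only`) or
#' correlation (under `autoscale`, the default) matrix of the input.
#' Loadings are orthonormal eigenvectors with a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix, samples x variables (>= 2 of each).
#' @param scaling `"autoscale"` (unit-variance scaling, correlation PCA) or
#'   `"center_only"`.
#' @return A `pca_model`: `loadings` (variables x components), `scores`
#'   (samples x components), `explained` (variance fractions), `sdev`,
#'   `center`, `scale`.
#' @export
pca_fit <- function(x, scaling = c("autoscale", "center_only")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 variables")
  center <- colMeans(x)
  scl <- if (scaling == "autoscale") apply(x, 2, stats::sd) else
    rep(1, ncol(x))
  if (any(scl == 0))
    stop("zero-variance column under autoscale: ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, center), 2, scl, `/`)
  ev <- eigen(stats::cov(xs), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  load <- ev$vectors
  # sign convention: largest-|loading| entry positive in every component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- xs %*% load
  structure(list(loadings = load, scores = scores,
                 explained = lambda / sum(lambda),
                 sdev = sqrt(lambda), center = center, scale = scl,
                 scaling = scaling),
            class = "pca_model")
}

#' Project new samples onto a fitted PCA
#'
#' @param model a `pca_model`.
#' @param newdata matrix with the same variables.
#' @return Score matrix.
#' @export
pca_project <- function(model, newdata) {
  xs <- sweep(sweep(as.matrix(newdata), 2, model$center), 2, model$scale, `/`)
  xs %*% model$loadings
}

#' Linear discriminant analysis
#'
#' Classical LDA under the assumptions of class-wise multivariate normality
#' with a common within-class covariance: class means `mu_k`, pooled
#' covariance `Sigma = sum_k (n_k - 1) S_k / (N - K)`, and linear
#' discriminant scores
#' `delta_k(x) = x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k`;
#' a sample is assigned to the class maximizing `delta_k` (ties broken
#' toward the lowest class index). A small ridge (`epsilon x mean diagonal`)
#' keeps the pooled covariance invertible.
#'
#' @param x numeric feature matrix, samples x variables.
#' @param y class labels (factor or character); >= 2 classes with >= 2
#'   samples each.
#' @param priors `"equal"` (default; class sizes here are similar) or
#'   `"proportional"`.
#' @param ridge ridge fraction epsilon (default 1e-8); `Sigma` gets
#'   `epsilon * mean(diag(Sigma))` added to its diagonal.
#' @return An `lda_model`: `means` (classes x variables), `sigma`,
#'   `sigma_inv`, `priors`, `classes`.
#' @export
lda_fit <- function(x, y, priors = c("equal", "proportional"),
                    ridge = 1e-8) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("need >= 2 classes")
  nk <- table(y)
  if (any(nk < 2)) stop("every class needs >= 2 samples")
  p <- ncol(x)
  means <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(p)))
  sigma <- matrix(0, p, p)
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    sigma <- sigma + stats::cov(xc) * (nrow(xc) - 1)
  }
  sigma <- sigma / (nrow(x) - length(classes))
  if (ridge > 0) sigma <- sigma + diag(ridge * mean(diag(sigma)), p)
  sigma_inv <- tryCatch(solve(sigma), error = function(e)
    stop("singular pooled covariance; increase the `ridge` argument"))
  pi_k <- if (priors == "equal") rep(1 / length(classes), length(classes))
          else as.numeric(nk) / nrow(x)
  names(pi_k) <- classes
  structure(list(means = means, sigma = sigma, sigma_inv = sigma_inv,
                 priors = pi_k, classes = classes, features = colnames(x)),
            class = "lda_model")
}

#' Discriminant scores and class assignment
#'
#' @param object an `lda_model`.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return List with `class` (factor of assignments) and `scores`
#'   (samples x classes discriminant values).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  A <- object$sigma_inv %*% t(object$means)          # p x K
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  scores <- sweep(x %*% A, 2, const, `+`)
  colnames(scores) <- object$classes
  assigned <- apply(scores, 1, which.max)             # first max: lowest index
  list(class = factor(object$classes[assigned], levels = object$classes),
       scores = scores)
}

#' Cross-validated classification accuracy
#'
#' Refits the LDA in each fold and scores the held-out samples.
#' Leave-one-out (default) is deterministic; k-fold uses a seeded,
#' class-stratified fold assignment. If a training fold loses a class
#' entirely, the fold is refit without it (with a warning).
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param scheme `"loo"` or an integer k (number of folds).
#' @param seed seed for k-fold assignment (ignored for LOO).
#' @param ... passed to [lda_fit()].
#' @return List with `confusion` (true x assigned counts), `accuracy`
#'   (per-class %), `total_accuracy` (%), `assigned`.
#' @export
cross_validate <- function(x, y, scheme = "loo", seed = NULL, ...) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  n <- nrow(x)
  folds <- if (identical(scheme, "loo")) seq_len(n) else {
    k <- as.integer(scheme)
    if (is.na(k) || k < 2 || k > n) stop("scheme must be 'loo' or 2 <= k <= n")
    with_seed(seed, {
      f <- integer(n)
      for (cl in levels(y)) {
        i <- which(y == cl)
        f[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      f
    })
  }
  assigned <- factor(rep(NA_character_, n), levels = levels(y))
  for (f in unique(folds)) {
    test <- which(folds == f)
    ytr <- droplevels(y[-test])
    if (nlevels(ytr) < nlevels(y))
      warning("fold ", f, " lost class(es): ",
              paste(setdiff(levels(y), levels(ytr)), collapse = ", "))
    model <- lda_fit(x[-test, , drop = FALSE], ytr, ...)
    pred <- predict(model, x[test, , drop = FALSE])$class
    assigned[test] <- factor(as.character(pred), levels = levels(y))
  }
  conf <- table(true = y, assigned = assigned)
  stats <- confusion_stats(conf)
  list(confusion = conf, accuracy = stats$per_class,
       total_accuracy = stats$total, assigned = assigned)
}

#' Permutation test of classification significance
#'
#' Builds an empirical null by permuting the class labels uniformly and
#' recomputing the cross-validated total accuracy for each permutation.
#' The p-value is `(1 + #{null >= observed}) / (1 + n_permutations)`.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed for the permutations.
#' @param scheme CV scheme, see [cross_validate()].
#' @param ... passed to [lda_fit()].
#' @return List with `observed` (CV total accuracy %), `null` (vector of
#'   permuted accuracies), `p`.
#' @export
permutation_test <- function(x, y, n_permutations = 100, seed = NULL,
                             scheme = "loo", ...) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  observed <- cross_validate(x, y, scheme = scheme, seed = seed,
                             ...)$total_accuracy
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      yp <- sample(y)
      cross_validate(x, yp, scheme = scheme, seed = NULL,
                     ...)$total_accuracy
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_permutations))
}

#' Per-class and total accuracy from a confusion matrix
#'
#' @param confusion square matrix of counts, true classes in rows, assigned
#'   classes in columns.
#' @return List with `per_class` (% correct per true class; `NA` with a
#'   warning for empty rows), `total` (%), `n`.
#' @export
confusion_stats <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0) || any(m != round(m)))
    stop("confusion matrix must hold non-negative integer counts")
  rs <- rowSums(m)
  per <- 100 * diag(m) / rs
  if (any(rs == 0)) {
    warning("class(es) with zero samples: accuracy undefined for ",
            paste(rownames(m)[rs == 0], collapse = ", "))
    per[rs == 0] <- NA_real_
  }
  names(per) <- rownames(m)
  list(per_class = per, total = 100 * sum(diag(m)) / sum(m), n = sum(m))
}

#' End-to-end botanical classification pipeline
#'
#' Runs the full chemometric workflow on a censored sample table:
#' censored-value substitution, log10 transform, variable screening,
#' stratified train/validation split, PCA on the training set, LDA with
#' cross-validation and permutation testing on the training set, and
#' prediction of the held-out validation set.
#'
#' @param table a [sample_table()].
#' @param train_n training-set size (default: 85/133 of the samples,
#'   rounded, the customary ~64% split of this workflow).
#' @param seed integer seed (split and permutations).
#' @param substitution censored-substitution strategy, see
#'   [substitute_censored()].
#' @param scaling PCA scaling, see [pca_fit()].
#' @param scheme CV scheme, see [cross_validate()].
#' @param priors LDA priors, see [lda_fit()].
#' @param n_permutations label permutations for the significance test.
#' @param min_quantified_fraction screening threshold.
#' @return A `classification_result`: list with `retained`, `split`
#'   (index vectors), `pca`, `lda`, `cv` (confusion + accuracies),
#'   `prediction` (confusion + accuracies on the validation set),
#'   `permutation` (observed/null/p), and `config` echoing all choices.
#' @export
classify_pipeline <- function(table, train_n = NULL, seed = 1L,
                              substitution = "half_lod",
                              scaling = "autoscale",
                              scheme = "loo",
                              priors = "equal",
                              n_permutations = 100,
                              min_quantified_fraction = 0.1) {
  n <- nrow(table$values)
  if (is.null(train_n)) train_n <- round(n * 85 / 133)
  retained <- screen_variables(table, min_quantified_fraction)
  full <- log_transform(
    substitute_censored(table, strategy = substitution)[, retained,
                                                        drop = FALSE])
  split <- split_train_validation(table, train_n, seed = seed)
  xtr <- full[split$train_idx, , drop = FALSE]
  xva <- full[split$validation_idx, , drop = FALSE]
  ytr <- droplevels(split$train$class)
  yva <- factor(as.character(split$validation$class), levels = levels(ytr))
  pca <- pca_fit(xtr, scaling = scaling)
  lda <- lda_fit(xtr, ytr, priors = priors)
  cv <- cross_validate(xtr, ytr, scheme = scheme, seed = seed,
                       priors = priors)
  perm <- permutation_test(xtr, ytr, n_permutations = n_permutations,
                           seed = seed, scheme = scheme, priors = priors)
  pred <- predict(lda, xva)$class
  conf <- table(true = yva, assigned = pred)
  pstats <- confusion_stats(conf)
  structure(list(retained = retained, split = split[c("train_idx",
                                                      "validation_idx")],
                 pca = pca, lda = lda, cv = cv,
                 prediction = list(confusion = conf,
                                   accuracy = pstats$per_class,
                                   total_accuracy = pstats$total),
                 permutation = perm,
                 config = list(train_n = train_n, seed = seed,
                               substitution = substitution,
                               scaling = scaling, scheme = scheme,
                               priors = priors,
                               n_permutations = n_permutations,
                               min_quantified_fraction =
                                 min_quantified_fraction)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("botanical classification:", length(x$retained), "elements,",
      length(x$split$train_idx), "train /",
      length(x$split$validation_idx), "validation samples\n")
  cat(sprintf("CV total accuracy: %.1f%%; prediction: %.1f%%; permutation p = %.4g\n",
              x$cv$total_accuracy, x$prediction$total_accuracy,
              x$permutation$p))
  cat("prediction confusion matrix:\n")
  print(x$prediction$confusion)
  invisible(x)
}
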