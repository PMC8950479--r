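# End-to-end runs with on-disk result bundles. The functions here are the
# workhorses behind the thin command-line wrapper shipped in
# inst/scripts/honeytrace (subcommands: simulate, doe, classify).

#' Run the classification workflow and write a result bundle
#'
#' Executes the full chemometric pipeline ([classify_pipeline()]) on a
#' sample table read from `input` (or generated synthetically when `input`
#' is `NULL`) and writes CSV reports plus a machine-readable run record to
#' `output_dir`: the per-class summary table, PCA scores and loadings,
#' cross-validation and prediction confusion matrices, the permutation null
#' distribution, and `run.json` echoing every configuration choice and
#' seed, sufficient to reproduce the run.
#'
#' @param input path to a sample-table CSV, or `NULL` to simulate.
#' @param output_dir directory for results (created if needed).
#' @param panel an [element_panel()].
#' @param seed integer seed used for simulation, split and permutations.
#' @param n_per_class synthetic samples per class when simulating.
#' @param ... passed to [classify_pipeline()].
#' @return The `classification_result`, invisibly.
#' @export
run_pipeline <- function(input = NULL, output_dir, panel = default_panel(),
                         seed = 20220321, n_per_class = 30, ...) {
  table <- if (is.null(input)) generate_samples(n_per_class, seed = seed,
                                                panel = panel)
           else read_sample_table(input, panel)
  res <- classify_pipeline(table, seed = seed, ...)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)
  utils::write.csv(summarize_table(table), out("summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(res$pca$scores),
                              res$pca$scores), out("pca_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(element = rownames(res$pca$loadings),
                              res$pca$loadings), out("pca_loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(res$cv$confusion),
                   out("cv_confusion.csv"))
  utils::write.csv(as.data.frame.matrix(res$prediction$confusion),
                   out("prediction_confusion.csv"))
  utils::write.csv(data.frame(permutation = seq_along(res$permutation$null),
                              null_accuracy = res$permutation$null),
                   out("permutation_null.csv"), row.names = FALSE)
  record <- c(res$config,
              list(input = if (is.null(input)) "synthetic" else input,
                   n_per_class = if (is.null(input)) n_per_class else NA,
                   retained = res$retained,
                   cv_total_accuracy = res$cv$total_accuracy,
                   prediction_total_accuracy = res$prediction$total_accuracy,
                   permutation_p = res$permutation$p,
                   package_version =
                     as.character(utils::packageVersion("honeytrace"))))
  jsonlite::write_json(record, out("run.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}

#' Fit a factorial design from CSV and write a coefficient report
#'
#' Reads a coded 2^2 + center design (see [read_doe()]; defaults to the
#' built-in digestion study when `input` is `NULL`), fits every response,
#' and writes a coefficient/significance table, center-point adequacy
#' verdicts, and a prediction grid per response.
#'
#' @param input DoE CSV path or `NULL` for the built-in digestion study.
#' @param output_dir directory for results.
#' @param factors list of two [factor_def()]s (defaults to the digestion
#'   study's factors when `input` is `NULL`).
#' @param resolution contour-grid resolution.
#' @return Named list of `mlr_fit`s, invisibly.
#' @export
run_doe <- function(input = NULL, output_dir, factors = NULL,
                    resolution = 25) {
  study <- if (is.null(input)) digestion_doe() else read_doe(input, factors)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  center <- study$x1 == 0 & study$x2 == 0
  fits <- lapply(names(study$responses), function(resp) {
    fit <- fit_factorial(study, resp)
    adequacy <- model_adequacy(fit, study$responses[[resp]][center])
    report <- data.frame(coefficient = names(fit$coef),
                         value = unname(fit$coef),
                         t = unname(fit$t), p = unname(fit$p),
                         significance = unname(fit$significance))
    utils::write.csv(report,
                     file.path(output_dir, paste0("coefficients_", resp,
                                                  ".csv")),
                     row.names = FALSE)
    utils::write.csv(contour_grid(fit, resolution = resolution),
                     file.path(output_dir, paste0("grid_", resp, ".csv")),
                     row.names = FALSE)
    c(fit = list(fit), adequacy = list(adequacy))
  })
  names(fits) <- names(study$responses)
  summary <- data.frame(
    response = names(study$responses),
    pure_error_sd = vapply(fits, function(f) f$fit$pure_error_sd, 0),
    center_prediction = vapply(fits, function(f) f$adequacy$predicted, 0),
    adequacy = vapply(fits, function(f) f$adequacy$verdict, ""))
  utils::write.csv(summary, file.path(output_dir, "doe_summary.csv"),
                   row.names = FALSE)
  invisible(fits)
}

#' Simulate a sample table to disk with a provenance sidecar
#'
#' @param output_dir directory for `samples.csv` and `provenance.json`.
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @param panel an [element_panel()].
#' @return Path of the written CSV, invisibly.
#' @export
run_simulate <- function(output_dir, n_per_class = 30, seed = 20220321,
                         panel = default_panel()) {
  table <- generate_samples(n_per_class, seed = seed, panel = panel)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(output_dir, "samples.csv")
  write_sample_table(table, path)
  jsonlite::write_json(
    list(generator = "honeytrace::generate_samples",
         n_per_class = n_per_class, seed = seed,
         panel_elements = panel$element,
         package_version =
           as.character(utils::packageVersion("honeytrace"))),
    file.path(output_dir, "provenance.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(path)
}
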