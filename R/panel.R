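#' Element panel: per-analyte acquisition and validation metadata
#'
#' An element panel is a data frame (class `element_panel`) with one row per
#' analyte, carrying the metadata that drives censoring and screening
#' throughout the package: isotope, acquisition mode, method limit of
#' detection (LoD) and quantification (LoQ) in ug/kg of honey, and the
#' instrumental calibration range in ug/dm^3 of digested solution. Honey
#' concentrations and instrumental solution concentrations are deliberately
#' kept in different units; conversion between the two happens only in
#' [quantify_concentration()].
#'
#' @param element character vector of element symbols (unique).
#' @param isotope integer mass numbers of the measured isotopes.
#' @param mode acquisition mode per analyte, `"KED"` (kinetic energy
#'   discrimination, He collision cell) or `"standard"`.
#' @param lod,loq method detection/quantification limits, ug/kg; `loq > lod > 0`.
#' @param cal_low,cal_high instrumental calibration range bounds, ug/dm^3.
#' @param ... further per-element columns (e.g. validation statistics); kept
#'   as-is.
#'
#' @return An `element_panel` data frame.
#' @seealso [default_panel()] for the 23-analyte honey panel.
#' @export
element_panel <- function(element, isotope, mode, lod, loq, cal_low, cal_high,
                          ...) {
  panel <- data.frame(element = as.character(element),
                      isotope = as.integer(isotope),
                      mode = as.character(mode),
                      lod = as.numeric(lod), loq = as.numeric(loq),
                      cal_low = as.numeric(cal_low),
                      cal_high = as.numeric(cal_high),
                      ...,
                      stringsAsFactors = FALSE)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$element))
    stop("duplicated element symbols in panel: ",
         paste(unique(panel$element[duplicated(panel$element)]), collapse = ", "))
  if (any(panel$lod <= 0))
    stop("panel LoD must be > 0 (element ",
         paste(panel$element[panel$lod <= 0], collapse = ", "), ")")
  if (any(panel$loq <= panel$lod))
    stop("panel LoQ must exceed LoD (element ",
         paste(panel$element[panel$loq <= panel$lod], collapse = ", "), ")")
  if (any(!panel$mode %in% c("KED", "standard")))
    stop("acquisition mode must be 'KED' or 'standard'")
  if (any(panel$cal_low >= panel$cal_high))
    stop("calibration range must have cal_low < cal_high")
  rownames(panel) <- NULL
  class(panel) <- c("element_panel", "data.frame")
  panel
}

#' Default 23-analyte honey panel
#'
#' The validated multi-element honey panel: Ag, As, Ba, Be, Bi, Cd, Co, Cr,
#' Cu, Fe, Hg, Li, Mn, Mo, Ni, Pb, Sb, Sn, Sr, Te, Tl, V and Zn, with the
#' measured isotope, acquisition mode (15 analytes in KED mode, 8 in
#' standard mode), method LoD/LoQ (ug/kg), instrumental calibration range
#' (ug/dm^3), repeatability and intermediate-precision CV%, and mean spike
#' recovery (%) with its standard deviation.
#'
#' @return An `element_panel` with 23 rows and validation columns
#'   `cv_repeatability`, `cv_intermediate`, `recovery_mean`, `recovery_sd`.
#' @export
default_panel <- function() {
  element_panel(
    element = c("Ag", "As", "Ba", "Be", "Bi", "Cd", "Co", "Cr", "Cu", "Fe",
                "Hg", "Li", "Mn", "Mo", "Ni", "Pb", "Sb", "Sn", "Sr", "Te",
                "Tl", "V", "Zn"),
    isotope = c(107L, 75L, 138L, 9L, 209L, 111L, 59L, 52L, 63L, 57L,
                202L, 7L, 55L, 98L, 60L, 208L, 121L, 120L, 88L, 120L,
                205L, 51L, 66L),
    mode = c("standard", "KED", "KED", "standard", "standard", "KED", "KED",
             "KED", "KED", "KED", "standard", "standard", "KED", "standard",
             "KED", "standard", "KED", "KED", "KED", "KED", "standard",
             "KED", "KED"),
    lod = c(5, 2, 20, 0.4, 0.1, 0.3, 0.3, 7, 20, 30,
            6, 2, 8, 0.7, 3, 3, 0.7, 2.1, 3, 1.2, 0.04, 0.2, 40),
    loq = c(17, 7, 70, 1.3, 0.3, 1.0, 1.0, 23, 70, 100,
            20, 7, 27, 2.3, 10, 10, 2.3, 6.9, 10, 3.9, 0.13, 0.7, 130),
    cal_low = c(0.1, 0.1, 1, 0.02, 0.005, 0.01, 0.01, 0.1, 1, 1,
                0.1, 0.1, 0.1, 0.04, 0.1, 0.1, 0.04, 0.1, 0.1, 0.04,
                0.005, 0.01, 1),
    cal_high = c(50, 50, 250, 50, 50, 50, 50, 50, 100, 100,
                 50, 500, 500, 50, 100, 250, 50, 50, 100, 50, 50, 50, 500),
    cv_repeatability = c(4, 4, 1, 4, 4, 4, 8, 4, 4, 4,
                         4, 4, 3, 4, 6, 4, 4, 5, 3, 4, 7, 4, 12),
    cv_intermediate = c(8, 6, 3, 13, 12, 8, 9, 5, 11, 17,
                        13, 14, 3, 8, 18, 6, 9, 5, 7, 21, 5, 6, 16),
    recovery_mean = c(106, 92, 90, 103, 85, 117, 99, 97, 107, 105,
                      130, 96, 107, 94, 95, 92, 115, 103, 103, 108, 96, 94, 101),
    recovery_sd = c(5, 1, 20, 1, 7, 1, 1, 1, 4, 15,
                    10, 1, 4, 1, 2, 1, 1, 2, 1, 3, 1, 2, 1)
  )
}

#' Read or write an element panel as CSV
#'
#' Plain comma-separated UTF-8 with a header row; one row per analyte.
#' `write_panel()` emits columns in the canonical order so output is
#' deterministic; `read_panel()` validates the invariants on the way in.
#'
#' @param path file path.
#' @param panel an `element_panel`.
#' @return `read_panel()` returns an `element_panel`; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("element", "isotope", "mode", "lod", "loq",
                "cal_low", "cal_high")
  missing <- setdiff(required, names(panel))
  if (length(missing))
    stop("panel file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  validate_panel(panel)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "element_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
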