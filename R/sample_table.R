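#' Sample tables of censored element concentrations
#'
#' A `sample_table` holds a samples x elements concentration matrix in ug/kg
#' together with a parallel censoring-flag matrix, the botanical class of
#' each sample, optional metadata, and the [element_panel()] the censoring
#' was resolved against. Each cell is one of
#' \describe{
#'   \item{`quantified`}{a numeric value `>= loq` of its element;}
#'   \item{`below_loq`}{detected but not quantifiable; the value, when
#'     recorded, lies in `[lod, loq)`, otherwise it is `NA`;}
#'   \item{`below_lod`}{not detected; the value is always `NA`.}
#' }
#'
#' @param values numeric matrix, samples x elements; `NA` for unrecorded
#'   cells. Column names must match `panel$element`.
#' @param censor character matrix of the same shape with entries
#'   `"quantified"`, `"below_loq"`, `"below_lod"`.
#' @param class botanical class per sample; one of `asphodel`, `eucalyptus`,
#'   `strawberry_tree`, `thistle`.
#' @param panel the [element_panel()] defining LoD/LoQ per element.
#' @param sample_id character sample identifiers (default `S1`, `S2`, ...).
#' @param metadata optional data frame of per-sample covariates (urbanization
#'   degree, altimetric area, ...); ignored by all computation.
#'
#' @return A `sample_table` object.
#' @export
sample_table <- function(values, censor, class, panel,
                         sample_id = NULL, metadata = NULL) {
  values <- as.matrix(values)
  censor <- as.matrix(censor)
  stopifnot(identical(dim(values), dim(censor)))
  if (is.null(colnames(values))) colnames(values) <- panel$element
  unknown <- setdiff(colnames(values), panel$element)
  if (length(unknown))
    stop("element column(s) not in panel: ", paste(unknown, collapse = ", "))
  # complete and order columns as in the panel
  missing <- setdiff(panel$element, colnames(values))
  if (length(missing))
    stop("panel element(s) absent from table: ", paste(missing, collapse = ", "))
  values <- values[, panel$element, drop = FALSE]
  colnames(censor) <- colnames(values)[seq_len(ncol(censor))]
  censor <- censor[, panel$element, drop = FALSE]

  bad <- !censor %in% c("quantified", "below_loq", "below_lod")
  if (any(bad)) stop("invalid censor flag(s): ",
                     paste(unique(censor[bad]), collapse = ", "))
  n <- nrow(values)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  class <- factor(as.character(class), levels = botanical_classes())
  if (anyNA(class)) stop("botanical_class outside ",
                         paste(botanical_classes(), collapse = "/"))
  if (length(class) != n) stop("one botanical class per sample required")
  if (is.null(metadata)) metadata <- data.frame(row.names = seq_len(n))

  lod <- panel$lod[match(colnames(values), panel$element)]
  loq <- panel$loq[match(colnames(values), panel$element)]
  lodm <- matrix(lod, n, ncol(values), byrow = TRUE)
  loqm <- matrix(loq, n, ncol(values), byrow = TRUE)
  if (any(censor == "below_lod" & !is.na(values)))
    stop("below_lod cells must not carry a value")
  if (any(censor == "quantified" & (is.na(values) | values < loqm)))
    stop("quantified cells must carry a value >= LoQ")
  i <- censor == "below_loq" & !is.na(values)
  if (any(values[i] < lodm[i] | values[i] >= loqm[i]))
    stop("recorded below_loq values must lie in [LoD, LoQ)")

  structure(list(sample_id = as.character(sample_id), class = class,
                 metadata = metadata, values = values, censor = censor,
                 panel = panel),
            class = "sample_table")
}

#' Botanical classes of the unifloral honeys
#'
#' @return Character vector of the four class labels, in canonical order.
#' @export
botanical_classes <- function() {
  c("asphodel", "eucalyptus", "strawberry_tree", "thistle")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table:", nrow(x$values), "samples x", ncol(x$values),
      "elements\n")
  print(table(x$class))
  frac <- mean(x$censor != "quantified")
  cat(sprintf("censored cells: %.1f%%\n", 100 * frac))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

#' Subset a sample table by row
#'
#' @param x a `sample_table`.
#' @param i row (sample) index.
#' @param ... ignored.
#' @return A `sample_table` with the selected samples.
#' @export
`[.sample_table` <- function(x, i, ...) {
  sample_table(x$values[i, , drop = FALSE], x$censor[i, , drop = FALSE],
               x$class[i], x$panel, sample_id = x$sample_id[i],
               metadata = x$metadata[i, , drop = FALSE])
}

#' Read and write sample tables as CSV
#'
#' The on-disk format mirrors a published concentration table: one row per
#' sample with columns `sample_id`, `botanical_class`, any metadata columns,
#' then one column per element symbol. Cells are numeric concentrations in
#' ug/kg or the censor tokens `<LOD` / `<LOQ` (case-insensitive). Numeric
#' cells are re-censored against the panel on the way in: values below the
#' element's LoD become `below_lod` (value dropped), values in `[LoD, LoQ)`
#' become `below_loq` with the value retained. The writer emits quantified
#' and recorded below-LoQ cells as numbers and everything else as tokens, so
#' a write/read round trip is lossless.
#'
#' @param path file path.
#' @param panel the [element_panel()] used to resolve censoring.
#' @param table a `sample_table`.
#' @return `read_sample_table()` returns a `sample_table`;
#'   `write_sample_table()` returns `path` invisibly.
#' @export
read_sample_table <- function(path, panel = default_panel()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "botanical_class") %in% names(raw)))
    stop("sample table needs 'sample_id' and 'botanical_class' columns")
  elem_cols <- intersect(names(raw), panel$element)
  # a column named like a chemical element but absent from the panel is a
  # data error, not metadata
  unknown <- setdiff(intersect(names(raw), chemical_symbols()), panel$element)
  if (length(unknown))
    stop("element column(s) not in panel: ", paste(unknown, collapse = ", "))
  missing <- setdiff(panel$element, elem_cols)
  if (length(missing))
    stop("panel element(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  n <- nrow(raw)
  values <- matrix(NA_real_, n, length(elem_cols),
                   dimnames = list(NULL, elem_cols))
  censor <- matrix("quantified", n, length(elem_cols),
                   dimnames = list(NULL, elem_cols))
  for (el in elem_cols) {
    lod <- panel$lod[panel$element == el]
    loq <- panel$loq[panel$element == el]
    cell <- trimws(raw[[el]])
    tok <- toupper(cell)
    is_lod <- tok == "<LOD"
    is_loq <- tok == "<LOQ"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_lod & !is_loq & is.na(num)
    if (any(bad))
      stop("non-numeric cell that is not a censor token at row ",
           which(bad)[1], ", column ", el, ": '", cell[which(bad)[1]], "'")
    censor[is_lod, el] <- "below_lod"
    censor[is_loq, el] <- "below_loq"
    idx <- which(!is_lod & !is_loq)
    v <- num[idx]
    censor[idx[v < lod], el] <- "below_lod"
    censor[idx[v >= lod & v < loq], el] <- "below_loq"
    v[v < lod] <- NA_real_
    values[idx, el] <- v
  }
  meta <- raw[, meta_columns(raw, panel), drop = FALSE]
  sample_table(values, censor, raw$botanical_class, panel,
               sample_id = raw$sample_id, metadata = meta)
}

meta_columns <- function(raw, panel) {
  setdiff(names(raw), c("sample_id", "botanical_class", panel$element))
}

chemical_symbols <- function() {
  c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
    "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
    "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce",
    "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm",
    "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
    "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U")
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  cells <- matrix("", nrow(table$values), ncol(table$values),
                  dimnames = dimnames(table$values))
  rec <- !is.na(table$values)
  cells[rec] <- format(table$values[rec], trim = TRUE, digits = 15,
                       scientific = FALSE)
  cells[!rec & table$censor == "below_loq"] <- "<LOQ"
  cells[table$censor == "below_lod"] <- "<LOD"
  out <- data.frame(sample_id = table$sample_id,
                    botanical_class = as.character(table$class),
                    table$metadata, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-class, per-element summary of a sample table
#'
#' Reproduces the layout of a published mean/range table: for every
#' botanical class and element, the arithmetic mean of the quantified values
#' only, the min--max range over all recorded values (quantified and
#' recorded below-LoQ), and counts of cells by censoring flag. When no value
#' was quantified the display column reports `<LoD` (or `<LoQ` when some
#' cells were detected), matching the convention of censored concentration
#' tables.
#'
#' @param table a `sample_table`.
#' @return A data frame with one row per class x element:
#'   `class`, `element`, `n`, `n_quantified`, `n_below_loq`, `n_below_lod`,
#'   `mean` (NA when nothing quantified), `range_low`, `range_high`,
#'   `display`.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (nrow(table$values) == 0L) stop("empty sample table")
  present <- levels(table$class)[table(table$class) > 0]
  absent <- setdiff(levels(table$class), present)
  if (length(absent))
    warning("class(es) with zero samples omitted from summary: ",
            paste(absent, collapse = ", "))
  rows <- lapply(present, function(cl) {
    sel <- table$class == cl
    v <- table$values[sel, , drop = FALSE]
    cen <- table$censor[sel, , drop = FALSE]
    do.call(rbind, lapply(colnames(v), function(el) {
      q <- cen[, el] == "quantified"
      recorded <- v[!is.na(v[, el]), el]
      m <- if (any(q)) mean(v[q, el]) else NA_real_
      lod <- table$panel$lod[table$panel$element == el]
      disp <- if (any(q)) format(signif(m, 3), trim = TRUE)
              else if (any(cen[, el] == "below_loq")) "<LoQ" else "<LoD"
      data.frame(class = cl, element = el, n = sum(sel),
                 n_quantified = sum(q),
                 n_below_loq = sum(cen[, el] == "below_loq"),
                 n_below_lod = sum(cen[, el] == "below_lod"),
                 mean = m,
                 range_low = if (length(recorded)) min(recorded) else NA_real_,
                 range_high = if (length(recorded)) max(recorded) else NA_real_,
                 display = disp, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
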