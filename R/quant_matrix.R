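#' Protein quantification matrix
#'
#' The pipeline's central container: a proteins x samples matrix of iBAQ
#' abundances together with the sample design, a detection mask and an
#' imputation-provenance mask. Missing values are stored as `NA`; an intensity
#' of zero in an input file means "not observed" and is converted to `NA` on
#' read.
#'
#' @param values numeric matrix (proteins in rows, samples in columns) of
#'   non-negative abundances; `NA` marks a missing (not observed) cell.
#'   Row names are protein identifiers, column names sample identifiers.
#' @param design an [rp_design()] whose `sample_id`s match `colnames(values)`.
#' @param scale one of `"raw"`, `"rp_normalized"`, `"log2"`; provenance of the
#'   values. On the `"log2"` scale negative values are allowed.
#' @param impute character matrix parallel to `values` with entries in
#'   `"observed"`, `"POV"`, `"MEC"`, or `NA` for cells still missing.
#'
#' @return An object of class `rp_matrix`: a list with elements `values`,
#'   `design`, `detect` (logical matrix, `TRUE` where observed before any
#'   imputation), `impute`, `scale`.
#' @export
rp_matrix <- function(values, design, scale = "raw", impute = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have protein row names and sample column names")
  }
  if (!inherits(design, "rp_design")) stop("design must be an rp_design")
  if (!identical(sort(colnames(values)), sort(design$sample_id))) {
    stop("column names of values must match design sample_ids")
  }
  # keep design order authoritative for columns
  values <- values[, design$sample_id, drop = FALSE]
  scale <- match.arg(scale, c("raw", "rp_normalized", "log2"))
  if (scale != "log2" && any(values < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative on the ", scale, " scale")
  }
  detect <- !is.na(values)
  if (is.null(impute)) {
    impute <- matrix(ifelse(detect, "observed", NA_character_),
                     nrow = nrow(values), dimnames = dimnames(values))
  } else {
    impute <- impute[, design$sample_id, drop = FALSE]
    stopifnot(identical(dim(impute), dim(values)))
    detect <- !is.na(impute) & impute == "observed"
  }
  structure(list(values = values, design = design, detect = detect,
                 impute = impute, scale = scale),
            class = "rp_matrix")
}

#' @export
print.rp_matrix <- function(x, ...) {
  cat(sprintf("rp_matrix: %d proteins x %d samples (%d tissues), scale=%s\n",
              nrow(x$values), ncol(x$values),
              length(design_tissues(x$design)), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)  imputed: %d POV, %d MEC\n",
              sum(is.na(x$values)),
              100 * mean(is.na(x$values)),
              sum(x$impute == "POV", na.rm = TRUE),
              sum(x$impute == "MEC", na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.rp_matrix <- function(x) dim(x$values)

#' Peptide-level quantification table
#'
#' Holds peptide abundances per sample plus the peptide-to-protein mapping and
#' the specificity flag (a peptide is *specific* when it maps to exactly one
#' protein; only specific peptides enter iBAQ).
#'
#' @param info data.frame with columns `peptide`, `protein`, `specific`
#'   (logical), one row per peptide.
#' @param values numeric matrix of non-negative abundances, one row per
#'   peptide (same order as `info`), one column per sample; `NA` = missing.
#' @param design an [rp_design()].
#' @return An object of class `peptide_quant`.
#' @export
peptide_quant <- function(info, values, design) {
  stopifnot(is.data.frame(info),
            all(c("peptide", "protein", "specific") %in% names(info)),
            nrow(info) == nrow(values))
  if (!inherits(design, "rp_design")) stop("design must be an rp_design")
  if (!identical(sort(colnames(values)), sort(design$sample_id))) {
    stop("column names of values must match design sample_ids")
  }
  values <- values[, design$sample_id, drop = FALSE]
  if (any(values < 0, na.rm = TRUE)) stop("peptide abundances must be >= 0")
  info$specific <- as.logical(info$specific)
  structure(list(info = info, values = values, design = design),
            class = "peptide_quant")
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat(sprintf("peptide_quant: %d peptides / %d proteins x %d samples\n",
              nrow(x$info), length(unique(x$info$protein)), ncol(x$values)))
  invisible(x)
}
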