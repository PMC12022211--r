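# Replicate-based detection filtering and normalization of iBAQ matrices.

# observed-replicate count per protein x tissue
obs_per_tissue <- function(mat) {
  tissues <- design_tissues(mat$design)
  out <- sapply(tissues, function(t) {
    cols <- tissue_samples(mat$design, t)
    rowSums(!is.na(mat$values[, cols, drop = FALSE]))
  })
  matrix(out, nrow = nrow(mat$values),
         dimnames = list(rownames(mat$values), tissues))
}

#' Replicate-based detection filter
#'
#' Applies the two-step reliability filter used on discovery data:
#' \enumerate{
#'   \item a protein is kept only if it was observed in *all* replicates of
#'     at least one tissue;
#'   \item within a kept protein, all values of a tissue in which the protein
#'     was observed in exactly one replicate are discarded (set missing).
#' }
#'
#' @param mat an [rp_matrix()].
#' @return The filtered [rp_matrix()] with its detection mask updated.
#' @export
filter_detection <- function(mat) {
  stopifnot(inherits(mat, "rp_matrix"))
  design <- mat$design
  tissues <- design_tissues(design)
  nrep <- table(design$tissue)[tissues]
  if (any(nrep < 2)) stop("each tissue needs at least 2 replicates")
  obs <- obs_per_tissue(mat)
  keep <- rowSums(obs == matrix(nrep, nrow(obs), length(tissues),
                                byrow = TRUE)) > 0
  values <- mat$values[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  for (t in tissues) {
    single <- obs[, t] == 1L
    if (any(single)) {
      values[single, tissue_samples(design, t)] <- NA_real_
    }
  }
  rp_matrix(values, design, scale = mat$scale)
}

#' Normalize abundances to the total ribosomal-protein signal
#'
#' Divides every cell by its sample's summed observed RP iBAQ, so that within
#' each sample the RP values sum to 1. Ratios between proteins within a
#' sample are conserved.
#'
#' @param mat an [rp_matrix()] on the raw scale.
#' @param rp_ids character vector of ribosomal-protein row ids.
#' @param restrict if `TRUE` (default), the returned matrix is restricted to
#'   the RP rows; set `FALSE` to keep all proteins normalized by the RP total.
#' @return An [rp_matrix()] with `scale = "rp_normalized"`.
#' @export
normalize_to_rp_total <- function(mat, rp_ids, restrict = TRUE) {
  stopifnot(inherits(mat, "rp_matrix"))
  rp_rows <- intersect(rownames(mat$values), rp_ids)
  if (length(rp_rows) == 0L) stop("no RP rows present in matrix")
  totals <- colSums(mat$values[rp_rows, , drop = FALSE], na.rm = TRUE)
  bad <- totals <= 0
  if (any(bad)) {
    stop("sample(s) with no observed RP signal: ",
         paste(names(totals)[bad], collapse = ", "))
  }
  values <- sweep(mat$values, 2, totals, "/")
  if (restrict) values <- values[rp_rows, , drop = FALSE]
  rp_matrix(values, mat$design, scale = "rp_normalized")
}

#' Fraction of the total protein signal carried by ribosomal proteins
#'
#' Per sample, the summed RP iBAQ divided by the summed iBAQ of all proteins
#' (a purity/enrichment readout for ribosomal fractions); per tissue, the
#' mean over its replicates.
#'
#' @param mat an [rp_matrix()] on the raw scale containing both RP and non-RP
#'   rows.
#' @param rp_ids character vector of RP row ids.
#' @return A list with `sample` (named numeric vector per sample) and
#'   `tissue` (named numeric vector of replicate means).
#' @export
rp_enrichment_fraction <- function(mat, rp_ids) {
  stopifnot(inherits(mat, "rp_matrix"))
  if (mat$scale != "raw") stop("enrichment fraction requires the raw scale")
  all_missing <- colSums(!is.na(mat$values)) == 0
  if (any(all_missing)) {
    stop("sample(s) with no observed protein: ",
         paste(colnames(mat$values)[all_missing], collapse = ", "))
  }
  rp_rows <- intersect(rownames(mat$values), rp_ids)
  rp_sum <- colSums(mat$values[rp_rows, , drop = FALSE], na.rm = TRUE)
  total <- colSums(mat$values, na.rm = TRUE)
  per_sample <- rp_sum / total
  tissues <- design_tissues(mat$design)
  per_tissue <- vapply(tissues, function(t) {
    mean(per_sample[tissue_samples(mat$design, t)])
  }, numeric(1))
  list(sample = per_sample, tissue = per_tissue)
}

#' Count reliably detected proteins per tissue
#'
#' A protein counts as detected in a tissue when it was observed in at least
#' `min_reps` of the tissue's replicates.
#'
#' @param mat an [rp_matrix()].
#' @param min_reps minimum number of observed replicates (default 2).
#' @return Named integer vector, one count per tissue.
#' @export
detected_per_tissue <- function(mat, min_reps = 2L) {
  stopifnot(inherits(mat, "rp_matrix"))
  obs <- obs_per_tissue(mat)
  counts <- colSums(obs >= min_reps)
  stats::setNames(as.integer(counts), colnames(obs))
}

#' Tissues in which each protein is detected
#'
#' Companion of [detected_per_tissue()]: for every protein, the set of
#' tissues with at least `min_reps` observed replicates. Used to flag
#' tissue-specific RPs (detected in at most two tissues).
#'
#' @inheritParams detected_per_tissue
#' @return Named list mapping protein id to a character vector of tissues.
#' @export
detected_tissues <- function(mat, min_reps = 2L) {
  obs <- obs_per_tissue(mat)
  apply(obs, 1, function(r) colnames(obs)[r >= min_reps], simplify = FALSE)
}
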