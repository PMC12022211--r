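# Organ-level RPKM renormalization and protein-transcript concordance.

#' Renormalize an organ-level RPKM table over the RP gene set
#'
#' Per organ, each RPKM value is scaled by `n_RP / sum(RPKM)`, so the mean of
#' the normalized values over the RP set is exactly 1 per organ. The scaling
#' makes datasets with different sequencing depths comparable; it is
#' invariant to any per-organ rescaling of the raw RPKM column. Relative
#' log2 values (normalized value over the gene's cross-organ mean) are
#' attached for heatmap-style comparison; genes with RPKM 0 in an organ are
#' treated as not detected there (`NA` in the relative matrix).
#'
#' @param rpkm numeric matrix, RP genes in rows, organs in columns,
#'   non-negative RPKM values.
#' @return A list of class `normalized_rpkm` with `normalized` (same shape
#'   as `rpkm`) and `rel_log2` (log2 relative values, `NA` where RPKM = 0).
#' @export
normalize_rpkm <- function(rpkm) {
  stopifnot(is.matrix(rpkm), is.numeric(rpkm))
  if (any(rpkm < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  sums <- colSums(rpkm, na.rm = TRUE)
  if (any(sums <= 0)) {
    stop("organ(s) with zero total RPKM: ",
         paste(colnames(rpkm)[sums <= 0], collapse = ", "))
  }
  normalized <- sweep(rpkm, 2, nrow(rpkm) / sums, "*")
  rel <- normalized
  rel[rel == 0] <- NA_real_
  rel <- log2(rel / rowMeans(rel, na.rm = TRUE))
  structure(list(normalized = normalized, rel_log2 = rel),
            class = "normalized_rpkm")
}

#' Align protein and transcript organ profiles
#'
#' Restricts a protein relative-abundance matrix and a transcript relative
#' matrix to their shared organs (after applying an organ-name mapping, e.g.
#' `c(cortex = "brain")` to pair a cortex proteomic column with a brain RNA
#' column) and shared RP ids, in matching order.
#'
#' @param prot RP x organ matrix of log2 relative protein abundances.
#' @param rna RP x organ matrix of log2 relative transcript values (e.g.
#'   `normalize_rpkm(x)$rel_log2`).
#' @param mapping named character vector renaming protein-side organ columns
#'   to the transcript-side vocabulary (`c(protein_organ = "rna_organ")`).
#' @return List with matrices `protein` and `rna`, identically dimensioned.
#' @export
align_organs <- function(prot, rna, mapping = NULL) {
  stopifnot(is.matrix(prot), is.matrix(rna))
  pn <- colnames(prot)
  if (!is.null(mapping)) {
    hit <- pn %in% names(mapping)
    pn[hit] <- mapping[pn[hit]]
    colnames(prot) <- pn
  }
  organs <- intersect(pn, colnames(rna))
  if (length(organs) == 0L) stop("no shared organs between datasets")
  genes <- intersect(rownames(prot), rownames(rna))
  if (length(genes) == 0L) stop("no shared RP ids between datasets")
  list(protein = prot[genes, organs, drop = FALSE],
       rna = rna[genes, organs, drop = FALSE])
}

#' Protein-transcript concordance per RP
#'
#' Pearson correlation, per RP, between its log2 relative protein abundance
#' and its log2 relative transcript expression across the shared organs
#' where both are defined. An RP is called concordant when `r >= r_min`;
#' RPs with fewer than `min_organs` complete pairs are flagged insufficient,
#' and constant profiles leave `r` undefined.
#'
#' @param paired list from [align_organs()] (elements `protein`, `rna`).
#' @param r_min concordance threshold on Pearson r (default 0.5).
#' @param min_organs minimum complete organ pairs (default 3).
#' @return data.frame with columns `protein`, `n_organs`, `r`, `concordant`,
#'   `insufficient`.
#' @export
protein_rna_concordance <- function(paired, r_min = 0.5, min_organs = 3L) {
  prot <- paired$protein; rna <- paired$rna
  stopifnot(identical(dim(prot), dim(rna)))
  out <- lapply(rownames(prot), function(g) {
    x <- prot[g, ]; y <- rna[g, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_organs) {
      return(data.frame(protein = g, n_organs = n, r = NA_real_,
                        concordant = NA, insufficient = TRUE))
    }
    r <- if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NA_real_
         else stats::cor(x[ok], y[ok])
    data.frame(protein = g, n_organs = n, r = r,
               concordant = if (is.na(r)) NA else r >= r_min,
               insufficient = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
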