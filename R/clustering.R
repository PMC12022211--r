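# Replicate correlation, relative-abundance profiles, Ward clustering and
# the clustering-derived variable set.

#' Pairwise Pearson correlation between samples
#'
#' Pearson correlation of log2 RP abundances between every pair of samples,
#' using pairwise-complete observations. Constant columns yield `NA` entries
#' (flagged with a warning).
#'
#' @param mat an [rp_matrix()] (log2 scale recommended) or a plain numeric
#'   matrix with samples in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(mat) {
  values <- if (inherits(mat, "rp_matrix")) mat$values else mat
  cc <- suppressWarnings(
    stats::cor(values, use = "pairwise.complete.obs", method = "pearson"))
  if (anyNA(cc)) warning("undefined correlations (constant column or <2 shared values)")
  diag(cc) <- 1
  cc
}

#' Relative abundance profiles of RPs
#'
#' Computes, per RP, the log2 ratio of its normalized abundance to its mean
#' across tissues (heatmap values) or across samples (sample-level profiles
#' used for replicate clustering).
#'
#' With `by = "tissue"`: replicates are averaged per tissue on the
#' RP-sum-normalized scale, each tissue column is renormalized to its RP sum,
#' every value is divided by the RP's mean over the tissues in which it was
#' detected, then log2-transformed. Tissues with no detection stay missing.
#' With `by = "sample"`: per-sample normalized values are divided by the RP's
#' mean over samples and log2-transformed.
#'
#' @param mat an [rp_matrix()] on the `rp_normalized` scale.
#' @param by `"tissue"` (default) or `"sample"`.
#' @return Numeric matrix (RP x tissue or RP x sample) of log2 relative
#'   abundances, `NA` where the RP was not detected.
#' @export
relative_abundance <- function(mat, by = c("tissue", "sample")) {
  stopifnot(inherits(mat, "rp_matrix"))
  if (mat$scale != "rp_normalized") {
    stop("relative_abundance expects an rp_normalized matrix")
  }
  by <- match.arg(by)
  if (by == "tissue") {
    tissues <- design_tissues(mat$design)
    prof <- sapply(tissues, function(t) {
      rowMeans(mat$values[, tissue_samples(mat$design, t), drop = FALSE],
               na.rm = TRUE)
    })
    prof <- matrix(prof, nrow = nrow(mat$values),
                   dimnames = list(rownames(mat$values), tissues))
    prof[is.nan(prof)] <- NA_real_
    # renormalize each tissue to its RP sum
    prof <- sweep(prof, 2, colSums(prof, na.rm = TRUE), "/")
  } else {
    prof <- mat$values
  }
  rel <- prof / rowMeans(prof, na.rm = TRUE)
  log2(rel)
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Agglomerative Ward linkage (`ward.D2`, heights on the Euclidean scale) on
#' the rows or columns of a value matrix. Missing cells must be handled by
#' the caller (see [clustering_variable_set()] for the convention used on
#' relative-abundance profiles).
#'
#' @param points numeric matrix without missing values.
#' @param on cluster `"rows"` (e.g. proteins) or `"cols"` (samples).
#' @return An object of class [stats::hclust].
#' @export
ward_cluster <- function(points, on = c("rows", "cols")) {
  on <- match.arg(on)
  if (on == "cols") points <- t(points)
  if (anyNA(points)) stop("ward_cluster requires a complete matrix")
  if (nrow(points) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(points, method = "euclidean"),
                method = "ward.D2")
}

#' Clustering-derived set of variable RPs
#'
#' Cuts the RP dendrogram (Ward linkage on Euclidean distances of relative
#' abundance profiles, missing cells treated as 0 = "at its cross-tissue
#' mean" for the distance computation only) into `k` groups. A group is
#' labeled variable when the mean across-tissue variance of its members'
#' profiles exceeds `threshold` (default: the grand mean of the per-RP
#' variances - per-RP variances are right-skewed, so the grand mean sits
#' between the tight stable block and the variable groups, whereas the
#' median falls inside the stable block). Tissue-restricted RPs (detected in
#' at most two tissues) are always part of the variable set: their relative
#' profile is degenerate (a profile relative to its own few detected
#' tissues), so the variance ranking cannot see them. Returns the union.
#'
#' @param rel RP x tissue matrix of log2 relative abundances (see
#'   [relative_abundance()]).
#' @param k number of groups to cut the dendrogram into (default 10; for a
#'   panel of ~85 RPs this is fine enough to separate locally variable
#'   patterns from the stable block, while the variance threshold keeps
#'   false positives at the percent level).
#' @param threshold numeric variance threshold; `NULL` (default) uses the
#'   grand mean per-RP variance.
#' @return Character vector of RP ids labeled variable by clustering.
#' @export
clustering_variable_set <- function(rel, k = 10L, threshold = NULL) {
  stopifnot(is.matrix(rel))
  v <- apply(rel, 1, stats::var, na.rm = TRUE)
  if (all(!is.finite(v)) || all(v == 0, na.rm = TRUE)) return(character(0))
  if (is.null(threshold)) threshold <- mean(v, na.rm = TRUE)
  filled <- rel
  filled[is.na(filled)] <- 0
  hc <- ward_cluster(filled, on = "rows")
  groups <- stats::cutree(hc, k = min(k, nrow(rel)))
  restricted <- rownames(rel)[rowSums(!is.na(rel)) <= 2L]
  out <- restricted
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    gv <- mean(v[members], na.rm = TRUE)
    if (is.finite(gv) && gv > threshold) out <- c(out, members)
  }
  sort(unique(out))
}

#' Overlap between two RP sets
#'
#' Exact set arithmetic behind a two-set Venn diagram.
#'
#' @param statistical,clustering character vectors (e.g. variable RPs from
#'   the statistical test and from clustering).
#' @return Named integer vector `c(both, statistical_only, clustering_only)`.
#' @export
venn_overlap <- function(statistical, clustering) {
  a <- unique(statistical); b <- unique(clustering)
  c(both = length(intersect(a, b)),
    statistical_only = length(setdiff(a, b)),
    clustering_only = length(setdiff(b, a)))
}
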