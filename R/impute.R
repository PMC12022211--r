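# Two-class missing-value handling on the log2 scale.
#
# A missing cell is a POV (partially observed value) when its tissue retains
# at least one observed replicate for that protein, and a MEC (missing in the
# entire condition) when the tissue has none. MEC cells are left-censored by
# construction (the protein was below detection in the whole tissue) and are
# floored to the lowest observed log2 value of their sample; POV cells are
# reconstructed from the within-tissue structure by a two-way least-squares
# fit (protein effect + sample offset), the sample offsets being estimated
# from proteins observed in all replicates of the tissue.

#' Log2-transform a normalized matrix and impute missing values
#'
#' @param mat an [rp_matrix()] on the `rp_normalized` scale that has been
#'   detection-filtered (see [filter_detection()]).
#' @param rng_seed integer seed threaded for reproducibility of any
#'   tie-breaking; the imputation itself is deterministic.
#' @return An [rp_matrix()] with `scale = "log2"`, no missing cells, and an
#'   imputation mask recording `"observed"`, `"POV"` or `"MEC"` per cell.
#' @export
log2_and_impute <- function(mat, rng_seed = 1L) {
  stopifnot(inherits(mat, "rp_matrix"))
  if (mat$scale != "rp_normalized") {
    stop("log2_and_impute expects an rp_normalized matrix")
  }
  design <- mat$design
  tissues <- design_tissues(design)
  lv <- log2(mat$values)
  impute <- matrix(ifelse(is.na(lv), NA_character_, "observed"),
                   nrow = nrow(lv), dimnames = dimnames(lv))
  obs <- obs_per_tissue(mat)

  # POV: within-tissue additive fit protein + sample offset
  for (t in tissues) {
    cols <- tissue_samples(design, t)
    sub <- lv[, cols, drop = FALSE]
    pov_rows <- which(obs[, t] > 0 & obs[, t] < length(cols))
    if (length(pov_rows) == 0L) next
    full <- obs[, t] == length(cols)
    if (any(full)) {
      comp <- sub[full, , drop = FALSE]
      offsets <- colMeans(comp) - mean(comp)
    } else {
      warning("tissue '", t, "' has no fully observed protein; ",
              "POV cells fall back to the within-tissue protein mean")
      offsets <- stats::setNames(rep(0, length(cols)), cols)
    }
    for (i in pov_rows) {
      seen <- !is.na(sub[i, ])
      prot_eff <- mean(sub[i, seen] - offsets[seen])
      fill <- which(!seen)
      sub[i, fill] <- prot_eff + offsets[fill]
      impute[i, cols[fill]] <- "POV"
    }
    lv[, cols] <- sub
  }

  # MEC: per-sample floor at the minimum observed log2 value of the column
  for (j in seq_len(ncol(lv))) {
    mec <- is.na(lv[, j])
    if (!any(mec)) next
    observed_col <- lv[impute[, j] %in% "observed", j]
    if (length(observed_col) == 0L) {
      stop("sample ", colnames(lv)[j], " has no observed value to floor to")
    }
    lv[mec, j] <- min(observed_col)
    impute[mec, j] <- "MEC"
  }

  rp_matrix(lv, design, scale = "log2", impute = impute)
}
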