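# Statistical layer: Benjamini-Hochberg step-up, one-way ANOVA across
# tissues, empirical-Bayes variance moderation (method-of-moments fit of a
# scaled inverse-chi-square prior, after Smyth 2004), and moderated
# one-versus-all contrasts.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1 and mapped back to the
#' input order. `NA` p-values propagate as `NA` and do not count toward `m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m > 0L) {
    o <- order(p)
    qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    tmp <- rep(NA_real_, m)
    tmp[o] <- qs
    q[ok] <- tmp
  }
  q
}

#' One-way ANOVA across tissues
#'
#' Classical fixed-effects one-way ANOVA F-test per protein, groups being the
#' tissues, computed on log2 (imputed) values. Proteins lacking two tissues
#' with two values each, or with zero residual degrees of freedom, get an
#' `NA` p-value.
#'
#' @param imputed an [rp_matrix()] on the log2 scale (see
#'   [log2_and_impute()]). Missing cells are tolerated and dropped per
#'   protein.
#' @param exclude_mec if `TRUE`, MEC-imputed cells are excluded from the
#'   test; the default keeps them (imputation precedes testing).
#' @return Named numeric vector of p-values, one per protein.
#' @export
anova_across_tissues <- function(imputed, exclude_mec = FALSE) {
  stopifnot(inherits(imputed, "rp_matrix"))
  values <- imputed$values
  if (exclude_mec) values[imputed$impute == "MEC"] <- NA_real_
  tissue <- imputed$design$tissue[match(colnames(values),
                                        imputed$design$sample_id)]
  apply(values, 1, function(x) {
    keep <- !is.na(x)
    g <- factor(tissue[keep])
    n_per <- table(g)
    if (sum(n_per >= 2) < 2 || sum(keep) - nlevels(g) < 1) return(NA_real_)
    if (stats::var(x[keep]) == 0) return(1)
    stats::oneway.test(x[keep] ~ g, var.equal = TRUE)$p.value
  })
}

# Newton solve of trigamma(x) = y, vectorized (y > 0)
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NA_real_)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0sq`) to a set of
#' per-protein sample variances by matching the moments of `log(s^2)`
#' (method of moments on the digamma/trigamma scale), and returns the
#' posterior (shrunken) variances `(d0*s0sq + d*s2) / (d0 + d)`. A
#' non-positive excess dispersion yields an infinite prior df (`d0 = Inf`,
#' all posterior variances equal `s0sq`).
#'
#' @param s2 numeric vector of per-protein sample variances (> 0; zeros and
#'   `NA`s are excluded from the fit but still receive a posterior value).
#' @param d residual degrees of freedom, scalar or vector parallel to `s2`.
#' @return A list of class `variance_moderation` with elements `d0`, `s0sq`,
#'   `post` (posterior variances) and `df_total` (`d + d0`).
#' @export
squeeze_variances <- function(s2, d) {
  if (length(d) == 1L) d <- rep(d, length(s2))
  stopifnot(length(d) == length(s2))
  ok <- is.finite(s2) & s2 > 0 & d > 0
  if (sum(ok) < 3L) {
    warning("fewer than 3 usable variances; no moderation applied (d0 = 0)")
    return(structure(list(d0 = 0, s0sq = NA_real_, post = s2,
                          df_total = d), class = "variance_moderation"))
  }
  z <- log(s2[ok])
  e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  post <- if (is.infinite(d0)) {
    rep(s0sq, length(s2))
  } else {
    (d0 * s0sq + d * ifelse(is.finite(s2), s2, 0)) / (d0 + d)
  }
  structure(list(d0 = d0, s0sq = s0sq, post = post, df_total = d + d0),
            class = "variance_moderation")
}

#' @export
print.variance_moderation <- function(x, ...) {
  cat(sprintf("variance moderation: d0 = %s, s0^2 = %.4g (%d variances)\n",
              format(x$d0), x$s0sq, length(x$post)))
  invisible(x)
}

# One contrast (one tissue vs pooled rest) for a matrix of log2 values.
# Returns per-protein n1, n2, contrast, pooled variance, df.
ova_contrast_stats <- function(values, in_tissue) {
  x1 <- values[, in_tissue, drop = FALSE]
  x2 <- values[, !in_tissue, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  d <- n1 + n2 - 2
  s2 <- ifelse(d > 0, (ss1 + ss2) / d, NA_real_)
  list(n1 = n1, n2 = n2, contrast = m1 - m2, s2 = s2, d = d)
}

#' Moderated one-versus-all differential-abundance test
#'
#' For every protein and tissue, compares the tissue's samples against the
#' pooled samples of all other tissues on log2 imputed values: the contrast
#' is the difference of group means, the test statistic a moderated t using
#' the empirical-Bayes posterior variance of the two-group pooled variance,
#' with `d + d0` degrees of freedom. p-values are adjusted by
#' Benjamini-Hochberg jointly across all (protein, tissue) pairs. The
#' reported log2 fold change is computed the same way but excluding
#' MEC-imputed cells from both group means; it is undefined (`NA`) when one
#' side retains no cell.
#'
#' @param imputed an [rp_matrix()] on the log2 scale, no missing cells (see
#'   [log2_and_impute()]); `NA` cells, if any, are dropped per contrast.
#' @param moderation optional `variance_moderation`-like list with elements
#'   `d0` and `s0sq` applied to every contrast (use `list(d0 = 0)` for an
#'   ordinary pooled-variance t-test, `list(d0 = Inf, s0sq = v)` for a
#'   z-statistic with fixed variance `v`). The default (`NULL`) fits the
#'   prior per tissue contrast across proteins with [squeeze_variances()].
#' @param proteins optional character vector restricting the test to a subset
#'   of proteins (typically the ANOVA-positive ones).
#' @return A data.frame of class `ova_test` with columns `protein`, `tissue`,
#'   `log2fc`, `t`, `df`, `p`, `q`.
#' @export
one_vs_all_test <- function(imputed, moderation = NULL, proteins = NULL) {
  stopifnot(inherits(imputed, "rp_matrix"))
  values <- imputed$values
  mec <- !is.na(imputed$impute) & imputed$impute == "MEC"
  if (!is.null(proteins)) {
    keep <- rownames(values) %in% proteins
    values <- values[keep, , drop = FALSE]
    mec <- mec[keep, , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no proteins to test")
  design <- imputed$design
  tissues <- design_tissues(design)
  if (length(tissues) < 2L) stop("one-vs-all needs at least 2 tissues")
  sample_tissue <- design$tissue[match(colnames(values), design$sample_id)]

  res <- vector("list", length(tissues))
  for (k in seq_along(tissues)) {
    in_t <- sample_tissue == tissues[k]
    st <- ova_contrast_stats(values, in_t)
    if (is.null(moderation)) {
      mod <- squeeze_variances(st$s2, st$d)
      d0 <- mod$d0; s0sq <- mod$s0sq
    } else {
      d0 <- moderation$d0
      s0sq <- if (is.null(moderation$s0sq)) NA_real_ else moderation$s0sq
    }
    post <- if (is.infinite(d0)) rep(s0sq, length(st$s2))
            else if (d0 == 0) st$s2
            else (d0 * s0sq + st$d * st$s2) / (d0 + st$d)
    se <- sqrt(post * (1 / st$n1 + 1 / st$n2))
    tstat <- st$contrast / se
    df <- st$d + d0
    p <- 2 * stats::pt(-abs(tstat), df = df)

    # fold change without MEC cells
    v_nomec <- values
    v_nomec[mec] <- NA_real_
    fc <- ova_contrast_stats(v_nomec, in_t)
    log2fc <- ifelse(fc$n1 > 0 & fc$n2 > 0, fc$contrast, NA_real_)

    res[[k]] <- data.frame(protein = rownames(values), tissue = tissues[k],
                           log2fc = log2fc, t = tstat, df = df, p = p,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  class(out) <- c("ova_test", "data.frame")
  out
}
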