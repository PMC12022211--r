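# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# literal step-up BH: q_i = min over j with p_j >= p_i of p_j * m / rank_j
brute_force_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min((p * m / r)[p >= p[i] - 1e-15 & r >= r[i]]))
  }, numeric(1))
}

# exhaustive greedy Ward agglomeration on raw coordinates; heights on the
# Euclidean (ward.D2) scale: sqrt(2 * increase in within-cluster SS)
greedy_ward <- function(x) {
  n <- nrow(x)
  cent <- x
  sizes <- rep(1, n)
  active <- seq_len(n)
  labels <- -seq_len(n)              # hclust merge convention
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      i <- active[a]; j <- active[b]
      d <- sizes[i] * sizes[j] / (sizes[i] + sizes[j]) *
        sum((cent[i, ] - cent[j, ])^2)
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[m, ] <- sort(c(labels[i], labels[j]))
    height[m] <- sqrt(2 * bestd)
    cent[i, ] <- (sizes[i] * cent[i, ] + sizes[j] * cent[j, ]) /
      (sizes[i] + sizes[j])
    sizes[i] <- sizes[i] + sizes[j]
    labels[i] <- m
    active <- setdiff(active, j)
  }
  list(merge = merge, height = height)
}

# textbook one-way fixed-effects ANOVA F p-value
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); n <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# small standard design used across unit tests: 3 tissues x 3 replicates
toy_design <- function(n_tissues = 3L, n_reps = 3L) {
  tis <- paste0("t", seq_len(n_tissues))
  rp_design(sample_id = paste(rep(tis, each = n_reps),
                              rep(seq_len(n_reps), n_tissues), sep = "_"),
            tissue = rep(tis, each = n_reps),
            replicate = rep(seq_len(n_reps), n_tissues))
}

# random complete rp_matrix on a toy design
toy_matrix <- function(n_prot = 6L, design = toy_design(), seed = 1L,
                       scale = "raw") {
  set.seed(seed)
  v <- matrix(stats::runif(n_prot * nrow(design), 1, 100), n_prot,
              dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                              design$sample_id))
  rp_matrix(v, design, scale = scale)
}
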