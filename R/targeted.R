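# PRM isotope-dilution quantification: transition-level quality filters,
# peptide-level signal, amount estimation from heavy/light ratios, reference
# normalization, and the targeted statistical layer.
#
# A transition table is a long-format data.frame with columns
#   peptide, protein, transition, channel ("endogenous"/"heavy"),
#   sample, area, snr
# one row per (peptide, transition, channel, sample). Skyline-like wide
# exports are reshaped to this layout upstream.

check_transition_table <- function(tt) {
  need <- c("peptide", "protein", "transition", "channel", "sample",
            "area", "snr")
  miss <- setdiff(need, names(tt))
  if (length(miss)) {
    stop("transition table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!all(tt$channel %in% c("endogenous", "heavy"))) {
    stop("channel must be 'endogenous' or 'heavy'")
  }
  ntr <- tapply(tt$transition, paste(tt$peptide, tt$channel),
                function(x) length(unique(x)))
  if (any(ntr > 5)) stop("more than 5 transitions for a (peptide, channel)")
  invisible(tt)
}

#' Read a transition-results table
#'
#' Reads a long-format tab- or comma-delimited PRM export with columns
#' `peptide`, `protein`, `transition`, `channel`, `sample`, `area`, `snr`.
#'
#' @param path file path.
#' @param design an [rp_design()]; samples in the file must belong to it.
#' @return A validated transition data.frame.
#' @export
read_transition_table <- function(path, design) {
  tt <- read_delim_sniff(path)
  check_transition_table(tt)
  unknown <- setdiff(unique(tt$sample), design$sample_id)
  if (length(unknown)) {
    stop("sample(s) not in design: ", paste(unknown, collapse = ", "))
  }
  tt
}

#' Discard peptides with unstable heavy-standard signal
#'
#' Computes, per peptide, the coefficient of variation (sd/mean) of the
#' peptide-level heavy signal (summed heavy transition areas) across all
#' samples of the experiment, and discards entirely every peptide whose CV
#' strictly exceeds `cv_max`. Peptides with zero mean heavy signal are
#' discarded and flagged.
#'
#' @param tt transition table (long format, see [read_transition_table()]).
#' @param cv_max CV threshold (default 0.5, i.e. 50%).
#' @return The filtered transition table; discarded peptides and their CVs
#'   are recorded in `attr(, "cv_summary")`.
#' @export
filter_heavy_cv <- function(tt, cv_max = 0.5) {
  check_transition_table(tt)
  heavy <- tt[tt$channel == "heavy", , drop = FALSE]
  sig <- tapply(heavy$area, list(heavy$peptide, heavy$sample), sum,
                na.rm = TRUE)
  cv <- apply(sig, 1, function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    if (m <= 0) return(Inf)  # flagged: no usable heavy signal
    stats::sd(x) / m
  })
  summary <- data.frame(peptide = rownames(sig), cv = cv,
                        kept = cv <= cv_max, row.names = NULL,
                        stringsAsFactors = FALSE)
  kept <- summary$peptide[summary$kept]
  out <- tt[tt$peptide %in% kept, , drop = FALSE]
  attr(out, "cv_summary") <- summary
  out
}

#' Signal-to-noise transition filter, per tissue
#'
#' Within each tissue, a transition is kept only if its signal-to-noise
#' ratio strictly exceeds `snr_min` in *all* replicates of that tissue (both
#' channels); transitions failing in a tissue are excluded for that tissue
#' only. With `scope = "global"` the requirement extends to all samples of
#' the experiment.
#'
#' @param tt transition table.
#' @param design an [rp_design()].
#' @param snr_min threshold (default 10; a ratio exactly equal to the
#'   threshold fails).
#' @param scope `"tissue"` (default) or `"global"`.
#' @return The filtered transition table.
#' @export
filter_snr <- function(tt, design, snr_min = 10, scope = c("tissue", "global")) {
  check_transition_table(tt)
  scope <- match.arg(scope)
  tissue_of <- design$tissue[match(tt$sample, design$sample_id)]
  if (anyNA(tissue_of)) stop("transition table contains samples not in design")
  key <- paste(tt$peptide, tt$transition, sep = "\r")
  if (scope == "global") {
    fail_key <- unique(key[tt$snr <= snr_min])
    return(tt[!(key %in% fail_key), , drop = FALSE])
  }
  fail <- unique(paste(key, tissue_of, sep = "\r")[tt$snr <= snr_min])
  keep <- !(paste(key, tissue_of, sep = "\r") %in% fail)
  tt[keep, , drop = FALSE]
}

#' Peptide-level signal
#'
#' Sums the surviving transition peak areas per (peptide, channel, sample).
#' Combinations with no surviving transition are absent from the output.
#'
#' @param tt transition table (after filtering).
#' @return data.frame with columns `peptide`, `channel`, `sample`, `signal`.
#' @export
peptide_signal <- function(tt) {
  check_transition_table(tt)
  agg <- stats::aggregate(area ~ peptide + channel + sample, data = tt,
                          FUN = sum)
  names(agg)[names(agg) == "area"] <- "signal"
  agg[order(agg$peptide, agg$channel, agg$sample), , drop = FALSE]
}

#' Endogenous amount from the heavy/light ratio
#'
#' Isotope-dilution quantification: `amount = (endo / heavy) * spiked`,
#' in the unit of the spiked amount (amol). A non-positive heavy signal
#' leaves the amount undefined (`NA`).
#'
#' @param endo,heavy numeric vectors of endogenous and heavy peptide-level
#'   signals.
#' @param spiked spiked heavy amount(s) in amol.
#' @return Numeric vector of endogenous amounts (amol).
#' @export
amount_from_ratio <- function(endo, heavy, spiked) {
  ifelse(is.na(heavy) | heavy <= 0, NA_real_, endo / heavy * spiked)
}

#' Peptide amounts across samples
#'
#' Runs the quantification chain on a filtered transition table: peptide
#' signals per channel, then endogenous amounts from the heavy/light ratio
#' and the spiked heavy amounts.
#'
#' @param tt filtered transition table.
#' @param spiked named numeric vector of spiked heavy amounts (amol) per
#'   peptide.
#' @return data.frame with columns `peptide`, `protein`, `sample`, `amount`.
#' @export
peptide_amounts <- function(tt, spiked) {
  sig <- peptide_signal(tt)
  wide_e <- sig[sig$channel == "endogenous", ]
  wide_h <- sig[sig$channel == "heavy", ]
  key_e <- paste(wide_e$peptide, wide_e$sample, sep = "\r")
  key_h <- paste(wide_h$peptide, wide_h$sample, sep = "\r")
  m <- match(key_e, key_h)
  miss_sp <- setdiff(unique(wide_e$peptide), names(spiked))
  if (length(miss_sp)) {
    stop("no spiked amount for peptide(s): ", paste(miss_sp, collapse = ", "))
  }
  prot <- tt$protein[match(wide_e$peptide, tt$peptide)]
  data.frame(peptide = wide_e$peptide, protein = prot,
             sample = wide_e$sample,
             amount = amount_from_ratio(wide_e$signal, wide_h$signal[m],
                                        spiked[wide_e$peptide]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize peptide amounts to a reference peptide
#'
#' Divides every amount by the amount of the reference peptide in the same
#' sample, removing sample-to-sample variation in ribosome input. The
#' reference row itself becomes 1 in every sample.
#'
#' @param amounts data.frame from [peptide_amounts()].
#' @param reference reference peptide sequence (default `"GTGIVSAPVPK"`,
#'   a proteotypic peptide of the stably incorporated Rps2).
#' @return The input data.frame with an extra `normalized_amount` column.
#' @export
normalize_to_reference <- function(amounts, reference = "GTGIVSAPVPK") {
  stopifnot(all(c("peptide", "sample", "amount") %in% names(amounts)))
  ref <- amounts[amounts$peptide == reference, ]
  samples <- unique(amounts$sample)
  missing_ref <- setdiff(samples, ref$sample[!is.na(ref$amount)])
  if (length(missing_ref)) {
    stop("reference peptide '", reference, "' not quantified in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  ref_amount <- ref$amount[match(amounts$sample, ref$sample)]
  amounts$normalized_amount <- amounts$amount / ref_amount
  amounts
}

#' Differential-abundance testing of targeted peptide amounts
#'
#' Reuses the discovery statistical layer at peptide granularity: log2 of
#' normalized amounts, one-way ANOVA across tissues with BH control,
#' moderated one-vs-all contrasts for ANOVA-positive peptides, and per-tissue
#' enriched/depleted calls. Peptides detected in at most two tissues are
#' flagged `specific` and excluded from testing.
#'
#' @param amounts data.frame from [normalize_to_reference()].
#' @param design an [rp_design()].
#' @param q_cut,fc_cut thresholds as in [classify_rps()].
#' @return A list of class `targeted_stats` with `anova` (peptide, p, q,
#'   specific), `contrasts` (with `call` column) and `specific_peptides`.
#' @export
targeted_stats <- function(amounts, design, q_cut = 0.01, fc_cut = 1.0) {
  stopifnot(all(c("peptide", "sample", "normalized_amount") %in%
                  names(amounts)))
  peptides <- sort(unique(amounts$peptide))
  values <- matrix(NA_real_, length(peptides), nrow(design),
                   dimnames = list(peptides, design$sample_id))
  idx <- cbind(match(amounts$peptide, peptides),
               match(amounts$sample, design$sample_id))
  keep <- !is.na(amounts$normalized_amount) & amounts$normalized_amount > 0
  values[idx[keep, , drop = FALSE]] <- log2(amounts$normalized_amount[keep])

  pm <- rp_matrix(values, design, scale = "log2")
  detected <- detected_tissues(pm, min_reps = 1L)
  n_det <- vapply(detected, length, integer(1))
  specific <- names(n_det)[n_det <= 2L]

  anova_p <- anova_across_tissues(pm)
  anova_p[specific] <- NA_real_
  anova_q <- bh_adjust(anova_p)
  names(anova_q) <- names(anova_p)
  positive <- names(anova_q)[!is.na(anova_q) & anova_q < q_cut]

  contrasts <- if (length(positive)) {
    cc <- one_vs_all_test(pm, proteins = positive)
    names(cc)[names(cc) == "protein"] <- "peptide"
    sig <- !is.na(cc$q) & cc$q < q_cut
    cc$call <- "ns"
    cc$call[sig & !is.na(cc$log2fc) & cc$log2fc > fc_cut] <- "enriched"
    cc$call[sig & !is.na(cc$log2fc) & cc$log2fc < -fc_cut] <- "depleted"
    cc$call[sig & is.na(cc$log2fc)] <- "not_detected"
    cc
  } else {
    data.frame(peptide = character(), tissue = character(),
               log2fc = numeric(), t = numeric(), df = numeric(),
               p = numeric(), q = numeric(), call = character())
  }
  structure(list(
    anova = data.frame(peptide = names(anova_p), p = anova_p, q = anova_q,
                       specific = names(anova_p) %in% specific,
                       row.names = NULL, stringsAsFactors = FALSE),
    contrasts = contrasts,
    specific_peptides = specific), class = "targeted_stats")
}
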