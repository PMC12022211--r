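# Synthetic multi-tissue ribosome-profiling-by-MS data with planted ground
# truth: peptide-level label-free tables, PRM transition tables and organ
# RPKM tables, all pure functions of (config, seed).

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

default_tissues <- c("cortex", "hippocampus", "olfactory_bulb", "cerebellum",
                     "retina", "heart", "muscle", "liver", "kidney",
                     "adrenal_gland", "intestine", "spleen", "lung", "testis")

#' Simulation configuration
#'
#' Study conditions for the synthetic generators: 14 tissues x 3 replicates,
#' 85 ribosomal proteins split into 59 stable, 22 variable and 4
#' tissue-specific paralogs (whose canonical partners, counted among the
#' variable, are reduced 2- to 4-fold in the paralog's host tissues), plus
#' non-RP background proteins. Replicate noise is lognormal (sd 0.3 on log2,
#' giving replicate Pearson r around 0.95-0.99); a small per-(RP, tissue)
#' organ modulation (sd 0.15 log2) gives every RP a reproducible organ
#' profile shared with the transcript side. Missingness combines an
#' abundance-dependent (MNAR, logistic in log2 intensity; a slope of 0
#' disables it) and a random (MCAR) component.
#'
#' @param n_tissues,n_reps,n_rp,n_background design dimensions.
#' @param n_stable,n_variable,n_specific RP category counts; must sum to
#'   `n_rp`. The `n_specific` paralogs pair with the first `n_specific`
#'   variable RPs as their canonical partners.
#' @param base_log2_range range of protein base log2 abundances.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param organ_sd sd of the per-(RP, tissue) organ modulation (log2).
#' @param variable_fc planted log2 fold changes cycled over the free
#'   variable RPs.
#' @param compensation_range canonical partners are reduced by a factor drawn
#'   uniformly in this range in the paralog's host tissues.
#' @param peptides_per_protein integer range of specific peptides per protein.
#' @param mnar_threshold,mnar_slope logistic MNAR missingness: a cell of
#'   log2 intensity x is missing with probability
#'   `plogis(-(x - mnar_threshold) * mnar_slope)`.
#' @param mcar_rate completely-at-random missingness rate.
#' @param n_rna_decorrelated number of variable RPs whose transcript profile
#'   is uncoupled from the protein profile.
#' @param rna_noise_sd log2 noise added on the transcript side.
#' @param prm_n_stable,prm_n_variable,prm_n_specific,prm_n_bad_cv PRM panel
#'   composition (plus one reference peptide).
#' @param prm_heavy_cv coefficient of variation of the heavy-standard signal
#'   for well-behaved peptides.
#' @param prm_noise_sd log2 noise of the endogenous/heavy ratio.
#' @param prm_spiked_range spiked heavy amounts (amol) drawn uniformly.
#' @param prm_n_low_snr number of planted (peptide, transition, tissue)
#'   signal-to-noise violations.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 14L, n_reps = 3L, n_rp = 85L,
                       n_background = 100L,
                       n_stable = 59L, n_variable = 22L, n_specific = 4L,
                       base_log2_range = c(16, 26),
                       noise_sd = 0.3, organ_sd = 0.15,
                       variable_fc = c(-2, -1.5, 1.5, 2),
                       compensation_range = c(2, 4),
                       peptides_per_protein = c(2L, 6L),
                       mnar_threshold = 14, mnar_slope = 1,
                       mcar_rate = 0.02,
                       n_rna_decorrelated = 6L, rna_noise_sd = 0.05,
                       prm_n_stable = 9L, prm_n_variable = 10L,
                       prm_n_specific = 5L, prm_n_bad_cv = 4L,
                       prm_heavy_cv = 0.1, prm_noise_sd = 0.15,
                       prm_spiked_range = c(50, 500),
                       prm_n_low_snr = 4L) {
  cfg <- as.list(environment())
  if (n_stable + n_variable + n_specific != n_rp) {
    stop("n_stable + n_variable + n_specific must equal n_rp")
  }
  if (n_tissues < 2L || n_reps < 2L) stop("need >= 2 tissues and replicates")
  if (n_specific > n_variable) {
    stop("each paralog needs a canonical partner among the variable RPs")
  }
  if (mcar_rate < 0 || mcar_rate > 1) stop("mcar_rate must be in [0, 1]")
  if (noise_sd < 0 || organ_sd < 0) stop("noise sds must be >= 0")
  if (n_rna_decorrelated > n_variable - n_specific) {
    stop("decorrelated set must fit in the free variable RPs")
  }
  structure(cfg, class = "sim_config")
}

sim_tissues <- function(n) {
  if (n <= length(default_tissues)) default_tissues[seq_len(n)]
  else c(default_tissues, sprintf("tissue%02d", seq_len(n - length(default_tissues))))
}

sim_design <- function(config) {
  tissues <- sim_tissues(config$n_tissues)
  rp_design(sample_id = paste(rep(tissues, each = config$n_reps),
                              rep(seq_len(config$n_reps), config$n_tissues),
                              sep = "_"),
            tissue = rep(tissues, each = config$n_reps),
            replicate = rep(seq_len(config$n_reps), config$n_tissues))
}

#' Simulate a label-free peptide quantification experiment
#'
#' Draws protein base abundances, plants the configured tissue effects
#' (enrichments/depletions for variable RPs, host-restricted paralogs with
#' canonical compensation), generates specific peptides with lognormal
#' replicate noise, and applies MNAR + MCAR missingness. The returned truth
#' records the planted categories and effects as well as the *expected*
#' normalized log2 tissue profiles and one-vs-all log2 fold changes, which
#' account for the RP-total normalization shift and are exact in the
#' noiseless limit.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return List with `peptides` (a [peptide_quant()]), `design`
#'   (an [rp_design()]) and `truth` (list; see Details).
#' @details `truth` contains `proteins` (data.frame with `protein`,
#'   `category`, `paralog_of`, `target_tissues`, `max_abs_fc`,
#'   `rna_decorrelated`), matrices `effects`, `tissue_profile`,
#'   `expected_log2fc` (RP x tissue), `present` (RP x tissue logical),
#'   `denominators`, `rp_ids`, `expected_missing_rate` and the `config`.
#' @export
simulate_labelfree <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    design <- sim_design(config)
    tissues <- design_tissues(design)
    nt <- length(tissues)
    rp_ids <- sprintf("RP%03d", seq_len(config$n_rp))
    bg_ids <- if (config$n_background > 0)
      sprintf("BG%03d", seq_len(config$n_background)) else character(0)

    idx_stable <- seq_len(config$n_stable)
    idx_variable <- config$n_stable + seq_len(config$n_variable)
    idx_specific <- config$n_stable + config$n_variable +
      seq_len(config$n_specific)
    idx_canonical <- idx_variable[seq_len(config$n_specific)]
    idx_free <- setdiff(idx_variable, idx_canonical)

    category <- rep("stable", config$n_rp)
    category[idx_variable] <- "variable"
    category[idx_specific] <- "tissue_specific"

    base <- stats::runif(config$n_rp, config$base_log2_range[1],
                         config$base_log2_range[2])
    # paralogs drawn from the upper half of the range: reliably detected in
    # their host tissues
    mid <- mean(config$base_log2_range)
    base[idx_specific] <- stats::runif(config$n_specific, mid,
                                       config$base_log2_range[2])

    effects <- matrix(0, config$n_rp, nt, dimnames = list(rp_ids, tissues))
    present <- matrix(TRUE, config$n_rp, nt, dimnames = list(rp_ids, tissues))
    paralog_of <- rep(NA_character_, config$n_rp)
    target_tissues <- rep("", config$n_rp)

    # paralog pairs: paralog restricted to 1-2 host tissues, canonical
    # reduced by the compensation factor there
    for (j in seq_len(config$n_specific)) {
      hosts <- sample(tissues, sample(1:2, 1))
      par <- idx_specific[j]; can <- idx_canonical[j]
      present[par, setdiff(tissues, hosts)] <- FALSE
      comp <- stats::runif(1, config$compensation_range[1],
                           config$compensation_range[2])
      effects[can, hosts] <- -log2(comp)
      paralog_of[par] <- rp_ids[can]
      target_tissues[par] <- paste(hosts, collapse = ",")
      target_tissues[can] <- paste(hosts, collapse = ",")
    }

    # free variable RPs: 1-2 target tissues, planted log2 fold changes
    fc_pool <- rep(config$variable_fc, length.out = length(idx_free))
    for (j in seq_along(idx_free)) {
      g <- idx_free[j]
      n_tgt <- 1L + (j %% 2L)
      tgt <- sample(tissues, n_tgt)
      effects[g, tgt[1]] <- fc_pool[j]
      if (n_tgt == 2L) effects[g, tgt[2]] <- -fc_pool[j]
      target_tissues[g] <- paste(tgt, collapse = ",")
    }

    # small organ modulation shared with the transcript side (row-centered)
    delta <- matrix(stats::rnorm(config$n_rp * nt, 0, config$organ_sd),
                    config$n_rp, nt)
    delta <- delta - rowMeans(delta)

    # peptides: 2-6 specific peptides per protein (RP and background),
    # drawn before the expected totals so the per-protein iBAQ constants
    # (summed peptide detectabilities / denominator) enter the expected
    # per-tissue RP totals and the noiseless expectations are exact
    all_ids <- c(rp_ids, bg_ids)
    n_all <- length(all_ids)
    npep <- sample(config$peptides_per_protein[1]:config$peptides_per_protein[2],
                   n_all, replace = TRUE)
    pep_prot <- rep(all_ids, npep)
    pep_id <- paste0(pep_prot, "_p", unlist(lapply(npep, seq_len)))
    eff <- stats::runif(length(pep_id), -2, 0)   # log2 detectability
    denominators <- stats::setNames(sample(5:40, n_all, replace = TRUE),
                                    all_ids)
    ibaq_const <- tapply(2^eff, factor(pep_prot, levels = all_ids), sum) /
      denominators
    c_rp <- as.numeric(ibaq_const[rp_ids])

    mu <- base + effects + delta            # expected log2 raw abundance
    lin <- (2^mu * c_rp) * present
    s_t <- colSums(lin)                     # expected per-tissue RP iBAQ total
    # expected log2 normalized abundance, up to a per-RP additive constant
    # (the iBAQ constant, which cancels in contrasts and per-RP centering)
    profile <- sweep(mu, 2, log2(s_t))
    profile[!present] <- NA_real_
    expected_fc <- matrix(NA_real_, config$n_rp, nt,
                          dimnames = list(rp_ids, tissues))
    complete <- rowSums(present) == nt
    for (t in seq_len(nt)) {
      expected_fc[complete, t] <- profile[complete, t] -
        rowMeans(profile[complete, -t, drop = FALSE])
    }

    rna_decorrelated <- rep(FALSE, config$n_rp)
    if (config$n_rna_decorrelated > 0) {
      rna_decorrelated[sample(idx_free, config$n_rna_decorrelated)] <- TRUE
    }

    mu_all <- rbind(mu, matrix(stats::runif(config$n_background,
                                            config$base_log2_range[1],
                                            config$base_log2_range[2]),
                               config$n_background, nt,
                               dimnames = list(bg_ids, tissues)))
    present_all <- rbind(present,
                         matrix(TRUE, config$n_background, nt,
                                dimnames = list(bg_ids, tissues)))
    tissue_of <- design$tissue
    pi <- match(pep_prot, all_ids)
    ti <- match(tissue_of, tissues)
    lmat <- mu_all[pi, ti, drop = FALSE] + eff +
      matrix(stats::rnorm(length(pep_id) * nrow(design), 0, config$noise_sd),
             length(pep_id), nrow(design))
    absent <- !present_all[pi, ti, drop = FALSE]
    lmat[absent] <- NA_real_

    p_mnar <- if (config$mnar_slope > 0) {
      stats::plogis(-(lmat - config$mnar_threshold) * config$mnar_slope)
    } else {
      matrix(0, nrow(lmat), ncol(lmat))
    }
    p_mnar[is.na(lmat)] <- 0
    miss <- matrix(stats::runif(length(lmat)) < p_mnar, nrow(lmat)) |
      matrix(stats::runif(length(lmat)) < config$mcar_rate, nrow(lmat))
    p_any <- 1 - (1 - p_mnar) * (1 - config$mcar_rate)
    expected_missing_rate <- mean(p_any[!is.na(lmat)])

    values <- 2^lmat
    values[miss] <- NA_real_
    dimnames(values) <- list(NULL, design$sample_id)

    info <- data.frame(peptide = pep_id, protein = pep_prot,
                       specific = TRUE, stringsAsFactors = FALSE)
    truth <- list(
      proteins = data.frame(
        protein = rp_ids, category = category, paralog_of = paralog_of,
        target_tissues = target_tissues,
        max_abs_fc = apply(abs(effects), 1, max),
        rna_decorrelated = rna_decorrelated,
        row.names = NULL, stringsAsFactors = FALSE),
      effects = effects, tissue_profile = profile,
      expected_log2fc = expected_fc, present = present,
      denominators = denominators, rp_ids = rp_ids,
      expected_missing_rate = expected_missing_rate,
      config = config)
    list(peptides = peptide_quant(info, values, design),
         design = design, truth = truth)
  })
}

#' Simulate a PRM isotope-dilution experiment
#'
#' Builds a transition table over 6 tissues x 3 replicates: one reference
#' peptide (`GTGIVSAPVPK`, stable), stable peptides, variable peptides with a
#' planted 4-fold enrichment or depletion in one tissue, tissue-specific
#' peptides present in only 1-2 tissues, and peptides whose heavy-standard
#' signal is deliberately unstable (alternating +-80%, realized CV about
#' 0.75) to exercise the CV filter. Five mono-charged y-ion transitions per
#' peptide and channel; signal-to-noise values grow with the transition area
#' and stay above 10 except for the planted violations.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `transitions` (long-format transition table), `spiked`
#'   (named amol amounts), `design` and `truth` (data.frame `peptides` with
#'   planted categories/effects, `true_amount` matrix (amol, peptide x
#'   tissue), `bad_cv_peptides`, `low_snr` data.frame, `reference`).
#' @export
simulate_prm <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    tissues <- c("hippocampus", "retina", "muscle", "heart", "liver",
                 "testis")
    n_reps <- config$n_reps
    design <- rp_design(
      sample_id = paste(rep(tissues, each = n_reps),
                        rep(seq_len(n_reps), length(tissues)), sep = "_"),
      tissue = rep(tissues, each = n_reps),
      replicate = rep(seq_len(n_reps), length(tissues)))
    nt <- length(tissues)

    n_pep <- 1L + config$prm_n_stable + config$prm_n_variable +
      config$prm_n_specific + config$prm_n_bad_cv
    category <- c("reference", rep("stable", config$prm_n_stable),
                  rep("variable", config$prm_n_variable),
                  rep("specific", config$prm_n_specific),
                  rep("bad_cv", config$prm_n_bad_cv))
    aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
    pep_seq <- c("GTGIVSAPVPK", vapply(seq_len(n_pep - 1L), function(i) {
      paste0(paste(sample(aa, sample(7:11, 1), replace = TRUE),
                   collapse = ""), sample(c("K", "R"), 1))
    }, character(1)))
    protein <- c("Rps2", paste0("TP", sprintf("%02d", seq_len(n_pep - 1L))))

    spiked <- stats::setNames(
      stats::runif(n_pep, config$prm_spiked_range[1],
                   config$prm_spiked_range[2]), pep_seq)
    resp <- stats::runif(n_pep, 0.5, 2)          # signal per amol
    ratio_base <- stats::runif(n_pep, 0.2, 2)    # endo/heavy baseline
    ratio_base[1] <- 1

    effects <- matrix(0, n_pep, nt, dimnames = list(pep_seq, tissues))
    present <- matrix(TRUE, n_pep, nt, dimnames = list(pep_seq, tissues))
    target <- rep("", n_pep)
    i_var <- which(category == "variable")
    for (j in seq_along(i_var)) {
      tgt <- sample(tissues, 1)
      effects[i_var[j], tgt] <- if (j %% 2L) -2 else 2   # 4-fold change
      target[i_var[j]] <- tgt
    }
    for (i in which(category == "specific")) {
      hosts <- sample(tissues, sample(1:2, 1))
      present[i, setdiff(tissues, hosts)] <- FALSE
      target[i] <- paste(hosts, collapse = ",")
    }

    # transition fractions (5 y-ions per peptide, shared across channels)
    frac <- matrix(stats::runif(n_pep * 5, 0.5, 1.5), n_pep, 5)
    frac <- frac / rowSums(frac)

    sdlog2 <- sqrt(log2(1 + config$prm_heavy_cv^2))  # lognormal on log2
    n_s <- nrow(design)
    ti <- match(design$tissue, tissues)
    heavy_pep <- matrix(spiked * resp, n_pep, n_s) *
      2^matrix(stats::rnorm(n_pep * n_s, 0, sdlog2), n_pep, n_s)
    bad <- category == "bad_cv"
    if (any(bad)) {   # alternating +-80%: realized CV ~ 0.75, robustly > 0.5
      alt <- matrix(rep_len(c(0.2, 1.8), n_s), sum(bad), n_s, byrow = TRUE)
      heavy_pep[bad, ] <- heavy_pep[bad, , drop = FALSE] * alt
    }
    ratio <- (ratio_base * 2^effects)[, ti, drop = FALSE] *
      2^matrix(stats::rnorm(n_pep * n_s, 0, config$prm_noise_sd), n_pep, n_s)
    endo_pep <- heavy_pep * ratio

    rows <- vector("list", n_pep * 5L * 2L)
    k <- 0L
    for (i in seq_len(n_pep)) {
      for (tr in 1:5) {
        for (ch in c("heavy", "endogenous")) {
          pep_lvl <- if (ch == "heavy") heavy_pep[i, ] else endo_pep[i, ]
          keep <- if (ch == "endogenous") present[i, ti] else rep(TRUE, n_s)
          if (!any(keep)) next
          area <- pep_lvl[keep] * frac[i, tr]
          snr <- 15 + 40 * area / (spiked[i] * resp[i] * frac[i, tr])
          k <- k + 1L
          rows[[k]] <- data.frame(
            peptide = pep_seq[i], protein = protein[i],
            transition = paste0("y", tr + 3L), channel = ch,
            sample = design$sample_id[keep], area = area, snr = snr,
            row.names = NULL, stringsAsFactors = FALSE)
        }
      }
    }
    tt <- do.call(rbind, rows[seq_len(k)])

    # planted signal-to-noise violations on otherwise good peptides
    good <- which(category %in% c("stable", "variable"))
    low_snr <- data.frame(peptide = character(), transition = character(),
                          tissue = character(), stringsAsFactors = FALSE)
    if (config$prm_n_low_snr > 0 && length(good)) {
      pick_pep <- sample(good, config$prm_n_low_snr, replace = TRUE)
      for (i in seq_along(pick_pep)) {
        p <- pep_seq[pick_pep[i]]
        tr <- paste0("y", sample(4:8, 1))
        tis <- sample(tissues, 1)
        if (any(low_snr$peptide == p & low_snr$transition == tr &
                  low_snr$tissue == tis)) next
        rep_hit <- sample(seq_len(n_reps), 1)
        hit <- tt$peptide == p & tt$transition == tr &
          tt$channel == "endogenous" &
          tt$sample == paste(tis, rep_hit, sep = "_")
        tt$snr[hit] <- stats::runif(1, 2, 9.5)
        low_snr <- rbind(low_snr, data.frame(peptide = p, transition = tr,
                                             tissue = tis,
                                             stringsAsFactors = FALSE))
      }
    }

    true_amount <- (ratio_base * 2^effects) * spiked
    true_amount[!present] <- NA_real_
    truth <- list(
      peptides = data.frame(peptide = pep_seq, protein = protein,
                            category = category, target_tissue = target,
                            spiked = unname(spiked),
                            row.names = NULL, stringsAsFactors = FALSE),
      true_amount = true_amount, present = present,
      bad_cv_peptides = pep_seq[bad], low_snr = low_snr,
      reference = "GTGIVSAPVPK", config = config)
    list(transitions = tt, spiked = spiked, design = design, truth = truth)
  })
}

#' Simulate an organ-level RPKM table from planted protein truth
#'
#' Transcript abundances for 7 shared organs are generated from the truth's
#' expected protein tissue profiles: concordant RPs get RPKM proportional to
#' 2^(profile) with small lognormal noise; RPs flagged decorrelated get an
#' uncoupled profile (flat plus an inverted, damped copy of the protein
#' effects - emulating transcripts whose organ pattern does not follow the
#' ribosomal fraction). Paralog genes get RPKM 0 (not detected) outside
#' their host organs.
#'
#' @param truth the `truth` element of [simulate_labelfree()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `rpkm` (gene x organ matrix; organ names on the
#'   transcript-side vocabulary with `brain` for cortex and `gland` for
#'   adrenal gland), `organ_map` (protein-side name -> transcript-side
#'   name) and `decorrelated` (character vector of gene ids).
#' @export
simulate_rpkm <- function(truth, config = truth$config, seed = 1L) {
  with_seed(seed, {
    organ_map <- c(cortex = "brain", adrenal_gland = "gland",
                   heart = "heart", kidney = "kidney", liver = "liver",
                   lung = "lung", testis = "testis")
    prot_tissues <- intersect(names(organ_map),
                              colnames(truth$tissue_profile))
    if (length(prot_tissues) < 3L) {
      stop("truth does not cover enough of the shared organs")
    }
    organ_map <- organ_map[prot_tissues]
    prof <- truth$tissue_profile[, prot_tissues, drop = FALSE]
    present <- truth$present[, prot_tissues, drop = FALSE]
    genes <- rownames(prof)
    n_g <- length(genes); n_o <- length(prot_tissues)

    centered <- prof - rowMeans(prof, na.rm = TRUE)
    centered[is.na(centered)] <- 0
    decor <- truth$proteins$rna_decorrelated
    rna_rel <- centered
    # uncoupled transcripts: a damped, inverted copy of the protein profile
    rna_rel[decor, ] <- -0.5 * centered[decor, , drop = FALSE]
    rna_rel <- rna_rel +
      matrix(stats::rnorm(n_g * n_o, 0, config$rna_noise_sd), n_g, n_o)

    # RP transcripts are uniformly highly expressed: a narrow base range
    # keeps the per-organ renormalization from being dominated by a few genes
    base <- stats::runif(n_g, 5, 8)          # log2 RPKM scale
    rpkm <- 2^(base + rna_rel)
    rpkm[!present] <- 0                      # paralogs absent outside hosts
    colnames(rpkm) <- unname(organ_map)
    rownames(rpkm) <- genes
    list(rpkm = rpkm, organ_map = organ_map,
         decorrelated = genes[decor])
  })
}
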