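# Classification of RPs into stable / variable / tissue-specific, and the
# end-to-end discovery pipeline gluing the label-free steps together.

#' Classify ribosomal proteins as stable, variable or tissue-specific
#'
#' Applies the decision rules of the discovery analysis:
#' \itemize{
#'   \item *tissue-specific*: detected in at most two tissues;
#'   \item *variable*: ANOVA q-value below `q_cut` and at least one tissue
#'     with a one-vs-all contrast q-value below `q_cut` and
#'     `|log2FC| > fc_cut`;
#'   \item *stable*: everything else.
#' }
#' Per-tissue calls accompany the categories: `enriched` (contrast
#' `q < q_cut` and `log2fc > fc_cut`), `depleted` (`q < q_cut`,
#' `log2fc < -fc_cut`), `not_detected` (`q < q_cut`, fold change undefined
#' because one side had only MEC cells), otherwise `ns`.
#'
#' @param contrasts an `ova_test` data.frame from [one_vs_all_test()],
#'   restricted to ANOVA-positive proteins.
#' @param anova_q named numeric vector of per-protein ANOVA q-values (over
#'   all proteins to classify).
#' @param detected named list from [detected_tissues()] giving, per protein,
#'   the tissues in which it was reliably detected.
#' @param q_cut q-value threshold (default 0.01).
#' @param fc_cut absolute log2 fold-change threshold (default 1.0).
#' @return A list of class `rp_classification` with elements
#'   `categories` (data.frame `protein`, `category`, `n_detected_tissues`),
#'   `contrasts` (the input contrasts with a `call` column), `anova_q`,
#'   `q_cut`, `fc_cut`.
#' @export
classify_rps <- function(contrasts, anova_q, detected,
                         q_cut = 0.01, fc_cut = 1.0) {
  proteins <- names(anova_q)
  if (is.null(proteins)) stop("anova_q must be a named vector")
  n_det <- vapply(detected[proteins], length, integer(1))

  call <- rep("ns", nrow(contrasts))
  sig <- !is.na(contrasts$q) & contrasts$q < q_cut
  call[sig & !is.na(contrasts$log2fc) & contrasts$log2fc > fc_cut] <- "enriched"
  call[sig & !is.na(contrasts$log2fc) & contrasts$log2fc < -fc_cut] <- "depleted"
  call[sig & is.na(contrasts$log2fc)] <- "not_detected"
  contrasts$call <- call

  hit <- contrasts$protein[call %in% c("enriched", "depleted")]
  category <- ifelse(
    n_det <= 2L, "tissue_specific",
    ifelse(!is.na(anova_q) & anova_q < q_cut & proteins %in% hit,
           "variable", "stable"))
  structure(list(
    categories = data.frame(protein = proteins, category = category,
                            n_detected_tissues = n_det,
                            row.names = NULL, stringsAsFactors = FALSE),
    contrasts = contrasts, anova_q = anova_q,
    q_cut = q_cut, fc_cut = fc_cut), class = "rp_classification")
}

#' @export
print.rp_classification <- function(x, ...) {
  tab <- table(factor(x$categories$category,
                      levels = c("stable", "variable", "tissue_specific")))
  cat(sprintf("RP classification (q < %g, |log2FC| > %g): %d stable, %d variable, %d tissue-specific\n",
              x$q_cut, x$fc_cut, tab["stable"], tab["variable"],
              tab["tissue_specific"]))
  invisible(x)
}

#' Run the full label-free discovery analysis on an iBAQ matrix
#'
#' Chains the discovery steps: detection filtering, normalization to the RP
#' total, log2 transform with POV/MEC imputation, one-way ANOVA with BH
#' control, moderated one-vs-all contrasts on ANOVA-positive proteins
#' (tissue-specific RPs, detected in at most two tissues, are set aside
#' before testing), and classification.
#'
#' @param mat an [rp_matrix()] of raw iBAQ values (RP rows and optionally
#'   background rows).
#' @param rp_ids character vector of ribosomal-protein row ids.
#' @param q_cut,fc_cut classification thresholds (defaults 0.01 and 1.0).
#' @param rng_seed seed threaded to the imputation step.
#' @param exclude_mec passed to [anova_across_tissues()].
#' @return A list of class `rp_pipeline` with elements `filtered`,
#'   `normalized`, `imputed` (rp_matrix stages), `anova` (data.frame
#'   `protein`, `p`, `q`), `contrasts`, `classification`, `detected`.
#' @export
run_labelfree <- function(mat, rp_ids, q_cut = 0.01, fc_cut = 1.0,
                          rng_seed = 1L, exclude_mec = FALSE) {
  filtered <- filter_detection(mat)
  normalized <- normalize_to_rp_total(filtered, rp_ids, restrict = TRUE)
  imputed <- log2_and_impute(normalized, rng_seed = rng_seed)
  detected <- detected_tissues(normalized)
  n_det <- vapply(detected, length, integer(1))
  testable <- rownames(imputed$values)[n_det > 2L]

  anova_p <- anova_across_tissues(imputed, exclude_mec = exclude_mec)
  anova_p[setdiff(names(anova_p), testable)] <- NA_real_
  anova_q <- bh_adjust(anova_p)
  names(anova_q) <- names(anova_p)

  positive <- names(anova_q)[!is.na(anova_q) & anova_q < q_cut]
  contrasts <- if (length(positive)) {
    one_vs_all_test(imputed, proteins = positive)
  } else {
    data.frame(protein = character(), tissue = character(),
               log2fc = numeric(), t = numeric(), df = numeric(),
               p = numeric(), q = numeric())
  }
  classification <- classify_rps(contrasts, anova_q, detected,
                                 q_cut = q_cut, fc_cut = fc_cut)
  structure(list(filtered = filtered, normalized = normalized,
                 imputed = imputed,
                 anova = data.frame(protein = names(anova_p), p = anova_p,
                                    q = anova_q, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 contrasts = classification$contrasts,
                 classification = classification,
                 detected = detected), class = "rp_pipeline")
}
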