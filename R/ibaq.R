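# iBAQ: summed specific-peptide intensity divided by the number of
# theoretically observable tryptic peptides of the protein.

#' Count theoretically observable tryptic peptides
#'
#' In-silico digestion used for the iBAQ denominator: cleavage C-terminal to
#' every K or R (Trypsin/P rule, i.e. including before proline), zero missed
#' cleavages, keeping fully tryptic peptides of length 7 to 30 residues.
#' Proteins whose digest yields no peptide in the window still get a
#' denominator of 1 so that iBAQ stays defined.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet; `X`
#'   tolerated). May be a character vector; the count is computed per element.
#' @param len_range integer length-2 vector, the observable peptide length
#'   window (default `c(7, 30)`).
#' @return Integer vector of peptide counts, each at least 1.
#' @examples
#' insilico_tryptic_count("MKRAAAAAAK")  # only "AAAAAAK" is in the window
#' @export
insilico_tryptic_count <- function(sequence, len_range = c(7L, 30L)) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("sequence must be non-empty")
    s <- toupper(s)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s)) {
      stop("sequence contains non-amino-acid characters: ", s)
    }
    # cut after every K/R (Trypsin/P: no proline exception)
    pieces <- strsplit(gsub("(?<=[KR])", "\r", s, perl = TRUE), "\r")[[1]]
    n <- sum(nchar(pieces) >= len_range[1] & nchar(pieces) <= len_range[2])
    max(n, 1L)
  }, integer(1), USE.NAMES = !is.null(names(sequence)))
}

#' Compute protein iBAQ from specific peptide abundances
#'
#' For each protein and sample, iBAQ is the sum of the abundances of the
#' protein's *specific* peptides observed in that sample, divided by the
#' protein's count of theoretically observable tryptic peptides. Samples in
#' which no specific peptide was observed yield a missing value. Non-specific
#' (shared) peptides never contribute.
#'
#' @param peptides a [peptide_quant()] table.
#' @param denominators named integer vector mapping protein id to its
#'   observable-peptide count (e.g. from [insilico_tryptic_count()] on the
#'   protein's FASTA sequence).
#' @return An [rp_matrix()] (`scale = "raw"`), one row per protein with at
#'   least one specific peptide.
#' @export
compute_ibaq <- function(peptides, denominators) {
  stopifnot(inherits(peptides, "peptide_quant"))
  spec <- peptides$info$specific
  proteins <- sort(unique(peptides$info$protein[spec]))
  if (length(proteins) == 0L) stop("no specific peptides in table")
  missing_den <- proteins[!(proteins %in% names(denominators))]
  if (length(missing_den)) {
    stop("missing iBAQ denominator for protein(s): ",
         paste(missing_den, collapse = ", "))
  }
  den <- denominators[proteins]
  if (any(is.na(den)) || any(den < 1)) {
    stop("iBAQ denominators must be positive integers")
  }
  vals <- peptides$values[spec, , drop = FALSE]
  grp <- factor(peptides$info$protein[spec], levels = proteins)
  out <- matrix(NA_real_, length(proteins), ncol(vals),
                dimnames = list(proteins, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    obs <- !is.na(vals[, j])
    if (!any(obs)) next
    sums <- tapply(vals[obs, j], grp[obs], sum)
    out[names(sums)[!is.na(sums)], j] <- sums[!is.na(sums)]
  }
  out <- out / as.numeric(den)
  rp_matrix(out, peptides$design, scale = "raw")
}
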