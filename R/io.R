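# Readers and writers for the wide tabular formats the pipeline touches.
# Tables are UTF-8, tab- or comma-delimited (sniffed on the header line);
# missing cells are encoded as empty or "NA". A stored intensity of 0 means
# "not observed" and becomes NA in quantification tables.

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

# split a wide quant table into meta columns + sample value matrix,
# validating the sample set against the design
split_wide_table <- function(tab, meta_cols, design, what) {
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  value_cols <- setdiff(names(tab), meta_cols)
  unknown <- setdiff(value_cols, design$sample_id)
  if (length(unknown)) {
    stop("sample column(s) not in design: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(design$sample_id, value_cols)
  if (length(absent)) {
    stop("design sample(s) missing from ", what, ": ",
         paste(absent, collapse = ", "))
  }
  values <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(values) <- "double"
  values[!is.na(values) & values == 0] <- NA_real_  # 0 = not observed
  list(meta = tab[, meta_cols, drop = FALSE], values = values)
}

#' Read a wide peptide quantification table
#'
#' Expects columns `peptide`, `protein`, `specific` (logical or 0/1) followed
#' by one abundance column per sample of the design. Blank, `NA` and zero
#' cells are stored as missing.
#'
#' @param path path to a tab- or comma-delimited file.
#' @param design an [rp_design()]; sample columns must match it exactly.
#' @return A [peptide_quant()] object.
#' @export
read_peptide_table <- function(path, design) {
  tab <- read_delim_sniff(path)
  parts <- split_wide_table(tab, c("peptide", "protein", "specific"),
                            design, "peptide table")
  info <- parts$meta
  sp <- info$specific
  if (is.character(sp)) {
    lg <- as.logical(sp)
    if (anyNA(lg)) lg <- suppressWarnings(as.numeric(sp)) != 0
    sp <- lg
  } else {
    sp <- as.logical(sp)
  }
  if (anyNA(sp)) stop("'specific' column must be logical or 0/1")
  info$specific <- sp
  if (any(parts$values < 0, na.rm = TRUE)) {
    stop("negative peptide abundance encountered")
  }
  peptide_quant(info, parts$values, design)
}

#' Read a wide protein quantification matrix
#'
#' Entry point when protein-level iBAQ values are supplied directly. Expects
#' a `protein` column followed by one abundance column per sample.
#'
#' @inheritParams read_peptide_table
#' @return An [rp_matrix()] with `scale = "raw"`, all present cells marked
#'   observed.
#' @export
read_protein_matrix <- function(path, design) {
  tab <- read_delim_sniff(path)
  parts <- split_wide_table(tab, "protein", design, "protein matrix")
  if (any(!is.na(parts$values) & parts$values < 0)) {
    stop("negative abundance encountered in protein matrix")
  }
  values <- parts$values
  rownames(values) <- as.character(parts$meta$protein)
  rp_matrix(values, design, scale = "raw")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]; the protein id is the
#' first whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of amino-acid sequences; names are the
#'   protein ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  seqs
}

# fixed output precision: 10 significant digits
format_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Write a pipeline result as a deterministic TSV
#'
#' Writes any pipeline output (an [rp_matrix()], a [peptide_quant()], or a
#' plain data.frame) as a tab-separated file with deterministic row order
#' (ascending protein/peptide id, where one exists) and floats at a fixed
#' precision of 10 significant digits. Missing cells are written as `NA`.
#'
#' @param result the object to write.
#' @param path destination path.
#' @return Invisibly, the path.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "rp_matrix")) {
    df <- data.frame(protein = rownames(result$values),
                     as.data.frame(result$values), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- df[order(df$protein), , drop = FALSE]
  } else if (inherits(result, "peptide_quant")) {
    df <- cbind(result$info,
                as.data.frame(result$values, optional = TRUE))
    df <- df[order(df$peptide, df$protein), , drop = FALSE]
  } else if (is.data.frame(result)) {
    df <- result
    key <- intersect(c("protein", "peptide"), names(df))
    if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
  } else {
    stop("don't know how to write an object of class ",
         paste(class(result), collapse = "/"))
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ok <- try(utils::write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write ", path)
  invisible(path)
}
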