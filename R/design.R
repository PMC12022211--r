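#' Sample design for a multi-tissue quantification experiment
#'
#' Builds and validates the sample-to-tissue mapping used throughout the
#' pipeline. Each row describes one MS run: a unique sample identifier, the
#' tissue (biological condition) it belongs to, and a replicate index unique
#' within its tissue.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param tissue character vector of tissue labels (at least 2 distinct
#'   tissues are required for any differential analysis, but a single-tissue
#'   design is accepted for purely descriptive use).
#' @param replicate positive integer vector; replicate index within tissue.
#'
#' @return A `data.frame` of class `rp_design` with columns `sample_id`,
#'   `tissue`, `replicate`.
#' @examples
#' rp_design(c("liver_1", "liver_2", "testis_1", "testis_2"),
#'           c("liver", "liver", "testis", "testis"), c(1, 2, 1, 2))
#' @export
rp_design <- function(sample_id, tissue, replicate) {
  sample_id <- as.character(sample_id)
  tissue <- as.character(tissue)
  replicate <- as.integer(replicate)
  n <- length(sample_id)
  if (length(tissue) != n || length(replicate) != n) {
    stop("sample_id, tissue and replicate must have equal length")
  }
  if (n == 0L) stop("design must contain at least one sample")
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  if (anyDuplicated(paste(tissue, replicate, sep = "\r"))) {
    stop("replicate indices must be unique within each tissue")
  }
  d <- data.frame(sample_id = sample_id, tissue = tissue,
                  replicate = replicate, stringsAsFactors = FALSE)
  class(d) <- c("rp_design", "data.frame")
  d
}

#' Read a sample design file
#'
#' Reads a tab- or comma-delimited file with columns `sample_id`, `tissue`,
#' `replicate` and validates it with [rp_design()].
#'
#' @param path path to the design file.
#' @return An `rp_design` object.
#' @export
read_design <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("sample_id", "tissue", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("design file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  rp_design(tab$sample_id, tab$tissue, tab$replicate)
}

# tissues in first-appearance order
design_tissues <- function(design) unique(design$tissue)

# sample ids of one tissue
tissue_samples <- function(design, tissue) {
  design$sample_id[design$tissue == tissue]
}
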