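#' Read a FASTQ file into a read tibble
#'
#' Thin wrapper around `Biostrings::readQualityScaledDNAStringSet()`; gzip
#' input is handled transparently. The returned tibble is the read
#' representation used throughout the package.
#'
#' @param path Path to a FASTQ (optionally gzipped) file.
#' @return Tibble with columns `read_id`, `sequence`, `quality` (Phred+33).
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTQ requires the Biostrings package")
  }
  x <- tryCatch(
    Biostrings::readQualityScaledDNAStringSet(path),
    error = function(e) abort(sprintf("unreadable FASTQ '%s': %s", path, conditionMessage(e)))
  )
  # as.character drops metadata columns with a chatty warning; silence it
  suppressWarnings(tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x))
  ))
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads_tbl(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$quality), con)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome (named character vector) as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  lines <- unlist(lapply(names(genome), function(nm) c(paste0(">", nm), genome[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

# generic TSV writers: exported tables use 1-based inclusive coordinates,
# documented in a header line
write_tsv_with_header <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment design table
#'
#' The design maps samples to sets (samples processed and sequenced
#' together), conditions, and time-zero status. Every set must contain at
#' least one time-zero sample and sample ids must be unique.
#'
#' @param path Path to a TSV with columns `sample_id`, `set_id`, `condition`,
#'   `is_time_zero`, `replicate_group`.
#' @return Validated design tibble.
#' @export
read_design <- function(path) {
  d <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#"))
  d$is_time_zero <- as.logical(d$is_time_zero)
  validate_design(d)
}

#' Validate an experiment design tibble
#'
#' @param design Tibble with columns `sample_id`, `set_id`, `condition`,
#'   `is_time_zero`, `replicate_group`.
#' @return The design, invisibly validated (returned unchanged).
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "set_id", "condition", "is_time_zero")
  if (!all(need %in% names(design))) {
    abort(sprintf("design must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("design sample_ids must be unique")
  no_t0 <- design |>
    summarise(has_t0 = any(.data$is_time_zero), .by = "set_id") |>
    filter(!.data$has_t0)
  if (nrow(no_t0)) {
    abort(sprintf("set(s) without a time-zero sample: %s",
                  paste(no_t0$set_id, collapse = ", ")))
  }
  if (!"replicate_group" %in% names(design)) design$replicate_group <- design$condition
  design
}
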