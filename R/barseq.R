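#' Count barcodes in one BarSeq sample
#'
#' Tallies barcodes with [tally_barcodes()] and removes one-substitution
#' artifacts with [filter_one_off_barcodes()].
#'
#' @param reads Read tibble for one sample.
#' @param spec [flank_spec()] for the counted barcode (UP by default in a
#'   Dub-seq assay; pass the DOWN spec for a DOWN-tag concordance run).
#' @return Filtered count tibble with attributes `total_reads` and
#'   `usable_reads`.
#' @export
count_sample <- function(reads, spec) {
  filter_one_off_barcodes(tally_barcodes(reads, spec))
}

#' Assemble the sample-by-barcode count table restricted to the reference
#'
#' Combines per-sample barcode counts into one long table over the reference
#' UP barcodes; barcodes observed in a sample but absent from the reference
#' are summed into that sample's unmapped tally, and barcode-sample
#' combinations with no reads get a zero.
#'
#' @param sample_counts Named list of per-sample count tibbles (names are
#'   sample ids), e.g. from [count_sample()].
#' @param reference Reference fragment tibble ([build_reference_set()]).
#' @param design Experiment design tibble (see [validate_design()]).
#' @return Long tibble with columns `barcode`, `sample_id`, `count` (class
#'   `dubseq_counts`), with a `sample_stats` attribute tibble
#'   (`sample_id`, `total_reads`, `usable_reads`, `mapped_reads`,
#'   `unmapped_reads`).
#' @export
assemble_count_matrix <- function(sample_counts, reference, design) {
  design <- validate_design(design)
  missing <- setdiff(design$sample_id, names(sample_counts))
  if (length(missing)) {
    abort(sprintf("design sample(s) missing from counts: %s",
                  paste(missing, collapse = ", ")))
  }
  ref_barcodes <- reference$up
  long <- bind_rows(sample_counts[design$sample_id], .id = "sample_id")
  stats <- tibble(
    sample_id = design$sample_id,
    total_reads = unname(vapply(sample_counts[design$sample_id], function(x)
      attr(x, "total_reads") %||% NA_integer_, numeric(1))),
    usable_reads = unname(vapply(sample_counts[design$sample_id], function(x)
      sum(x$count), numeric(1)))
  )
  mapped <- long |> filter(.data$barcode %in% ref_barcodes)
  stats <- stats |>
    left_join(mapped |> summarise(mapped_reads = sum(.data$count),
                                  .by = "sample_id"),
              by = "sample_id") |>
    mutate(mapped_reads = coalesce(.data$mapped_reads, 0),
           unmapped_reads = .data$usable_reads - .data$mapped_reads)
  out <- tidyr::expand_grid(barcode = ref_barcodes,
                            sample_id = design$sample_id) |>
    left_join(mapped, by = c("barcode", "sample_id")) |>
    mutate(count = coalesce(.data$count, 0L))
  attr(out, "sample_stats") <- stats
  class(out) <- c("dubseq_counts", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
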