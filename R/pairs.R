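#' Associate UP and DOWN barcodes from BPseq reads
#'
#' Each BPseq read carries both random barcodes of one plasmid at known
#' relative positions. Both barcodes are extracted with their own
#' [flank_spec()]; reads yielding only one barcode are counted as unusable.
#' The UP and DOWN barcode tables are then cleaned independently with
#' [filter_one_off_barcodes()] and pairs containing a removed barcode are
#' dropped.
#'
#' @param reads BPseq read tibble (`read_id`, `sequence`, `quality`).
#' @param up_spec,down_spec [flank_spec()] for the UP and DOWN barcode.
#' @return Tibble with columns `up`, `down`, `count`, one row per surviving
#'   barcode pair, with attributes `total_reads` (input reads) and
#'   `paired_reads` (reads yielding both barcodes).
#' @export
associate_barcode_pairs <- function(reads, up_spec, down_spec) {
  up <- extract_barcodes(reads, up_spec)
  dn <- extract_barcodes(reads, down_spec)
  paired <- inner_join(
    select(up, "read_id", up = "barcode"),
    select(dn, "read_id", down = "barcode"),
    by = "read_id"
  )
  pairs <- paired |>
    count(.data$up, .data$down, name = "count") |>
    arrange(desc(.data$count), .data$up, .data$down)

  # one-off cleanup on each barcode table independently, against the
  # unfiltered per-barcode totals
  up_counts <- pairs |> summarise(count = sum(.data$count), .by = "up") |>
    rename(barcode = "up")
  dn_counts <- pairs |> summarise(count = sum(.data$count), .by = "down") |>
    rename(barcode = "down")
  up_keep <- filter_one_off_barcodes(up_counts)$barcode
  dn_keep <- filter_one_off_barcodes(dn_counts)$barcode
  out <- pairs |>
    filter(.data$up %in% up_keep, .data$down %in% dn_keep)
  attr(out, "total_reads") <- nrow(reads)
  attr(out, "paired_reads") <- nrow(paired)
  out
}

#' Remove chimeric-PCR barcode pairs
#'
#' Two pairs are *related* when they share the UP or the DOWN barcode; a
#' shared barcode across pairs is the signature of chimeric PCR. A pair is
#' kept iff it has no related pair, or its count is at least two times the
#' count of its most abundant related pair. Each pair is judged against the
#' unfiltered pair table.
#'
#' @param pairs Tibble with columns `up`, `down`, `count`.
#' @return Filtered pair tibble; attributes of `pairs` are preserved and
#'   `usable_reads` is set to the sum of retained counts.
#' @export
filter_chimeric_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  max_other <- function(key) {
    # for each row, the max count among other rows sharing `key`
    grp_max <- stats::ave(pairs$count, key, FUN = max)
    grp_n_at_max <- stats::ave(pairs$count, key, FUN = function(x) sum(x == max(x)))
    grp_second <- stats::ave(pairs$count, key, FUN = function(x) {
      if (length(x) == 1) -Inf else max(x[-which.max(x)])
    })
    ifelse(pairs$count == grp_max & grp_n_at_max == 1, grp_second, grp_max)
  }
  rel <- pmax(max_other(pairs$up), max_other(pairs$down))
  keep <- rel == -Inf | pairs$count >= 2 * rel
  out <- pairs[keep, ]
  attr(out, "total_reads") <- attr(pairs, "total_reads")
  attr(out, "paired_reads") <- attr(pairs, "paired_reads")
  attr(out, "usable_reads") <- sum(out$count)
  out
}

#' Characterize a BPseq library: pair association plus chimera filtering
#'
#' Convenience wrapper chaining [associate_barcode_pairs()] and
#' [filter_chimeric_pairs()], i.e. the full BPseq stage.
#'
#' @inheritParams associate_barcode_pairs
#' @return Filtered pair tibble (see [filter_chimeric_pairs()]).
#' @export
characterize_bpseq <- function(reads, up_spec, down_spec) {
  filter_chimeric_pairs(associate_barcode_pairs(reads, up_spec, down_spec))
}
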