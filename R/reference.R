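#' Join barcode pairs with genomic junctions into the fragment reference set
#'
#' For each barcode pair whose UP and DOWN barcodes both resolved to a
#' junction, requires: the same contig; inward-facing orientations (the
#' junction whose insert extends `+` must lie before the junction whose
#' insert extends `-`, so both point toward each other); and a fragment
#' length between `min_length` and `max_length` nt. Surviving pairs become
#' reference fragments `[start, end)` with `start = min(junctions)`,
#' `end = max(junctions)` (0-based half-open). Each barcode can appear in at
#' most one fragment; a violation is an internal error.
#'
#' @param pairs Filtered barcode-pair tibble (`up`, `down`, `count`), e.g.
#'   from [characterize_bpseq()].
#' @param up_maps,down_maps Resolved mapping tibbles for UP and DOWN barcodes
#'   (see [resolve_barcode_locations()]).
#' @param min_length,max_length Accepted fragment length window in nt
#'   (defaults 100 and 6000).
#' @return Tibble with columns `up`, `down`, `contig`, `start`, `end`,
#'   `length`, `count`, plus a `drop_reasons` attribute tallying pairs
#'   removed at each check.
#' @export
build_reference_set <- function(pairs, up_maps, down_maps,
                                min_length = 100L, max_length = 6000L) {
  joined <- pairs |>
    left_join(rename(up_maps, up_contig = "contig", up_junction = "junction",
                     up_direction = "direction", up_n = "count"),
              by = c(up = "barcode")) |>
    left_join(rename(down_maps, down_contig = "contig",
                     down_junction = "junction",
                     down_direction = "direction", down_n = "count"),
              by = c(down = "barcode"))

  joined <- joined |>
    mutate(
      reason = case_when(
        is.na(.data$up_contig) & is.na(.data$down_contig) ~ "both_unmapped",
        is.na(.data$up_contig) ~ "up_unmapped",
        is.na(.data$down_contig) ~ "down_unmapped",
        .data$up_contig != .data$down_contig ~ "different_contigs",
        .data$up_direction == .data$down_direction ~ "orientation",
        (.data$up_direction == "+" & .data$up_junction >= .data$down_junction) |
          (.data$up_direction == "-" & .data$down_junction >= .data$up_junction)
          ~ "orientation",
        abs(.data$down_junction - .data$up_junction) < min_length ~ "too_short",
        abs(.data$down_junction - .data$up_junction) > max_length ~ "too_long",
        TRUE ~ "pass"
      )
    )

  drop_reasons <- joined |>
    count(.data$reason, name = "n_pairs") |>
    arrange(desc(.data$n_pairs))

  out <- joined |>
    filter(.data$reason == "pass") |>
    transmute(
      .data$up, .data$down,
      contig = .data$up_contig,
      start = pmin(.data$up_junction, .data$down_junction),
      end = pmax(.data$up_junction, .data$down_junction),
      length = .data$end - .data$start,
      count = .data$count
    )
  if (anyDuplicated(out$up) || anyDuplicated(out$down)) {
    abort("internal error: a barcode appears in more than one reference fragment")
  }
  attr(out, "drop_reasons") <- drop_reasons
  out
}

#' Export a reference fragment table as TSV (1-based inclusive coordinates)
#'
#' @param fragments Reference fragment tibble from [build_reference_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_tsv <- function(fragments, path) {
  out <- fragments |>
    transmute(.data$up, .data$down, .data$contig,
              start_1based = .data$start + 1L,
              end_1based = .data$end,  # half-open end == 1-based inclusive end
              .data$length)
  write_tsv_with_header(out, path,
    comment = "reference fragments; coordinates 1-based inclusive")
}
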