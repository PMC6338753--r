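#' Flanking-sequence specification for barcode extraction
#'
#' Describes where a random DNA barcode sits inside a read: two 9-nt anchor
#' sequences that must match exactly on either side of the barcode, the
#' expected (0-based) read offset of the barcode start, and the quality gates
#' applied to the barcode bases. The anchors are vector-specific and therefore
#' configuration, not constants; the simulator writes its own anchors into the
#' specs it returns.
#'
#' @param upstream_anchor 9-nt DNA string immediately 5' of the barcode.
#' @param downstream_anchor 9-nt DNA string immediately 3' of the barcode.
#' @param expected_start Integer 0-based read offset where the barcode is
#'   expected to begin.
#' @param max_shift Maximum shift (nt) of the barcode start away from
#'   `expected_start` that is still searched (default 2).
#' @param barcode_length Barcode length in nt (default 20).
#' @param min_base_quality Minimum Phred quality required at every barcode
#'   base (default 20).
#' @param min_tail_length Minimum length (nt) of the genomic tail downstream
#'   of the 3' anchor for tail extraction (default 15; used by BAGseq).
#' @return An object of class `flank_spec`.
#' @export
#' @examples
#' flank_spec("GATGTCCAC", "AGAGACCTC", expected_start = 14)
flank_spec <- function(upstream_anchor, downstream_anchor, expected_start,
                       max_shift = 2L, barcode_length = 20L,
                       min_base_quality = 20L, min_tail_length = 15L) {
  for (a in c(upstream_anchor, downstream_anchor)) {
    if (nchar(a) != 9L || grepl("[^ACGT]", a)) {
      abort("anchors must be exactly 9 nt over {A,C,G,T}")
    }
  }
  if (max_shift < 0) abort("max_shift must be >= 0")
  if (barcode_length <= 0) abort("barcode_length must be > 0")
  if (expected_start < 9L) abort("expected_start must leave room for the 9-nt upstream anchor")
  structure(
    list(
      upstream_anchor = upstream_anchor,
      downstream_anchor = downstream_anchor,
      expected_start = as.integer(expected_start),
      max_shift = as.integer(max_shift),
      barcode_length = as.integer(barcode_length),
      min_base_quality = as.integer(min_base_quality),
      min_tail_length = as.integer(min_tail_length)
    ),
    class = "flank_spec"
  )
}

#' @export
print.flank_spec <- function(x, ...) {
  cat(sprintf(
    "<flank_spec> %s [%d nt barcode] %s @ %d +/- %d, Q>=%d\n",
    x$upstream_anchor, x$barcode_length, x$downstream_anchor,
    x$expected_start, x$max_shift, x$min_base_quality
  ))
  invisible(x)
}

# regex character class matching Phred+33 quality characters BELOW min_q
low_quality_class <- function(min_q) {
  if (min_q <= 0) return(NULL)
  sprintf("[\\x21-\\x%02x]", 32L + min_q)
}

check_reads_tbl <- function(reads) {
  stopifnot(is.data.frame(reads))
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(reads))) {
    abort("reads must have columns read_id, sequence, quality")
  }
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    abort(sprintf(
      "malformed read(s): sequence/quality length mismatch at record(s) %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(reads)
}

#' Extract barcodes from reads using flanking-sequence anchors
#'
#' Scans each read for the barcode defined by a [flank_spec()]: at some offset
#' within `expected_start +/- max_shift` both 9-nt anchors must match exactly
#' and every barcode base must reach `min_base_quality`; barcodes containing
#' non-ACGT characters are rejected. When several offsets match, the one
#' closest to the expected position wins (ties go to the smaller offset).
#' With `with_tail = TRUE` the sequence 3' of the downstream anchor is
#' returned as a candidate genomic fragment, and reads whose tail is shorter
#' than `min_tail_length` yield nothing.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 encoded, same length as `sequence`).
#' @param spec A [flank_spec()].
#' @param with_tail Also return the genomic tail (BAGseq mode)?
#' @return Tibble with columns `read_id`, `barcode`, `offset` (0-based
#'   barcode start) and, if requested, `tail`. Reads yielding no barcode are
#'   absent from the result; malformed reads (sequence/quality length
#'   mismatch) raise an error.
#' @export
extract_barcodes <- function(reads, spec, with_tail = FALSE) {
  check_reads_tbl(reads)
  n <- nrow(reads)
  out_offset <- rep(NA_integer_, n)
  if (n > 0) {
    shifts <- seq(-spec$max_shift, spec$max_shift)
    shifts <- shifts[order(abs(shifts), shifts)]
    offsets <- spec$expected_start + shifts
    offsets <- offsets[offsets >= 9L]
    lowq <- low_quality_class(spec$min_base_quality)
    blen <- spec$barcode_length
    seqs <- reads$sequence
    quals <- reads$quality
    for (o in offsets) {
      todo <- which(is.na(out_offset))
      if (!length(todo)) break
      up <- substr(seqs[todo], o - 8L, o)
      dn <- substr(seqs[todo], o + blen + 1L, o + blen + 9L)
      ok <- up == spec$upstream_anchor & dn == spec$downstream_anchor
      if (any(ok)) {
        cand <- todo[ok]
        bc <- substr(seqs[cand], o + 1L, o + blen)
        keep <- !grepl("[^ACGT]", bc) & nchar(bc) == blen
        if (!is.null(lowq)) {
          keep <- keep & !grepl(lowq, substr(quals[cand], o + 1L, o + blen), perl = TRUE)
        }
        out_offset[cand[keep]] <- o
      }
    }
  }
  hit <- which(!is.na(out_offset))
  o <- out_offset[hit]
  res <- tibble(
    read_id = reads$read_id[hit],
    barcode = substr(reads$sequence[hit], o + 1L, o + spec$barcode_length),
    offset = o
  )
  if (with_tail) {
    res$tail <- substr(reads$sequence[hit], o + spec$barcode_length + 10L,
                       nchar(reads$sequence[hit]))
    res <- res[nchar(res$tail) >= spec$min_tail_length, ]
  }
  res
}

#' Tally barcode read counts in a sample
#'
#' Runs [extract_barcodes()] over a read set and counts reads per barcode.
#' Total and usable (barcode-yielding) read numbers are attached as
#' attributes for reporting.
#'
#' @inheritParams extract_barcodes
#' @return Tibble with columns `barcode`, `count`, sorted by decreasing
#'   count, with attributes `total_reads` and `usable_reads`
#'   (`usable_reads == sum(count)`).
#' @export
tally_barcodes <- function(reads, spec) {
  hits <- extract_barcodes(reads, spec)
  counts <- hits |>
    count(.data$barcode, name = "count") |>
    arrange(desc(.data$count), .data$barcode)
  attr(counts, "total_reads") <- nrow(reads)
  attr(counts, "usable_reads") <- sum(counts$count)
  counts
}

# all Hamming-distance-1 neighbours of each barcode present in `barcodes`;
# returns for each input barcode the max count among its observed neighbours
# (NA when it has none)
max_neighbor_count <- function(barcodes, counts) {
  n <- length(barcodes)
  if (n == 0) return(integer(0))
  L <- nchar(barcodes[1])
  best <- rep(NA_integer_, n)
  for (p in seq_len(L)) {
    orig <- substr(barcodes, p, p)
    for (b in c("A", "C", "G", "T")) {
      variant <- paste0(substr(barcodes, 1, p - 1), b, substr(barcodes, p + 1, L))
      idx <- match(variant, barcodes)
      valid <- which(!is.na(idx) & orig != b)
      if (length(valid)) {
        cand <- counts[idx[valid]]
        cur <- best[valid]
        best[valid] <- ifelse(is.na(cur), cand, pmax(cur, cand))
      }
    }
  }
  best
}

#' Remove likely single-substitution barcode artifacts
#'
#' Two barcodes are *similar* when they differ at exactly one position.
#' A barcode passes the filter iff it has no similar barcode in the table, or
#' its count is at least two times the count of its most abundant similar
#' barcode (inclusive: `count >= 2 * max_neighbor`). Each barcode is judged
#' against the original, unfiltered table.
#'
#' @param counts Tibble with columns `barcode`, `count` (e.g. from
#'   [tally_barcodes()]).
#' @return The filtered tibble; attributes `total_reads` (if present) are
#'   kept and `usable_reads` is recomputed as the sum of retained counts.
#' @export
filter_one_off_barcodes <- function(counts) {
  if (nrow(counts) == 0) return(counts)
  nb <- max_neighbor_count(counts$barcode, counts$count)
  keep <- is.na(nb) | counts$count >= 2 * nb
  out <- counts[keep, ]
  attr(out, "total_reads") <- attr(counts, "total_reads")
  attr(out, "usable_reads") <- sum(out$count)
  out
}
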