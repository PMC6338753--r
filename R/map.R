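#' Build an exact k-mer index of a genome
#'
#' Indexes every k-mer start position of each contig for exact-seed lookup by
#' [map_tail_to_genome()].
#'
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @param k Seed length in nt (default 15, the minimum accepted alignment
#'   block).
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 15L) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("genome must be a named character vector of contigs")
  }
  idx <- lapply(genome, function(seq) {
    L <- nchar(seq)
    if (L < k) return(list())
    starts <- seq_len(L - k + 1L)
    split(starts, substring(seq, starts, starts + k - 1L))
  })
  structure(
    list(k = as.integer(k), genome = genome,
         contig_lengths = nchar(genome), index = idx),
    class = "genome_index"
  )
}

# match runs of query vs genome along one diagonal d (g = q + d, 1-based);
# returns tibble of TRUE-runs (qstart, qend, len)
diagonal_runs <- function(query, contig_seq, d) {
  Lq <- nchar(query)
  Lc <- nchar(contig_seq)
  qlo <- max(1L, 1L - d)
  qhi <- min(Lq, Lc - d)
  if (qhi < qlo) return(NULL)
  qs <- strsplit(substr(query, qlo, qhi), "", fixed = TRUE)[[1]]
  gs <- strsplit(substr(contig_seq, qlo + d, qhi + d), "", fixed = TRUE)[[1]]
  r <- rle(qs == gs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  if (!any(ok)) return(NULL)
  tibble(
    qstart = qlo + starts[ok] - 1L,
    qend = qlo + ends[ok] - 1L,
    len = r$lengths[ok]
  )
}

# best merged alignment across the diagonals of one cluster; diagonals carry
# their best exact-match run. One extra diagonal = one indel.
combine_cluster <- function(runs_by_diag) {
  diags <- as.integer(names(runs_by_diag))
  best_single <- lapply(runs_by_diag, function(r) r[which.max(r$len), ])
  lens <- vapply(best_single, function(r) r$len, numeric(1))
  top <- which.max(lens)
  out <- list(block = lens[top], indels = 0L,
              qstart = best_single[[top]]$qstart,
              qend = best_single[[top]]$qend,
              d_first = diags[top], d_last = diags[top])
  if (length(diags) >= 2) {
    for (i in seq_along(diags)) for (j in seq_along(diags)) {
      if (i == j || abs(diags[i] - diags[j]) > 1) next
      a <- best_single[[i]]; b <- best_single[[j]]
      # runs may overlap in query coordinates when matches extend by chance
      # across the indel point; trim the second run to start after the first
      if (b$qend > a$qend) {
        cand <- a$len + (b$qend - max(a$qend, b$qstart - 1L))
        if (cand > out$block) {
          out <- list(block = cand, indels = 1L, qstart = a$qstart,
                      qend = b$qend, d_first = diags[i], d_last = diags[j])
        }
      }
    }
  }
  out
}

#' Map a candidate genomic tail to the genome
#'
#' Seed-and-extend alignment honoring the acceptance rules of the reference
#' mapping stage: exact k-mer (15-mer) seeds on both strands, ungapped
#' extension along each seed diagonal, and a single-indel rescue that merges
#' adjacent diagonals. A hit qualifies when its alignment block size is at
#' least `min_block` nt with at most `max_indels` indel. The tail must map to
#' exactly one genomic location: zero or multiple qualifying locations
#' (repeat regions) return `NULL`.
#'
#' @param tail DNA string (the candidate genomic fragment downstream of a
#'   barcode), length >= 15.
#' @param index A [genome_index()].
#' @param min_block Minimum alignment block size in nt (default 15).
#' @param max_indels Maximum number of indels (default 1).
#' @return One-row tibble with columns `contig`, `position` (0-based
#'   alignment start), `strand`, `block_size`, `indels`, `junction` (0-based
#'   genomic coordinate of the insert breakpoint adjacent to the barcode) and
#'   `direction` (which way the insert extends from the junction), or `NULL`.
#' @export
map_tail_to_genome <- function(tail, index, min_block = 15L, max_indels = 1L) {
  if (!inherits(index, "genome_index")) abort("index must be a genome_index")
  k <- index$k
  locations <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") tail else revcomp(tail)
    Lq <- nchar(query)
    if (Lq < k) next
    qpos <- seq_len(Lq - k + 1L)
    seeds <- substring(query, qpos, qpos + k - 1L)
    for (contig in names(index$index)) {
      hits <- index$index[[contig]][seeds]
      nhit <- lengths(hits)
      if (!sum(nhit)) next
      d <- unlist(hits, use.names = FALSE) - rep(qpos, nhit)
      diags <- sort(unique(d))
      runs <- lapply(diags, function(dd)
        diagonal_runs(query, index$genome[[contig]], dd))
      names(runs) <- diags
      runs <- runs[!vapply(runs, is.null, logical(1))]
      if (!length(runs)) next
      # cluster diagonals within max_indels of each other: one location each
      dv <- as.integer(names(runs))
      cl <- cumsum(c(1L, diff(dv) > max_indels))
      for (g in split(seq_along(dv), cl)) {
        if (length(g) - 1L > max_indels) next  # needs too many indels
        cand <- combine_cluster(runs[g])
        if (cand$block >= min_block && cand$indels <= max_indels) {
          locations[[length(locations) + 1L]] <- c(
            cand, list(contig = contig, strand = strand, Lq = Lq)
          )
        }
      }
    }
  }
  if (length(locations) != 1L) return(NULL)  # none, or repeat region
  h <- locations[[1L]]
  if (h$strand == "+") {
    junction <- h$d_first        # query pos 1 -> genome (1 + d), 0-based = d
    direction <- "+"
  } else {
    junction <- h$Lq + h$d_last  # exclusive end adjacent to the tail start
    direction <- "-"
  }
  tibble(
    contig = h$contig,
    position = h$qstart + (if (h$strand == "+") h$d_first else h$d_first) - 1L,
    strand = h$strand,
    block_size = as.integer(h$block),
    indels = h$indels,
    junction = as.integer(junction),
    direction = direction
  )
}

#' Map many tails, caching repeated tail sequences
#'
#' @param tails Tibble with columns `read_id`, `barcode`, `tail`.
#' @inheritParams map_tail_to_genome
#' @return Tibble with one row per mapped read: `read_id`, `barcode`,
#'   `contig`, `junction`, `direction`, `block_size`, `indels`.
#' @export
map_tails <- function(tails, index, min_block = 15L, max_indels = 1L) {
  uniq <- unique(tails$tail)
  hits <- lapply(uniq, map_tail_to_genome, index = index,
                 min_block = min_block, max_indels = max_indels)
  names(hits) <- uniq
  mapped <- !vapply(hits, is.null, logical(1))
  hit_tbl <- bind_rows(hits[mapped], .id = "tail")
  if (nrow(hit_tbl) == 0) {
    return(tibble(read_id = character(), barcode = character(),
                  contig = character(), junction = integer(),
                  direction = character(), block_size = integer(),
                  indels = integer()))
  }
  tails |>
    inner_join(hit_tbl, by = "tail") |>
    select("read_id", "barcode", "contig", "junction", "direction",
           "block_size", "indels")
}

#' Resolve each barcode to a single genomic location
#'
#' The same barcode can be associated with different locations through PCR
#' chimeras or multiple cloning events. A barcode is kept with its most
#' abundant location iff it has a single associated location, or the top
#' location's read count is at least two times every other location's count;
#' otherwise the barcode is discarded.
#'
#' @param locations Tibble of per-read (or pre-tallied) barcode-location
#'   associations with columns `barcode`, `contig`, `junction`, `direction`
#'   and optionally `count` (defaults to one per row).
#' @return Tibble with columns `barcode`, `contig`, `junction`, `direction`,
#'   `count`, one row per resolved barcode.
#' @export
resolve_barcode_locations <- function(locations) {
  if (!"count" %in% names(locations)) locations$count <- 1L
  tally <- locations |>
    summarise(count = sum(.data$count),
              .by = c("barcode", "contig", "junction", "direction"))
  tally |>
    mutate(
      top = max(.data$count),
      second = if (n() == 1) 0 else max(.data$count[-which.max(.data$count)]),
      .by = "barcode"
    ) |>
    filter(.data$count == .data$top, .data$top >= 2 * .data$second) |>
    # a tie at the top yields two rows failing the 2x rule upstream; the
    # filter above already removed them (top >= 2*top only when 0)
    distinct(.data$barcode, .keep_all = TRUE) |>
    select("barcode", "contig", "junction", "direction", "count")
}

#' Characterize a BAGseq library: barcode-to-junction mapping
#'
#' Full BAGseq stage for one barcode tag: extract barcodes with genomic
#' tails, clean the barcode table with [filter_one_off_barcodes()], map the
#' tails with [map_tails()], and resolve each barcode to a unique junction
#' with [resolve_barcode_locations()].
#'
#' @param reads BAGseq read tibble.
#' @param spec [flank_spec()] for this tag's barcode.
#' @param index A [genome_index()].
#' @inheritParams map_tail_to_genome
#' @return Resolved mapping tibble (see [resolve_barcode_locations()]) with
#'   attributes `total_reads` and `usable_reads` (reads supporting the
#'   resolved mappings).
#' @export
characterize_bagseq <- function(reads, spec, index, min_block = 15L,
                                max_indels = 1L) {
  tails <- extract_barcodes(reads, spec, with_tail = TRUE)
  bc_counts <- tails |> count(.data$barcode, name = "count")
  keep <- filter_one_off_barcodes(bc_counts)$barcode
  tails <- tails |> filter(.data$barcode %in% keep)
  mapped <- map_tails(tails, index, min_block, max_indels)
  out <- resolve_barcode_locations(mapped)
  attr(out, "total_reads") <- nrow(reads)
  attr(out, "usable_reads") <- mapped |>
    semi_join(out, by = c("barcode", "contig", "junction", "direction")) |>
    nrow()
  out
}

#' Import pre-computed alignments in PSL format
#'
#' Reads a (headerless) 21-column PSL file, applies the same acceptance
#' rules as the built-in mapper (largest block >= `min_block` nt, at most
#' `max_indels` indels, unique qualifying location per query), and converts
#' accepted hits to junction records.
#'
#' @param path Path to a PSL file (no header lines).
#' @inheritParams map_tail_to_genome
#' @return Tibble with columns `query`, `contig`, `junction`, `direction`,
#'   `block_size`, `indels`, one row per query with a unique accepted hit.
#' @export
read_psl_hits <- function(path, min_block = 15L, max_indels = 1L) {
  cols <- c("matches", "mismatches", "rep_matches", "n_count", "q_num_insert",
            "q_base_insert", "t_num_insert", "t_base_insert", "strand",
            "q_name", "q_size", "q_start", "q_end", "t_name", "t_size",
            "t_start", "t_end", "block_count", "block_sizes", "q_starts",
            "t_starts")
  cc <- rep(NA, 21); cc[19:21] <- "character"
  psl <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = cols, colClasses = cc, comment.char = "")
  psl$block_size <- vapply(strsplit(psl$block_sizes, ","),
                           function(x) max(as.integer(x)), integer(1))
  psl$indels <- psl$q_num_insert + psl$t_num_insert
  ok <- psl[psl$block_size >= min_block & psl$indels <= max_indels, ]
  uniq <- names(which(table(ok$q_name) == 1))
  ok <- ok[ok$q_name %in% uniq, ]
  tibble(
    query = ok$q_name,
    contig = ok$t_name,
    junction = ifelse(ok$strand == "+", ok$t_start, ok$t_end),
    direction = ok$strand,
    block_size = ok$block_size,
    indels = as.integer(ok$indels)
  )
}
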