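#' Summarize a Dub-seq reference library
#'
#' Computes the standard library-characterization summaries: the fragment
#' insert-size distribution, the distribution of genes completely covered
#' per fragment, per-gene independent-fragment counts, the cumulative
#' coverage curve (percentage of genes covered by at least k fragments), and
#' fragment coverage of the genome in fixed windows (default 10 kb).
#'
#' @param fragments Reference (or truth) fragment tibble.
#' @param genes Gene annotation tibble.
#' @param contig_lengths Named vector of contig lengths (for the window
#'   coverage track); inferred from fragment extents when missing.
#' @param window Window size in nt (default 10000).
#' @return Object of class `dubseq_library_summary` with elements
#'   `fragment_sizes`, `genes_per_fragment`, `per_gene`, `cumulative`,
#'   `windows`, `n_fragments`, `n_genes`.
#' @export
summarize_library <- function(fragments, genes, contig_lengths = NULL,
                              window = 10000L) {
  A <- build_coverage_matrix(fragments, genes)
  genes_per_frag <- as.integer(Matrix::rowSums(A))
  per_gene <- tibble(gene_id = genes$gene_id,
                     n_fragments = as.integer(Matrix::colSums(A)))
  ks <- 0:max(per_gene$n_fragments)
  cumulative <- tibble(
    k = ks,
    pct_genes = vapply(ks, function(k)
      100 * mean(per_gene$n_fragments >= k), numeric(1))
  )
  if (is.null(contig_lengths)) {
    contig_lengths <- fragments |>
      summarise(len = max(.data$end), .by = "contig") |>
      (\(d) setNames(d$len, d$contig))()
  }
  windows <- purrr::imap(as.list(contig_lengths), function(len, contig) {
    starts <- seq(0L, len - 1L, by = window)
    n <- vapply(starts, function(w) {
      sum(fragments$contig == contig & fragments$start < w + window &
            fragments$end > w)
    }, numeric(1))
    tibble(contig = contig, window_start = starts, n_fragments = as.integer(n))
  }) |> bind_rows()
  structure(
    list(
      fragment_sizes = tibble(length = fragments$end - fragments$start),
      genes_per_fragment = tibble(n_genes = genes_per_frag) |>
        count(.data$n_genes, name = "n_fragments"),
      per_gene = per_gene,
      cumulative = cumulative,
      windows = windows,
      n_fragments = nrow(fragments),
      n_genes = nrow(genes)
    ),
    class = "dubseq_library_summary"
  )
}

#' @export
print.dubseq_library_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dubseq_library_summary> %d fragments, %d genes\n",
           "  median insert %.0f nt; mean genes fully covered/fragment %.2f\n",
           "  %.1f%% of genes covered by >= 1 fragment\n"),
    x$n_fragments, x$n_genes,
    median(x$fragment_sizes$length),
    sum(x$genes_per_fragment$n_genes * x$genes_per_fragment$n_fragments) /
      x$n_fragments,
    x$cumulative$pct_genes[x$cumulative$k == 1]
  ))
  invisible(x)
}

#' Percentage of usable reads
#'
#' @param total_reads Total reads in the assay.
#' @param usable_reads Reads supporting the reference set.
#' @return `100 * usable / total`; `NA` when `total_reads` is zero.
#' @export
#' @examples
#' usable_read_percentage(5436798, 2933702)
usable_read_percentage <- function(total_reads, usable_reads) {
  stopifnot(usable_reads <= total_reads, usable_reads >= 0)
  if (total_reads == 0) return(NA_real_)
  100 * usable_reads / total_reads
}
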