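#' Adjacent gene pairs from an annotation table
#'
#' Pairs of genes that are consecutive along a contig (their intergenic
#' region included implicitly: a fragment covering both genes also covers
#' the region between them).
#'
#' @param genes Gene annotation tibble (`gene_id`, `contig`, `start`, `end`).
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
adjacent_gene_pairs <- function(genes) {
  genes |>
    arrange(.data$contig, .data$start) |>
    mutate(next_gene = lead(.data$gene_id), next_contig = lead(.data$contig)) |>
    filter(.data$contig == .data$next_contig) |>
    transmute(gene_a = .data$gene_id, gene_b = .data$next_gene)
}

#' Score adjacent gene pairs for epistatic fitness contributions
#'
#' Augments the single-gene coverage model with one extra column per
#' adjacent gene pair, set for fragments that cover both genes entirely, and
#' re-runs the two-pass NNLS. Within one experiment a pair passes iff its
#' score exceeds both single-gene regression scores and it is supported by
#' at least `min_support` fragments; replicate consistency is applied across
#' experiments by [combine_gene_pair_calls()].
#'
#' @inheritParams compute_gene_scores_mean
#' @param genes Gene annotation tibble used to define adjacency.
#' @param min_support Minimum number of fragments covering both genes
#'   (default 2, i.e. more than one fragment).
#' @return Tibble with columns `gene_a`, `gene_b`, `pair_score`, `score_a`,
#'   `score_b`, `supporting_fragments`, `passes`.
#' @export
fit_gene_pairs <- function(fscores, A, genes, min_support = 2L) {
  single <- tidy(fit_gene_scores(fscores, A))
  A2 <- restrict_coverage(fscores, A)
  pairs <- adjacent_gene_pairs(genes) |>
    filter(.data$gene_a %in% colnames(A2), .data$gene_b %in% colnames(A2))
  empty <- tibble(gene_a = character(), gene_b = character(),
                  pair_score = numeric(), score_a = numeric(),
                  score_b = numeric(), supporting_fragments = integer(),
                  passes = logical())
  if (nrow(pairs) == 0 || nrow(A2) == 0) return(empty)
  pair_cols <- purrr::map(seq_len(nrow(pairs)), function(i) {
    A2[, pairs$gene_a[i]] * A2[, pairs$gene_b[i]]
  })
  support <- vapply(pair_cols, sum, numeric(1))
  keep <- support >= 1
  pairs <- pairs[keep, ]
  if (nrow(pairs) == 0) return(empty)
  P <- do.call(cbind, pair_cols[keep])
  Ad <- cbind(as.matrix(A2), P)
  f <- fscores$f[match(rownames(A2), fscores$barcode)]
  pos <- pracma::lsqnonneg(Ad, f)$x
  neg <- pracma::lsqnonneg(Ad, -f)$x
  g <- pos - neg
  pair_idx <- ncol(A2) + seq_len(nrow(pairs))
  pairs |>
    mutate(
      pair_score = g[pair_idx],
      score_a = single$score[match(.data$gene_a, single$gene_id)],
      score_b = single$score[match(.data$gene_b, single$gene_id)],
      supporting_fragments = as.integer(support[keep]),
      passes = .data$pair_score > .data$score_a &
        .data$pair_score > .data$score_b &
        .data$supporting_fragments >= min_support
    )
}

#' Combine gene-pair scores across replicate experiments
#'
#' A pair qualifies only when the within-experiment pass criterion of
#' [fit_gene_pairs()] holds in every replicate of the condition.
#'
#' @param pair_fits Named list of per-replicate tibbles from
#'   [fit_gene_pairs()].
#' @return Tibble with `gene_a`, `gene_b`, `mean_pair_score`,
#'   `n_replicates`, `n_pass`, `passes` (pass in all replicates).
#' @export
combine_gene_pair_calls <- function(pair_fits) {
  n_rep <- length(pair_fits)
  bind_rows(pair_fits, .id = "experiment") |>
    summarise(
      mean_pair_score = mean(.data$pair_score),
      n_replicates = n(),
      n_pass = sum(.data$passes),
      .by = c("gene_a", "gene_b")
    ) |>
    mutate(passes = .data$n_pass == .env$n_rep & .data$n_replicates == .env$n_rep)
}
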