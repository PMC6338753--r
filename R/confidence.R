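#' Poisson-derived noise and z statistic per gene
#'
#' Under the best case of Poisson counting noise, a fragment score's
#' expected noise is `sqrt(1/(1 + s) + 1/(1 + t)) / ln(2)` (with `s` the
#' condition count and `t` the summed time-zero count, the same counts that
#' enter the score). The noise of the mean of a gene's covering fragment
#' scores is `sqrt(sum(fragment_noise^2)) / n_fragments`, and
#' `z = mean(fragment score) / gene_noise` ideally follows a standard
#' normal.
#'
#' @inheritParams compute_gene_scores_mean
#' @return Tibble with columns `gene_id`, `n_fragments`, `mean_f`,
#'   `gene_noise`, `z`.
#' @export
gene_noise_z <- function(fscores, A) {
  A2 <- restrict_coverage(fscores, A)
  if (ncol(A2) == 0 || nrow(A2) == 0) {
    return(tibble(gene_id = character(), n_fragments = integer(),
                  mean_f = numeric(), gene_noise = numeric(), z = numeric()))
  }
  idx <- match(rownames(A2), fscores$barcode)
  f <- fscores$f[idx]
  noise2 <- (1 / (1 + fscores$s[idx]) + 1 / (1 + fscores$t[idx])) / log(2)^2
  n <- Matrix::colSums(A2)
  gene_noise <- sqrt(as.numeric(Matrix::crossprod(A2, noise2))) / as.numeric(n)
  mean_f <- as.numeric(Matrix::crossprod(A2, f)) / as.numeric(n)
  tibble(
    gene_id = colnames(A2),
    n_fragments = as.integer(n),
    mean_f = mean_f,
    gene_noise = gene_noise,
    z = mean_f / gene_noise
  )
}

#' Fragment-consistency test per gene
#'
#' For genes covered by two or more scored fragments: a two-tailed
#' one-sample t-test of the covering fragments' scores against a reference
#' value `r`. To allow for uncertainty in the experiment-wide centering, `r`
#' is the mean of all fragment scores in the experiment when that mean has
#' the same sign as the gene's score (which makes the filter more
#' stringent), and zero otherwise. For single-fragment genes the t-test is
#' impossible; instead the fragment's |score| must fall in the top
#' `top_frac` (default 1%) of |fragment scores| for the experiment.
#' Degenerate case: identical fragment scores (zero variance) pass when
#' their common value differs from `r` (the p-value limit is 0) and fail
#' otherwise.
#'
#' @inheritParams compute_gene_scores_mean
#' @param gene_scores Tibble with `gene_id`, `score` (the signed regression
#'   scores, used only for the sign comparison).
#' @param alpha Significance threshold (default 0.05).
#' @param top_frac Top fraction of |f| accepted for single-fragment genes
#'   (default 0.01).
#' @return Tibble with columns `gene_id`, `n_fragments`, `p_value` (NA for
#'   single-fragment genes), `passes_consistency`.
#' @export
consistency_test <- function(fscores, A, gene_scores, alpha = 0.05,
                             top_frac = 0.01) {
  A2 <- restrict_coverage(fscores, A)
  if (ncol(A2) == 0 || nrow(A2) == 0) {
    return(tibble(gene_id = character(), n_fragments = integer(),
                  p_value = numeric(), passes_consistency = logical()))
  }
  all_f <- fscores$f
  exp_mean <- mean(all_f)
  top_threshold <- quantile(abs(all_f), 1 - top_frac, names = FALSE)
  f_by_gene <- apply(as.matrix(A2) > 0, 2, function(col)
    fscores$f[match(rownames(A2)[col], fscores$barcode)], simplify = FALSE)
  purrr::imap(f_by_gene, function(f, gene) {
    n <- length(f)
    if (n == 1) {
      return(tibble(gene_id = gene, n_fragments = 1L, p_value = NA_real_,
                    passes_consistency = abs(f) >= top_threshold))
    }
    score <- gene_scores$score[match(gene, gene_scores$gene_id)]
    r <- if (!is.na(score) && sign(exp_mean) == sign(score)) exp_mean else 0
    p <- if (sd(f) == 0) {
      if (mean(f) != r) 0 else 1
    } else {
      t.test(f, mu = r)$p.value
    }
    tibble(gene_id = gene, n_fragments = n, p_value = p,
           passes_consistency = p < alpha)
  }) |>
    bind_rows()
}

#' Call reliable gene effects for one experiment
#'
#' An effect is *reliable* when all three filters pass: magnitude
#' (|regression score| at or above `min_score`), fragment consistency (see
#' [consistency_test()]), and Poisson noise (|z| at or above `min_z`, with z
#' computed from the fragment-score mean per [gene_noise_z()]).
#'
#' @param gscore A `dubseq_gscore` fit from [fit_gene_scores()].
#' @param A Coverage matrix (same one used for the fit).
#' @param min_score Magnitude threshold on |score| (default 2).
#' @param alpha Consistency-test significance threshold (default 0.05).
#' @param min_z Noise threshold on |z| (default 4).
#' @param top_frac Single-fragment top-|f| fraction (default 0.01).
#' @return Effect-call tibble: `gene_id`, `experiment`, `score`,
#'   `score_mean`, `n_fragments`, `z`, `p_value`, `passes_magnitude`,
#'   `passes_consistency`, `passes_noise`, `reliable`.
#' @export
call_reliable <- function(gscore, A, min_score = 2, alpha = 0.05, min_z = 4,
                          top_frac = 0.01) {
  stopifnot(inherits(gscore, "dubseq_gscore"))
  fscores <- gscore$fscores
  scores <- gscore$scores
  noise <- gene_noise_z(fscores, A)
  cons <- consistency_test(fscores, A, scores, alpha, top_frac)
  scores |>
    select("gene_id", "score", "score_mean", "n_fragments") |>
    left_join(select(noise, "gene_id", "z"), by = "gene_id") |>
    left_join(select(cons, "gene_id", "p_value", "passes_consistency"),
              by = "gene_id") |>
    mutate(
      experiment = gscore$experiment %||% NA_character_,
      passes_magnitude = abs(.data$score) >= min_score,
      passes_noise = abs(.data$z) >= min_z,
      reliable = .data$passes_magnitude & .data$passes_consistency &
        .data$passes_noise
    ) |>
    select("gene_id", "experiment", "score", "score_mean", "n_fragments",
           "z", "p_value", "passes_magnitude", "passes_consistency",
           "passes_noise", "reliable")
}

#' Upgrade reliable effects to high confidence
#'
#' Because single-fragment effects risk reflecting secondary mutations, a
#' reliable effect is *high confidence* iff the gene is covered by more than
#' one fragment, or some other experiment for the same compound shows a
#' large effect (|score| at or above `min_other_score`) for the gene.
#'
#' @param calls Effect-call tibble (rows from [call_reliable()] across
#'   experiments, bound together).
#' @param compound_map Tibble with `experiment`, `compound` mapping each
#'   experiment to its compound/condition.
#' @param min_other_score Threshold for the supporting effect in another
#'   experiment (default 2).
#' @return `calls` with a `high_confidence` column appended.
#' @export
call_high_confidence <- function(calls, compound_map, min_other_score = 2) {
  calls <- calls |> left_join(compound_map, by = "experiment")
  support <- calls |>
    inner_join(calls, by = c("gene_id", "compound"),
               suffix = c("", ".other"), relationship = "many-to-many") |>
    filter(.data$experiment != .data$experiment.other,
           abs(.data$score.other) >= min_other_score) |>
    distinct(.data$gene_id, .data$experiment) |>
    mutate(has_support = TRUE)
  calls |>
    left_join(support, by = c("gene_id", "experiment")) |>
    mutate(
      high_confidence = .data$reliable &
        (.data$n_fragments >= 2 | coalesce(.data$has_support, FALSE))
    ) |>
    select(-"has_support", -"compound")
}

#' Fraction of filtered effects consistent between replicates
#'
#' For each reliable effect in one replicate, the effect is consistent when
#' the paired replicate shows |score| at or above `min_score` with the same
#' sign. Both directions of each pair are evaluated.
#'
#' @param calls Effect-call tibble across experiments.
#' @param replicate_pairs Tibble with columns `experiment_a`,
#'   `experiment_b`.
#' @param min_score Replicate magnitude threshold (default 1.5).
#' @return List with `fraction` (overall fraction consistent), `n_effects`,
#'   and the per-effect tibble `detail`.
#' @export
replicate_consistency <- function(calls, replicate_pairs, min_score = 1.5) {
  both_dir <- bind_rows(
    replicate_pairs,
    rename(replicate_pairs, experiment_a = "experiment_b",
           experiment_b = "experiment_a")
  )
  detail <- calls |>
    filter(.data$reliable) |>
    inner_join(both_dir, by = c(experiment = "experiment_a"),
               relationship = "many-to-many") |>
    left_join(
      calls |> select("gene_id", "experiment", other_score = "score"),
      by = c("gene_id", experiment_b = "experiment")
    ) |>
    mutate(consistent = !is.na(.data$other_score) &
             abs(.data$other_score) >= min_score &
             sign(.data$other_score) == sign(.data$score))
  list(
    fraction = if (nrow(detail)) mean(detail$consistent) else NA_real_,
    n_effects = nrow(detail),
    detail = detail |> select("gene_id", "experiment", "experiment_b",
                              "score", "other_score", "consistent")
  )
}

#' Expected false positives from the z filter
#'
#' Number of genes times the two-tailed standard-normal tail probability at
#' the z threshold: the per-experiment count of genes expected to pass
#' |z| >= `z_threshold` by chance alone.
#'
#' @param n_genes Number of genes assayed.
#' @param z_threshold The |z| cutoff.
#' @return Expected false-positive count (numeric scalar).
#' @export
#' @examples
#' expected_false_positives(4303, 4)
expected_false_positives <- function(n_genes, z_threshold) {
  stopifnot(z_threshold >= 0)
  n_genes * 2 * pnorm(-z_threshold)
}

#' Compare high-confidence effect rates by operon position
#'
#' Tests whether genes first in a transcript are more likely to show a
#' high-confidence effect than genes later in an operon. Genes listed as
#' both first and later (in different transcripts) are excluded; only genes
#' present in `calls` are considered. Association is tested with Fisher's
#' exact test (two-sided).
#'
#' @param calls Effect-call tibble with `high_confidence` (see
#'   [call_high_confidence()]).
#' @param operons Tibble with columns `gene_id`, `position` (values
#'   `"first"` or `"later"`).
#' @return One-row tibble: group sizes, numbers and proportions with a
#'   high-confidence effect, `odds_ratio`, `p_value`, `applicable` (FALSE
#'   when a position category is empty).
#' @export
operon_position_comparison <- function(calls, operons) {
  ambiguous <- operons |>
    distinct(.data$gene_id, .data$position) |>
    count(.data$gene_id) |>
    filter(.data$n > 1) |>
    pull("gene_id")
  gene_hc <- calls |>
    summarise(hc = any(.data$high_confidence), .by = "gene_id")
  tab <- operons |>
    distinct(.data$gene_id, .data$position) |>
    filter(!.data$gene_id %in% ambiguous) |>
    inner_join(gene_hc, by = "gene_id") |>
    summarise(n = n(), n_hc = sum(.data$hc), .by = "position")
  first <- tab |> filter(.data$position == "first")
  later <- tab |> filter(.data$position == "later")
  if (nrow(first) == 0 || nrow(later) == 0 ||
      first$n == 0 || later$n == 0) {
    return(tibble(n_first = if (nrow(first)) first$n else 0L,
                  n_later = if (nrow(later)) later$n else 0L,
                  hc_first = NA_integer_, hc_later = NA_integer_,
                  prop_first = NA_real_, prop_later = NA_real_,
                  odds_ratio = NA_real_, p_value = NA_real_,
                  applicable = FALSE))
  }
  m <- matrix(c(first$n_hc, first$n - first$n_hc,
                later$n_hc, later$n - later$n_hc),
              nrow = 2, byrow = TRUE)
  ft <- fisher.test(m)
  tibble(
    n_first = first$n, n_later = later$n,
    hc_first = first$n_hc, hc_later = later$n_hc,
    prop_first = first$n_hc / first$n,
    prop_later = later$n_hc / later$n,
    odds_ratio = (first$n_hc * (later$n - later$n_hc)) /
      ((first$n - first$n_hc) * later$n_hc),
    p_value = ft$p.value,
    applicable = TRUE
  )
}
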