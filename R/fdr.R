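# reliable/high-confidence calling with the MEAN gene score standing in for
# the regression score; used by the shuffle-FDR estimator
call_effects_mean <- function(fscores_by_exp, A, compound_map, min_score = 2,
                              alpha = 0.05, min_z = 4, top_frac = 0.01,
                              min_other_score = 2) {
  calls <- purrr::imap(fscores_by_exp, function(fscores, exp_id) {
    mean_scores <- compute_gene_scores_mean(fscores, A) |>
      rename(score = "score_mean")
    if (nrow(mean_scores) == 0) return(NULL)
    noise <- gene_noise_z(fscores, A)
    cons <- consistency_test(fscores, A, mean_scores, alpha, top_frac)
    mean_scores |>
      left_join(select(noise, "gene_id", "z"), by = "gene_id") |>
      left_join(select(cons, "gene_id", "p_value", "passes_consistency"),
                by = "gene_id") |>
      mutate(
        experiment = exp_id,
        passes_magnitude = abs(.data$score) >= min_score,
        passes_noise = abs(.data$z) >= min_z,
        reliable = .data$passes_magnitude & .data$passes_consistency &
          .data$passes_noise
      )
  }) |>
    bind_rows()
  if (nrow(calls) == 0) return(calls)
  call_high_confidence(calls, compound_map, min_other_score)
}

#' Estimate the false discovery rate by barcode-to-fragment shuffling
#'
#' Randomly permutes the assignment of barcodes (count rows) to reference
#' fragments, recomputes mean gene scores for every experiment, applies the
#' same reliable/high-confidence calling as for the genuine data, and counts
#' high-confidence effects. The FDR estimate is the mean shuffled count
#' divided by the genuine high-confidence count. Because all fragment-score
#' variability is treated as noise, and because the mean (not regression)
#' score is used in the shuffled replicates, the estimate is conservative.
#'
#' @param counts Long count tibble from [assemble_count_matrix()].
#' @param reference Reference fragment tibble.
#' @param genes Gene annotation tibble.
#' @param design Experiment design tibble.
#' @param actual_calls Genuine effect-call tibble with a `high_confidence`
#'   column (from the regression-based pipeline).
#' @param n_shuffles Number of shuffles (default 10).
#' @param seed Integer seed for the shuffle RNG.
#' @param min_t0_reads,min_score,alpha,min_z,top_frac,min_other_score
#'   Thresholds forwarded to scoring and calling (package defaults).
#' @return Object of class `dubseq_fdr` with fields `shuffled_counts`,
#'   `actual_count`, `fdr` (NA when the genuine count is zero),
#'   `n_shuffles`, `seed`.
#' @export
estimate_fdr_by_shuffling <- function(counts, reference, genes, design,
                                      actual_calls, n_shuffles = 10L,
                                      seed = 1L, min_t0_reads = 10L,
                                      min_score = 2, alpha = 0.05, min_z = 4,
                                      top_frac = 0.01, min_other_score = 2) {
  design <- validate_design(design)
  A <- build_coverage_matrix(reference, genes)
  cond <- design |> filter(!.data$is_time_zero) |> pull("sample_id")
  fscores_by_exp <- lapply(cond, function(sid)
    compute_fragment_scores(counts, design, sid, min_t0_reads))
  names(fscores_by_exp) <- cond
  compound_map <- design |>
    filter(!.data$is_time_zero) |>
    transmute(experiment = .data$sample_id, compound = .data$condition)

  shuffled_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      A_shuf <- A
      rownames(A_shuf) <- sample(rownames(A))
      shuf_calls <- call_effects_mean(fscores_by_exp, A_shuf, compound_map,
                                      min_score, alpha, min_z, top_frac,
                                      min_other_score)
      if (nrow(shuf_calls) == 0) 0 else sum(shuf_calls$high_confidence)
    }, numeric(1))
  })
  actual <- sum(actual_calls$high_confidence)
  structure(
    list(
      shuffled_counts = shuffled_counts,
      actual_count = actual,
      fdr = if (actual > 0) mean(shuffled_counts) / actual else NA_real_,
      n_shuffles = as.integer(n_shuffles),
      seed = as.integer(seed)
    ),
    class = "dubseq_fdr"
  )
}

#' @export
print.dubseq_fdr <- function(x, ...) {
  cat(sprintf(
    "<dubseq_fdr> %d shuffles (seed %d): mean shuffled = %.1f, actual = %d, FDR = %s\n",
    x$n_shuffles, x$seed, mean(x$shuffled_counts), x$actual_count,
    if (is.na(x$fdr)) "n/a (no genuine effects)" else sprintf("%.2f%%", 100 * x$fdr)
  ))
  invisible(x)
}

#' Per-shuffle high-confidence counts of an FDR estimate
#'
#' @param x A `dubseq_fdr` from [estimate_fdr_by_shuffling()].
#' @param ... Unused.
#' @return Tibble with columns `shuffle`, `n_high_confidence`.
#' @export
tidy.dubseq_fdr <- function(x, ...) {
  tibble(shuffle = seq_along(x$shuffled_counts),
         n_high_confidence = x$shuffled_counts)
}

#' One-row summary of an FDR estimate
#'
#' @inheritParams tidy.dubseq_fdr
#' @return Tibble with `n_shuffles`, `mean_shuffled`, `actual_count`, `fdr`.
#' @export
glance.dubseq_fdr <- function(x, ...) {
  tibble(n_shuffles = x$n_shuffles,
         mean_shuffled = mean(x$shuffled_counts),
         actual_count = x$actual_count, fdr = x$fdr)
}
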