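#' Run the full Dub-seq pipeline on in-memory inputs
#'
#' Orchestrates every stage: BPseq pair association and chimera filtering,
#' BAGseq mapping for both tags, the reference-set join, per-sample BarSeq
#' counting, fragment scoring, two-pass NNLS gene scoring, and
#' reliable/high-confidence effect calling (optionally followed by the
#' shuffle FDR). Per-stage record tallies are collected in a stage log.
#'
#' @param bpseq_reads,bagseq_up_reads,bagseq_down_reads Read tibbles.
#' @param barseq_reads Named list of read tibbles, one per design sample.
#' @param genome Named character vector of contigs.
#' @param genes Gene annotation tibble.
#' @param design Experiment design tibble.
#' @param specs Named list of [flank_spec()]s: `up`, `down_bpseq`, `down`
#'   (as returned by [sim_flank_specs()]).
#' @param min_t0_reads,min_score,alpha,min_z,top_frac,min_other_score
#'   Scoring/calling thresholds (package defaults).
#' @param fdr_shuffles Number of FDR shuffles; 0 skips the FDR stage.
#' @param seed Seed for the FDR shuffles.
#' @param output_dir Optional directory; when given, stage outputs are also
#'   written as TSV.
#' @return List with `pairs`, `up_maps`, `down_maps`, `reference`, `counts`,
#'   `fscores` (long tibble), `gscores` (list of `dubseq_gscore` per
#'   experiment), `calls` (effect-call tibble with `high_confidence`),
#'   `fdr` (`dubseq_fdr` or NULL), `summary`
#'   ([summarize_library()] result), `stage_log` (tibble).
#' @export
run_pipeline <- function(bpseq_reads, bagseq_up_reads, bagseq_down_reads,
                         barseq_reads, genome, genes, design, specs,
                         min_t0_reads = 10L, min_score = 2, alpha = 0.05,
                         min_z = 4, top_frac = 0.01, min_other_score = 2,
                         fdr_shuffles = 0L, seed = 1L, output_dir = NULL) {
  design <- validate_design(design)
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, records_in = n_in,
                                       records_out = n_out,
                                       filtered_out = n_in - n_out)
  }

  pairs <- characterize_bpseq(bpseq_reads, specs$up, specs$down_bpseq)
  note("bpseq", nrow(bpseq_reads), nrow(pairs))

  index <- genome_index(genome)
  up_maps <- characterize_bagseq(bagseq_up_reads, specs$up, index)
  note("bagseq_up", nrow(bagseq_up_reads), nrow(up_maps))
  down_maps <- characterize_bagseq(bagseq_down_reads, specs$down, index)
  note("bagseq_down", nrow(bagseq_down_reads), nrow(down_maps))

  reference <- build_reference_set(pairs, up_maps, down_maps)
  note("bpag", nrow(pairs), nrow(reference))

  sample_counts <- lapply(barseq_reads, count_sample, spec = specs$up)
  counts <- assemble_count_matrix(sample_counts, reference, design)
  note("barseq", sum(vapply(barseq_reads, nrow, numeric(1))),
       sum(counts$count))

  fscores_long <- fragment_score_table(counts, design, min_t0_reads)
  A <- build_coverage_matrix(reference, genes)
  cond <- design |> filter(!.data$is_time_zero) |> pull("sample_id")
  gscores <- lapply(cond, function(sid) {
    fs <- compute_fragment_scores(counts, design, sid, min_t0_reads)
    fit_gene_scores(fs, A)
  })
  names(gscores) <- cond
  note("gscore", length(cond) * nrow(reference),
       sum(vapply(gscores, function(g) g$n_genes, numeric(1))))

  compound_map <- design |>
    filter(!.data$is_time_zero) |>
    transmute(experiment = .data$sample_id, compound = .data$condition)
  calls <- purrr::map(gscores, call_reliable, A = A, min_score = min_score,
                      alpha = alpha, min_z = min_z, top_frac = top_frac) |>
    bind_rows() |>
    call_high_confidence(compound_map, min_other_score)
  note("confidence", nrow(calls), sum(calls$reliable))

  fdr <- NULL
  if (fdr_shuffles > 0) {
    fdr <- estimate_fdr_by_shuffling(counts, reference, genes, design, calls,
                                     n_shuffles = fdr_shuffles, seed = seed,
                                     min_t0_reads = min_t0_reads,
                                     min_score = min_score, alpha = alpha,
                                     min_z = min_z, top_frac = top_frac,
                                     min_other_score = min_other_score)
  }

  res <- list(
    pairs = pairs, up_maps = up_maps, down_maps = down_maps,
    reference = reference, counts = counts, fscores = fscores_long,
    gscores = gscores, calls = calls, fdr = fdr,
    summary = summarize_library(reference, genes,
                                contig_lengths = nchar(genome)),
    stage_log = bind_rows(log)
  )
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

# TSV exports for every stage artifact (1-based inclusive coordinates where
# genomic intervals appear)
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_with_header(res$pairs, file.path(dir, "bpseq_pairs.tsv"),
                        "BPseq barcode pairs after one-off and chimera filters")
  write_tsv_with_header(res$up_maps, file.path(dir, "bagseq_up.tsv"),
                        "UP barcode junctions; junction 0-based")
  write_tsv_with_header(res$down_maps, file.path(dir, "bagseq_down.tsv"),
                        "DOWN barcode junctions; junction 0-based")
  write_reference_tsv(res$reference, file.path(dir, "reference_fragments.tsv"))
  write_tsv_with_header(tidyr::pivot_wider(res$counts,
                                           names_from = "sample_id",
                                           values_from = "count"),
                        file.path(dir, "counts.tsv"),
                        "BarSeq counts over reference UP barcodes")
  write_tsv_with_header(res$fscores, file.path(dir, "fragment_scores.tsv"),
                        "fragment fitness scores (median-centered log2)")
  gtab <- purrr::map(res$gscores, function(g) select(tidy(g), -"fragments")) |>
    bind_rows(.id = "experiment")
  write_tsv_with_header(gtab, file.path(dir, "gene_scores.tsv"),
                        "NNLS gene scores (score = pos - neg pass)")
  write_tsv_with_header(res$calls, file.path(dir, "effect_calls.tsv"),
                        "reliable / high-confidence effect calls")
  if (!is.null(res$fdr)) {
    write_tsv_with_header(glance(res$fdr), file.path(dir, "fdr.tsv"),
                          "shuffle-based FDR estimate")
  }
  write_tsv_with_header(res$stage_log, file.path(dir, "stage_log.tsv"),
                        "per-stage record tallies")
  invisible(dir)
}
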