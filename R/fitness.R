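#' Select barcodes adequately represented at time zero
#'
#' A barcode is valid for an experiment set iff it has at least
#' `min_t0_reads` reads in at least one of that set's time-zero samples.
#' Fitness scores are computed only for valid barcodes.
#'
#' @param counts Long count tibble from [assemble_count_matrix()].
#' @param design Experiment design tibble.
#' @param min_t0_reads Minimum reads in some time-zero sample (default 10).
#' @return Tibble with columns `set_id`, `barcode`, one row per valid
#'   barcode per set.
#' @export
select_valid_barcodes <- function(counts, design, min_t0_reads = 10L) {
  design <- validate_design(design)
  t0 <- design |> filter(.data$is_time_zero)
  counts |>
    inner_join(select(t0, "sample_id", "set_id"), by = "sample_id") |>
    summarise(max_t0 = max(.data$count), .by = c("set_id", "barcode")) |>
    filter(.data$max_t0 >= min_t0_reads) |>
    select("set_id", "barcode")
}

#' Compute fragment fitness scores for one condition sample
#'
#' For every valid barcode in the sample's set, the raw score is
#' `f_raw = log2((s + 1) / (t + 1))` where `s` is the barcode's count in the
#' condition sample and `t` is the sum of its counts across the set's
#' time-zero samples. Scores are then normalized so the median over valid
#' fragments in the experiment is zero: `f = f_raw - median(f_raw)`.
#'
#' @inheritParams select_valid_barcodes
#' @param sample_id The condition sample to score.
#' @return Tibble with columns `barcode`, `s`, `t`, `f_raw`, `f`, with
#'   attributes `sample_id` and `set_id`.
#' @export
compute_fragment_scores <- function(counts, design, sample_id,
                                    min_t0_reads = 10L) {
  design <- validate_design(design)
  row <- design |> filter(.data$sample_id == .env$sample_id)
  if (nrow(row) != 1) abort(sprintf("unknown sample_id '%s'", sample_id))
  set <- row$set_id
  valid <- select_valid_barcodes(counts, design, min_t0_reads) |>
    filter(.data$set_id == set)
  t0_samples <- design |>
    filter(.data$set_id == set, .data$is_time_zero) |>
    pull("sample_id")
  t_tbl <- counts |>
    filter(.data$sample_id %in% t0_samples) |>
    summarise(t = sum(.data$count), .by = "barcode")
  s_tbl <- counts |>
    filter(.data$sample_id == .env$sample_id) |>
    select("barcode", s = "count")
  out <- valid |>
    select("barcode") |>
    left_join(s_tbl, by = "barcode") |>
    left_join(t_tbl, by = "barcode") |>
    mutate(
      s = coalesce(.data$s, 0L),
      t = coalesce(.data$t, 0L),
      f_raw = log2((.data$s + 1) / (.data$t + 1)),
      f = .data$f_raw - median(.data$f_raw)
    )
  attr(out, "sample_id") <- sample_id
  attr(out, "set_id") <- set
  out
}

#' Fragment scores for every condition sample in a design
#'
#' @inheritParams select_valid_barcodes
#' @return Long tibble with an `experiment` column (the condition sample id)
#'   prepended to the per-sample output of [compute_fragment_scores()].
#' @export
fragment_score_table <- function(counts, design, min_t0_reads = 10L) {
  design <- validate_design(design)
  cond <- design |> filter(!.data$is_time_zero) |> pull("sample_id")
  purrr::map(cond, function(sid)
    compute_fragment_scores(counts, design, sid, min_t0_reads)) |>
    setNames(cond) |>
    bind_rows(.id = "experiment")
}

#' Build the fragment-by-gene coverage matrix
#'
#' Entry `(i, j)` is 1 iff fragment `i` contains gene `j` completely (start
#' to stop): same contig, `gene_start >= frag_start` and
#' `gene_end <= frag_end` (0-based half-open on both sides; containment is
#' inclusive, so a gene exactly equal to the fragment interval is covered).
#' Strand is ignored.
#'
#' @param fragments Reference fragment tibble (`up`, `contig`, `start`,
#'   `end`); rows are identified by the UP barcode.
#' @param genes Gene annotation tibble with columns `gene_id`, `contig`,
#'   `start`, `end` (0-based half-open).
#' @param contig_lengths Optional named vector; when supplied, genes beyond
#'   contig bounds raise an annotation error.
#' @return Sparse binary matrix (`Matrix::dgCMatrix`) with fragment UP
#'   barcodes as rownames and gene ids as colnames.
#' @export
build_coverage_matrix <- function(fragments, genes, contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    bad <- genes$start < 0 | genes$end > contig_lengths[genes$contig]
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      abort(sprintf("gene(s) beyond contig bounds: %s",
                    paste(head(genes$gene_id[which(bad | is.na(bad))], 5),
                          collapse = ", ")))
    }
  }
  hits <- inner_join(
    fragments |> select("up", "contig", frag_start = "start", frag_end = "end"),
    genes |> select("gene_id", "contig", gene_start = "start", gene_end = "end"),
    by = "contig", relationship = "many-to-many"
  ) |>
    filter(.data$gene_start >= .data$frag_start,
           .data$gene_end <= .data$frag_end)
  Matrix::sparseMatrix(
    i = match(hits$up, fragments$up),
    j = match(hits$gene_id, genes$gene_id),
    x = 1,
    dims = c(nrow(fragments), nrow(genes)),
    dimnames = list(fragments$up, genes$gene_id)
  )
}

# rows of A for the scored fragments; genes with no covering scored fragment
# are dropped (reported as missing, not zero)
restrict_coverage <- function(fscores, A) {
  rows <- intersect(fscores$barcode, rownames(A))
  A2 <- A[rows, , drop = FALSE]
  A2[, Matrix::colSums(A2) > 0, drop = FALSE]
}

#' Mean gene scores (average over fully covering fragments)
#'
#' The naive estimator: the mean fitness of all valid fragments that contain
#' the gene in its entirety. Kept for comparison with the regression score,
#' which removes the inflation that the mean suffers for neutral genes whose
#' covering fragments also carry a causative neighbor.
#'
#' @param fscores Fragment score tibble from [compute_fragment_scores()].
#' @param A Coverage matrix from [build_coverage_matrix()].
#' @return Tibble with columns `gene_id`, `score_mean`, `n_fragments`; genes
#'   covered by no scored fragment are absent.
#' @export
compute_gene_scores_mean <- function(fscores, A) {
  A2 <- restrict_coverage(fscores, A)
  if (ncol(A2) == 0 || nrow(A2) == 0) {
    return(tibble(gene_id = character(), score_mean = numeric(),
                  n_fragments = integer()))
  }
  f <- fscores$f[match(rownames(A2), fscores$barcode)]
  n <- Matrix::colSums(A2)
  tibble(
    gene_id = colnames(A2),
    score_mean = as.numeric(Matrix::crossprod(A2, f)) / as.numeric(n),
    n_fragments = as.integer(n)
  )
}

#' Deconvolve fragment fitness into gene scores by non-negative least squares
#'
#' Models each fragment's fitness as the sum of the scores of the genes it
#' covers completely and solves `argmin ||A g - f||^2` subject to `g >= 0`
#' (Lawson-Hanson NNLS). Because the non-negativity constraint can only
#' describe beneficial genes, a second pass is run with the signs of the
#' fragment scores flipped to estimate deleterious scores; the reported
#' signed score is `score_pos - score_neg`. Genes covered by no scored
#' fragment are reported as missing, not zero.
#'
#' @inheritParams compute_gene_scores_mean
#' @return Object of class `dubseq_gscore`; use [tidy.dubseq_gscore()] for
#'   the per-gene table and [glance.dubseq_gscore()] for fit-level summaries.
#' @export
fit_gene_scores <- function(fscores, A) {
  A2 <- restrict_coverage(fscores, A)
  empty <- ncol(A2) == 0 || nrow(A2) == 0
  f <- if (empty) numeric(0) else fscores$f[match(rownames(A2), fscores$barcode)]
  if (empty) {
    scores <- tibble(gene_id = character(), score = numeric(),
                     score_pos = numeric(), score_neg = numeric(),
                     score_mean = numeric(), n_fragments = integer(),
                     fragments = list())
    sse <- c(pos = 0, neg = 0)
  } else {
    Ad <- as.matrix(A2)
    pos <- pracma::lsqnonneg(Ad, f)
    neg <- pracma::lsqnonneg(Ad, -f)
    n <- Matrix::colSums(A2)
    scores <- tibble(
      gene_id = colnames(A2),
      score = pos$x - neg$x,
      score_pos = pos$x,
      score_neg = neg$x,
      score_mean = as.numeric(Matrix::crossprod(A2, f)) / as.numeric(n),
      n_fragments = as.integer(n),
      fragments = apply(Ad > 0, 2, function(col) rownames(A2)[col],
                        simplify = FALSE)
    )
    sse <- c(pos = pos$resid.norm, neg = neg$resid.norm)
  }
  structure(
    list(scores = scores, sse = sse, n_fragments = nrow(A2),
         n_genes = nrow(scores), fscores = fscores,
         experiment = attr(fscores, "sample_id")),
    class = "dubseq_gscore"
  )
}

#' @export
print.dubseq_gscore <- function(x, ...) {
  cat(sprintf("<dubseq_gscore> %d genes from %d fragments%s\n",
              x$n_genes, x$n_fragments,
              if (is.null(x$experiment)) "" else paste0(" [", x$experiment, "]")))
  print(x$scores, ...)
  invisible(x)
}

#' Tidy a gene-score fit into its per-gene table
#'
#' @param x A `dubseq_gscore` from [fit_gene_scores()].
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `score` (signed regression score),
#'   `score_pos`, `score_neg`, `score_mean`, `n_fragments`, `fragments`
#'   (list of supporting fragment UP barcodes).
#' @export
tidy.dubseq_gscore <- function(x, ...) x$scores

#' One-row summary of a gene-score fit
#'
#' @inheritParams tidy.dubseq_gscore
#' @return Tibble with `n_genes`, `n_fragments`, `sse_pos`, `sse_neg`
#'   (residual sums of squares of the two NNLS passes).
#' @export
glance.dubseq_gscore <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_fragments = x$n_fragments,
         sse_pos = unname(x$sse["pos"]), sse_neg = unname(x$sse["neg"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Clone count required for a target genome coverage probability
#'
#' Number of random shotgun clones needed so each genomic locus is covered
#' with probability `coverage_prob`:
#' `N = ln(1 - coverage_prob) / ln(1 - insert_size / genome_size)`,
#' rounded up.
#'
#' @param insert_size Mean insert size in nt (must be `< genome_size`).
#' @param genome_size Genome size in nt.
#' @param coverage_prob Target coverage probability in (0, 1); default 0.99.
#' @return Tibble with the inputs, the exact value `n_exact` and the
#'   rounded-up clone count `n_clones`.
#' @export
#' @examples
#' estimate_clone_requirement(3000, 4.7e6)
estimate_clone_requirement <- function(insert_size, genome_size,
                                       coverage_prob = 0.99) {
  if (insert_size <= 0 || insert_size >= genome_size) {
    abort("insert_size must be in (0, genome_size)")
  }
  if (coverage_prob <= 0 || coverage_prob >= 1) {
    abort("coverage_prob must be in (0, 1)")
  }
  n <- log(1 - coverage_prob) / log(1 - insert_size / genome_size)
  tibble(insert_size = insert_size, genome_size = genome_size,
         coverage_prob = coverage_prob, n_exact = n, n_clones = ceiling(n))
}
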