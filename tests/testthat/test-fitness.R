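test_that("time-zero representation gates barcode validity", {
  counts <- toy_counts(c("b1", "b2"), t0_1 = c(12L, 3L), t0_2 = c(0L, 0L),
                       s1 = c(5L, 5L))
  valid <- select_valid_barcodes(counts, toy_design())
  expect_equal(valid$barcode, "b1")

  # at least 10 reads in at least ONE time-zero sample suffices
  counts2 <- toy_counts("b2", t0_1 = 3L, t0_2 = 10L, s1 = 5L)
  expect_equal(select_valid_barcodes(counts2, toy_design())$barcode, "b2")

  counts3 <- toy_counts(c("b1", "b2"), t0_1 = c(0L, 0L), t0_2 = c(0L, 0L),
                        s1 = c(50L, 50L))
  expect_equal(nrow(select_valid_barcodes(counts3, toy_design())), 0)

  no_t0 <- toy_design() |> dplyr::mutate(is_time_zero = FALSE)
  expect_error(select_valid_barcodes(counts, no_t0), "time-zero")
})

test_that("fragment scores follow the pseudocounted log2 ratio and center to 0", {
  # t sums across both time-zero samples
  counts <- toy_counts(c("b1", "b2", "b3"),
                       t0_1 = c(10L, 10L, 10L), t0_2 = c(5L, 5L, 53L),
                       s1 = c(15L, 63L, 130L))
  fs <- compute_fragment_scores(counts, toy_design(), "condA_r1")
  expect_equal(fs$t, c(15L, 15L, 63L))
  expect_equal(fs$f_raw[fs$barcode == "b1"], 0)            # log2(16/16)
  expect_equal(fs$f_raw[fs$barcode == "b2"], 2)            # log2(64/16)
  expect_equal(median(fs$f), 0, tolerance = 1e-12)
  expect_equal(fs$f, fs$f_raw - median(fs$f_raw))

  # invalid barcodes receive no score
  counts2 <- toy_counts(c("b1", "b2"), t0_1 = c(12L, 3L), t0_2 = c(0L, 3L),
                        s1 = c(5L, 500L))
  fs2 <- compute_fragment_scores(counts2, toy_design(), "condA_r1")
  expect_equal(fs2$barcode, "b1")
})

test_that("coverage requires full gene containment on the same contig", {
  frags <- tibble::tibble(up = c("F1", "F2"), contig = c("chr1", "chr2"),
                          start = c(0L, 0L), end = c(100L, 500L))
  genes <- tibble::tibble(gene_id = c("gin", "gpart", "gexact", "gother"),
                          contig = c("chr1", "chr1", "chr1", "chr2"),
                          start = c(10L, 90L, 0L, 10L),
                          end = c(20L, 110L, 100L, 20L))
  A <- build_coverage_matrix(frags, genes)
  expect_equal(A["F1", "gin"], 1)
  expect_equal(A["F1", "gpart"], 0)    # partial overlap is not coverage
  expect_equal(A["F1", "gexact"], 1)   # equality is inclusive containment
  expect_equal(A["F1", "gother"], 0)   # different contig
  expect_equal(A["F2", "gother"], 1)

  expect_error(
    build_coverage_matrix(frags, genes, contig_lengths = c(chr1 = 50, chr2 = 600)),
    "beyond contig bounds")
})

fs_fixture <- function(barcodes, f, s = 100L, t = 100L) {
  tibble::tibble(barcode = barcodes, s = s, t = t, f_raw = f, f = f)
}

cov_fixture <- function(barcodes, genes, pairs) {
  Matrix::sparseMatrix(
    i = match(pairs$frag, barcodes), j = match(pairs$gene, genes), x = 1,
    dims = c(length(barcodes), length(genes)),
    dimnames = list(barcodes, genes))
}

test_that("mean scores average covering fragments (and inherit neighbor bias)", {
  A <- cov_fixture(c("F1", "F2", "F3"), "g1",
                   tibble::tibble(frag = c("F1", "F2", "F3"), gene = "g1"))
  fs <- fs_fixture(c("F1", "F2", "F3"), c(2, 2, 2))
  expect_equal(compute_gene_scores_mean(fs, A)$score_mean, 2)

  fs2 <- fs_fixture(c("F1", "F2", "F3"), c(3, 0, 0))
  A2 <- cov_fixture(c("F1", "F2", "F3"), "g1",
                    tibble::tibble(frag = c("F1", "F2"), gene = c("g1", "g1")))
  expect_equal(compute_gene_scores_mean(fs2, A2)$score_mean, 1.5)
  expect_equal(compute_gene_scores_mean(fs2, A2)$n_fragments, 2L)
})

test_that("NNLS assigns the causative gene and zeros its neutral neighbor", {
  # fragments: {g1} f=3, {g1,g2} f=3, {g2} f=0
  bcs <- c("F1", "F2", "F3")
  A <- cov_fixture(bcs, c("g1", "g2"), tibble::tibble(
    frag = c("F1", "F2", "F2", "F3"), gene = c("g1", "g1", "g2", "g2")))
  fs <- fs_fixture(bcs, c(3, 3, 0))
  fit <- fit_gene_scores(fs, A)
  sc <- tidy(fit)
  expect_equal(sc$score[sc$gene_id == "g1"], 3, tolerance = 1e-8)
  expect_equal(sc$score[sc$gene_id == "g2"], 0, tolerance = 1e-8)
  # the mean estimator inflates the neutral neighbor instead
  expect_equal(sc$score_mean[sc$gene_id == "g2"], 1.5)
  expect_equal(glance(fit)$n_genes, 2L)

  # single gene, consistent coverage: plain average
  A1 <- cov_fixture(bcs, "g1", tibble::tibble(frag = bcs, gene = "g1"))
  fit1 <- fit_gene_scores(fs_fixture(bcs, c(2, 2, 2)), A1)
  expect_equal(tidy(fit1)$score, 2, tolerance = 1e-8)

  # all-nonpositive scores leave the positive pass at zero
  fitn <- fit_gene_scores(fs_fixture(bcs, c(-1, -2, -3)), A1)
  expect_true(all(tidy(fitn)$score_pos == 0))
  expect_lt(tidy(fitn)$score, 0)

  # degenerate input: no fragments
  fit0 <- fit_gene_scores(fs_fixture(character(0), numeric(0)), A1)
  expect_equal(nrow(tidy(fit0)), 0)
})

test_that("NNLS matches the grid oracle and the unconstrained OLS limit", {
  withr::local_seed(51)
  for (i in 1:8) {
    n_genes <- sample(2:4, 1)
    n_frags <- sample(3:8, 1)
    repeat {
      A <- matrix(rbinom(n_frags * n_genes, 1, 0.5), n_frags, n_genes)
      # full column rank keeps the constrained optimum unique, so the two
      # routes are comparable
      if (all(colSums(A) > 0) && all(rowSums(A) > 0) &&
          qr(A)$rank == n_genes) break
    }
    truth <- round(runif(n_genes, 0, 2), 2)
    f <- as.numeric(A %*% truth) + round(rnorm(n_frags, 0, 0.2), 2)
    bcs <- sprintf("F%d", seq_len(n_frags))
    dimnames(A) <- list(bcs, sprintf("g%d", seq_len(n_genes)))
    fit <- fit_gene_scores(fs_fixture(bcs, f), Matrix::Matrix(A, sparse = TRUE))
    oracle <- grid_nnls(A, f, upper = max(abs(f)) + 1)
    expect_equal(tidy(fit)$score_pos, oracle, tolerance = 0.021)
  }

  # when OLS is elementwise nonnegative, NNLS equals OLS
  A <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0), 4, 2)
  dimnames(A) <- list(sprintf("F%d", 1:4), c("g1", "g2"))
  f <- as.numeric(A %*% c(1.5, 0.7)) + c(0.05, -0.05, 0.02, 0)
  ols <- as.numeric(solve(crossprod(A), crossprod(A, f)))
  expect_true(all(ols >= 0))
  fit <- fit_gene_scores(fs_fixture(rownames(A), f),
                         Matrix::Matrix(A, sparse = TRUE))
  expect_equal(tidy(fit)$score_pos, ols, tolerance = 1e-6)
})

test_that("clone-count formula reproduces closed-form values and monotonicity", {
  # insert/genome = 0.5 at 99%: ln(0.01)/ln(0.5) ~ 6.64 -> 7 clones
  est <- estimate_clone_requirement(500, 1000, 0.99)
  expect_equal(est$n_exact, log(0.01) / log(0.5), tolerance = 1e-12)
  expect_equal(est$n_clones, 7)

  # the formula as printed for a 3 kb insert and 4.7 Mb genome
  est2 <- estimate_clone_requirement(3000, 4.7e6, 0.99)
  expect_equal(est2$n_exact, log(0.01) / log(1 - 3000 / 4.7e6), tolerance = 1e-9)
  expect_equal(est2$n_clones, 7213)

  probs <- c(0.5, 0.9, 0.99, 0.999)
  ns <- vapply(probs, function(p)
    estimate_clone_requirement(3000, 4.7e6, p)$n_exact, numeric(1))
  expect_true(all(diff(ns) > 0))

  expect_error(estimate_clone_requirement(5000, 4000), "insert_size")
  expect_error(estimate_clone_requirement(10, 100, 1), "coverage_prob")
})
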