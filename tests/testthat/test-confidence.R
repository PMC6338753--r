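one_gene_cov <- function(bcs, gene = "g1") {
  Matrix::sparseMatrix(i = seq_along(bcs), j = rep(1, length(bcs)), x = 1,
                       dims = c(length(bcs), 1),
                       dimnames = list(bcs, gene))
}

fs_tbl <- function(bcs, f, s = 100L, t = 100L) {
  tibble::tibble(barcode = bcs, s = s, t = t, f_raw = f, f = f)
}

test_that("Poisson noise and z follow the closed-form expressions", {
  # one fragment, s = t = 63: noise = sqrt(2/64)/ln 2
  fs <- fs_tbl("F1", f = 1, s = 63L, t = 63L)
  nz <- gene_noise_z(fs, one_gene_cov("F1"))
  expect_equal(nz$gene_noise, sqrt(2 / 64) / log(2), tolerance = 1e-12)
  expect_equal(nz$gene_noise, 0.2551, tolerance = 1e-3)
  expect_equal(nz$z, 1 / (sqrt(2 / 64) / log(2)), tolerance = 1e-12)

  # deep counts: noise vanishes, |z| blows up
  fs2 <- fs_tbl("F1", f = 0.1, s = 10000000L, t = 10000000L)
  nz2 <- gene_noise_z(fs2, one_gene_cov("F1"))
  expect_lt(nz2$gene_noise, 1e-3)
  expect_gt(abs(nz2$z), 100)

  # two fragments of equal noise nu: gene noise = nu / sqrt(2)
  fs3 <- fs_tbl(c("F1", "F2"), f = c(1, 1), s = 63L, t = 63L)
  nz3 <- gene_noise_z(fs3, one_gene_cov(c("F1", "F2")))
  nu <- sqrt(2 / 64) / log(2)
  expect_equal(nz3$gene_noise, nu / sqrt(2), tolerance = 1e-12)
})

test_that("consistency t-test matches the closed-form statistic", {
  # f = [3.0, 3.1, 2.9] vs 0: t = 3 / (0.1/sqrt(3)) ~ 51.96
  t_manual <- 3 / (sd(c(3.0, 3.1, 2.9)) / sqrt(3))
  expect_equal(t_manual, 51.96, tolerance = 1e-3)
  # experiment with background fragments keeping the global mean near zero;
  # the reference is that mean (same sign as the score), still far from 3
  bcs <- c("F1", "F2", "F3", sprintf("B%02d", 1:17))
  fs <- fs_tbl(bcs, c(3.0, 3.1, 2.9, rep(c(-0.05, 0.05), length.out = 17)))
  A <- Matrix::sparseMatrix(i = 1:3, j = rep(1, 3), x = 1, dims = c(20, 1),
                            dimnames = list(bcs, "g1"))
  gs <- tibble::tibble(gene_id = "g1", score = 3)
  res <- consistency_test(fs, A, gs)
  r_expected <- mean(fs$f)
  expect_equal(t.test(c(3.0, 3.1, 2.9), mu = r_expected)$p.value, res$p_value)
  expect_lt(res$p_value, 0.05)
  expect_true(res$passes_consistency)

  # noisy, mean ~ 0: fails
  bcs4 <- c("F1", "F2", "F3", "F4")
  fs4 <- fs_tbl(bcs4, c(3, -2, 2, -1))
  res4 <- consistency_test(fs4, one_gene_cov(bcs4),
                           tibble::tibble(gene_id = "g1", score = 0.5))
  expect_false(res4$passes_consistency)

  # identical scores (zero variance) pass when the mean differs from r
  fs0 <- fs_tbl(bcs, c(2, 2, 2, rep(0, 17)))
  res0 <- consistency_test(fs0, A,
                           tibble::tibble(gene_id = "g1", score = 2))
  expect_true(res0$passes_consistency)
  expect_equal(res0$p_value, 0)
})

test_that("single-fragment genes use the top-1% rule over |f|", {
  withr::local_seed(61)
  n <- 1000
  f_all <- sort(abs(rnorm(n)))          # ranks are easy to read off
  bcs <- sprintf("F%04d", seq_len(n))
  fs <- fs_tbl(bcs, f_all)
  top_bc <- bcs[996]                    # 99.5th percentile of |f|
  mid_bc <- bcs[950]                    # 95th percentile
  A <- Matrix::sparseMatrix(i = match(c(top_bc, mid_bc), bcs), j = c(1, 2),
                            x = 1, dims = c(n, 2),
                            dimnames = list(bcs, c("gtop", "gmid")))
  gs <- tibble::tibble(gene_id = c("gtop", "gmid"), score = c(3, 3))
  res <- consistency_test(fs, A, gs)
  expect_true(res$passes_consistency[res$gene_id == "gtop"])
  expect_false(res$passes_consistency[res$gene_id == "gmid"])
  expect_true(is.na(res$p_value[res$gene_id == "gtop"]))
})

test_that("reliable calls are the conjunction of the three filters", {
  # three covering fragments plus neutral background fragments (so the
  # experiment-wide mean stays near zero)
  withr::local_seed(62)
  cov_bcs <- c("F1", "F2", "F3")
  bg_bcs <- sprintf("B%02d", 1:20)
  bcs <- c(cov_bcs, bg_bcs)
  A <- Matrix::sparseMatrix(i = 1:3, j = rep(1, 3), x = 1,
                            dims = c(23, 1), dimnames = list(bcs, "g1"))
  mk_fit <- function(f_cov, s = 2000L, t = 2000L) {
    f <- c(f_cov, round(rnorm(20, 0, 0.1), 3))
    fit_gene_scores(fs_tbl(bcs, f, s = s, t = t), A)
  }
  call1 <- call_reliable(mk_fit(c(3.0, 3.1, 2.9)), A)
  expect_true(call1$reliable)
  expect_true(call1$passes_magnitude && call1$passes_noise &&
                call1$passes_consistency)

  # magnitude below 2 fails even if consistent and low-noise
  call2 <- call_reliable(mk_fit(c(1.9, 1.9, 1.9)), A)
  expect_false(call2$passes_magnitude)
  expect_true(call2$passes_noise)
  expect_false(call2$reliable)

  # shallow counts push |z| under 4: not reliable
  call3 <- call_reliable(mk_fit(c(3.0, 3.1, 2.9), s = 1L, t = 1L), A)
  expect_false(call3$passes_noise)
  expect_false(call3$reliable)
})

test_that("high confidence needs multi-fragment support or compound replication", {
  calls <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gC"),
    experiment = c("e1", "e1", "e1", "e2"),
    score = c(3, 3, 3, 2.4),
    n_fragments = c(3L, 1L, 1L, 1L),
    reliable = c(TRUE, TRUE, TRUE, FALSE)
  )
  cm <- tibble::tibble(experiment = c("e1", "e2"), compound = "nickel")
  out <- call_high_confidence(calls, cm)
  expect_true(out$high_confidence[out$gene_id == "gA"])                 # >1 fragment
  expect_false(out$high_confidence[out$gene_id == "gB"])                # lone fragment
  expect_true(out$high_confidence[out$gene_id == "gC" &
                                    out$experiment == "e1"])            # |2.4| >= 2 in e2
})

test_that("replicate consistency applies the 1.5 same-sign rule", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    experiment = rep(c("r1", "r2"), 3),
    score = c(3.0, 1.6, 3.0, -2.0, 3.0, 1.4),
    n_fragments = 2L,
    reliable = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  pairs <- tibble::tibble(experiment_a = "r1", experiment_b = "r2")
  res <- replicate_consistency(calls, pairs)
  expect_equal(res$n_effects, 3)
  d <- res$detail
  expect_true(d$consistent[d$gene_id == "g1"])
  expect_false(d$consistent[d$gene_id == "g2"])   # sign flip
  expect_false(d$consistent[d$gene_id == "g3"])   # 1.4 < 1.5
  expect_equal(res$fraction, 1 / 3)
})

test_that("expected false positives follow the normal tail and scale linearly", {
  expect_equal(expected_false_positives(4303, 4), 4303 * 2 * pnorm(-4))
  expect_equal(expected_false_positives(4303, 4), 0.27, tolerance = 0.01)
  expect_equal(expected_false_positives(0, 4), 0)
  expect_equal(expected_false_positives(100, 0), 100)
  zs <- seq(0, 6, by = 0.5)
  vals <- vapply(zs, expected_false_positives, numeric(1), n_genes = 1000)
  expect_true(all(diff(vals) < 0))
  expect_equal(expected_false_positives(2000, 3),
               2 * expected_false_positives(1000, 3))
})

test_that("operon-position comparison builds the 2x2 and matches an exact oracle", {
  # 30/100 first-gene hits vs 13/100 later-gene hits
  genes <- c(sprintf("f%03d", 1:100), sprintf("l%03d", 1:100))
  operons <- tibble::tibble(gene_id = genes,
                            position = rep(c("first", "later"), each = 100))
  calls <- tibble::tibble(
    gene_id = genes,
    experiment = "e1",
    high_confidence = c(rep(TRUE, 30), rep(FALSE, 70),
                        rep(TRUE, 13), rep(FALSE, 87))
  )
  res <- operon_position_comparison(calls, operons)
  expect_equal(res$prop_first, 0.30)
  expect_equal(res$prop_later, 0.13)
  expect_equal(res$odds_ratio, 30 * 87 / (70 * 13), tolerance = 1e-9)

  # independent two-sided Fisher p by hypergeometric enumeration
  enum_p <- local({
    k <- 0:43
    probs <- dhyper(k, 43, 157, 100)
    p_obs <- dhyper(30, 43, 157, 100)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  })
  expect_equal(res$p_value, enum_p, tolerance = 1e-6)
  expect_lt(res$p_value, 0.05)

  # ambiguous genes are excluded; empty categories give not-applicable
  operons2 <- dplyr::bind_rows(operons,
                               tibble::tibble(gene_id = "f001", position = "later"))
  res2 <- operon_position_comparison(calls, operons2)
  expect_equal(res2$n_first, 99)
  res3 <- operon_position_comparison(calls,
                                     operons |> dplyr::filter(position == "first"))
  expect_false(res3$applicable)
})
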