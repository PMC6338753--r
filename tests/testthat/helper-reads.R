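# shared fixtures: a small flank spec and constructors for synthetic reads

UP5 <- "GATGTCCAC"
UP3 <- "AGAGACCTC"

test_spec <- function(...) {
  flank_spec(UP5, UP3, expected_start = 14L, ...)
}

# build one read: pad + anchor + barcode + anchor + tail, constant quality
make_read <- function(barcode, pad = "ACGTA", tail = "", q = 35L,
                      id = "r1", up5 = UP5, up3 = UP3) {
  seq <- paste0(pad, up5, barcode, up3, tail)
  tibble::tibble(read_id = id, sequence = seq,
                 quality = strrep(intToUtf8(33L + q), nchar(seq)))
}

make_reads <- function(barcodes, ...) {
  purrr::imap(barcodes, function(b, i)
    make_read(b, id = paste0("r", i), ...)) |>
    dplyr::bind_rows()
}

# set one read's quality at barcode position `pos` (1-based within barcode)
set_barcode_quality <- function(reads, pos, q, offset = 14L) {
  p <- offset + pos
  substr(reads$quality, p, p) <- intToUtf8(33L + q)
  reads
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_barcodes <- function(n, len = 20L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# exhaustive full-scan alignment oracle for substitution-free tails:
# find all exact occurrences of tail (both strands) in a genome string
scan_oracle <- function(tail, genome) {
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tail else dubseqr::revcomp(tail)
    m <- gregexpr(q, genome, fixed = TRUE)[[1]]
    if (m[1] != -1) {
      for (p in as.integer(m)) {
        hits[[length(hits) + 1]] <- list(pos = p - 1L, strand = strand)
      }
    }
  }
  hits
}

# grid-based NNLS oracle: full enumeration for <= 2 genes, cyclic
# grid-coordinate descent otherwise (convex objective: converges to the
# global constrained optimum); independent of the Lawson-Hanson route
grid_nnls <- function(A, f, step = 0.01, upper = NULL) {
  A <- as.matrix(A)
  p <- ncol(A)
  if (is.null(upper)) upper <- max(abs(f), 1) + 1
  grid <- seq(0, upper, by = step)
  obj <- function(g) sum((A %*% g - f)^2)
  if (p <= 2) {
    if (p == 1) {
      vals <- vapply(grid, function(g) obj(g), numeric(1))
      return(grid[which.min(vals)])
    }
    best <- c(0, 0); best_obj <- obj(best)
    for (g1 in grid) for (g2 in grid) {
      o <- obj(c(g1, g2))
      if (o < best_obj) { best <- c(g1, g2); best_obj <- o }
    }
    return(best)
  }
  g <- rep(0, p)
  repeat {
    changed <- FALSE
    for (j in seq_len(p)) {
      r <- f - A[, -j, drop = FALSE] %*% g[-j]
      vals <- vapply(grid, function(v) sum((A[, j] * v - r)^2), numeric(1))
      new <- grid[which.min(vals)]
      if (new != g[j]) { g[j] <- new; changed <- TRUE }
    }
    # pairwise 2-D grid sweeps escape single-coordinate zigzag stalls on
    # correlated columns
    for (j in seq_len(p - 1)) for (k in (j + 1):p) {
      r <- f - A[, -c(j, k), drop = FALSE] %*% g[-c(j, k)]
      win_j <- grid[abs(grid - g[j]) <= 0.5]
      win_k <- grid[abs(grid - g[k]) <= 0.5]
      best <- c(g[j], g[k]); best_obj <- sum((A[, j] * g[j] + A[, k] * g[k] - r)^2)
      for (vj in win_j) {
        resid_j <- A[, j] * vj - r
        for (vk in win_k) {
          o <- sum((resid_j + A[, k] * vk)^2)
          if (o < best_obj - 1e-12) { best <- c(vj, vk); best_obj <- o }
        }
      }
      if (!identical(best, c(g[j], g[k]))) { g[j] <- best[1]; g[k] <- best[2]; changed <- TRUE }
    }
    if (!changed) break
  }
  g
}

# tiny count/design fixture used across scoring tests
toy_design <- function() {
  tibble::tibble(
    sample_id = c("t0_1", "t0_2", "condA_r1", "condA_r2"),
    set_id = "set1",
    condition = c("time0", "time0", "condA", "condA"),
    is_time_zero = c(TRUE, TRUE, FALSE, FALSE),
    replicate_group = c("time0", "time0", "condA", "condA")
  )
}

toy_counts <- function(barcodes, t0_1, t0_2, s1, s2 = s1) {
  tibble::tibble(
    barcode = rep(barcodes, 4),
    sample_id = rep(c("t0_1", "t0_2", "condA_r1", "condA_r2"),
                    each = length(barcodes)),
    count = c(t0_1, t0_2, s1, s2)
  )
}
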