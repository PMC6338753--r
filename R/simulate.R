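#' Configuration for the synthetic Dub-seq data generator
#'
#' Bundles the study conditions emulated by the simulator: a random genome
#' with non-overlapping genes, a fragment library with normally distributed
#' insert sizes (clamped to the 100-6000 nt cloning window), dual random
#' barcodes per fragment, read generation for the three assay types with
#' configurable base-error and chimera rates, and a Poisson count model
#' around a log-normal library-abundance baseline with gene effects injected
#' as log2 fold-changes.
#'
#' @param genome_length Genome size in nt (default 50000).
#' @param n_genes Number of genes (default 40).
#' @param gene_length Length-2 range of gene lengths in nt (default
#'   `c(500, 1500)`).
#' @param n_fragments Number of library fragments (default 500).
#' @param fragment_mean,fragment_sd Normal insert-size parameters in nt
#'   (defaults 2600 and 700, the library-scale insert distribution).
#' @param barcode_length Barcode length in nt (default 20).
#' @param error_rate Per-base substitution error rate in reads (default 0).
#' @param base_quality Constant Phred quality written to reads (default 35).
#' @param chimera_rate Fraction of BPseq reads whose DOWN barcode is taken
#'   from another fragment, emulating chimeric PCR (default 0).
#' @param effects Named numeric vector of gene effects: log2 fitness
#'   fold-change per generation-collapsed assay (unnamed genes are neutral).
#' @param depth Expected reads per sample in the count model (default 50000,
#'   i.e. a mean of 100 reads per fragment at 500 fragments).
#' @param reads_per_fragment Mean characterization reads per fragment for
#'   BPseq/BAGseq (default 20).
#' @param tail_length Genomic tail length in BAGseq reads (default 50).
#' @param n_t0 Number of time-zero samples in the set (default 2).
#' @param conditions Character vector of condition names (default "cond1").
#' @param n_replicates Replicate condition samples per condition (default 2).
#' @param seed Base integer seed; every stage derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L, n_genes = 40L,
                       gene_length = c(500L, 1500L), n_fragments = 500L,
                       fragment_mean = 2600, fragment_sd = 700,
                       barcode_length = 20L, error_rate = 0,
                       base_quality = 35L, chimera_rate = 0,
                       effects = numeric(0), depth = 50000L,
                       reads_per_fragment = 20, tail_length = 50L,
                       n_t0 = 2L, conditions = "cond1", n_replicates = 2L,
                       seed = 1L) {
  stopifnot(genome_length > 0, n_genes > 0, n_fragments > 0,
            error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# simulator vector context: anchor sequences flanking the two barcodes
SIM_ANCHORS <- list(
  up5 = "GATGTCCAC", up3 = "AGAGACCTC",
  down5 = "GTCGACCTG", down3 = "CGGTACGCT"
)

#' Flanking-sequence specs matching the simulator's read layouts
#'
#' @param config A [sim_config()].
#' @return Named list of [flank_spec()] objects: `up` (BPseq/BarSeq/BAGseq
#'   UP barcode), `down_bpseq` (DOWN barcode inside a BPseq read), `down`
#'   (DOWN barcode in BAGseq/BarSeq DOWN reads).
#' @export
sim_flank_specs <- function(config) {
  bl <- config$barcode_length
  list(
    up = flank_spec(SIM_ANCHORS$up5, SIM_ANCHORS$up3, expected_start = 14L,
                    barcode_length = bl),
    down_bpseq = flank_spec(SIM_ANCHORS$down5, SIM_ANCHORS$down3,
                            expected_start = 14L + bl + 9L + 10L + 9L,
                            barcode_length = bl),
    down = flank_spec(SIM_ANCHORS$down5, SIM_ANCHORS$down3,
                      expected_start = 14L, barcode_length = bl)
  )
}

#' Simulate a genome and a non-overlapping gene annotation
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default derived from `config$seed`).
#' @return List with `genome` (named character vector, one contig) and
#'   `genes` (tibble `gene_id`, `contig`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @export
simulate_genome_and_genes <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    genome <- random_dna(config$genome_length)
    lens <- sample(seq(config$gene_length[1], config$gene_length[2]),
                   config$n_genes, replace = TRUE)
    min_gap <- 50L
    slack <- config$genome_length - sum(lens) - min_gap * (config$n_genes + 1L)
    if (slack < 0) {
      abort("genes cannot be placed: genome too small for n_genes at these lengths")
    }
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, config$n_genes + 1L)))
    gaps <- min_gap + extra
    starts <- cumsum(gaps[seq_len(config$n_genes)]) +
      cumsum(c(0L, lens[-config$n_genes]))
    genes <- tibble(
      gene_id = sprintf("g%03d", seq_len(config$n_genes)),
      contig = "chr1",
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    )
    list(genome = c(chr1 = genome), genes = genes)
  })
}

#' Simulate the fragment library with dual barcodes
#'
#' Fragment lengths are drawn Normal(`fragment_mean`, `fragment_sd`) and
#' clamped to the 100-6000 nt cloning window; positions are uniform; every
#' fragment gets a unique random UP/DOWN barcode pair and a random insert
#' orientation.
#'
#' @inheritParams simulate_genome_and_genes
#' @param genome Named character vector from [simulate_genome_and_genes()].
#' @return Truth fragment tibble: `up`, `down`, `contig`, `start`, `end`,
#'   `length`, `orientation` (0-based half-open).
#' @export
simulate_library <- function(config, genome, seed = config$seed + 1L) {
  withr::with_seed(seed, {
    L <- nchar(genome[[1]])
    n <- config$n_fragments
    lens <- pmin(pmax(round(rnorm(n, config$fragment_mean, config$fragment_sd)),
                      100L), 6000L)
    lens <- pmin(lens, L)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                     integer(1))
    n_bc <- 2L * n
    repeat {
      bcs <- vapply(seq_len(n_bc), function(i)
        random_dna(config$barcode_length), character(1))
      if (!anyDuplicated(bcs)) break
    }
    tibble(
      up = bcs[seq_len(n)],
      down = bcs[n + seq_len(n)],
      contig = names(genome)[1],
      start = as.integer(starts),
      end = as.integer(starts + lens),
      length = as.integer(lens),
      orientation = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

# random substitution errors at rate `rate`, vectorized over sequences
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# per-read 5' pads of length 5 +/- 2 nt, exercising the anchored-search
# shift window
random_pads <- function(n) {
  shifts <- sample(-2:2, n, replace = TRUE)
  vapply(5L + shifts, function(l) random_dna(l), character(1))
}

#' Simulate reads for one assay type
#'
#' Emits reads laid out to match [sim_flank_specs()]: a random-length 5' pad
#' (5 +/- 2 nt), the anchored barcode block(s), and for BAGseq the genomic
#' sequence flanking the insert junction. BPseq chimeras are injected at
#' `config$chimera_rate` and truth-labeled in the read id
#' (`chimera=1`). Base errors are substitutions at `config$error_rate`;
#' qualities are constant at `config$base_quality`.
#'
#' @inheritParams simulate_library
#' @param truth Truth fragment tibble from [simulate_library()].
#' @param assay One of `"bpseq"`, `"bagseq_up"`, `"bagseq_down"`,
#'   `"barseq"`.
#' @param counts For `assay = "barseq"`: tibble `barcode`, `count` giving
#'   reads per UP barcode (e.g. one sample of a simulated count matrix).
#' @return Read tibble (`read_id`, `sequence`, `quality`); read ids carry
#'   `frag=<up barcode>` truth labels.
#' @export
simulate_reads <- function(truth, genome, config,
                           assay = c("bpseq", "bagseq_up", "bagseq_down",
                                     "barseq"),
                           counts = NULL, seed = config$seed + 2L) {
  assay <- match.arg(assay)
  an <- SIM_ANCHORS
  gseq <- genome[[1]]
  withr::with_seed(seed, {
    if (assay == "barseq") {
      if (is.null(counts)) abort("barseq simulation needs per-barcode counts")
      idx <- rep(seq_len(nrow(counts)), counts$count)
      bc <- counts$barcode[idx]
      n <- length(bc)
      post <- vapply(rep(10L, n), random_dna, character(1))
      body <- paste0(an$up5, bc, an$up3, post)
      ids <- sprintf("bar_%07d|frag=%s", seq_len(n), bc)
    } else {
      n_reads <- pmax(2L, rpois(nrow(truth), config$reads_per_fragment))
      idx <- rep(seq_len(nrow(truth)), n_reads)
      n <- length(idx)
      up <- truth$up[idx]
      if (assay == "bpseq") {
        down <- truth$down[idx]
        chim <- runif(n) < config$chimera_rate
        if (any(chim)) {
          other <- vapply(idx[chim], function(i)
            sample(truth$down[-i], 1L), character(1))
          down[chim] <- other
        }
        spacer <- vapply(rep(10L, n), random_dna, character(1))
        body <- paste0(an$up5, up, an$up3, spacer,
                       an$down5, down, an$down3)
        ids <- sprintf("bp_%07d|frag=%s|chimera=%d", seq_len(n), truth$up[idx],
                       as.integer(chim))
      } else {
        tl <- config$tail_length
        s <- truth$start[idx]; e <- truth$end[idx]
        ori <- truth$orientation[idx]
        at_start <- if (assay == "bagseq_up") ori == "+" else ori == "-"
        tail <- ifelse(
          at_start,
          substring(gseq, s + 1L, pmin(s + tl, e)),
          revcomp(substring(gseq, pmax(e - tl + 1L, s + 1L), e))
        )
        bc <- if (assay == "bagseq_up") up else truth$down[idx]
        anch <- if (assay == "bagseq_up") c(an$up5, an$up3) else c(an$down5, an$down3)
        body <- paste0(anch[1], bc, anch[2], tail)
        ids <- sprintf("%s_%07d|frag=%s", assay, seq_len(n), truth$up[idx])
      }
    }
    pads <- random_pads(n)
    seqs <- inject_errors(paste0(pads, body), config$error_rate)
    tibble(
      read_id = ids,
      sequence = seqs,
      quality = strrep(intToUtf8(33L + config$base_quality), nchar(seqs))
    )
  })
}

#' Experiment design table for a simulated assay set
#'
#' One set with `n_t0` time-zero samples and `n_replicates` condition
#' samples per condition.
#'
#' @param config A [sim_config()].
#' @return Design tibble (see [validate_design()]).
#' @export
sim_design <- function(config) {
  t0 <- tibble(
    sample_id = sprintf("t0_%d", seq_len(config$n_t0)),
    set_id = "set1", condition = "time0", is_time_zero = TRUE,
    replicate_group = "time0"
  )
  cond <- tidyr::expand_grid(condition = config$conditions,
                             rep = seq_len(config$n_replicates)) |>
    transmute(
      sample_id = sprintf("%s_r%d", .data$condition, .data$rep),
      set_id = "set1", condition = .data$condition, is_time_zero = FALSE,
      replicate_group = .data$condition
    )
  bind_rows(t0, cond)
}

#' Simulate BarSeq count data under a fragment-abundance growth model
#'
#' Each fragment gets a log-normal library abundance. Time-zero counts are
#' Poisson around abundance scaled to `depth`; condition counts are Poisson
#' around abundance multiplied by `2^(sum of covered gene effects)` and
#' rescaled to `depth`. Gene effects come from `config$effects` (log2
#' units); unnamed genes are neutral.
#'
#' @inheritParams simulate_library
#' @param truth Truth fragment tibble.
#' @param genes Gene annotation tibble.
#' @param design Optional design tibble (default [sim_design()]).
#' @return List with `counts` (long `dubseq_counts`-style tibble `barcode`,
#'   `sample_id`, `count`), `design`, and `truth_fitness` (tibble `up`,
#'   `expected_f` = summed covered gene effects).
#' @export
simulate_fitness_counts <- function(truth, genes, config,
                                    design = sim_design(config),
                                    seed = config$seed + 3L) {
  design <- validate_design(design)
  A <- build_coverage_matrix(truth, genes)
  beta <- setNames(rep(0, nrow(genes)), genes$gene_id)
  if (length(config$effects)) {
    unknown <- setdiff(names(config$effects), genes$gene_id)
    if (length(unknown)) {
      abort(sprintf("effects name unknown gene(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    beta[names(config$effects)] <- config$effects
  }
  expected_f <- as.numeric(A %*% beta)
  withr::with_seed(seed, {
    abundance <- rlnorm(nrow(truth), meanlog = 0, sdlog = 1)
    p0 <- abundance / sum(abundance)
    w <- abundance * 2^expected_f
    p1 <- w / sum(w)
    counts <- purrr::map(seq_len(nrow(design)), function(i) {
      p <- if (design$is_time_zero[i]) p0 else p1
      tibble(barcode = truth$up,
             sample_id = design$sample_id[i],
             count = rpois(length(p), config$depth * p))
    }) |> bind_rows()
  })
  counts <- as_tibble(counts)
  class(counts) <- c("dubseq_counts", class(counts))
  list(counts = counts,
       design = design,
       truth_fitness = tibble(up = truth$up, expected_f = expected_f))
}

#' Simulate a complete Dub-seq experiment bundle
#'
#' Chains the genome, library and count simulators (and optionally the read
#' simulators) under one base seed, returning every input the pipeline
#' needs together with the truth tables.
#'
#' @param config A [sim_config()].
#' @param reads Also generate read tibbles for BPseq, both BAGseq tags and
#'   every BarSeq sample? (Default FALSE; count-level studies don't need
#'   them.)
#' @return List with `genome`, `genes`, `fragments` (truth), `design`,
#'   `counts`, `truth_fitness`, `specs` ([sim_flank_specs()]), and when
#'   `reads = TRUE` also `bpseq_reads`, `bagseq_up_reads`,
#'   `bagseq_down_reads`, `barseq_reads` (named list per sample).
#' @export
simulate_experiment <- function(config, reads = FALSE) {
  gg <- simulate_genome_and_genes(config)
  fragments <- simulate_library(config, gg$genome)
  fit <- simulate_fitness_counts(fragments, gg$genes, config)
  out <- list(genome = gg$genome, genes = gg$genes, fragments = fragments,
              design = fit$design, counts = fit$counts,
              truth_fitness = fit$truth_fitness,
              specs = sim_flank_specs(config))
  if (reads) {
    out$bpseq_reads <- simulate_reads(fragments, gg$genome, config, "bpseq")
    out$bagseq_up_reads <- simulate_reads(fragments, gg$genome, config,
                                          "bagseq_up",
                                          seed = config$seed + 11L)
    out$bagseq_down_reads <- simulate_reads(fragments, gg$genome, config,
                                            "bagseq_down",
                                            seed = config$seed + 12L)
    samples <- fit$design$sample_id
    out$barseq_reads <- lapply(seq_along(samples), function(i) {
      per_sample <- fit$counts |>
        filter(.data$sample_id == samples[i]) |>
        select("barcode", "count")
      simulate_reads(fragments, gg$genome, config, "barseq",
                     counts = per_sample, seed = config$seed + 20L + i)
    })
    names(out$barseq_reads) <- samples
  }
  out
}
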