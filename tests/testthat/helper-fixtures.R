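# Shared fixtures. Heavy simulations are built lazily and cached for the
# whole test run; everything is a pure function of fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small hand-made transcriptome: two genes on opposite strands plus a
# pair of overlapping transcripts for ambiguity cases
toy_txome <- function() {
  tx <- tibble::tribble(
    ~transcript_id, ~gene_id, ~chrom, ~start, ~end, ~strand, ~cds_start,
    ~cds_end,
    "t_plus", "g1", "chr1", 100L, 1100L, "+", 250L, 950L,
    "t_minus", "g2", "chr1", 2000L, 3000L, "-", 2150L, 2850L,
    "t_ovlA", "g3", "chr2", 100L, 700L, "+", 150L, 650L,
    "t_ovlB", "g4", "chr2", 300L, 900L, "+", 350L, 850L
  )
  ex <- tibble::tribble(
    ~transcript_id, ~chrom, ~start, ~end, ~strand,
    "t_plus", "chr1", 100L, 400L, "+",
    "t_plus", "chr1", 700L, 1100L, "+",
    "t_minus", "chr1", 2000L, 2300L, "-",
    "t_minus", "chr1", 2600L, 3000L, "-",
    "t_ovlA", "chr2", 100L, 300L, "+",
    "t_ovlA", "chr2", 500L, 700L, "+",
    "t_ovlB", "chr2", 300L, 900L, "+"
  )
  transcriptome(tx, ex)
}

# mid-sized simulated experiment used across peak/motif/differential tests
small_config <- function(seed = 42) {
  sim_config(seed = seed, n_genes = 40, n_peaks = 20,
             reads_per_sample = 40000)
}

small_sim <- function() {
  cached("small_sim", function() {
    cfg <- small_config()
    sim <- simulate_transcriptome(cfg)
    truth <- plant_peaks(sim, cfg)
    sim$genome <- truth$genome
    list(cfg = cfg, sim = sim, truth = truth)
  })
}

# the full study-conditions experiment shared by the acceptance tests:
# default config, WT replicates called and intersected
acceptance_experiment <- function() {
  cached("acceptance_experiment", function() {
    cfg <- sim_config(seed = 20260101)
    sim <- simulate_transcriptome(cfg)
    truth <- plant_peaks(sim, cfg)
    sim$genome <- truth$genome
    rep_peaks <- lapply(seq_len(cfg$n_replicates), function(r) {
      ip <- simulate_reads(sim, truth, cfg, "WT", r, "IP")
      input <- simulate_reads(sim, truth, cfg, "WT", r, "input")
      call_peaks(ip, input, sim$txome)
    })
    final <- replicate_intersection(rep_peaks)
    list(cfg = cfg, sim = sim, truth = truth, rep_peaks = rep_peaks,
         final = final)
  })
}

# control sequences for motif analyses: windows at random transcript-
# interior positions (what input-derived expected peaks converge to under
# the uniform background)
control_sequences <- function(txome, genome, n = 100, flank = 250L,
                              seed = 7) {
  withr::with_seed(seed, {
    tx <- txome$transcripts
    i <- sample(nrow(tx), n, replace = TRUE)
    pos <- tx$start[i] +
      floor(runif(n) * (tx$end[i] - tx$start[i]))
    pos <- pmin(pmax(pos, tx$start[i] + flank + 1L),
                tx$end[i] - flank - 1L)
    pk <- peak_table(tx$chrom[i], pmax(pos - 100L, 0L), pos + 101L, pos,
                     0.5, 0.5, 1)
    extract_peak_sequences(pk, txome, genome, flank = flank)
  })
}

# brute-force helpers (independent oracles)
poisson_tail_series <- function(k, lam) {
  # forward summation of the upper tail: all terms positive, no
  # cancellation; log-scale terms for large lam
  i <- k
  term <- exp(-lam + i * log(lam) - lgamma(i + 1))
  total <- 0
  repeat {
    total <- total + term
    i <- i + 1
    term <- term * lam / i
    if (term < total * 1e-16 || i > k + 10000) break
  }
  min(total, 1)
}

wilcoxon_exact_enumeration <- function(a, b, alternative = "two.sided") {
  n <- length(a)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n * (n + 1) / 2
  }
  u_obs <- u_of(seq_len(n))
  all_u <- apply(utils::combn(length(pooled), n), 2, u_of)
  switch(alternative,
    two.sided = {
      mu <- n * length(b) / 2
      mean(abs(all_u - mu) >= abs(u_obs - mu))
    },
    less = mean(all_u <= u_obs),
    greater = mean(all_u >= u_obs)
  )
}
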