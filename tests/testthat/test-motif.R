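# deterministic synthetic sequence sets used across the motif tests
random_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

plant_motif <- function(seqs, motif, at) {
  # `at` is a 1-based start offset per sequence
  for (i in seq_along(seqs)) {
    substr(seqs[i], at[i], at[i] + nchar(motif) - 1L) <- motif
  }
  seqs
}

test_that("stranded sequence extraction follows transcript strand", {
  txome <- toy_txome()
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 1000), collapse = ""),
    chr2 = paste(rep("GGCA", 500), collapse = "")
  ))
  pk <- peak_table("chr1", 400L, 601L, 500L, 1e-4, 1e-4, 2)
  out <- extract_peak_sequences(pk, txome, genome, flank = 50)
  expect_equal(nrow(out), 1L)
  expect_equal(out$strand, "+")
  expect_equal(out$seq,
               as.character(Biostrings::subseq(genome[["chr1"]], 451, 551)))
  pk_minus <- peak_table("chr1", 2400L, 2601L, 2500L, 1e-4, 1e-4, 2)
  out2 <- extract_peak_sequences(pk_minus, txome, genome, flank = 50)
  expect_equal(out2$strand, "-")
  expect_equal(out2$seq, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[["chr1"]], 2451, 2551))))
  # a peak overlapping no transcript is dropped
  pk_none <- peak_table("chr1", 5000L, 5201L, 5100L, 1e-4, 1e-4, 2)
  expect_equal(nrow(extract_peak_sequences(pk_none, txome, genome)), 0L)
})

test_that("peaks spanning transcripts on both strands are duplicated", {
  tx <- tibble::tribble(
    ~transcript_id, ~gene_id, ~chrom, ~start, ~end, ~strand, ~cds_start,
    ~cds_end,
    "fwd", "g1", "chr1", 100L, 600L, "+", 150L, 550L,
    "rev", "g2", "chr1", 300L, 800L, "-", 350L, 750L
  )
  ex <- dplyr::select(tx, "transcript_id", "chrom", "start", "end",
                      "strand")
  both <- transcriptome(tx, ex)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 500), collapse = "")))
  pk <- peak_table("chr1", 350L, 551L, 450L, 1e-4, 1e-4, 2)
  out <- extract_peak_sequences(pk, both, genome, flank = 50)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$strand, c("+", "-"))
})

test_that("first-order Markov fit matches hand-computed counts", {
  bg <- fit_markov1("AACG")
  # dinucleotides: AA, AC, CG; row A total 2, row C total 1
  expect_equal(bg$transition["A", "A"], (1 + 1) / (2 + 4))
  expect_equal(bg$transition["A", "C"], (1 + 1) / (2 + 4))
  expect_equal(bg$transition["C", "G"], (1 + 1) / (1 + 4))
  expect_equal(unname(rowSums(bg$transition)), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(unname(bg$initial),
               c(2, 1, 1, 0) / 4)
  big <- random_seqs(1, 100000, seed = 4)
  bg2 <- fit_markov1(big)
  expect_true(all(abs(bg2$transition - 0.25) < 0.01))
  expect_error(fit_markov1(character()), "sequence")
})

test_that("a planted center motif is recovered as the top central motif", {
  n <- 60
  seqs <- random_seqs(n, 501, seed = 12)
  seqs <- plant_motif(seqs, "TTCTT", at = rep(249L, n))
  ctl <- random_seqs(n, 501, seed = 13)
  bg <- fit_markov1(ctl)
  motifs <- discover_motifs(seqs, ctl, bg, width_range = c(5L, 6L),
                            n_motifs = 2)
  top <- motifs[[1]]
  expect_true(grepl("UUCUU", top$consensus))
  # EM objective is non-decreasing
  expect_true(all(diff(top$ll_trace) >= -1e-6))
  judged <- motif_centrality(top, seqs)
  expect_equal(judged$centrality, "central")
  expect_lt(judged$centrality_p, 1e-6)
})

test_that("width window restricts reported motif widths", {
  n <- 30
  seqs <- random_seqs(n, 201, seed = 21)
  seqs <- plant_motif(seqs, "TTCTT", at = rep(99L, n))
  bg <- fit_markov1(random_seqs(10, 1000, seed = 22))
  motifs <- discover_motifs(seqs, NULL, bg, width_range = c(5L, 5L),
                            n_motifs = 3)
  expect_true(all(vapply(motifs, `[[`, integer(1), "width") == 5L))
})

test_that("label-shuffled positives show no spurious enrichment", {
  pool <- random_seqs(60, 201, seed = 31)
  bg <- fit_markov1(pool)
  obs <- discover_motifs(pool[1:30], pool[31:60], bg,
                         width_range = c(5L, 6L), n_motifs = 1,
                         n_seeds = 1)[[1]]$enrichment_score
  null_scores <- vapply(1:20, function(s) {
    idx <- withr::with_seed(100 + s, sample(60))
    discover_motifs(pool[idx[1:30]], pool[idx[31:60]], bg,
                    width_range = c(5L, 6L), n_motifs = 1,
                    n_seeds = 1)[[1]]$enrichment_score
  }, numeric(1))
  expect_lte(obs, stats::quantile(null_scores, 0.95) + 1e-9)
})

test_that("centrality judgment separates central from uniform placement", {
  w <- 5L
  # null proportion arithmetic for the standard window
  expect_equal((100 - w + 1) / (501 - w + 1), 96 / 497)
  planted_central <- 0L
  uniform_decentered <- 0L
  base_motif <- structure(
    list(pwm = {
      m <- matrix(0.04, 4, 5)
      codes <- match(strsplit("TTCTT", "")[[1]], c("A", "C", "G", "T"))
      for (k in 1:5) m[codes[k], k] <- 0.88
      m
    }, width = 5L, consensus = "UUCUU"), class = "motif_model")
  for (s in 1:20) {
    n <- 60
    central <- plant_motif(random_seqs(n, 501, seed = 200 + s), "TTCTT",
                           at = rep(249L, n))
    expect_equal(motif_centrality(base_motif, central)$centrality,
                 "central")
    at <- withr::with_seed(300 + s, sample.int(497, n, replace = TRUE))
    uniform <- plant_motif(random_seqs(n, 501, seed = 400 + s), "TTCTT",
                           at = at)
    if (motif_centrality(base_motif, uniform)$centrality == "decentered") {
      uniform_decentered <- uniform_decentered + 1L
    }
  }
  expect_gte(uniform_decentered, 19L)
})

test_that("motif discovery is symmetric under reverse complement", {
  n <- 40
  seqs <- random_seqs(n, 201, seed = 61)
  seqs <- plant_motif(seqs, "TTCAT", at = rep(99L, n))
  ctl <- random_seqs(n, 201, seed = 62)
  bg <- fit_markov1(ctl)
  fwd <- discover_motifs(seqs, ctl, bg, width_range = c(5L, 5L),
                         n_motifs = 1, n_seeds = 1)[[1]]
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  bg_rc <- fit_markov1(rc(ctl))
  rev <- discover_motifs(rc(seqs), rc(ctl), bg_rc,
                         width_range = c(5L, 5L), n_motifs = 1,
                         n_seeds = 1)[[1]]
  expect_equal(rev$pwm, fwd$pwm[4:1, ncol(fwd$pwm):1], tolerance = 1e-6)
})
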