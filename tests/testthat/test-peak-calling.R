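test_that("poisson_tail matches the series oracle and handles edge cases", {
  expect_equal(poisson_tail(0, 5), 1.0)
  expect_equal(poisson_tail(0, 0.01), 1.0)
  # frozen from the series oracle: P(X >= 5 | lam = 1)
  expect_equal(poisson_tail(5, 1), 0.00365984682734371, tolerance = 1e-10)
  expect_error(poisson_tail(3, 0), "lam")
  expect_error(poisson_tail(-1, 1), "k")
  for (lam in c(0.1, 0.5, 1, 2, 5, 10, 20, 30)) {
    for (k in c(0:10, 20, 35, 50)) {
      expect_equal(poisson_tail(k, lam), poisson_tail_series(k, lam),
                   tolerance = 1e-10)
    }
  }
})

test_that("effective transcriptome size counts shared regions once", {
  mk <- function(spans) {
    tx <- tibble::tibble(
      transcript_id = paste0("t", seq_along(spans)),
      gene_id = paste0("g", seq_along(spans)), chrom = "chr1",
      start = vapply(spans, `[`, integer(1), 1),
      end = vapply(spans, `[`, integer(1), 2), strand = "+"
    )
    ex <- dplyr::mutate(tx, transcript_id = .data$transcript_id)
    transcriptome(tx, ex[, c("transcript_id", "chrom", "start", "end",
                             "strand")])
  }
  expect_equal(effective_transcriptome_size(
    mk(list(c(0L, 1000L), c(500L, 2000L)))), 2000L)
  expect_equal(effective_transcriptome_size(
    mk(list(c(0L, 1000L), c(5000L, 6000L)))), 2000L)
  expect_equal(effective_transcriptome_size(
    mk(list(c(0L, 1000L), c(0L, 1000L)))), 1000L)
  empty <- transcriptome(
    tibble::tibble(transcript_id = character(), gene_id = character(),
                   chrom = character(), start = integer(),
                   end = integer(), strand = character()),
    tibble::tibble(transcript_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   strand = character()))
  expect_error(effective_transcriptome_size(empty), "empty")
})

test_that("planted peaks are recovered with correct geometry", {
  fx <- small_sim()
  ip <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "IP")
  input <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "input")
  peaks <- call_peaks(ip, input, fx$sim$txome)
  expect_s3_class(peaks, "hmerip_peaks")
  expect_true(all(peaks$end - peaks$start == 201L))
  expect_true(all(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  d <- vapply(fx$truth$peaks$center,
              function(c0) min(abs(peaks$summit - c0)), numeric(1))
  expect_gte(mean(d <= 50), 0.9)
  # every peak overlaps the transcript union
  u <- dplyr::summarise(
    dplyr::group_by(fx$sim$txome$transcripts, .data$chrom),
    lo = min(.data$start), hi = max(.data$end))
  tx <- fx$sim$txome$transcripts
  in_tx <- vapply(seq_len(nrow(peaks)), function(i) {
    any(tx$chrom == peaks$chrom[i] & tx$start < peaks$end[i] &
          tx$end > peaks$start[i])
  }, logical(1))
  expect_true(all(in_tx))
})

test_that("calling is invariant to read order and chromosome renaming", {
  fx <- small_sim()
  ip <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "IP")
  input <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "input")
  ref <- call_peaks(ip, input, fx$sim$txome)
  withr::with_seed(1, {
    ip_shuf <- read_set(ip$reads[sample(nrow(ip$reads)), ], "x", "WT",
                        "IP", 1)
  })
  expect_equal(as.data.frame(call_peaks(ip_shuf, input, fx$sim$txome)),
               as.data.frame(ref))
  # renaming chromosomes permutes but preserves the per-chromosome calls
  flip <- function(x) ifelse(x == "chrS1", "zchr", x)
  txf <- fx$sim$txome
  tx2 <- transcriptome(
    dplyr::mutate(txf$transcripts, chrom = flip(.data$chrom)),
    dplyr::mutate(txf$exons, chrom = flip(.data$chrom)))
  ipf <- read_set(dplyr::mutate(ip$reads, chrom = flip(.data$chrom)),
                  "x", "WT", "IP", 1)
  inf <- read_set(dplyr::mutate(input$reads, chrom = flip(.data$chrom)),
                  "x", "WT", "input", 1)
  got <- call_peaks(ipf, inf, tx2)
  got$chrom <- ifelse(got$chrom == "zchr", "chrS1", got$chrom)
  got <- dplyr::arrange(got, .data$chrom, .data$start)
  got$name <- ref$name
  expect_equal(as.data.frame(got), as.data.frame(ref))
})

test_that("sensitivity is monotone in planted fold", {
  sens <- vapply(c(2, 4, 8), function(fold) {
    cfg <- sim_config(seed = 101, n_genes = 30, n_peaks = 15,
                      peak_fold = fold, reads_per_sample = 30000)
    sim <- simulate_transcriptome(cfg)
    truth <- plant_peaks(sim, cfg)
    ip <- simulate_reads(sim, truth, cfg, "WT", 1, "IP")
    input <- simulate_reads(sim, truth, cfg, "WT", 1, "input")
    peaks <- call_peaks(ip, input, sim$txome)
    if (nrow(peaks) == 0) return(0)
    mean(vapply(truth$peaks$center,
                function(c0) min(abs(peaks$summit - c0)) <= 100,
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], 0.9)
})

test_that("expected peaks respond to input hotspots and stay silent on flat input", {
  cfg <- sim_config(seed = 55, n_genes = 20, n_peaks = 10,
                    reads_per_sample = 20000)
  sim <- simulate_transcriptome(cfg)
  truth <- plant_peaks(sim, cfg)
  input <- simulate_reads(sim, truth, cfg, "WT", 1, "input")
  # flat input: no expected peaks at q < 0.05
  expect_equal(nrow(call_expected_peaks(input, sim$txome)), 0L)
  # spike a hotspot into one transcript interior
  tx <- sim$txome$transcripts[1, ]
  c0 <- (tx$start + tx$end) %/% 2L
  hot <- tibble::tibble(chrom = tx$chrom,
                        start = rep(c0 - 125L, 600L),
                        end = rep(c0 + 125L, 600L), strand = ".")
  spiked <- read_set(dplyr::bind_rows(input$reads, hot), "spiked", "WT",
                     "input", 1)
  ep <- call_expected_peaks(spiked, sim$txome)
  expect_gte(nrow(ep), 1L)
  expect_lte(min(abs(ep$summit - c0)), 125L)
  # count grows (weakly) with the q threshold
  n_loose <- nrow(call_expected_peaks(spiked, sim$txome,
                                      peak_call_params(q_threshold = 0.5)))
  expect_gte(n_loose, nrow(ep))
})

test_that("replicate intersection follows the all-replicates rule", {
  mk <- function(spans, q = 1e-6) {
    peak_table(chrom = rep("chr1", length(spans)),
               start = vapply(spans, `[`, integer(1), 1),
               end = vapply(spans, `[`, integer(1), 2),
               summit = vapply(spans, function(s) (s[1] + s[2]) %/% 2L,
                               integer(1)),
               pvalue = q, qvalue = q, fold_enrichment = 5)
  }
  same <- mk(list(c(100L, 301L)))
  out <- replicate_intersection(list(same, same, same))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(100L, 301L))
  # present in only 2 of 3 replicates: dropped
  out2 <- replicate_intersection(list(same, same, mk(list(c(900L, 1101L)))))
  expect_equal(nrow(out2), 0L)
  # intersection arithmetic
  out3 <- replicate_intersection(list(mk(list(c(100L, 301L))),
                                      mk(list(c(150L, 351L))),
                                      mk(list(c(120L, 321L)))))
  expect_equal(c(out3$start, out3$end), c(150L, 301L))
  expect_warning(replicate_intersection(list(same)), "single replicate")
})

test_that("replicate intersection equals brute force on random triplets", {
  withr::with_seed(17, {
    for (i in seq_len(500)) {
      spans <- lapply(1:3, function(r) {
        s <- sample.int(400, 1)
        c(s, s + sample.int(300, 1))
      })
      lists <- lapply(spans, function(s) {
        peak_table("chr1", s[1], s[2], s[1], 1e-4, 1e-4, 2)
      })
      got <- replicate_intersection(lists)
      # brute force: per-base membership in all three peaks
      base <- seq.int(0, 800)
      covered <- Reduce(`&`, lapply(spans, function(s) {
        base >= s[1] & base < s[2]
      }))
      if (!any(covered)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(nrow(got), 1L)
        expect_equal(got$start, min(base[covered]))
        expect_equal(got$end, max(base[covered]) + 1L)
      }
    }
  })
})

test_that("q-values are BH-monotone and bounded", {
  fx <- small_sim()
  ip <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "IP")
  input <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "input")
  peaks <- call_peaks(ip, input, fx$sim$txome)
  expect_true(all(peaks$qvalue >= 0 & peaks$qvalue <= 1))
  ord <- order(peaks$pvalue)
  expect_true(all(diff(peaks$qvalue[ord]) >= -1e-12))
})
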