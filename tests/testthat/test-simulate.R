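test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 7, n_genes = 10, n_peaks = 5,
                    reads_per_sample = 5000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_transcriptome(cfg)
    truth <- plant_peaks(sim, cfg)
    write_gtf(sim$txome, file.path(d, "t.gtf"))
    Biostrings::writeXStringSet(truth$genome, file.path(d, "g.fa"))
    write_reads(simulate_reads(sim, truth, cfg, "WT", 1, "IP"),
                file.path(d, "ip.bed"))
  }
  for (f in c("t.gtf", "g.fa", "ip.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("transcript geometry honors the configured ranges", {
  cfg <- sim_config(seed = 3, n_genes = 50, exons_per_gene = c(3L, 5L),
                    n_peaks = 10)
  sim <- simulate_transcriptome(cfg)
  expect_equal(nrow(sim$txome$transcripts), 50L)
  ex_counts <- table(sim$txome$exons$transcript_id)
  expect_true(all(ex_counts >= 3 & ex_counts <= 5))
  ex_len <- sim$txome$exons$end - sim$txome$exons$start
  expect_true(all(ex_len >= cfg$exon_len[1] & ex_len <= cfg$exon_len[2]))
  introns <- dplyr::group_by(dplyr::arrange(sim$txome$exons, .data$start),
                             .data$transcript_id)
  il <- dplyr::summarise(introns,
                         gaps = list(.data$start[-1] - .data$end[-dplyr::n()]))
  gaps <- unlist(il$gaps)
  expect_true(all(gaps >= cfg$intron_len[1] & gaps <= cfg$intron_len[2]))
  expect_error(
    simulate_transcriptome(sim_config(seed = 1, n_genes = 50,
                                      chrom_len = 1000L)),
    "sizing error")
})

test_that("planted peaks respect intron placement and carry the motif", {
  cfg <- sim_config(seed = 5, n_genes = 40, n_peaks = 30,
                    intron_fraction_of_peaks = 1)
  sim <- simulate_transcriptome(cfg)
  truth <- plant_peaks(sim, cfg)
  expect_equal(nrow(truth$peaks), 30L)
  expect_setequal(truth$marked_transcripts,
                  unique(truth$peaks$transcript_id))
  # all centers inside introns: outside every exon, inside the span
  for (i in seq_len(nrow(truth$peaks))) {
    p <- truth$peaks[i, ]
    ex <- dplyr::filter(sim$txome$exons,
                        .data$transcript_id == p$transcript_id)
    expect_false(any(ex$start <= p$center & p$center < ex$end))
    tx <- dplyr::filter(sim$txome$transcripts,
                        .data$transcript_id == p$transcript_id)
    expect_true(tx$start <= p$center && p$center < tx$end)
  }
  # genome sequence at the center reads the motif on the transcript strand
  for (i in seq_len(nrow(truth$peaks))) {
    p <- truth$peaks[i, ]
    s <- Biostrings::subseq(truth$genome[[p$chrom]], p$center - 1L,
                            width = 5)
    if (p$strand == "-") s <- Biostrings::reverseComplement(s)
    expect_equal(as.character(s), "TTCTT")
  }
  expect_error(plant_peaks(sim, sim_config(seed = 1, n_genes = 40,
                                           n_peaks = 100)),
               "sizing error")
})

test_that("read counts are conserved and IP enrichment is calibrated", {
  fx <- small_sim()
  ip <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "IP")
  input <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "input")
  expect_equal(ip$library_size, nrow(ip$reads))
  # same stream twice is identical; different replicate differs
  ip_again <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 1, "IP")
  expect_identical(ip$reads, ip_again$reads)
  ip2 <- simulate_reads(fx$sim, fx$truth, fx$cfg, "WT", 2, "IP")
  expect_false(identical(ip$reads, ip2$reads))

  # pileup ratio at interior planted centers ~ peak_fold (ratio-of-means
  # estimator, 3 SE)
  tx <- fx$sim$txome$transcripts
  pk <- dplyr::inner_join(fx$truth$peaks,
                          dplyr::select(tx, "transcript_id",
                                        tx_start = "start",
                                        tx_end = "end"),
                          by = "transcript_id")
  pk <- dplyr::filter(pk, .data$center - .data$tx_start >= 300,
                      .data$tx_end - .data$center >= 300)
  pileup_at <- function(rs, chrom, pos) {
    sum(rs$reads$chrom == chrom & rs$reads$start <= pos &
          rs$reads$end > pos)
  }
  ipc <- mapply(function(ch, c0) pileup_at(ip, ch, c0), pk$chrom,
                pk$center)
  inc <- mapply(function(ch, c0) pileup_at(input, ch, c0), pk$chrom,
                pk$center)
  ratio <- sum(ipc) / sum(inc)
  se <- ratio * sqrt(1 / sum(ipc) + 1 / sum(inc))
  expect_lt(abs(ratio - fx$cfg$peak_fold), 3 * se)
})

test_that("peak_fold = 1 makes IP and input statistically indistinguishable", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_genes = 10, n_peaks = 5, peak_fold = 1,
                      reads_per_sample = 5000)
    sim <- simulate_transcriptome(cfg)
    truth <- plant_peaks(sim, cfg)
    ip <- simulate_reads(sim, truth, cfg, "WT", 1, "IP")
    input <- simulate_reads(sim, truth, cfg, "WT", 1, "input")
    ks <- suppressWarnings(stats::ks.test(ip$reads$start,
                                          input$reads$start))
    if (ks$p.value > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("fate tables carry the planted half-life effect and a null TE", {
  fx <- small_sim()
  ft <- simulate_fate_tables(fx$truth, fx$cfg)
  marked <- ft$half_life$transcript_id %in% fx$truth$marked_transcripts
  gm <- function(x) exp(mean(log(x)))
  ratio <- gm(ft$half_life$half_life[marked]) /
    gm(ft$half_life$half_life[!marked])
  # fate_effect = 0.5 with sdlog 0.5 over ~20/20 transcripts
  expect_lt(abs(log(ratio) - log(fx$cfg$fate_effect)),
            3 * fx$cfg$fate_sdlog * sqrt(1 / sum(marked) +
                                           1 / sum(!marked)))
  te_mod <- ft$te$te[marked]
  te_un <- ft$te$te[!marked]
  expect_gt(wilcoxon_rank_sum(te_mod, te_un)$p_value, 0.01)
  # TPM: a configurable fraction sits below the expression threshold
  expect_true(any(ft$tpm$tpm < 1) && mean(ft$tpm$tpm > 1) > 0.7)
})

test_that("a written experiment round-trips through the readers", {
  cfg <- sim_config(seed = 11, n_genes = 8, n_peaks = 4,
                    reads_per_sample = 2000, n_replicates = 1L)
  exp <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(exp, dir)
  txome <- read_gtf(file.path(dir, "transcriptome.gtf"))
  expect_equal(txome$exons[order(txome$exons$transcript_id,
                                 txome$exons$start), ],
               exp$txome$exons[order(exp$txome$exons$transcript_id,
                                     exp$txome$exons$start), ])
  rs <- read_reads(file.path(dir, "WT_IP_rep1.bed"), condition = "WT",
                   role = "IP")
  expect_equal(rs$library_size, exp$reads$WT$IP[[1]]$library_size)
  expect_equal(rs$reads$start, exp$reads$WT$IP[[1]]$reads$start)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$marked_transcripts,
                  exp$truth$marked_transcripts)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome), as.character(exp$genome))
})
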