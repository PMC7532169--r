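#' Simulation configuration
#'
#' Bundles every knob of the synthetic hMeRIP experiment: transcriptome
#' geometry, planted 5hmC peaks and their motif, the IP/input read model,
#' the replicate/condition design, and the downstream fate tables. The
#' defaults describe the study conditions used throughout the package's
#' tests: 3 IP + 3 input replicates per condition, 200,000 fragments of
#' 200-300 bp per sample, 100 planted peaks at 8-fold IP enrichment
#' (80% intronic) carrying a UC-rich motif at their centers, a second
#' condition in which 70% of peaks drop to 0.4x enrichment (true ratio
#' 2.5), a 2-fold half-life deficit for marked transcripts, and
#' translation efficiency generated under the null.
#'
#' @param seed Master seed; all per-sample streams are derived from it.
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param exon_len,intron_len Inclusive ranges of exon/intron lengths (bp).
#' @param n_chroms Number of synthetic chromosomes.
#' @param gene_gap Intergenic gap (bp).
#' @param chrom_len Optional fixed chromosome length; an error is raised
#'   when the requested genes do not fit. `NULL` sizes chromosomes to fit.
#' @param n_peaks Number of planted 5hmC peaks (at most one per gene).
#' @param peak_width Planted peak width (bp).
#' @param peak_fold IP enrichment of planted peaks over background in the
#'   reference condition (> 1).
#' @param intron_fraction_of_peaks Fraction of peak centers placed in
#'   introns.
#' @param motif_consensus Motif written at each peak center, RNA or DNA
#'   alphabet (U is stored as T).
#' @param fragment_len_range Fragment length range (bp), emulating RNA
#'   fragmented to an average size of 200-300 bp.
#' @param reads_per_sample Expected fragments per sample.
#' @param n_replicates IP/input replicate pairs per condition.
#' @param conditions Named numeric vector of per-condition multipliers on
#'   `peak_fold`; the first entry is the reference and must be 1.
#' @param frac_changed Fraction of planted peaks whose enrichment follows
#'   the non-reference multipliers (the rest keep `peak_fold` in every
#'   condition, providing true-negative peaks for the differential rule).
#' @param fate_effect Multiplier on marked transcripts' half-life
#'   (0.5 = twofold destabilization; 1 = null).
#' @param fate_sdlog Log-normal sdlog of half-life/TE/TPM noise.
#' @param baseline_half_life Unmarked half-life geometric mean (hours).
#' @param non_expressed_frac Fraction of transcripts simulated below the
#'   1 TPM expression threshold.
#' @param splice_effect Multiplier on the unspliced/spliced ratio of
#'   marked transcripts at 4 h in the reference condition.
#' @param unspliced_fraction Baseline unspliced/spliced ratio.
#' @param t_half_stable,t_half_unstable Half-lives (h) used by the decay
#'   time-course generator for stable/unstable transcripts.
#' @param rip_fold Planted IP/input TPM ratio for Tet-bound transcripts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       exons_per_gene = c(3L, 5L),
                       exon_len = c(200L, 400L),
                       intron_len = c(300L, 600L),
                       n_chroms = 2L,
                       gene_gap = 500L,
                       chrom_len = NULL,
                       n_peaks = 100L,
                       peak_width = 200L,
                       peak_fold = 8,
                       intron_fraction_of_peaks = 0.8,
                       motif_consensus = "UUCUU",
                       fragment_len_range = c(200L, 300L),
                       reads_per_sample = 200000L,
                       n_replicates = 3L,
                       conditions = c(WT = 1, TKO = 0.4),
                       frac_changed = 0.7,
                       fate_effect = 0.5,
                       fate_sdlog = 0.5,
                       baseline_half_life = 6,
                       non_expressed_frac = 0.1,
                       splice_effect = 2,
                       unspliced_fraction = 0.1,
                       t_half_stable = 20,
                       t_half_unstable = 2,
                       rip_fold = 2) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 1, length(cfg$exons_per_gene) == 2,
    cfg$exons_per_gene[1] >= 1,
    diff(cfg$exons_per_gene) >= 0, diff(cfg$exon_len) >= 0,
    diff(cfg$intron_len) >= 0, cfg$peak_fold > 0, cfg$peak_width >= 1,
    cfg$intron_fraction_of_peaks >= 0, cfg$intron_fraction_of_peaks <= 1,
    cfg$frac_changed >= 0, cfg$frac_changed <= 1,
    diff(cfg$fragment_len_range) >= 0, cfg$reads_per_sample >= 1,
    cfg$n_replicates >= 1, length(cfg$conditions) >= 1,
    cfg$conditions[[1]] == 1, cfg$fate_effect > 0, cfg$splice_effect > 0,
    cfg$rip_fold > 0
  )
  if (is.null(names(cfg$conditions))) {
    abort("conditions must be a named numeric vector")
  }
  structure(cfg, class = "sim_config")
}

# deterministic 31-bit stream seed from the master seed and a key path, so
# each sample draws from its own reproducible stream
stream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a transcriptome and genome
#'
#' Places non-overlapping multi-exon genes with random strands on
#' synthetic chromosomes and draws the genome from a uniform ACGT
#' background. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `txome` (a [transcriptome]) and `genome`
#'   (a named `DNAStringSet`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(stream_seed(config$seed, "transcriptome"), {
    n <- config$n_genes
    n_ex <- runif_int(n, config$exons_per_gene)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    chrom_of <- sort(rep_len(seq_len(config$n_chroms), n))
    cursor <- rep(config$gene_gap, config$n_chroms)
    tx_rows <- vector("list", n)
    ex_rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_ex[i]
      elens <- runif_int(k, config$exon_len)
      ilens <- if (k > 1) runif_int(k - 1, config$intron_len) else integer()
      chrom <- sprintf("chrS%d", chrom_of[i])
      s <- cursor[chrom_of[i]]
      starts <- s + cumsum(c(0L, head(elens, -1) + ilens))
      ends <- starts + elens
      span_end <- ends[k]
      cds_start <- starts[1] + elens[1] %/% 2L
      cds_end <- span_end - elens[k] %/% 2L
      tx_rows[[i]] <- tibble(
        transcript_id = sprintf("tx%04d", i),
        gene_id = sprintf("gene%04d", i), chrom = chrom, start = s,
        end = span_end, strand = strands[i],
        cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
      )
      ex_rows[[i]] <- tibble(
        transcript_id = sprintf("tx%04d", i), chrom = chrom,
        start = as.integer(starts), end = as.integer(ends),
        strand = strands[i]
      )
      cursor[chrom_of[i]] <- span_end + config$gene_gap
    }
    if (!is.null(config$chrom_len) && any(cursor > config$chrom_len)) {
      abort(sprintf(
        "sizing error: %d genes need %d bases but chrom_len is %d",
        n, max(cursor), config$chrom_len))
    }
    chrom_lens <- if (is.null(config$chrom_len)) cursor
                  else rep(config$chrom_len, config$n_chroms)
    genome <- Biostrings::DNAStringSet(vapply(
      chrom_lens,
      function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""),
      character(1)
    ))
    names(genome) <- sprintf("chrS%d", seq_len(config$n_chroms))
    list(
      txome = transcriptome(bind_rows(tx_rows), bind_rows(ex_rows)),
      genome = genome
    )
  })
}

transcript_introns <- function(txome, transcript_id) {
  e <- arrange(filter(txome$exons, .data$transcript_id == !!transcript_id),
               .data$start)
  if (nrow(e) < 2) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble(chrom = e$chrom[1], start = e$end[-nrow(e)], end = e$start[-1])
}

#' Plant 5hmC peaks and their motif into a simulated genome
#'
#' Places `n_peaks` peak intervals of `peak_width` (at most one per gene,
#' centers in introns with probability `intron_fraction_of_peaks`), writes
#' the motif consensus into the genome at each peak center on the
#' transcript's strand, and assigns per-condition enrichment folds:
#' a `frac_changed` subset of peaks follows the condition multipliers,
#' the rest keep the reference fold everywhere.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `peaks` (tibble with per-condition
#'   `fold_*` columns), `marked_transcripts`, the modified `genome`, and
#'   the `config`.
#' @export
plant_peaks <- function(sim, config) {
  txome <- sim$txome
  genome <- sim$genome
  if (nrow(txome$transcripts) == 0) abort("empty transcriptome")
  if (config$n_peaks > nrow(txome$transcripts)) {
    abort(sprintf(
      "sizing error: %d peaks requested but only %d genes available",
      config$n_peaks, nrow(txome$transcripts)))
  }
  motif <- toupper(gsub("U", "T", config$motif_consensus))
  if (!grepl("^[ACGT]+$", motif)) abort("motif_consensus must be over ACGU/T")
  w <- config$peak_width
  with_stream(stream_seed(config$seed, "peaks"), {
    tx_ids <- sample(txome$transcripts$transcript_id, config$n_peaks)
    in_intron <- runif(config$n_peaks) < config$intron_fraction_of_peaks
    rows <- vector("list", config$n_peaks)
    for (i in seq_along(tx_ids)) {
      t <- filter(txome$transcripts, .data$transcript_id == tx_ids[i])
      pool <- if (in_intron[i]) transcript_introns(txome, tx_ids[i])
              else filter(txome$exons, .data$transcript_id == tx_ids[i])
      if (nrow(pool) == 0) { # single-exon gene cannot host an intronic peak
        pool <- filter(txome$exons, .data$transcript_id == tx_ids[i])
        in_intron[i] <- FALSE
      }
      el <- pool[sample.int(nrow(pool), 1), ]
      margin <- nchar(motif) %/% 2 + 1L
      center <- sample(seq(el$start + margin, el$end - margin), 1)
      p_start <- max(t$start, center - w %/% 2L)
      p_end <- min(t$end, p_start + w)
      rows[[i]] <- tibble(
        peak_id = sprintf("planted_%03d", i), transcript_id = tx_ids[i],
        chrom = t$chrom, start = as.integer(p_start),
        end = as.integer(p_end), center = as.integer(center),
        strand = t$strand, element = ifelse(in_intron[i], "intron", "exon")
      )
    }
    peaks <- bind_rows(rows)
    n_changed <- round(config$frac_changed * config$n_peaks)
    changed_ids <- sample(peaks$peak_id, n_changed)
    peaks$changed <- peaks$peak_id %in% changed_ids
    for (cond in names(config$conditions)) {
      mult <- config$conditions[[cond]]
      peaks[[paste0("fold_", cond)]] <-
        ifelse(peaks$changed, config$peak_fold * mult, config$peak_fold)
    }
    for (i in seq_len(nrow(peaks))) {
      m_start <- peaks$center[i] - nchar(motif) %/% 2L # 0-based
      ins <- if (peaks$strand[i] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
      } else motif
      Biostrings::subseq(genome[[peaks$chrom[i]]], start = m_start + 1L,
                         width = nchar(motif)) <- Biostrings::DNAString(ins)
    }
    structure(
      list(peaks = peaks,
           marked_transcripts = sort(unique(peaks$transcript_id)),
           transcript_ids = txome$transcripts$transcript_id,
           genome = genome, config = config),
      class = "sim_truth"
    )
  })
}

#' Simulate an IP or input read sample
#'
#' Fragments with lengths uniform in `fragment_len_range` are placed along
#' transcript spans at a uniform per-base background rate (Poisson counts
#' per transcript). For IP samples, fragments overlapping a planted peak
#' are emitted at `fold(condition)` times the background rate. Each
#' (condition, replicate, role) sample has its own RNG stream.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param truth Output of [plant_peaks()].
#' @param config A [sim_config()].
#' @param condition Condition name (must appear in `config$conditions`).
#' @param replicate Replicate number.
#' @param role `"IP"` or `"input"`.
#' @return A [read_set()].
#' @export
simulate_reads <- function(sim, truth, config, condition, replicate,
                           role = c("IP", "input")) {
  role <- match.arg(role)
  if (!condition %in% names(config$conditions)) {
    abort(sprintf("unknown condition '%s'", condition))
  }
  tx <- sim$txome$transcripts
  span_len <- tx$end - tx$start
  rho <- config$reads_per_sample / sum(span_len) # background starts per base
  flr <- config$fragment_len_range
  mean_len <- mean(flr)
  with_stream(stream_seed(config$seed, "reads", condition, replicate, role), {
    n_bg <- rpois(nrow(tx), rho * span_len)
    idx <- rep.int(seq_len(nrow(tx)), n_bg)
    len_bg <- runif_int(length(idx), flr)
    # starts uniform over the whole span (exact homogeneous Poisson
    # process); fragments are truncated at the transcript 3' end, as RNA
    # fragmentation bounds fragments by the transcript itself
    start_bg <- tx$start[idx] +
      floor(runif(length(idx)) * (tx$end[idx] - tx$start[idx]))
    end_bg <- pmin(start_bg + len_bg, tx$end[idx])
    reads <- tibble(chrom = tx$chrom[idx], start = as.integer(start_bg),
                    end = as.integer(end_bg),
                    transcript_id = tx$transcript_id[idx])
    if (role == "IP" && nrow(truth$peaks) > 0) {
      pk <- truth$peaks
      folds <- pk[[paste0("fold_", condition)]]
      # enrichment model: extra fragments with midpoints uniform in the
      # peak, count calibrated so the IP pileup at the peak CENTER is
      # fold x the background pileup (background pileup = rho * mean_len)
      lam_extra <- (folds - 1) * rho * pmax(mean_len, pk$end - pk$start)
      n_extra <- rpois(nrow(pk), pmax(lam_extra, 0))
      jdx <- rep.int(seq_len(nrow(pk)), n_extra)
      if (length(jdx) > 0) {
        len_x <- runif_int(length(jdx), flr)
        mid <- pk$start[jdx] +
          floor(runif(length(jdx)) * (pk$end[jdx] - pk$start[jdx]))
        start_x <- mid - len_x %/% 2L
        t_start <- tx$start[match(pk$transcript_id[jdx], tx$transcript_id)]
        t_end <- tx$end[match(pk$transcript_id[jdx], tx$transcript_id)]
        start_x <- pmax(start_x, t_start)
        end_x <- pmin(start_x + len_x, t_end)
        reads <- bind_rows(reads, tibble(
          chrom = pk$chrom[jdx], start = as.integer(start_x),
          end = as.integer(end_x),
          transcript_id = pk$transcript_id[jdx]
        ))
      }
    }
    reads$strand <- "."
    read_set(select(reads, "chrom", "start", "end", "strand"),
             sample_id = sprintf("%s_%s_rep%d", condition, role, replicate),
             condition = condition, role = role, replicate = replicate)
  })
}

#' Simulate downstream fate tables with planted truth
#'
#' Generates per-transcript TPM, half-life, translation-efficiency and
#' spliced/unspliced tables. Marked transcripts receive `fate_effect`
#' times the baseline half-life (log-normal noise); TE is drawn
#' identically for both groups (null); the unspliced/spliced ratio of
#' marked transcripts is multiplied by `splice_effect` at 4 h in the
#' reference condition.
#'
#' @param truth Output of [plant_peaks()].
#' @param config A [sim_config()].
#' @param seed Stream seed override; defaults to the config seed so the
#'   tables are deterministic parts of the same experiment.
#' @return List of tibbles `tpm`, `half_life`, `te`, `splicing`.
#' @export
simulate_fate_tables <- function(truth, config, seed = config$seed) {
  ids <- truth$transcript_ids
  marked <- ids %in% truth$marked_transcripts
  n <- length(ids)
  with_stream(stream_seed(seed, "fate"), {
    non_expr <- runif(n) < config$non_expressed_frac
    raw <- rlnorm(n, meanlog = ifelse(non_expr, log(1e-4), log(20)),
                  sdlog = config$fate_sdlog)
    tpm <- tibble(transcript_id = ids, tpm = 1e6 * raw / sum(raw))
    hl_true <- config$baseline_half_life *
      ifelse(marked, config$fate_effect, 1)
    half_life <- tibble(
      transcript_id = ids,
      half_life = rlnorm(n, log(hl_true), config$fate_sdlog),
      true_half_life = hl_true
    )
    te <- tibble(transcript_id = ids,
                 te = rlnorm(n, 0, config$fate_sdlog))
    ref <- names(config$conditions)[1]
    splicing <- tidyr::expand_grid(
      transcript_id = ids,
      condition = names(config$conditions),
      time_h = c(0, 4)
    )
    splicing <- mutate(splicing,
      marked = .data$transcript_id %in% truth$marked_transcripts,
      true_ratio = config$unspliced_fraction *
        ifelse(.data$marked & .data$time_h == 4 & .data$condition == ref,
               config$splice_effect, 1),
      spliced = rpois(n(), 200),
      unspliced = rpois(n(), 200 * .data$true_ratio)
    )
    list(tpm = tpm, half_life = half_life, te = te,
         splicing = select(splicing, -"marked"))
  })
}

#' Simulate a transcription-shutoff decay time course
#'
#' Counts at 0 h and 4 h after transcription shutoff for each condition
#' and replicate, under first-order decay. In the reference condition,
#' marked transcripts decay with `t_half_unstable`; everything else (and
#' every transcript in non-reference conditions, where the mark is lost)
#' decays with `t_half_stable`. Poisson counting noise.
#'
#' @inheritParams simulate_fate_tables
#' @param n_replicates Replicates per time point (default from config).
#' @return Tibble: `condition`, `transcript_id`, `replicate`, `count_0h`,
#'   `count_4h`, `true_half_life`.
#' @export
simulate_decay_tables <- function(truth, config, seed = config$seed,
                                  n_replicates = config$n_replicates) {
  ids <- truth$transcript_ids
  marked <- ids %in% truth$marked_transcripts
  ref <- names(config$conditions)[1]
  with_stream(stream_seed(seed, "decay"), {
    base <- rlnorm(length(ids), log(500), 0.5)
    out <- vector("list", 0)
    for (cond in names(config$conditions)) {
      t_half <- ifelse(marked & cond == ref, config$t_half_unstable,
                       config$t_half_stable)
      for (rep_i in seq_len(n_replicates)) {
        out[[length(out) + 1]] <- tibble(
          condition = cond, transcript_id = ids, replicate = rep_i,
          count_0h = rpois(length(ids), base),
          count_4h = rpois(length(ids), base * 2^(-4 / t_half)),
          true_half_life = t_half
        )
      }
    }
    bind_rows(out)
  })
}

#' Simulate RIP-Seq count tables with planted Tet binding
#'
#' Tet1 and Tet2 each bind all marked transcripts plus a random 10% of
#' the unmarked ones; bound transcripts get `rip_fold` times their input
#' abundance in the IP library. Counts are Poisson draws per replicate.
#'
#' @inheritParams simulate_fate_tables
#' @param n_replicates IP/input replicate pairs (default 2).
#' @return List: `counts` (tibble with `protein`, `replicate`,
#'   `transcript_id`, `ip_count`, `input_count`), `lengths` (tibble),
#'   `bound` (named list of planted bound sets).
#' @export
simulate_rip_tables <- function(truth, config, seed = config$seed,
                                n_replicates = 2L) {
  ids <- truth$transcript_ids
  marked <- ids %in% truth$marked_transcripts
  with_stream(stream_seed(seed, "rip"), {
    lengths <- tibble(transcript_id = ids,
                      length = runif_int(length(ids), c(800L, 3000L)))
    base <- rlnorm(length(ids), log(200), 0.7)
    bound <- list()
    rows <- list()
    for (protein in c("Tet1", "Tet2")) {
      extra <- sample(ids[!marked], round(0.1 * sum(!marked)))
      bound[[protein]] <- sort(c(ids[marked], extra))
      is_bound <- ids %in% bound[[protein]]
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1]] <- tibble(
          protein = protein, replicate = rep_i, transcript_id = ids,
          ip_count = rpois(length(ids),
                           base * ifelse(is_bound, config$rip_fold, 1)),
          input_count = rpois(length(ids), base)
        )
      }
    }
    list(counts = bind_rows(rows), lengths = lengths, bound = bound)
  })
}

#' Run the full synthetic experiment
#'
#' Convenience orchestrator: transcriptome, planted peaks, one IP and one
#' input read set per replicate and condition, and all downstream tables.
#'
#' @param config A [sim_config()].
#' @return List with `txome`, `genome`, `truth`, `reads` (nested list
#'   `reads[[condition]][[role]][[replicate]]`), `fate`, `decay`, `rip`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  sim <- simulate_transcriptome(config)
  truth <- plant_peaks(sim, config)
  sim$genome <- truth$genome
  reads <- list()
  for (cond in names(config$conditions)) {
    reads[[cond]] <- list(IP = list(), input = list())
    for (rep_i in seq_len(config$n_replicates)) {
      reads[[cond]]$IP[[rep_i]] <-
        simulate_reads(sim, truth, config, cond, rep_i, "IP")
      reads[[cond]]$input[[rep_i]] <-
        simulate_reads(sim, truth, config, cond, rep_i, "input")
    }
  }
  list(txome = sim$txome, genome = sim$genome, truth = truth, reads = reads,
       fate = simulate_fate_tables(truth, config),
       decay = simulate_decay_tables(truth, config),
       rip = simulate_rip_tables(truth, config))
}

#' Write a simulated experiment to disk
#'
#' Emits GTF + FASTA + per-sample BED + TSV tables + a truth JSON, the
#' on-disk layout consumed by the command-line interface.
#'
#' @param exp Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(exp$txome, file.path(dir, "transcriptome.gtf"))
  Biostrings::writeXStringSet(exp$genome, file.path(dir, "genome.fa"))
  for (cond in names(exp$reads)) {
    for (role in names(exp$reads[[cond]])) {
      for (rs in exp$reads[[cond]][[role]]) {
        write_reads(rs, file.path(dir, paste0(rs$sample_id, ".bed")))
      }
    }
  }
  for (nm in names(exp$fate)) {
    readr::write_tsv(exp$fate[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  readr::write_tsv(exp$decay, file.path(dir, "decay.tsv"))
  readr::write_tsv(exp$rip$counts, file.path(dir, "rip_counts.tsv"))
  readr::write_tsv(exp$rip$lengths, file.path(dir, "rip_lengths.tsv"))
  truth <- exp$truth
  jsonlite::write_json(
    list(peaks = truth$peaks, marked_transcripts = truth$marked_transcripts,
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
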