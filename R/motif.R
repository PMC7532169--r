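#' Extract stranded peak-center sequences
#'
#' Each peak is associated with the transcripts its interval overlaps;
#' the peak takes its transcript's strand, peaks overlapping transcripts
#' on both strands are emitted twice (once per strand) and unassociated
#' peaks are dropped. Sequences are the peak center extended by `flank`
#' bases on both sides (length `2*flank + 1`), reverse-complemented for
#' minus-strand transcripts, truncated at chromosome ends with a warning.
#'
#' @param peaks An `hmerip_peaks` tibble.
#' @param txome A [transcriptome].
#' @param genome Named `DNAStringSet` (or objects coercible to it).
#' @param flank Extension on each side of the peak center (default 250).
#' @return Tibble: `name`, `strand`, `seq` (character, DNA alphabet).
#' @export
extract_peak_sequences <- function(peaks, txome, genome, flank = 250L) {
  genome <- Biostrings::DNAStringSet(genome)
  if (nrow(peaks) == 0) {
    return(tibble(name = character(), strand = character(),
                  seq = character()))
  }
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome '%s' absent from genome", missing_chrom[1]))
  }
  gr <- as_granges(peaks)
  GenomicRanges::strand(gr) <- "*"
  hits <- GenomicRanges::findOverlaps(gr, txome$index, ignore.strand = TRUE)
  assoc <- distinct(tibble(
    peak_idx = S4Vectors::queryHits(hits),
    strand = txome$transcripts$strand[S4Vectors::subjectHits(hits)]
  ))
  if (nrow(assoc) == 0) {
    return(tibble(name = character(), strand = character(),
                  seq = character()))
  }
  center <- (peaks$start + peaks$end) %/% 2L
  n_trunc <- 0L
  rows <- pmap(assoc, function(peak_idx, strand) {
    chrom <- peaks$chrom[peak_idx]
    c0 <- center[peak_idx]
    lo <- c0 - flank
    hi <- c0 + flank + 1L
    cl <- length(genome[[chrom]])
    if (lo < 0 || hi > cl) {
      n_trunc <<- n_trunc + 1L
      lo <- max(lo, 0L)
      hi <- min(hi, cl)
    }
    s <- Biostrings::subseq(genome[[chrom]], lo + 1L, hi)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    tibble(name = peaks$name[peak_idx], strand = strand,
           seq = as.character(s))
  })
  if (n_trunc > 0) {
    warn(sprintf("%d peak window(s) truncated at chromosome ends", n_trunc))
  }
  bind_rows(rows)
}

#' Fit a first-order Markov background model
#'
#' Transition probabilities are dinucleotide counts with additive
#' smoothing, `(count(xy) + alpha) / (count(x.) + 4*alpha)`; the initial
#' distribution is the mononucleotide frequency.
#'
#' @param sequences Character vector of DNA sequences (typically input/
#'   control sequences).
#' @param alpha Additive smoothing pseudocount (default 1).
#' @return List of class `markov_bg`: `order`, `initial` (length-4),
#'   `transition` (4x4 row-stochastic), both named by A,C,G,T.
#' @export
fit_markov1 <- function(sequences, alpha = 1) {
  if (length(sequences) == 0 || sum(nchar(sequences)) == 0) {
    abort("no sequence data to fit the Markov background")
  }
  dss <- Biostrings::DNAStringSet(toupper(sequences))
  mono <- colSums(Biostrings::oligonucleotideFrequency(dss, 1))[
    c("A", "C", "G", "T")]
  di <- colSums(Biostrings::oligonucleotideFrequency(dss, 2))
  if (sum(di) == 0) abort("total dinucleotide count is zero")
  tr <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  for (x in rownames(tr)) for (y in colnames(tr)) {
    tr[x, y] <- di[[paste0(x, y)]]
  }
  row_tot <- rowSums(tr)
  tr <- (tr + alpha) / (row_tot + 4 * alpha)
  structure(list(order = 1L, initial = mono / sum(mono), transition = tr),
            class = "markov_bg")
}

markov_kmer_prob <- function(kmer_codes, bg) {
  p <- bg$initial[kmer_codes[1]]
  if (length(kmer_codes) > 1) {
    for (i in 2:length(kmer_codes)) {
      p <- p * bg$transition[kmer_codes[i - 1], kmer_codes[i]]
    }
  }
  unname(p)
}

encode_seqs <- function(sequences) {
  chars <- strsplit(toupper(sequences), "", fixed = TRUE)
  L <- max(lengths(chars))
  X <- matrix(NA_integer_, length(chars), L)
  for (i in seq_along(chars)) {
    codes <- match(chars[[i]], c("A", "C", "G", "T"))
    X[i, seq_along(codes)] <- codes
  }
  X
}

# windows containing NA (non-ACGT or ragged ends) or masked positions are
# excluded from seeding and EM
valid_windows <- function(X, mask, w) {
  n <- nrow(X)
  m <- ncol(X) - w + 1L
  bad <- is.na(X) | mask
  cum <- t(apply(bad, 1, cumsum))
  cum <- cbind(0, cum)
  ok <- matrix(FALSE, n, m)
  for (j in seq_len(m)) ok[, j] <- (cum[, j + w] - cum[, j]) == 0
  ok
}

seed_kmers <- function(sequences, X, mask, w, bg, n_seeds) {
  n <- nrow(X)
  m <- ncol(X) - w + 1L
  if (m < 1) return(tibble(kmer = character(), score = numeric()))
  ok <- valid_windows(X, mask, w)
  all_k <- unlist(map(seq_len(n), function(i) {
    j <- which(ok[i, ])
    if (length(j) == 0) return(character())
    substring(sequences[i], j, j + w - 1L)
  }))
  if (length(all_k) == 0) return(tibble(kmer = character(),
                                        score = numeric()))
  tab <- table(all_k)
  kmers <- names(tab)
  counts <- as.integer(tab)
  keep <- counts >= 2
  kmers <- kmers[keep]
  counts <- counts[keep]
  if (length(kmers) == 0) return(tibble(kmer = character(),
                                        score = numeric()))
  exp_p <- vapply(kmers, function(k) {
    markov_kmer_prob(match(strsplit(k, "")[[1]], c("A", "C", "G", "T")), bg)
  }, numeric(1))
  score <- log(counts / sum(counts)) - log(exp_p)
  ord <- order(-score, kmers) # score desc, then lexicographic: deterministic
  head(tibble(kmer = kmers[ord], score = score[ord]), n_seeds)
}

em_zoops <- function(X, mask, seed, bg_log, max_iter = 100, tol = 1e-4) {
  w <- nchar(seed)
  n <- nrow(X)
  m <- ncol(X) - w + 1L
  ok <- valid_windows(X, mask, w)
  codes <- match(strsplit(seed, "")[[1]], c("A", "C", "G", "T"))
  pwm <- matrix(0.1, 4, w)
  for (k in seq_len(w)) pwm[codes[k], k] <- 0.7
  # per-window background log-probability (0-order from the Markov
  # initial distribution)
  Xz <- X
  Xz[is.na(Xz)] <- 1L
  Blog <- matrix(0, n, m)
  for (k in seq_len(w)) {
    Blog <- Blog + matrix(bg_log[Xz[, k:(k + m - 1L), drop = FALSE]], n, m)
  }
  gamma <- 0.5
  ll_trace <- numeric()
  Z <- NULL
  for (iter in seq_len(max_iter)) {
    lpwm <- log(pwm)
    S <- matrix(0, n, m)
    for (k in seq_len(w)) {
      S <- S + matrix(lpwm[cbind(as.vector(Xz[, k:(k + m - 1L),
                                               drop = FALSE]),
                                 k)], n, m)
    }
    R <- exp(S - Blog)
    R[!ok] <- 0
    denom <- (1 - gamma) + gamma / m * rowSums(R)
    # MAP-EM objective: data log-likelihood (relative to background) plus
    # the Dirichlet(1.25) log-prior matching the smoothed M-step; this is
    # the quantity EM is guaranteed not to decrease
    ll <- sum(log(denom)) + 0.25 * sum(log(pwm))
    if (length(ll_trace) > 0 && ll < tail(ll_trace, 1) - 1e-6) {
      abort("EM objective decreased") # invariant, never expected
    }
    converged <- length(ll_trace) > 0 && ll - tail(ll_trace, 1) < tol
    ll_trace <- c(ll_trace, ll)
    Z <- (gamma / m * R) / denom
    if (converged) break
    counts <- matrix(0, 4, w)
    for (k in seq_len(w)) {
      v <- Xz[, k:(k + m - 1L), drop = FALSE]
      for (a in 1:4) counts[a, k] <- sum(Z[v == a])
    }
    pwm <- sweep(counts + 0.25, 2, colSums(counts) + 1, "/")
    gamma <- min(max(mean(rowSums(Z)), 1e-4), 0.999)
  }
  list(pwm = pwm, width = w, gamma = gamma, ll_trace = ll_trace, Z = Z,
       ok = ok)
}

pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)], collapse = "")
}

# best (leftmost-maximal) site per sequence under log2(pwm/bg) scoring;
# returns offsets (1-based start), scores, and the maximum attainable score
best_sites <- function(pwm, X, bg_log2, ok = NULL) {
  w <- ncol(pwm)
  n <- nrow(X)
  m <- ncol(X) - w + 1L
  Xz <- X
  Xz[is.na(Xz)] <- 1L
  lpwm <- log2(pwm)
  S <- matrix(0, n, m)
  for (k in seq_len(w)) {
    S <- S + matrix(lpwm[cbind(as.vector(Xz[, k:(k + m - 1L),
                                             drop = FALSE]), k)], n, m) -
      matrix(bg_log2[Xz[, k:(k + m - 1L), drop = FALSE]], n, m)
  }
  if (!is.null(ok)) S[!ok] <- -Inf
  offset <- max.col(S, ties.method = "first")
  score <- S[cbind(seq_len(n), offset)]
  max_score <- sum(apply(sweep(lpwm, 1, bg_log2, "-"), 2, max))
  list(offset = offset, score = score, max_score = max_score)
}

#' Discover enriched ungapped motifs by seeded ZOOPS-EM
#'
#' Enumerates over-represented k-mers at each width in the window,
#' scored by `log(observed frequency / Markov-expected probability)`,
#' seeds an expectation-maximization under the zero-or-one-occurrence-
#' per-sequence model from the top seeds, iterates to convergence
#' (log-likelihood gain below `tol` or `max_iter` iterations), and
#' reports up to `n_motifs` motifs ranked by their enrichment in
#' positives versus controls. Sites of each reported motif are masked
#' before the next motif is sought. A sequence carries a motif when its
#' best site scores at least `score_frac` of the maximum attainable
#' log-odds score; the enrichment score is the log-odds of carrying the
#' motif in positives versus controls.
#'
#' @param positives Character vector of peak sequences (>= 20).
#' @param controls Character vector of control sequences (e.g. expected-
#'   peak sequences); `NULL` falls back to comparing against the Markov
#'   background alone.
#' @param background A [fit_markov1()] model.
#' @param width_range Integer pair, motif widths searched (default
#'   c(5, 12)).
#' @param n_motifs Maximum number of motifs reported (default 10).
#' @param n_seeds Seeds tried per width (default 2).
#' @param score_frac Fraction of the maximum PWM score that defines a
#'   motif occurrence (default 0.75).
#' @param max_iter,tol EM stopping rule.
#' @return List of class `motif_set`; each element has `pwm` (4 x width,
#'   columns sum to 1), `width`, `consensus` (RNA alphabet),
#'   `enrichment_score`, `gamma`, `n_sites`, `ll_trace`.
#' @export
discover_motifs <- function(positives, controls, background,
                            width_range = c(5L, 12L), n_motifs = 10L,
                            n_seeds = 2L, score_frac = 0.75,
                            max_iter = 100L, tol = 1e-4) {
  if (length(positives) < 20) {
    abort("at least 20 positive sequences are required")
  }
  positives <- toupper(positives)
  X <- encode_seqs(positives)
  Xc <- if (!is.null(controls) && length(controls) > 0) {
    encode_seqs(toupper(controls))
  } else NULL
  mask <- matrix(FALSE, nrow(X), ncol(X))
  bg_log <- log(unname(background$initial))
  bg_log2 <- log2(unname(background$initial))
  widths <- seq(width_range[1], width_range[2])
  motifs <- list()
  for (round in seq_len(n_motifs)) {
    seeds <- bind_rows(map(widths, function(w) {
      seed_kmers(positives, X, mask, w, background, n_seeds)
    }))
    if (nrow(seeds) == 0) {
      if (round == 1) warn("no seed k-mers found; returning no motifs")
      else warn(sprintf("seeds exhausted after %d motif(s)", round - 1))
      break
    }
    # all per-width top seeds are refined; the winner is the fit with the
    # best positives-vs-controls enrichment, so widths compete on the
    # evidence of their refined models rather than on raw seed scores
    fits <- map(seeds$kmer, function(s) {
      em_zoops(X, mask, s, bg_log, max_iter = max_iter, tol = tol)
    })
    scored <- map_dbl(fits, function(f) {
      motif_enrichment(f$pwm, X, Xc, bg_log2, score_frac, f$ok)$score
    })
    best <- which.max(scored)
    fit <- fits[[best]]
    enr <- motif_enrichment(fit$pwm, X, Xc, bg_log2, score_frac, fit$ok)
    hits <- enr$pos_sites
    has_site <- hits$score >= score_frac * hits$max_score
    motifs[[round]] <- structure(
      list(pwm = fit$pwm, width = fit$width,
           consensus = gsub("T", "U", pwm_consensus(fit$pwm)),
           enrichment_score = enr$score, gamma = fit$gamma,
           n_sites = sum(has_site), ll_trace = fit$ll_trace,
           seed = seeds$kmer[best]),
      class = "motif_model"
    )
    # mask reported occurrences so later motifs describe new signal
    for (i in which(has_site)) {
      mask[i, hits$offset[i]:(hits$offset[i] + fit$width - 1L)] <- TRUE
    }
  }
  motifs <- motifs[order(-map_dbl(motifs, "enrichment_score"))]
  structure(motifs, class = "motif_set",
            n_positives = length(positives),
            n_controls = if (is.null(Xc)) 0L else nrow(Xc))
}

motif_enrichment <- function(pwm, X, Xc, bg_log2, score_frac, ok = NULL) {
  pos <- best_sites(pwm, X, bg_log2, ok)
  thr <- score_frac * pos$max_score
  p_pos <- (sum(pos$score >= thr) + 1) / (nrow(X) + 2)
  if (is.null(Xc)) {
    # against background alone: expected hit rate if sites were uniform
    p_ctl <- 1 / (nrow(X) + 2)
  } else {
    ctl <- best_sites(pwm, Xc, bg_log2)
    p_ctl <- (sum(ctl$score >= thr) + 1) / (nrow(Xc) + 2)
  }
  odds <- function(p) p / (1 - p)
  list(score = log2(odds(p_pos) / odds(p_ctl)), pos_sites = pos)
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motif(s) from %d positive sequences\n",
              length(x), attr(x, "n_positives")))
  for (i in seq_along(x)) {
    m <- x[[i]]
    cat(sprintf("  %d. %s (w=%d, enrichment=%.2f, sites=%d%s)\n", i,
                m$consensus, m$width, m$enrichment_score, m$n_sites,
                if (!is.null(m$centrality)) {
                  sprintf(", %s p=%.2g", m$centrality, m$centrality_p)
                } else ""))
  }
  invisible(x)
}

#' Judge the positional centrality of a motif
#'
#' Tests whether the motif's best-match sites concentrate in the central
#' window of the (peak-centered) sequences: a one-sided binomial test of
#' the number of best sites lying fully inside the central
#' `central_width` bases against the null proportion
#' `(central_width - w + 1) / (L - w + 1)`. Motifs failing the test are
#' `decentered` and are excluded from the final report by
#' [centrality_filter()].
#'
#' @param motif A `motif_model` (element of a [discover_motifs()] set).
#' @param positives Character vector of peak-centered sequences.
#' @param central_width Width of the central window (default 100).
#' @param alpha Significance level (default 0.05).
#' @return The motif with added `centrality` (`"central"`/`"decentered"`)
#'   and `centrality_p` fields.
#' @export
motif_centrality <- function(motif, positives, central_width = 100L,
                             alpha = 0.05) {
  X <- encode_seqs(toupper(positives))
  w <- motif$width
  L <- ncol(X)
  sites <- best_sites(motif$pwm, X, log2(rep(0.25, 4)))
  lo <- (L - central_width) %/% 2L # 0-based start of central window
  # site (1-based offset) fully inside [lo, lo + central_width)
  start0 <- sites$offset - 1L
  inside <- start0 >= lo & (start0 + w) <= lo + central_width
  p0 <- (central_width - w + 1) / (L - w + 1)
  k <- sum(inside)
  n <- length(inside)
  pval <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  motif$centrality <- if (pval < alpha) "central" else "decentered"
  motif$centrality_p <- pval
  motif
}

#' Drop decentered motifs from a motif set
#'
#' Applies [motif_centrality()] to each motif and keeps only the central
#' ones.
#'
#' @param motifs A `motif_set`.
#' @inheritParams motif_centrality
#' @return A `motif_set` of central motifs (centrality fields attached).
#' @export
centrality_filter <- function(motifs, positives, central_width = 100L,
                              alpha = 0.05) {
  judged <- map(motifs, motif_centrality, positives = positives,
                central_width = central_width, alpha = alpha)
  keep <- map_chr(judged, "centrality") == "central"
  structure(judged[keep], class = "motif_set",
            n_positives = attr(motifs, "n_positives"),
            n_controls = attr(motifs, "n_controls"))
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A `motif_set`.
#' @param path Output path.
#' @param background Optional [fit_markov1()] model for the background
#'   frequency line.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (!is.null(background)) {
    lines <- c(lines, "Background letter frequencies",
               paste(sprintf("%s %.6f", names(background$initial),
                             background$initial), collapse = " "), "")
  }
  for (m in motifs) {
    lines <- c(lines,
               sprintf("MOTIF %s", m$consensus),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= %d",
                 m$width, m$n_sites),
               apply(m$pwm, 2, function(col) {
                 paste(sprintf("%.6f", col), collapse = " ")
               }),
               "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}
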