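#' Upper tail of the Poisson distribution
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, computed through the survival
#' function in log space for numerical stability. This is the enrichment
#' test at the core of the peak caller.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lam Expected count(s), > 0.
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' poisson_tail(5, 1)
poisson_tail <- function(k, lam) {
  if (any(lam <= 0)) abort("lam must be > 0")
  if (any(k < 0)) abort("k must be >= 0")
  # P(X >= k) = P(X > k - 1); exp(log-survival) keeps tiny tails accurate
  exp(ppois(k - 1, lam, lower.tail = FALSE, log.p = TRUE))
}

#' Peak-calling parameters
#'
#' @param q_threshold BH q-value threshold (default 0.05).
#' @param resize_flank Bases added on each side of the summit; every
#'   reported peak has length `2 * resize_flank + 1` (default 100).
#' @param window_size Scan window width in bases.
#' @param step Scan step in bases.
#' @param local_windows Local background window sizes centered on each
#'   candidate window, truncated at transcript-union boundaries.
#' @param min_region_len Minimum merged significant region length.
#' @param summit_min_frac Significance contour for sub-summits: within a
#'   merged region, a local pileup maximum is reported as a summit only
#'   if it reaches this fraction of the region's maximum pileup
#'   (default 0.5). This keeps genuine secondary summits while dropping
#'   noise maxima in the low-coverage tails of merged regions.
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(q_threshold = 0.05, resize_flank = 100L,
                             window_size = 200L, step = 50L,
                             local_windows = c(1000L, 5000L),
                             min_region_len = 1L,
                             summit_min_frac = 0.5) {
  stopifnot(q_threshold > 0, q_threshold < 1, resize_flank > 0,
            window_size >= 1, step >= 1, min_region_len >= 1,
            summit_min_frac >= 0, summit_min_frac <= 1)
  structure(list(q_threshold = q_threshold,
                 resize_flank = as.integer(resize_flank),
                 window_size = as.integer(window_size),
                 step = as.integer(step),
                 local_windows = as.integer(local_windows),
                 min_region_len = as.integer(min_region_len),
                 summit_min_frac = summit_min_frac),
            class = "peak_call_params")
}

# Per-union-region scan state: per-base fragment-start counts and pileup,
# restricted to [start, end), via vectorized difference arrays.
region_profile_fast <- function(reads, region) {
  sel <- which(reads$chrom == region$chrom & reads$end > region$start &
                 reads$start < region$end)
  L <- region$end - region$start
  if (length(sel) == 0) {
    return(list(starts = integer(L), cov = integer(L)))
  }
  rs <- reads$start[sel]
  re <- reads$end[sel]
  s_in <- rs[rs >= region$start]
  starts <- tabulate(s_in - region$start + 1L, nbins = L)
  a <- pmax(rs, region$start) - region$start + 1L
  b <- pmin(re, region$end) - region$start
  delta_up <- tabulate(a, nbins = L + 1L)
  delta_dn <- tabulate(b + 1L, nbins = L + 1L)
  cov <- cumsum(delta_up - delta_dn)[seq_len(L)]
  list(starts = starts, cov = cov)
}

window_offsets <- function(L, width, step) {
  if (L <= width) return(0L)
  off <- seq.int(0L, L - width, by = step)
  if (tail(off, 1) != L - width) off <- c(off, L - width)
  off
}

# windowed sums of a per-base vector for windows [centers - half,
# centers + half) truncated to [0, L); returns count and covered length
local_window_sum <- function(cum, centers, half, L) {
  lo <- pmax(centers - half, 0L)
  hi <- pmin(centers + half, L)
  count <- cum[hi + 1L] - cum[lo + 1L]
  list(count = count, len = hi - lo)
}

scan_windows <- function(sig_prof, ctl_prof, region, params, lam_cfg) {
  L <- region$end - region$start
  W <- min(params$window_size, L)
  off <- window_offsets(L, W, params$step)
  cum_sig <- c(0L, cumsum(sig_prof$starts))
  k <- cum_sig[off + W + 1L] - cum_sig[off + 1L]
  lam <- rep(lam_cfg$rate_bg * W, length(off))
  if (!is.null(ctl_prof)) {
    cum_ctl <- c(0, cumsum(ctl_prof$starts))
    centers <- off + W %/% 2L
    for (lw in params$local_windows) {
      ls <- local_window_sum(cum_ctl, centers, lw %/% 2L, L)
      ok <- ls$len > 0
      lam_loc <- ifelse(ok, ls$count / pmax(ls$len, 1L) * W *
                          lam_cfg$depth_ratio, 0)
      lam <- pmax(lam, lam_loc)
    }
  }
  tibble(chrom = region$chrom, w_start = region$start + off,
         w_end = region$start + off + W, k = k, lam = lam,
         p = poisson_tail(k, lam))
}

merge_significant <- function(wins) {
  wins <- arrange(wins, .data$chrom, .data$w_start)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$w_start <= cur$end) {
      cur$end <- max(cur$end, w$w_end)
      cur$p <- min(cur$p, w$p)
      cur$q <- min(cur$q, w$q)
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- list(chrom = w$chrom, start = w$w_start, end = w$w_end,
                  p = w$p, q = w$q)
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  bind_rows(map(out, as_tibble))
}

# leftmost position of each local pileup maximum: a summit is a position
# whose coverage equals the running maximum over +/- flank, clustered so
# that candidates within flank of each other yield one (leftmost) summit
find_summits <- function(cov, flank) {
  L <- length(cov)
  if (L == 0 || max(cov) == 0) return(integer())
  winmax <- vapply(seq_len(L), function(i) {
    max(cov[max(1L, i - flank):min(L, i + flank)])
  }, numeric(1))
  cand <- which(cov == winmax & cov > 0)
  if (length(cand) == 0) return(integer())
  cl <- cumsum(c(1L, as.integer(diff(cand) > flank)))
  as.integer(vapply(split(cand, cl), min, numeric(1)))
}

call_peaks_engine <- function(signal, control, txome, params, analytic_bg) {
  regions <- interval_union(txome$transcripts)
  eff <- effective_transcriptome_size(txome)
  sig_total <- signal$library_size
  if (sig_total == 0) abort("signal read set is empty")
  rate_bg <- sig_total / eff # signal fragment starts per base
  depth_ratio <- if (analytic_bg) 1 else sig_total / control$library_size
  lam_cfg <- list(rate_bg = rate_bg, depth_ratio = depth_ratio)
  profs <- vector("list", nrow(regions))
  wins <- vector("list", nrow(regions))
  any_overlap <- FALSE
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    sp <- region_profile_fast(signal$reads, region)
    cp <- if (analytic_bg) NULL else region_profile_fast(control$reads,
                                                         region)
    profs[[i]] <- list(sig = sp, ctl = cp, region = region)
    if (sum(sp$starts) > 0) any_overlap <- TRUE
    wins[[i]] <- scan_windows(sp, cp, region, params, lam_cfg)
  }
  if (!any_overlap) {
    warn("no overlap between reads and the transcriptome; no peaks called")
    return(empty_peaks())
  }
  wins <- bind_rows(wins)
  wins$q <- p.adjust(wins$p, method = "BH")
  sig <- filter(wins, .data$q < params$q_threshold)
  if (nrow(sig) == 0) return(empty_peaks())
  merged <- merge_significant(sig)
  merged <- filter(merged, .data$end - .data$start >= params$min_region_len)
  # control pileup floor: genome-wide per-base control coverage rate
  ctl_cov_rate <- if (analytic_bg) {
    sum(signal$reads$end - signal$reads$start) / eff
  } else {
    sum(control$reads$end - control$reads$start) / eff
  }
  flank <- params$resize_flank
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    m <- filter(merged, .data$chrom == region$chrom,
                .data$start < region$end, .data$end > region$start)
    if (nrow(m) == 0) next
    sp <- profs[[i]]$sig
    cp <- profs[[i]]$ctl
    for (j in seq_len(nrow(m))) {
      rel_s <- m$start[j] - region$start + 1L
      rel_e <- m$end[j] - region$start
      reg_cov <- sp$cov[rel_s:rel_e]
      summits_rel <- find_summits(reg_cov, flank) + rel_s - 1L
      contour <- params$summit_min_frac * max(reg_cov)
      summits_rel <- summits_rel[sp$cov[summits_rel] >= contour]
      for (s_rel in summits_rel) {
        s_abs <- region$start + s_rel - 1L
        cov_sig <- sp$cov[s_rel]
        cov_ctl <- if (analytic_bg) {
          if (is.null(cp)) sp$cov[s_rel] else cp$cov[s_rel]
        } else cp$cov[s_rel]
        ctl_depth <- if (analytic_bg) sig_total else control$library_size
        fe <- (cov_sig / sig_total) /
          (max(if (analytic_bg) ctl_cov_rate else cov_ctl, ctl_cov_rate) /
             ctl_depth)
        rows[[length(rows) + 1]] <- tibble(
          chrom = region$chrom, start = s_abs - flank,
          end = s_abs + flank + 1L, summit = s_abs, pvalue = m$p[j],
          qvalue = m$q[j], fold_enrichment = fe
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_peaks())
  peaks <- distinct(bind_rows(rows))
  peaks <- arrange(peaks, .data$chrom, .data$start)
  peaks$start <- pmax(peaks$start, 0L)
  peak_table(peaks$chrom, peaks$start, peaks$end, peaks$summit,
             peaks$pvalue, peaks$qvalue, peaks$fold_enrichment)
}

empty_peaks <- function() {
  peak_table(character(), integer(), integer(), integer(), numeric(),
             numeric(), numeric())
}

#' Call 5hmC peaks from IP versus input coverage
#'
#' Slides a window over the genomic union of transcript spans, tests the
#' IP fragment-start count of each window against a Poisson background
#' whose rate is the maximum of the genome-wide rate (over the effective
#' transcriptome size) and input-derived local rates (windows in
#' `local_windows`, scaled to IP depth), BH-corrects across all tested
#' windows, merges significant windows into regions, places one summit
#' per local pileup maximum (leftmost on ties) and resizes every peak to
#' `resize_flank` bases on both sides of its summit.
#'
#' @param ip,input [read_set()] objects for the IP and input libraries.
#' @param txome A [transcriptome].
#' @param params A [peak_call_params()].
#' @return An `hmerip_peaks` tibble; fold_enrichment is the
#'   depth-normalized IP/input pileup ratio at the summit, with the input
#'   pileup floored at its genome-wide rate.
#' @export
call_peaks <- function(ip, input, txome, params = peak_call_params()) {
  stopifnot(inherits(params, "peak_call_params"))
  if (ip$library_size == 0 || input$library_size == 0) {
    abort("both IP and input read sets must be nonempty")
  }
  call_peaks_engine(ip, input, txome, params, analytic_bg = FALSE)
}

#' Call expected peaks from the input library alone
#'
#' Runs the identical scan with the input as signal against the analytic
#' uniform background (genome-wide input rate over the effective
#' transcriptome size). Expected peaks are the regions most likely to
#' generate peaks by read abundance alone and serve as negative controls
#' for motif and distribution analyses.
#'
#' @param input A [read_set()].
#' @inheritParams call_peaks
#' @return An `hmerip_peaks` tibble.
#' @export
call_expected_peaks <- function(input, txome, params = peak_call_params()) {
  stopifnot(inherits(params, "peak_call_params"))
  if (input$library_size == 0) abort("input read set is empty")
  call_peaks_engine(input, NULL, txome, params, analytic_bg = TRUE)
}

#' Intersect peak lists across replicates
#'
#' Emits one final peak for each maximal genomic region covered by at
#' least one peak from every replicate; the emitted interval is the
#' intersection of the contributing replicate peaks, and the summit and
#' statistics are taken from the contributing peak with the smallest
#' q-value (summit clamped into the emitted interval if needed).
#'
#' @param peak_lists List of `hmerip_peaks` tibbles, one per replicate.
#' @return An `hmerip_peaks` tibble of replicated peaks.
#' @export
replicate_intersection <- function(peak_lists) {
  if (length(peak_lists) == 0) abort("no peak lists supplied")
  if (length(peak_lists) == 1) {
    warn("single replicate: replicate intersection is the identity")
    return(peak_lists[[1]])
  }
  if (any(map_int(peak_lists, nrow) == 0)) return(empty_peaks())
  covers <- map(peak_lists, function(p) {
    gr <- as_granges(p)
    GenomicRanges::strand(gr) <- "*"
    GenomicRanges::reduce(gr)
  })
  common <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, covers)
  if (length(common) == 0) return(empty_peaks())
  out <- granges_to_tbl(common)
  all_peaks <- bind_rows(peak_lists)
  pk_gr <- as_granges(all_peaks)
  GenomicRanges::strand(pk_gr) <- "*"
  hits <- GenomicRanges::findOverlaps(common, pk_gr, ignore.strand = TRUE)
  best <- summarise(
    group_by(tibble(region = S4Vectors::queryHits(hits),
                    peak = S4Vectors::subjectHits(hits)), .data$region),
    peak = .data$peak[which.min(all_peaks$qvalue[.data$peak])],
    .groups = "drop"
  )
  src <- all_peaks[best$peak[match(seq_len(nrow(out)), best$region)], ]
  out$summit <- pmin(pmax(src$summit, out$start), out$end - 1L)
  out$pvalue <- src$pvalue
  out$qvalue <- src$qvalue
  out$fold_enrichment <- src$fold_enrichment
  peak_table(out$chrom, out$start, out$end, out$summit, out$pvalue,
             out$qvalue, out$fold_enrichment)
}
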