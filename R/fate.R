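#' Stratify expressed transcripts by 5hmC status
#'
#' Keeps transcripts of expressed genes (TPM > 1) and labels each
#' `modified` when at least one final 5hmC peak overlaps the transcript,
#' `unmodified` otherwise.
#'
#' @param fate_table Tibble with `transcript_id`, `tpm` and any fate
#'   columns (e.g. `half_life`, `te`).
#' @param final_peaks An `hmerip_peaks` tibble of replicated peaks.
#' @param txome A [transcriptome].
#' @return The expressed subset of `fate_table` with an added
#'   `hmc_status` column, class `hmerip_fate`.
#' @export
stratify <- function(fate_table, final_peaks, txome) {
  marked <- character()
  if (nrow(final_peaks) > 0) {
    gr <- as_granges(final_peaks)
    GenomicRanges::strand(gr) <- "*"
    hits <- GenomicRanges::findOverlaps(gr, txome$index,
                                        ignore.strand = TRUE)
    marked <- unique(
      txome$transcripts$transcript_id[S4Vectors::subjectHits(hits)])
  }
  out <- mutate(filter(fate_table, .data$tpm > 1),
                hmc_status = ifelse(.data$transcript_id %in% marked,
                                    "modified", "unmodified"))
  class(out) <- unique(c("hmerip_fate", class(tibble())))
  out
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. The p-value is exact (from the
#' null distribution of the Mann-Whitney U statistic) when
#' `min(n, m) <= 8` and there are no ties, and uses the normal
#' approximation with tie and continuity corrections otherwise.
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   with respect to `group_a`.
#' @return Tibble: `statistic` (U for group A), `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(group_a, group_b,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be nonempty")
  }
  n <- length(group_a)
  m <- length(group_b)
  r <- rank(c(group_a, group_b)) # midranks
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- min(n, m) <= 8 && !has_ties
  if (exact) {
    p <- switch(alternative,
      two.sided = {
        if (u > n * m / 2) min(1, 2 * pwilcox(u - 1, n, m,
                                              lower.tail = FALSE))
        else min(1, 2 * pwilcox(u, n, m))
      },
      less = pwilcox(u, n, m),
      greater = pwilcox(u - 1, n, m, lower.tail = FALSE)
    )
    method <- "exact"
  } else {
    mu <- n * m / 2
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    cc <- 0.5 # continuity correction
    p <- switch(alternative,
      two.sided = {
        z <- (abs(u - mu) - cc) / sigma
        min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
      },
      less = pnorm((u - mu + cc) / sigma),
      greater = pnorm((u - mu - cc) / sigma, lower.tail = FALSE)
    )
    method <- "normal approximation"
  }
  tibble(statistic = u, p_value = p, method = method)
}

#' Compare half-life or translation efficiency between 5hmC groups
#'
#' Wilcoxon rank-sum test of a fate variable between modified and
#' unmodified transcripts of a stratified table.
#'
#' @param records Output of [stratify()].
#' @param value Column to compare (string, e.g. `"half_life"` or
#'   `"te"`).
#' @param alternative Passed to [wilcoxon_rank_sum()]; the first group is
#'   the modified one.
#' @return Tibble with group sizes and medians plus the test result.
#' @export
compare_fate <- function(records, value, alternative = "two.sided") {
  v <- records[[value]]
  mod <- v[records$hmc_status == "modified" & !is.na(v)]
  unmod <- v[records$hmc_status == "unmodified" & !is.na(v)]
  test <- wilcoxon_rank_sum(mod, unmod, alternative)
  tibble(variable = value, n_modified = length(mod),
         n_unmodified = length(unmod), median_modified = median(mod),
         median_unmodified = median(unmod), statistic = test$statistic,
         p_value = test$p_value, method = test$method)
}

#' Median-of-ratios size factors
#'
#' For a count matrix (transcripts x samples): the pseudo-reference is
#' the per-transcript geometric mean across samples (rows with any zero
#' excluded); each sample's size factor is the median count/reference
#' ratio, rescaled so the size factors have geometric mean 1.
#'
#' @param mat Non-negative count matrix, transcripts in rows.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  ok <- rowSums(mat == 0) == 0
  if (!any(ok)) abort("no transcript has nonzero counts in every sample")
  logref <- rowMeans(log(mat[ok, , drop = FALSE]))
  sf <- apply(mat[ok, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - logref))
  })
  sf / exp(mean(log(sf)))
}

#' Transcription-shutoff decay analysis
#'
#' Counts at 0 h and 4 h after transcription shutoff are normalized with
#' median-of-ratios size factors across all samples; per transcript, the
#' log2 fold change of the mean normalized abundance (4 h over 0 h) is
#' tested with a two-sided t-test on per-replicate normalized log2
#' abundances, BH-adjusted. A transcript is `destabilized` when
#' `log2fc <= -log2(fc_threshold)` and `adj_p < alpha` (`stabilized`
#' symmetric). Assuming first-order decay, the half-life estimate is
#' `4 * ln(2) / ln(N0/N4)` hours when abundance decreases.
#'
#' @param decay_tbl Tibble with columns `transcript_id`, `replicate`,
#'   `count_0h`, `count_4h` (one condition).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param shutoff_hours Time between the two points (default 4).
#' @return Tibble of class `hmerip_decay`: `transcript_id`, `n0`, `n4`,
#'   `log2fc`, `p_value`, `adj_p`, `stable_call`, `half_life_est`,
#'   `flag`.
#' @export
decay_analysis <- function(decay_tbl, fc_threshold = 1.5, alpha = 0.05,
                           shutoff_hours = 4) {
  wide <- tidyr::pivot_wider(
    select(decay_tbl, "transcript_id", "replicate", "count_0h",
           "count_4h"),
    names_from = "replicate", values_from = c("count_0h", "count_4h")
  )
  mat <- as.matrix(select(wide, -"transcript_id"))
  if (ncol(mat) < 4) abort("at least 2 replicates per time point required")
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  is0 <- grepl("^count_0h", colnames(mat))
  n0 <- rowMeans(norm[, is0, drop = FALSE])
  n4 <- rowMeans(norm[, !is0, drop = FALSE])
  skipped <- n0 == 0 & n4 == 0
  log2fc <- log2(n4 / n0)
  pvals <- rep(NA_real_, nrow(norm))
  for (i in which(!skipped)) {
    a <- log2(norm[i, is0] + 1)
    b <- log2(norm[i, !is0] + 1)
    pvals[i] <- if (isTRUE(all.equal(var(a) + var(b), 0))) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else t.test(b, a)$p.value
  }
  adj_p <- rep(NA_real_, length(pvals))
  adj_p[!skipped] <- p.adjust(pvals[!skipped], method = "BH")
  thr <- log2(fc_threshold)
  out <- tibble(
    transcript_id = wide$transcript_id, n0 = n0, n4 = n4,
    log2fc = log2fc, p_value = pvals, adj_p = adj_p,
    stable_call = dplyr::case_when(
      skipped ~ NA_character_,
      log2fc <= -thr & adj_p < alpha ~ "destabilized",
      log2fc >= thr & adj_p < alpha ~ "stabilized",
      TRUE ~ "unchanged"
    ),
    half_life_est = ifelse(!skipped & n4 < n0 & n4 > 0,
                           shutoff_hours * log(2) / log(n0 / n4),
                           NA_real_),
    flag = ifelse(skipped, "skipped", "ok")
  )
  class(out) <- unique(c("hmerip_decay", class(tibble())))
  out
}

#' Normalized unspliced/spliced ratios
#'
#' Per transcript, condition and time point: `ratio = unspliced /
#' spliced` (records with zero spliced counts are skipped with a flag);
#' the normalized ratio divides by the same transcript and condition's
#' ratio at 0 h, so the 0 h normalized ratio is exactly 1.
#'
#' @param splice_tbl Tibble with columns `transcript_id`, `condition`,
#'   `time_h`, `unspliced`, `spliced`.
#' @param transcripts Optional character vector restricting the analysis
#'   (e.g. expressed transcripts with intronic 5hmC peaks).
#' @return Tibble with added `ratio`, `norm_ratio`, `flag` columns.
#' @export
splicing_ratio <- function(splice_tbl, transcripts = NULL) {
  tbl <- splice_tbl
  if (!is.null(transcripts)) {
    tbl <- filter(tbl, .data$transcript_id %in% transcripts)
  }
  tbl <- mutate(tbl,
                ratio = ifelse(.data$spliced > 0,
                               .data$unspliced / .data$spliced, NA_real_))
  base <- filter(tbl, .data$time_h == 0)
  base <- select(base, "transcript_id", "condition", ratio_0h = "ratio")
  tbl <- left_join(tbl, base, by = c("transcript_id", "condition"))
  mutate(tbl,
         norm_ratio = ifelse(!is.na(.data$ratio) & !is.na(.data$ratio_0h) &
                               .data$ratio_0h > 0,
                             .data$ratio / .data$ratio_0h, NA_real_),
         flag = ifelse(is.na(.data$ratio) | is.na(.data$ratio_0h) |
                         .data$ratio_0h == 0, "skipped", "ok"))
}
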