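#' Transcripts-per-million from counts
#'
#' `rate_i = count_i / length_i; TPM_i = 1e6 * rate_i / sum(rate)`.
#' Columns always sum to one million.
#'
#' @param counts Non-negative per-transcript counts.
#' @param lengths Effective transcript lengths (> 0).
#' @return Numeric TPM vector.
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (any(lengths <= 0)) abort("lengths must be > 0")
  if (all(counts == 0)) abort("all counts are zero")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Call protein-bound transcripts from IP and input TPM
#'
#' A pseudocount of 1 TPM is added to both libraries; the enrichment is
#' `log2((ip + 1) / (input + 1))` and a transcript is bound when its IP
#' TPM strictly exceeds its input TPM.
#'
#' @param ip_tpm,input_tpm TPM vectors over the same transcript universe.
#' @param pseudocount Added to both sides (default 1).
#' @return Tibble: `enrichment` (log2), `bound` (logical).
#' @export
#' @examples
#' call_bound(5, 3)
call_bound <- function(ip_tpm, input_tpm, pseudocount = 1) {
  stopifnot(length(ip_tpm) == length(input_tpm))
  tibble(
    enrichment = log2((ip_tpm + pseudocount) / (input_tpm + pseudocount)),
    bound = ip_tpm > input_tpm
  )
}

#' RIP-Seq bound-transcript calls from replicate count tables
#'
#' Converts counts to TPM per sample, applies [call_bound()] per
#' replicate pair, and combines replicates: with `combine = "all"` a
#' transcript is bound only when bound in every replicate (mirroring the
#' all-replicates intersection used for peaks); `combine = "mean"` calls
#' on mean TPM instead.
#'
#' @param counts Tibble with columns `replicate`, `transcript_id`,
#'   `ip_count`, `input_count` (one protein; filter first).
#' @param lengths Tibble `transcript_id`, `length`.
#' @param combine `"all"` or `"mean"`.
#' @param expressed_min Universe filter: transcripts with input TPM above
#'   this in every replicate form the universe (default 1).
#' @return Tibble: `transcript_id`, `mean_enrichment`, `bound`,
#'   restricted to the expressed universe.
#' @export
rip_call_bound <- function(counts, lengths, combine = c("all", "mean"),
                           expressed_min = 1) {
  combine <- match.arg(combine)
  counts <- left_join(counts, lengths, by = "transcript_id")
  if (any(is.na(counts$length))) abort("missing transcript lengths")
  per_rep <- ungroup(mutate(
    group_by(counts, .data$replicate),
    ip_tpm = tpm_from_counts(.data$ip_count, .data$length),
    input_tpm = tpm_from_counts(.data$input_count, .data$length)
  ))
  per_rep <- mutate(per_rep, call_bound(.data$ip_tpm, .data$input_tpm))
  if (combine == "mean") {
    out <- summarise(group_by(per_rep, .data$transcript_id),
                     ip = mean(.data$ip_tpm),
                     input = mean(.data$input_tpm),
                     expressed = all(.data$input_tpm > expressed_min),
                     .groups = "drop")
    calls <- call_bound(out$ip, out$input)
    out <- tibble(transcript_id = out$transcript_id,
                  mean_enrichment = calls$enrichment, bound = calls$bound,
                  expressed = out$expressed)
  } else {
    out <- summarise(group_by(per_rep, .data$transcript_id),
                     mean_enrichment = mean(.data$enrichment),
                     bound = all(.data$bound),
                     expressed = all(.data$input_tpm > expressed_min),
                     .groups = "drop")
  }
  select(filter(out, .data$expressed), -"expressed")
}

#' Partition transcripts by 5hmC marking and Tet binding
#'
#' Exact set algebra over a transcript universe: each transcript falls in
#' one binding category (`both`, `Tet1_only`, `Tet2_only`, `neither`)
#' crossed with its 5hmC status.
#'
#' @param hmc_transcripts,tet1_bound,tet2_bound Character vectors of
#'   transcript ids, all subsets of `universe`.
#' @param universe Character vector of all considered transcripts.
#' @return List of class `overlap_partition`: `assignments` (tibble),
#'   `counts` (binding x 5hmC cell counts), `pct_hmc_bound` (percentage
#'   of 5hmC+ transcripts bound by Tet1 and/or Tet2).
#' @export
overlap_partition <- function(hmc_transcripts, tet1_bound, tet2_bound,
                              universe) {
  for (s in list(hmc_transcripts, tet1_bound, tet2_bound)) {
    if (!all(s %in% universe)) {
      abort("set element outside the transcript universe")
    }
  }
  t1 <- universe %in% tet1_bound
  t2 <- universe %in% tet2_bound
  assignments <- tibble(
    transcript_id = universe,
    binding = dplyr::case_when(t1 & t2 ~ "both", t1 ~ "Tet1_only",
                               t2 ~ "Tet2_only", TRUE ~ "neither"),
    hmc = ifelse(universe %in% hmc_transcripts, "5hmC+", "5hmC-")
  )
  counts <- tidyr::complete(
    dplyr::count(assignments, .data$binding, .data$hmc),
    binding = c("both", "Tet1_only", "Tet2_only", "neither"),
    hmc = c("5hmC+", "5hmC-"), fill = list(n = 0L)
  )
  n_hmc <- sum(assignments$hmc == "5hmC+")
  pct <- if (n_hmc == 0) NA_real_ else {
    100 * sum(assignments$hmc == "5hmC+" &
                assignments$binding != "neither") / n_hmc
  }
  structure(list(assignments = assignments, counts = counts,
                 pct_hmc_bound = pct),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition> %d transcripts; %.1f%% of 5hmC+ bound\n",
              nrow(x$assignments), x$pct_hmc_bound))
  print(tidyr::pivot_wider(x$counts, names_from = "hmc",
                           values_from = "n"))
  invisible(x)
}
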