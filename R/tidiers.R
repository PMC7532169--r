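#' Tidy a motif set
#'
#' @param x A `motif_set` from [discover_motifs()].
#' @param ... Unused.
#' @return One row per motif: consensus, width, enrichment score, site
#'   count, ZOOPS occurrence prior, and centrality verdict when judged.
#' @export
tidy.motif_set <- function(x, ...) {
  bind_rows(map(x, function(m) {
    tibble(consensus = m$consensus, width = m$width,
           enrichment_score = m$enrichment_score, n_sites = m$n_sites,
           gamma = m$gamma,
           centrality = m$centrality %||% NA_character_,
           centrality_p = m$centrality_p %||% NA_real_)
  }))
}

#' @rdname tidy.motif_set
#' @export
glance.motif_set <- function(x, ...) {
  tibble(n_motifs = length(x),
         n_positives = attr(x, "n_positives"),
         n_controls = attr(x, "n_controls"),
         best_enrichment = if (length(x)) x[[1]]$enrichment_score
                           else NA_real_)
}

#' Tidy an overlap partition
#'
#' @param x An [overlap_partition()] object.
#' @param ... Unused.
#' @return The binding-by-5hmC cell counts with percentages of each 5hmC
#'   stratum.
#' @export
tidy.overlap_partition <- function(x, ...) {
  ungroup(mutate(group_by(x$counts, .data$hmc),
                 pct_of_stratum = 100 * .data$n / sum(.data$n)))
}

#' @rdname tidy.overlap_partition
#' @export
glance.overlap_partition <- function(x, ...) {
  tibble(n_transcripts = nrow(x$assignments),
         n_hmc = sum(x$assignments$hmc == "5hmC+"),
         pct_hmc_bound = x$pct_hmc_bound)
}

#' Summaries of peak tables
#'
#' @param x An `hmerip_peaks` tibble.
#' @param ... Unused.
#' @return `glance()`: peak count, width and q-value summaries.
#' @export
glance.hmerip_peaks <- function(x, ...) {
  tibble(n_peaks = nrow(x),
         median_width = if (nrow(x)) median(x$end - x$start) else NA_real_,
         median_q = if (nrow(x)) median(x$qvalue) else NA_real_,
         median_fold = if (nrow(x)) median(x$fold_enrichment) else NA_real_)
}

#' Summaries of differential-marking calls
#'
#' @param x An `hmerip_diff` tibble from [differential_call()].
#' @param ... Unused.
#' @return `glance()`: counts by direction.
#' @export
glance.hmerip_diff <- function(x, ...) {
  tibble(n_peaks = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_unchanged = sum(x$direction == "unchanged"))
}

#' Summaries of decay results
#'
#' @param x An `hmerip_decay` tibble from [decay_analysis()].
#' @param ... Unused.
#' @return `glance()`: counts by stability call and median half-life.
#' @export
glance.hmerip_decay <- function(x, ...) {
  tibble(n_tested = sum(x$flag == "ok"),
         n_destabilized = sum(x$stable_call == "destabilized",
                              na.rm = TRUE),
         n_stabilized = sum(x$stable_call == "stabilized", na.rm = TRUE),
         median_half_life = median(x$half_life_est, na.rm = TRUE))
}
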