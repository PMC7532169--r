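#' Plot a peak table
#'
#' Histogram of summit fold enrichments, colored by q-value band.
#'
#' @param object An `hmerip_peaks` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmerip_peaks <- function(object, ...) {
  ggplot(object, aes(x = .data$fold_enrichment)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = "fold enrichment at summit", y = "peaks",
                  title = sprintf("%d peaks", nrow(object))) +
    ggplot2::theme_minimal()
}

#' Plot differential marking as a condition-vs-condition scatter
#'
#' Enrichment ratios of the two conditions on log scales, with the
#' fold-change diagonal band; points outside the band are the
#' differentially marked peaks.
#'
#' @param object An `hmerip_diff` tibble from [differential_call()].
#' @param threshold Band half-width as a fold change (default 1.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmerip_diff <- function(object, threshold = 1.5, ...) {
  ggplot(object, aes(x = .data$ratio_a, y = .data$ratio_b,
                     color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = log10(threshold),
                         linetype = 3) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(threshold),
                         linetype = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("enrichment ratio (%s)",
                              object$condition_a[1]),
                  y = sprintf("enrichment ratio (%s)",
                              object$condition_b[1])) +
    ggplot2::theme_minimal()
}

#' Plot observed-vs-expected peak distribution
#'
#' Paired bars of observed and expected percentages per structural
#' label, annotated with the percentage-point enrichment.
#'
#' @param object An `hmerip_distribution` tibble from
#'   [distribution_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmerip_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("observed_pct", "expected_pct"),
                              names_to = "set", values_to = "pct")
  ggplot(long, aes(x = .data$label, y = .data$pct, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a discovered motif as a position-probability heatmap
#'
#' @param object A `motif_set`; the first (top) motif is drawn unless
#'   `which` says otherwise.
#' @param which Motif index (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_set <- function(object, which = 1, ...) {
  m <- object[[which]]
  df <- as_tibble(as.data.frame(as.table(m$pwm)))
  names(df) <- c("base", "position", "prob")
  df$base <- factor(c("A", "C", "G", "U")[as.integer(df$base)],
                    levels = c("A", "C", "G", "U"))
  df$position <- as.integer(df$position)
  ggplot(df, aes(x = .data$position, y = .data$base,
                 fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(title = m$consensus, fill = "probability") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a decay analysis
#'
#' @param object An `hmerip_decay` tibble from [decay_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmerip_decay <- function(object, ...) {
  ok <- filter(object, .data$flag == "ok")
  ggplot(ok, aes(x = .data$log2fc, y = -log10(pmax(.data$adj_p, 1e-300)),
                 color = .data$stable_call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "log2 fold change (4 h / 0 h)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
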