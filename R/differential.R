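#' Count metasample fragments in peaks
#'
#' A fragment counts toward every peak it overlaps by at least one base
#' (half-open intervals).
#'
#' @param meta A [read_set()] (typically a metasample, see
#'   [build_metasample()]).
#' @param peaks An `hmerip_peaks` tibble (or any interval tibble with a
#'   `name` column).
#' @return Tibble `name`, `count`.
#' @export
count_in_peaks <- function(meta, peaks) {
  if (nrow(peaks) == 0) return(tibble(name = character(), count = integer()))
  if (!"name" %in% names(peaks)) {
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  pk <- as_granges(peaks)
  GenomicRanges::strand(pk) <- "*"
  if (nrow(meta$reads) == 0) {
    return(tibble(name = peaks$name, count = 0L))
  }
  rd <- as_granges(meta$reads)
  GenomicRanges::strand(rd) <- "*"
  tibble(name = peaks$name,
         count = GenomicRanges::countOverlaps(pk, rd, ignore.strand = TRUE))
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Fragment count(s) in a region.
#' @param peak_len Region length(s) in bases (> 0).
#' @param library_size Total mapped fragments in the library (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(10, 201, 1e6)
rpkm <- function(count, peak_len, library_size) {
  if (any(peak_len <= 0)) abort("peak_len must be > 0")
  if (any(library_size <= 0)) abort("library_size must be > 0")
  count / ((peak_len / 1000) * (library_size / 1e6))
}

#' Quantify peaks in one condition
#'
#' Counts IP and input metasample fragments in each peak and computes the
#' condition's enrichment ratio, IP RPKM over input RPKM. When either raw
#' count is zero, one raw read is added to both counts before RPKM so the
#' ratio is always defined (mirroring the 1-TPM pseudocount convention
#' used for RIP enrichment).
#'
#' @param peaks An `hmerip_peaks` tibble.
#' @param ip_meta,input_meta IP and input metasamples ([read_set()]).
#' @param condition Condition label attached to the output.
#' @return Tibble: `name`, `condition`, `ip_count`, `input_count`,
#'   `ip_rpkm`, `input_rpkm`, `enrichment_ratio`.
#' @export
quantify_peaks <- function(peaks, ip_meta, input_meta,
                           condition = ip_meta$condition) {
  ipc <- count_in_peaks(ip_meta, peaks)
  inc <- count_in_peaks(input_meta, peaks)
  len <- peaks$end - peaks$start
  pseudo <- ipc$count == 0 | inc$count == 0
  ip_adj <- ipc$count + as.integer(pseudo)
  in_adj <- inc$count + as.integer(pseudo)
  tibble(
    name = peaks$name, condition = condition,
    ip_count = ipc$count, input_count = inc$count,
    ip_rpkm = rpkm(ip_adj, len, ip_meta$library_size),
    input_rpkm = rpkm(in_adj, len, input_meta$library_size),
    enrichment_ratio = rpkm(ip_adj, len, ip_meta$library_size) /
      rpkm(in_adj, len, input_meta$library_size)
  )
}

#' Combine the final peak lists of two conditions for quantification
#'
#' With `mode = "union"` (default) the replicated peaks of both
#' conditions are quantified together, so a peak absent from one
#' condition's final list remains comparable; `mode = "reference"` keeps
#' only the first condition's peaks. Identical intervals are
#' deduplicated; overlapping peaks are kept as distinct rows.
#'
#' @param peaks_a,peaks_b `hmerip_peaks` tibbles (condition A is the
#'   reference).
#' @param mode `"union"` or `"reference"`.
#' @return An `hmerip_peaks` tibble with fresh names.
#' @export
combine_condition_peaks <- function(peaks_a, peaks_b,
                                    mode = c("union", "reference")) {
  mode <- match.arg(mode)
  out <- if (mode == "reference") peaks_a else {
    distinct(bind_rows(peaks_a, peaks_b), .data$chrom, .data$start,
             .data$end, .keep_all = TRUE)
  }
  out <- arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  new_peak_tbl(out)
}

#' Call differentially marked peaks between two conditions
#'
#' A peak is differentially marked when the fold change between the two
#' conditions' enrichment ratios is at least `threshold` (default 1.5).
#' Direction describes condition B relative to condition A: `up` when
#' B's ratio exceeds A's by at least the threshold, `down` when A's
#' exceeds B's by at least the threshold, `unchanged` otherwise.
#'
#' @param quant_a,quant_b Outputs of [quantify_peaks()] for the same peak
#'   set in the two conditions.
#' @param threshold Minimum fold change (>= 1).
#' @return Tibble of class `hmerip_diff`: `name`, `ratio_a`, `ratio_b`,
#'   `fold_change` (always >= 1), `direction` in
#'   `{"up", "down", "unchanged"}` (change in B with respect to A).
#' @export
differential_call <- function(quant_a, quant_b, threshold = 1.5) {
  stopifnot(threshold >= 1)
  m <- inner_join(select(quant_a, "name", ratio_a = "enrichment_ratio"),
                  select(quant_b, "name", ratio_b = "enrichment_ratio"),
                  by = "name")
  m <- mutate(m,
    fold_change = pmax(.data$ratio_a, .data$ratio_b) /
      pmin(.data$ratio_a, .data$ratio_b),
    direction = dplyr::case_when(
      .data$ratio_b / .data$ratio_a >= threshold ~ "up",
      .data$ratio_a / .data$ratio_b >= threshold ~ "down",
      TRUE ~ "unchanged"
    )
  )
  m <- mutate(m, condition_a = quant_a$condition[1],
              condition_b = quant_b$condition[1])
  class(m) <- unique(c("hmerip_diff", class(tibble())))
  m
}

#' Summarize differential calls per transcript
#'
#' A transcript is `reduced` when at least one of its peaks is down and
#' none is up, `increased` symmetrically, `mixed` when both directions
#' occur, `unchanged` otherwise.
#'
#' @param calls Output of [differential_call()].
#' @param peaks The peak tibble the calls refer to (for coordinates).
#' @param txome A [transcriptome].
#' @return Tibble `transcript_id`, `n_peaks`, `status`.
#' @export
transcript_level_summary <- function(calls, peaks, txome) {
  pk <- inner_join(select(peaks, "name", "chrom", "start", "end"),
                   select(calls, "name", "direction"), by = "name")
  if (nrow(pk) == 0) {
    return(tibble(transcript_id = character(), n_peaks = integer(),
                  status = character()))
  }
  gr <- GenomicRanges::GRanges(pk$chrom,
                               IRanges::IRanges(pk$start + 1L, pk$end))
  hits <- GenomicRanges::findOverlaps(gr, txome$index, ignore.strand = TRUE)
  ann <- tibble(
    transcript_id =
      txome$transcripts$transcript_id[S4Vectors::subjectHits(hits)],
    direction = pk$direction[S4Vectors::queryHits(hits)]
  )
  summarise(group_by(ann, .data$transcript_id),
            n_peaks = n(),
            status = {
              has_dn <- any(.data$direction == "down")
              has_up <- any(.data$direction == "up")
              if (has_dn && has_up) "mixed"
              else if (has_dn) "reduced"
              else if (has_up) "increased"
              else "unchanged"
            },
            .groups = "drop")
}
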