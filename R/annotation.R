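#' Assign peaks to transcript structural elements
#'
#' Summit-based assignment: a peak belongs to an exon when its summit
#' lies inside an annotated exon of an overlapping coding transcript, to
#' an intron when the summit is inside the transcript but outside its
#' exons. Peaks whose summit overlaps no coding transcript, or whose
#' overlapping transcripts disagree, are left `unannotated`. The same
#' uniqueness rule assigns the summit to the CDS or the flanking UTRs
#' (strand-aware: the 5'UTR is upstream of the CDS on the transcript's
#' strand).
#'
#' @param peaks An `hmerip_peaks` tibble.
#' @param txome A [transcriptome].
#' @return `peaks` with added `element` (exon/intron/unannotated) and
#'   `region` (5'UTR/CDS/3'UTR/unannotated) columns, class
#'   `hmerip_annotated`.
#' @export
annotate_peaks <- function(peaks, txome) {
  n <- nrow(peaks)
  if (n == 0) {
    out <- mutate(peaks, element = character(), region = character())
    class(out) <- unique(c("hmerip_annotated", class(tibble())))
    return(out)
  }
  verdicts <- summit_verdicts(peaks, txome)
  per_peak <- summarise(
    group_by(verdicts, .data$peak_idx),
    element = unique_or_unannotated(.data$element),
    region = unique_or_unannotated(.data$region),
    .groups = "drop"
  )
  out <- mutate(peaks,
                element = "unannotated", region = "unannotated")
  out$element[per_peak$peak_idx] <- per_peak$element
  out$region[per_peak$peak_idx] <- per_peak$region
  class(out) <- unique(c("hmerip_annotated", class(tibble())))
  out
}

unique_or_unannotated <- function(x) {
  u <- unique(x)
  if (length(u) == 1) u else "unannotated"
}

# one row per (peak summit, overlapping coding transcript) with that
# transcript's exon/intron and CDS/UTR verdicts
summit_verdicts <- function(peaks, txome) {
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$summit + 1L,
                                               peaks$summit + 1L))
  hits <- GenomicRanges::findOverlaps(s, txome$index, ignore.strand = TRUE)
  tx <- txome$transcripts[S4Vectors::subjectHits(hits), ]
  peak_idx <- S4Vectors::queryHits(hits)
  keep <- !is.na(tx$cds_start)
  tx <- tx[keep, ]
  peak_idx <- peak_idx[keep]
  if (nrow(tx) == 0) {
    return(tibble(peak_idx = integer(), element = character(),
                  region = character()))
  }
  summit <- peaks$summit[peak_idx]
  # exon containment per (peak, transcript)
  ex_gr <- as_granges(txome$exons)
  pt_gr <- GenomicRanges::GRanges(peaks$chrom[peak_idx],
                                  IRanges::IRanges(summit + 1L, summit + 1L))
  ex_hits <- GenomicRanges::findOverlaps(pt_gr, ex_gr, ignore.strand = TRUE)
  in_exon <- logical(length(peak_idx))
  ok <- txome$exons$transcript_id[S4Vectors::subjectHits(ex_hits)] ==
    tx$transcript_id[S4Vectors::queryHits(ex_hits)]
  in_exon[unique(S4Vectors::queryHits(ex_hits)[ok])] <- TRUE
  upstream <- summit < tx$cds_start
  downstream <- summit >= tx$cds_end
  region <- dplyr::case_when(
    upstream & tx$strand == "+" ~ "5'UTR",
    upstream & tx$strand == "-" ~ "3'UTR",
    downstream & tx$strand == "+" ~ "3'UTR",
    downstream & tx$strand == "-" ~ "5'UTR",
    TRUE ~ "CDS"
  )
  tibble(peak_idx = peak_idx,
         transcript_id = tx$transcript_id,
         element = ifelse(in_exon, "exon", "intron"),
         region = region)
}

#' Structural element of peak summits
#'
#' Convenience wrapper around [annotate_peaks()].
#'
#' @inheritParams annotate_peaks
#' @return Character vector: `"exon"`, `"intron"` or `"unannotated"`.
#' @export
assign_structural <- function(peaks, txome) {
  annotate_peaks(peaks, txome)$element
}

#' CDS/UTR region of peak summits
#'
#' @inheritParams annotate_peaks
#' @return Character vector: `"5'UTR"`, `"CDS"`, `"3'UTR"` or
#'   `"unannotated"`.
#' @export
assign_region <- function(peaks, txome) {
  annotate_peaks(peaks, txome)$region
}

#' Distribution enrichment of observed versus expected peaks
#'
#' For each structural label, the enrichment is the difference between
#' the observed and expected percentages of peaks carrying that label
#' (percentage points); percentages are computed over all peaks,
#' unannotated included, so enrichments sum to zero.
#'
#' @param observed,expected Character vectors of labels (e.g. the
#'   `element` column of [annotate_peaks()] output) for 5hmC peaks and
#'   expected peaks.
#' @return Tibble of class `hmerip_distribution`: `label`,
#'   `observed_pct`, `expected_pct`, `enrichment`.
#' @export
distribution_enrichment <- function(observed, expected) {
  if (length(observed) == 0 || length(expected) == 0) {
    abort("observed and expected label sets must be nonempty")
  }
  labels <- sort(unique(c(observed, expected)))
  out <- tibble(
    label = labels,
    observed_pct = 100 * vapply(labels, function(l) mean(observed == l),
                                numeric(1), USE.NAMES = FALSE),
    expected_pct = 100 * vapply(labels, function(l) mean(expected == l),
                                numeric(1), USE.NAMES = FALSE)
  )
  out <- mutate(out, enrichment = .data$observed_pct - .data$expected_pct)
  class(out) <- unique(c("hmerip_distribution", class(tibble())))
  out
}
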