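#' Build a tibble of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`. Strand is one of
#' `"+"`, `"-"` or `"."` (unstranded).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start >= 0`, `end > start`.
#' @param strand Strand characters, recycled; default `"."`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
#' @examples
#' genomic_intervals("chr1", 0L, 100L, "+")
genomic_intervals <- function(chrom, start, end, strand = ".") {
  tbl <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(tbl)
  tbl
}

validate_intervals <- function(tbl, allow_unstranded = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(tbl)))
  if (any(tbl$start < 0)) abort("interval start must be >= 0")
  if (any(tbl$end <= tbl$start)) abort("interval end must be > start")
  allowed <- if (allow_unstranded) c("+", "-", ".") else c("+", "-")
  if (!all(tbl$strand %in% allowed)) {
    abort(sprintf("strand must be one of: %s", paste(allowed, collapse = " ")))
  }
  invisible(tbl)
}

# tibble (0-based half-open) -> GRanges (1-based closed). The `*` strand is
# GRanges' spelling of unstranded.
as_granges <- function(tbl) {
  strand <- ifelse(tbl$strand == ".", "*", tbl$strand)
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

granges_to_tbl <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", ".", strand)
  )
}

# Genomic union of a set of intervals, strand-blind: tibble of maximal
# non-overlapping covered regions.
interval_union <- function(tbl) {
  gr <- as_granges(tbl)
  GenomicRanges::strand(gr) <- "*"
  granges_to_tbl(GenomicRanges::reduce(gr))
}
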