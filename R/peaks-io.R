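#' Build a peak table
#'
#' Peaks are tibbles with one row per peak: interval, summit (a single
#' 0-based position inside the interval), Poisson tail p-value, BH
#' q-value and fold enrichment at the summit.
#'
#' @param chrom,start,end,strand Peak interval, 0-based half-open.
#' @param summit Summit position, `start <= summit < end`.
#' @param pvalue,qvalue Probabilities in \[0, 1\].
#' @param fold_enrichment Non-negative IP/input enrichment at the summit.
#' @param name Optional peak names; autogenerated when omitted.
#' @return A tibble of class `hmerip_peaks`.
#' @export
peak_table <- function(chrom, start, end, summit, pvalue, qvalue,
                       fold_enrichment, strand = ".", name = NULL) {
  tbl <- tibble(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end),
    name = name %||% sprintf("peak_%d", seq_along(chrom)),
    strand = rep_len(as.character(strand), length(chrom)),
    summit = as.integer(summit), pvalue = as.numeric(pvalue),
    qvalue = as.numeric(qvalue),
    fold_enrichment = as.numeric(fold_enrichment)
  )
  validate_peaks(tbl)
  new_peak_tbl(tbl)
}

new_peak_tbl <- function(tbl) {
  class(tbl) <- unique(c("hmerip_peaks", class(tibble())))
  tbl
}

validate_peaks <- function(tbl) {
  validate_intervals(tbl)
  if (any(tbl$summit < tbl$start | tbl$summit >= tbl$end)) {
    abort("peak summit must lie inside the peak interval")
  }
  if (any(tbl$pvalue < 0 | tbl$pvalue > 1) ||
      any(tbl$qvalue < 0 | tbl$qvalue > 1)) {
    abort("p/q-values must be in [0, 1]")
  }
  if (any(tbl$fold_enrichment < 0)) abort("fold_enrichment must be >= 0")
  invisible(tbl)
}

bed_score <- function(qvalue) {
  as.integer(pmin(1000, round(-10 * log10(pmax(qvalue, 1e-100)))))
}

#' Write peaks to a BED6+ file
#'
#' Columns: chrom, start, end, name, score (`min(1000,
#' round(-10*log10(q)))`), strand, then summit, pvalue, qvalue and
#' fold_enrichment. Round-trips losslessly through [read_peaks()].
#'
#' @param peaks An `hmerip_peaks` tibble (see [peak_table()]).
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%s\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   bed_score(peaks$qvalue), peaks$strand, peaks$summit,
                   format(peaks$pvalue, digits = 17, trim = TRUE),
                   format(peaks$qvalue, digits = 17, trim = TRUE),
                   format(peaks$fold_enrichment, digits = 17, trim = TRUE))
  tryCatch(readr::write_lines(lines, path),
           error = function(e) abort(sprintf("cannot write '%s': %s", path,
                                             conditionMessage(e))))
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#'
#' @param path Path to a BED6+4 peak file.
#' @return An `hmerip_peaks` tibble.
#' @export
read_peaks <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand", "summit",
                                             "pvalue", "qvalue",
                                             "fold_enrichment"),
                         col_types = "ciiciciddd", progress = FALSE)
  tbl <- select(tbl, -"score")
  tbl$summit <- as.integer(tbl$summit)
  validate_peaks(tbl)
  new_peak_tbl(tbl)
}
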