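#' Construct a read set
#'
#' A read set holds the aligned fragment intervals of one sequencing
#' sample together with its metadata (condition, IP/input role,
#' replicate). `library_size` is always the number of fragments.
#'
#' @param reads Tibble of fragment intervals (`chrom`, `start`, `end`,
#'   `strand`); strand may be `"."` for unstranded libraries.
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"WT"`).
#' @param role `"IP"` or `"input"`.
#' @param replicate Replicate number (>= 1).
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, sample_id, condition, role = c("IP", "input"),
                     replicate = 1L) {
  role <- match.arg(role)
  reads <- as_tibble(reads)
  if (!"strand" %in% names(reads)) reads$strand <- "."
  if (nrow(reads) > 0) validate_intervals(reads)
  structure(
    list(sample_id = sample_id, condition = condition, role = role,
         replicate = as.integer(replicate), reads = reads,
         library_size = nrow(reads)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s [%s %s rep%d]: %d fragments\n", x$sample_id,
              x$condition, x$role, x$replicate, x$library_size))
  invisible(x)
}

#' Read aligned fragments from a BED or SAM file
#'
#' BED6 (or BED3) is the primary format; a minimal SAM reader is provided
#' behind the same contract (header lines skipped, FLAG 0x4 records
#' dropped, reference span from the CIGAR string). Zero-length records are
#' dropped with a logged count.
#'
#' @param path Path to a `.bed` or `.sam` file.
#' @param sample_id,condition,role,replicate Sample metadata, see
#'   [read_set()].
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @return A [read_set()].
#' @export
read_reads <- function(path, sample_id = basename(path), condition = "NA",
                       role = "IP", replicate = 1L, format = "auto") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  reads <- switch(format, bed = parse_bed_reads(path),
                  sam = parse_sam_reads(path),
                  abort(sprintf("unknown read format '%s'", format)))
  n_zero <- sum(reads$end <= reads$start)
  if (n_zero > 0) {
    inform(sprintf("[reads] %s: dropped %d zero-length record(s)", path,
                   n_zero))
    reads <- filter(reads, .data$end > .data$start)
  }
  read_set(reads, sample_id = sample_id, condition = condition, role = role,
           replicate = replicate)
}

parse_bed_reads <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  if (ncol(tbl) < 3) abort(sprintf("'%s' is not BED (fewer than 3 columns)",
                                   path))
  out <- tibble(chrom = as.character(tbl[[1]]),
                start = as.integer(tbl[[2]]), end = as.integer(tbl[[3]]),
                strand = if (ncol(tbl) >= 6) as.character(tbl[[6]]) else ".")
  if (any(is.na(out$start) | is.na(out$end)) || any(out$start < 0)) {
    abort(sprintf("negative or non-numeric coordinates in '%s'", path))
  }
  out
}

parse_sam_reads <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 11)
  flag <- as.integer(f[, 2])
  keep <- bitwAnd(flag, 4L) == 0L & f[, 3] != "*"
  n_drop <- sum(!keep)
  if (n_drop > 0) inform(sprintf("[reads] %s: dropped %d unmapped record(s)",
                                 path, n_drop))
  pos <- as.integer(f[keep, 4])
  width <- cigar_ref_width(f[keep, 6])
  tibble(chrom = f[keep, 3], start = pos - 1L, end = pos - 1L + width,
         strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"))
}

# reference-space width of a CIGAR: sum of M/D/N/=/X operation lengths
cigar_ref_width <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  map_int(ops, function(m) {
    if (nrow(m) == 0) return(0L)
    consume <- m[, 3] %in% c("M", "D", "N", "=", "X")
    as.integer(sum(as.integer(m[consume, 2])))
  })
}

#' Write a read set to BED6
#'
#' @param rs A [read_set()].
#' @param path Output path.
#' @export
write_reads <- function(rs, path) {
  r <- rs$reads
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", r$chrom, r$start, r$end,
                   paste0(rs$sample_id, "_", seq_len(nrow(r))), r$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Pool replicate read sets into a metasample
#'
#' Concatenates the mapped fragments of all replicates of one condition
#' and role; the metasample's library size is the sum of the inputs'.
#'
#' @param read_sets List of [read_set()] objects with identical condition
#'   and role.
#' @return A [read_set()] with replicate 0 (pooled).
#' @export
build_metasample <- function(read_sets) {
  if (length(read_sets) == 0) abort("no read sets supplied")
  conds <- unique(map_chr(read_sets, "condition"))
  roles <- unique(map_chr(read_sets, "role"))
  if (length(conds) != 1 || length(roles) != 1) {
    abort("metasample requires identical condition and role across inputs")
  }
  reads <- bind_rows(map(read_sets, "reads"))
  read_set(reads, sample_id = sprintf("%s_%s_meta", conds, roles),
           condition = conds, role = roles, replicate = 0L)
}
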