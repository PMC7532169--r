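#' Construct a transcriptome object
#'
#' A transcriptome bundles transcript models (span, strand, optional CDS)
#' with their exon structure and an interval index for overlap queries.
#' All coordinates are internal 0-based half-open.
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (`+`/`-` only) and optional
#'   `cds_start`, `cds_end` (NA when non-coding).
#' @param exons Tibble with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; exons of a transcript must be sorted, pairwise
#'   disjoint and tile the transcript span at its two ends.
#' @return An object of class `transcriptome`.
#' @export
transcriptome <- function(transcripts, exons) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_integer_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_integer_
  if (anyDuplicated(transcripts$transcript_id)) {
    abort("transcript_id values must be unique")
  }
  if (nrow(transcripts) > 0) {
    validate_intervals(transcripts, allow_unstranded = FALSE)
    validate_intervals(exons, allow_unstranded = FALSE)
    check_exon_structure(transcripts, exons)
  }
  idx <- if (nrow(transcripts) > 0) as_granges(transcripts) else
    GenomicRanges::GRanges()
  structure(
    list(transcripts = transcripts, exons = exons, index = idx),
    class = "transcriptome"
  )
}

check_exon_structure <- function(transcripts, exons) {
  ex <- dplyr::group_split(group_by(arrange(exons, .data$transcript_id,
                                            .data$start),
                                    .data$transcript_id))
  tx <- transcripts[match(
    map_chr(ex, ~ .x$transcript_id[1]), transcripts$transcript_id), ]
  for (i in seq_along(ex)) {
    e <- ex[[i]]
    t <- tx[i, ]
    if (is.na(t$transcript_id)) {
      abort(sprintf("exons reference unknown transcript '%s'",
                    e$transcript_id[1]))
    }
    if (length(unique(e$strand)) > 1 || any(e$strand != t$strand) ||
        any(e$chrom != t$chrom)) {
      abort(sprintf("transcript '%s' has exons with inconsistent strand/chrom",
                    t$transcript_id))
    }
    if (any(e$start[-1] < e$end[-nrow(e)])) {
      abort(sprintf("transcript '%s' has overlapping exons", t$transcript_id))
    }
    if (e$start[1] != t$start || e$end[nrow(e)] != t$end ||
        any(e$start < t$start) || any(e$end > t$end)) {
      abort(sprintf("exons of transcript '%s' do not fit its span",
                    t$transcript_id))
    }
    if (!is.na(t$cds_start) &&
        (t$cds_start < t$start || t$cds_end > t$end)) {
      abort(sprintf("CDS of transcript '%s' outside its span",
                    t$transcript_id))
    }
  }
  invisible(NULL)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' Read a transcriptome from a GTF file
#'
#' Ingests `exon` and optional `CDS` features, grouped by `transcript_id`.
#' GTF 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. Book-ended exons are merged.
#'
#' @param path Path to a GTF file.
#' @return A [transcriptome] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  body_lines <- prescan_gtf(path)
  gr <- if (body_lines == 0) GenomicRanges::GRanges()
        else rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) {
    warn(sprintf("GTF file '%s' contains no features", path))
    return(transcriptome(
      tibble(transcript_id = character(), gene_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character()),
      tibble(transcript_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character())
    ))
  }
  md <- S4Vectors::mcols(gr)
  feat <- tibble(
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = if ("gene_id" %in% names(md)) as.character(md$gene_id)
              else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  exons <- filter(feat, .data$type == "exon")
  if (nrow(exons) == 0) abort("GTF contains no exon features")
  exons <- merge_bookended(arrange(exons, .data$transcript_id, .data$start))
  declared <- filter(feat, .data$type == "transcript")
  if (nrow(declared) > 0) {
    chk <- left_join(exons,
                     select(declared, "transcript_id",
                            tx_start = "start", tx_end = "end"),
                     by = "transcript_id")
    bad <- filter(chk, !is.na(.data$tx_start) &
                    (.data$start < .data$tx_start | .data$end > .data$tx_end))
    if (nrow(bad) > 0) {
      abort(sprintf("exon outside declared span for transcript '%s'",
                    bad$transcript_id[1]))
    }
  }
  cds <- filter(feat, .data$type == "CDS")
  cds <- if (nrow(cds) == 0) {
    tibble(transcript_id = character(), cds_start = integer(),
           cds_end = integer())
  } else {
    summarise(group_by(cds, .data$transcript_id),
              cds_start = min(.data$start), cds_end = max(.data$end),
              .groups = "drop")
  }
  strands <- distinct(exons, .data$transcript_id, .data$strand)
  multi <- strands$transcript_id[duplicated(strands$transcript_id)]
  if (length(multi) > 0) {
    abort(sprintf("transcript '%s' has exons on both strands", multi[1]))
  }
  tx <- summarise(
    group_by(exons, .data$transcript_id),
    gene_id = .data$gene_id[1], chrom = .data$chrom[1],
    start = min(.data$start), end = max(.data$end),
    strand = .data$strand[1], .groups = "drop"
  )
  tx <- left_join(tx, cds, by = "transcript_id")
  transcriptome(tx, select(exons, "transcript_id", "chrom", "start",
                           "end", "strand"))
}

# cheap structural scan so a malformed line is reported by number before
# the real parser sees it
prescan_gtf <- function(path) {
  lines <- readr::read_lines(path)
  n_body <- 0L
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (l == "" || startsWith(l, "#")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      abort(sprintf("malformed GTF record at line %d of '%s'", i, path))
    }
    n_body <- n_body + 1L
  }
  n_body
}

merge_bookended <- function(exons) {
  out <- dplyr::group_modify(group_by(exons, .data$transcript_id),
    function(e, key) {
      keep <- logical(nrow(e))
      keep[1] <- TRUE
      j <- 1
      if (nrow(e) > 1) for (i in 2:nrow(e)) {
        if (e$start[i] <= e$end[j]) {
          e$end[j] <- max(e$end[j], e$end[i])
        } else {
          j <- i
          keep[i] <- TRUE
        }
      }
      e[keep, ]
    })
  ungroup(out)
}

#' Write a transcriptome to a GTF file
#'
#' Emits `transcript`, `exon` and (where present) `CDS` features with
#' 1-based inclusive coordinates. Round-trips exactly through [read_gtf()].
#'
#' @param txome A [transcriptome].
#' @param path Output path.
#' @export
write_gtf <- function(txome, path) {
  tx <- txome$transcripts
  ex <- txome$exons
  fmt <- function(chrom, src, type, start, end, strand, tid, gid) {
    sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      chrom, src, type, start + 1L, end, strand, gid, tid
    )
  }
  gid <- setNames(tx$gene_id, tx$transcript_id)
  lines <- c(
    fmt(tx$chrom, "hmeripr", "transcript", tx$start, tx$end, tx$strand,
        tx$transcript_id, tx$gene_id),
    fmt(ex$chrom, "hmeripr", "exon", ex$start, ex$end, ex$strand,
        ex$transcript_id, gid[ex$transcript_id])
  )
  coding <- filter(tx, !is.na(.data$cds_start))
  if (nrow(coding) > 0) {
    lines <- c(lines, fmt(coding$chrom, "hmeripr", "CDS", coding$cds_start,
                          coding$cds_end, coding$strand,
                          coding$transcript_id, coding$gene_id))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Transcripts overlapping a query interval
#'
#' Uses the transcriptome's interval index; a transcript matches when its
#' span overlaps the query by at least one base (strand-blind).
#'
#' @param txome A [transcriptome].
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return Tibble of matching transcript rows.
#' @export
transcripts_overlapping <- function(txome, chrom, start, end) {
  if (nrow(txome$transcripts) == 0) return(txome$transcripts)
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, txome$index, ignore.strand = TRUE)
  txome$transcripts[S4Vectors::subjectHits(hits), ]
}

#' Effective transcriptome size
#'
#' Total length of the genomic union of all transcript spans, exons and
#' introns included, with regions shared by several transcripts counted
#' only once. Used as the effective region size for the peak caller's
#' background rate.
#'
#' @param txome A [transcriptome].
#' @return Integer number of bases.
#' @export
effective_transcriptome_size <- function(txome) {
  if (nrow(txome$transcripts) == 0) abort("empty transcriptome")
  u <- interval_union(txome$transcripts)
  sum(u$end - u$start)
}
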