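#' Per-base genomic tracks
#'
#' Tracks hold one run-length-encoded numeric vector per chromosome
#' (`S4Vectors::Rle`), indexed 0-based internally. Two kinds exist:
#'
#' * **conservation** tracks: per-base scores in \[0, 1\]; bases without
#'   data are `NA` ("absent").
#' * **signal** tracks: per-base non-negative coverage; absent bases are
#'   0. A signal track also carries `total_reads` (the number of reads
#'   contributing, used for reads-per-1e7 scaling; `NA` when the source
#'   is an already-processed signal file) and `mapq_min` (the
#'   mapping-quality floor applied at import, `NA` when not applicable).
#'
#' @param values Named list (by chromosome) of numeric vectors or `Rle`.
#' @param kind `"signal"` or `"conservation"`.
#' @param total_reads Reads contributing to a signal track.
#' @param mapq_min Mapping-quality floor applied at import.
#' @return An object of class `signal_track` or `conservation_track`
#'   (both inherit from `genome_track`).
#' @export
genome_track <- function(values, kind = c("signal", "conservation"),
                         total_reads = NA_real_, mapq_min = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, function(v) {
    if (!methods::is(v, "Rle")) v <- S4Vectors::Rle(as.numeric(v))
    v
  })
  for (chrom in names(values)) {
    v <- S4Vectors::runValue(values[[chrom]])
    if (kind == "conservation") {
      bad <- !is.na(v) & (v < 0 | v > 1)
      if (any(bad)) stop("conservation scores outside [0,1] on ", chrom)
    } else {
      if (any(is.na(v)) || any(v < 0))
        stop("signal track must be non-negative and NA-free on ", chrom)
    }
  }
  structure(list(values = values,
                 chrom_lengths = vapply(values, length, numeric(1)),
                 total_reads = total_reads, mapq_min = mapq_min),
            class = c(paste0(kind, "_track"), "genome_track"))
}

track_kind <- function(track) {
  if (inherits(track, "conservation_track")) "conservation" else "signal"
}

#' @export
print.genome_track <- function(x, ...) {
  cat(sprintf("%s_track: %d chromosome(s), %.0f bases%s\n",
              track_kind(x), length(x$values), sum(x$chrom_lengths),
              if (is.finite(x$total_reads))
                sprintf(", %.0f reads", x$total_reads) else ""))
  invisible(x)
}

# Build an Rle from disjoint scored runs (0-based half-open), filling
# gaps with `fill`. Errors on overlap, naming the offending interval.
rle_from_runs <- function(starts, ends, scores, len, fill) {
  if (length(starts) == 0) return(S4Vectors::Rle(fill, len))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; scores <- scores[o]
  if (any(starts[-1] < ends[-length(ends)])) {
    i <- which(starts[-1] < ends[-length(ends)])[1]
    stop(sprintf("overlapping track intervals: [%d,%d) and [%d,%d)",
                 starts[i], ends[i], starts[i + 1], ends[i + 1]),
         call. = FALSE)
  }
  if (ends[length(ends)] > len) stop("track interval beyond chromosome end")
  gap_before <- starts - c(0, ends[-length(ends)])
  vals <- as.vector(rbind(fill, scores))
  lens <- as.vector(rbind(gap_before, ends - starts))
  tail_gap <- len - ends[length(ends)]
  if (tail_gap > 0) { vals <- c(vals, fill); lens <- c(lens, tail_gap) }
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' Read a per-base track from bedGraph or wiggle
#'
#' bedGraph intervals are 0-based half-open and expanded per base;
#' wiggle (fixedStep/variableStep) is 1-based per the UCSC convention
#' and converted at parse. Overlapping bedGraph intervals are an error.
#' Bases without data become `NA` in a conservation track and 0 in a
#' signal track.
#'
#' @param path File path (`.bg`/`.bedgraph` or `.wig`).
#' @param kind `"conservation"` or `"signal"`.
#' @param chrom_lengths Optional named vector of chromosome lengths; the
#'   maximum covered position per chromosome is used when omitted.
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @return A [genome_track()].
#' @export
read_track <- function(path, kind = c("conservation", "signal"),
                       chrom_lengths = NULL,
                       format = c("auto", "bedGraph", "wig")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  fill <- if (kind == "conservation") NA_real_ else 0
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!is.null(chrom_lengths)) chroms <- union(chroms, names(chrom_lengths))
  values <- lapply(stats::setNames(chroms, chroms), function(chrom) {
    sub <- gr[GenomicRanges::seqnames(gr) == chrom]
    starts <- GenomicRanges::start(sub) - 1
    ends <- GenomicRanges::end(sub)
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      chrom_lengths[[chrom]] else if (length(ends)) max(ends) else 0
    rle_from_runs(starts, ends, sub$score, len, fill)
  })
  genome_track(values, kind = kind)
}

#' Write a track as bedGraph
#'
#' Absent bases (`NA` scores for conservation, zero for signal) are not
#' written, so write-then-read round-trips to identical per-base values.
#'
#' @param track A [genome_track()].
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  runs <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    rv <- S4Vectors::runValue(v)
    rl <- S4Vectors::runLength(v)
    ends <- cumsum(rl)
    starts <- ends - rl
    keep <- if (track_kind(track) == "conservation") !is.na(rv) else rv != 0
    data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
               end = ends[keep], score = rv[keep],
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  gr <- GenomicRanges::GRanges(runs$chrom,
                               IRanges::IRanges(start = runs$start + 1,
                                                end = runs$end),
                               score = runs$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Import a signal track from read intervals (BED with mapping quality)
#'
#' Reads with mapping quality at or below `mapq_min` are discarded
#' ("uniquely aligned" filter). The per-base pileup is divided by the
#' mean read length so that a window sum estimates a read count,
#' commensurable with processed bedGraph signal.
#'
#' @param path BED file; column 5 (score) holds the mapping quality.
#' @param mapq_min Strict lower bound on mapping quality (default 10).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A `signal_track` with `total_reads` = number of reads kept.
#' @export
read_signal_from_reads <- function(path, mapq_min = 10, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  gr <- gr[!is.na(gr$score) & gr$score > mapq_min]
  if (!is.null(chrom_lengths)) {
    GenomicRanges::seqlengths(gr) <-
      chrom_lengths[GenomicRanges::seqlevels(gr)]
  }
  cov <- GenomicRanges::coverage(gr)
  rl <- if (length(gr)) mean(GenomicRanges::width(gr)) else 1
  values <- lapply(stats::setNames(names(cov), names(cov)),
                   function(chrom) cov[[chrom]] / rl)
  genome_track(values, kind = "signal", total_reads = length(gr),
               mapq_min = mapq_min)
}

#' Per-base values of a track window
#'
#' @param track A [genome_track()].
#' @param chrom Chromosome.
#' @param start,end 0-based half-open window (must lie on the chromosome).
#' @return Numeric vector of length `end - start`.
#' @export
track_window_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome ", chrom, " not in track")
  stopifnot(start >= 0, end <= length(v), start < end)
  as.numeric(S4Vectors::window(v, start + 1, end))
}

# Vectorised window sums on one chromosome (0-based half-open windows);
# windows must lie on the chromosome. NA (absent) contributes 0.
track_window_sums <- function(track, chrom, starts, ends) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome ", chrom, " not in track")
  stopifnot(all(starts >= 0), all(ends <= length(v)), all(starts < ends))
  vw <- IRanges::Views(v, start = starts + 1, end = ends)
  IRanges::viewSums(vw, na.rm = TRUE)
}

#' Sum of track values over a window
#'
#' Absent (`NA`) bases contribute 0.
#'
#' @inheritParams track_window_values
#' @return Scalar sum.
#' @export
track_window_sum <- function(track, chrom, start, end) {
  as.numeric(track_window_sums(track, chrom, start, end))
}
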