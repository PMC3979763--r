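#' Read ChIP-seq peak calls (BED-like, MACS dialect)
#'
#' Expects at least `chrom`, `start`, `end` (0-based half-open) columns;
#' peak name, a height column (MACS pileup-derived score, unitless) and
#' a summit column are configurable because peak callers differ. The
#' summit column may hold an offset from `start` (MACS convention) or an
#' absolute coordinate. Records whose summit falls outside
#' `[start, end)` are rejected with a warning.
#'
#' @param path Peak file path (tab-separated, no header; `#` comments
#'   and `track` lines are skipped).
#' @param height_column 1-based column index of the peak height
#'   (default 5, the BED score column).
#' @param summit_column 1-based column index of the summit (default 6);
#'   `NA` uses the interval midpoint.
#' @param summit_type `"offset"` (relative to `start`) or `"absolute"`.
#' @return Data frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit` (absolute, 0-based), `height`.
#' @export
read_peaks <- function(path, height_column = 5, summit_column = 6,
                       summit_type = c("offset", "absolute")) {
  summit_type <- match.arg(summit_type)
  empty <- data.frame(peak_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      summit = numeric(), height = numeric(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty)
  tab <- utils::read.table(text = lines, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("peak file needs at least 3 columns: ", path)
  n <- nrow(tab)
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("peak_", seq_len(n))
  height <- if (ncol(tab) >= height_column)
    as.numeric(tab[[height_column]]) else rep(NA_real_, n)
  summit <- if (!is.na(summit_column) && ncol(tab) >= summit_column) {
    s <- as.numeric(tab[[summit_column]])
    if (summit_type == "offset") start + s else s
  } else floor((start + end) / 2)
  keep <- summit >= start & summit < end
  if (any(!keep))
    warning(sum(!keep), " peak record(s) with summit outside [start,end) rejected")
  data.frame(peak_id = name, chrom = as.character(tab[[1]]),
             start = start, end = end, summit = summit, height = height,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Write peaks in the MACS-like dialect read by [read_peaks()]
#'
#' Columns: chrom, start, end, name, height, summit offset from start.
#'
#' @param peaks Data frame as returned by [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE,
                                        trim = TRUE),
                    format(peaks$end, scientific = FALSE, trim = TRUE),
                    peaks$peak_id, peaks$height,
                    format(peaks$summit - peaks$start, scientific = FALSE,
                           trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter peaks by minimum height
#'
#' Retains peaks with height at least `min_height` (inclusive), input
#' order preserved.
#'
#' @param peaks Peak data frame.
#' @param min_height Threshold (default 12).
#' @return Filtered data frame.
#' @export
filter_peaks <- function(peaks, min_height = 12) {
  peaks[!is.na(peaks$height) & peaks$height >= min_height, , drop = FALSE]
}
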