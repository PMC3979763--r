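#' Convert a 1-based inclusive interval to 0-based half-open
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention). GTF, refGene and wiggle inputs are 1-based inclusive and
#' are converted at parse time with this helper, so that a printed
#' interval `a-b` has length `b - a + 1`.
#'
#' @param start,end Numeric vectors, 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` (0-based half-open).
#' @examples
#' iv <- from_1based(93697292, 93698116)
#' iv$end - iv$start  # 825
#' @export
from_1based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' Create a genomic interval record
#'
#' @param chrom Chromosome name (non-empty).
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nzchar(chrom),
            start >= 0, start < end,
            strand %in% c("+", "-", "."))
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

# width of 0-based half-open intervals given as a two-column matrix
interval_widths <- function(m) m[, 2] - m[, 1]
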