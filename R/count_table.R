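#' Per-gene read-count table
#'
#' Holds the non-negative integer read counts per gene and sample plus
#' each sample's library size (total mapped reads, which may exceed the
#' column sum because reads also map outside gene models).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample labels).
#' @param library_size Named numeric vector, one entry per sample; must
#'   be at least the corresponding column sum.
#' @return A list of class `count_table` with fields `gene_ids`,
#'   `samples`, `counts`, `library_size`.
#' @export
count_table <- function(counts, library_size) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  library_size <- library_size[colnames(counts)]
  if (any(is.na(library_size)))
    stop("library_size must name every sample")
  if (any(library_size < colSums(counts)))
    stop("library_size below column sum for sample(s): ",
         paste(colnames(counts)[library_size < colSums(counts)],
               collapse = ", "))
  structure(list(gene_ids = rownames(counts), samples = colnames(counts),
                 counts = counts, library_size = library_size),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Read a count table from TSV
#'
#' First column `gene_id`, remaining columns one per sample. Library
#' sizes are carried in a leading comment line of the form
#' `# library_size: sample=value ...`; when absent, column sums are
#' used with a warning.
#'
#' @param path TSV path.
#' @return A [count_table()].
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  lib <- NULL
  if (grepl("^#\\s*library_size:", first)) {
    fields <- strsplit(sub("^#\\s*library_size:\\s*", "", first), "\\s+")[[1]]
    kv <- strsplit(fields, "=")
    lib <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                  numeric(1)),
                           vapply(kv, `[`, character(1), 1))
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (is.null(lib)) {
    warning("no library_size header in ", path, "; using column sums")
    lib <- colSums(m)
  }
  count_table(m, lib)
}

#' Write a count table as TSV (with library-size header line)
#'
#' @param ct A [count_table()].
#' @param path Output path.
#' @export
write_counts <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# library_size: ",
                    paste(sprintf("%s=%.0f", names(ct$library_size),
                                  ct$library_size), collapse = " ")), con)
  tab <- data.frame(gene_id = ct$gene_ids, ct$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
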