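#' Construct a union-exon gene model
#'
#' A gene model collapses all transcripts of a gene into one set of
#' non-overlapping, sorted exon intervals (the "union gene model" used
#' for read counting and RPKM), keeps the strand, and records every
#' distinct transcription start site so that downstream TSS-selection
#' rules can operate on the full list.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of 0-based half-open exon
#'   intervals (possibly overlapping; they are merged here).
#' @param tss_list Integer vector of 0-based TSS coordinates (one per
#'   distinct transcript 5' end). Derived from `exons` when `NULL`
#'   (single-transcript convenience).
#' @return A list of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons` (merged matrix), `tss_list`, `exon_length_bp`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, tss_list = NULL) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2,
            nrow(exons) >= 1, all(exons[, 1] < exons[, 2]))
  merged <- merge_intervals(exons)
  if (is.null(tss_list)) {
    tss_list <- if (strand == "+") min(merged[, 1]) else max(merged[, 2]) - 1
  }
  structure(list(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = merged,
    tss_list = sort(unique(as.numeric(tss_list))),
    exon_length_bp = sum(interval_widths(merged))
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%s %d exon(s), %d bp, %d TSS\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$exon_length_bp, length(x$tss_list)))
  invisible(x)
}

# merge possibly-overlapping 0-based half-open intervals (two-column
# matrix) into disjoint sorted intervals; adjacency is merged too
merge_intervals <- function(m) {
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1, end = m[, 2]))
  cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Read gene annotation into union-exon gene models
#'
#' Accepts either an Ensembl-dialect GTF (exon features carrying
#' `gene_id`/`transcript_id` attributes) or a refGene-style tab table
#' (columns `name`, `chrom`, `strand`, `txStart`, `txEnd`, `exonStarts`,
#' `exonEnds`, `name2`). All transcripts of a gene are merged into union
#' exons; every distinct transcript 5' end is kept in `tss_list`. GTF
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; refGene tables are already 0-based half-open.
#'
#' A gene whose transcripts sit on more than one chromosome is skipped
#' with a warning.
#'
#' @param path File path.
#' @param format `"gtf"` or `"refgene"`; guessed from the extension when
#'   `"auto"` (`.gtf` vs anything else).
#' @return Named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "refgene")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "refgene"
  }
  if (format == "gtf") read_annotation_gtf(path) else read_annotation_refgene(path)
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(list())
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    tx_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  build_models_from_exons(df)
}

read_annotation_refgene <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop("refGene parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("name", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds", "name2")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("refGene table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    es <- as.numeric(strsplit(tab$exonStarts[i], ",")[[1]])
    ee <- as.numeric(strsplit(tab$exonEnds[i], ",")[[1]])
    if (length(es) != length(ee) || any(is.na(es)) || any(is.na(ee)))
      stop("refGene parse error in ", path, " at line ", i + 1,
           ": malformed exonStarts/exonEnds", call. = FALSE)
    data.frame(gene_id = tab$name2[i], tx_id = tab$name[i],
               chrom = tab$chrom[i], strand = tab$strand[i],
               start = es, end = ee, stringsAsFactors = FALSE)
  })
  build_models_from_exons(do.call(rbind, rows))
}

# df: gene_id, tx_id, chrom, strand, start, end (0-based half-open)
build_models_from_exons <- function(df) {
  models <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1) {
      warning("gene ", g, " has transcripts on multiple chromosomes; skipped")
      next
    }
    strand <- sub$strand[1]
    # TSS per transcript: 5'-most position respecting strand
    tss <- vapply(split(sub, sub$tx_id), function(tx) {
      if (strand == "+") min(tx$start) else max(tx$end) - 1
    }, numeric(1))
    models[[g]] <- gene_model(g, sub$chrom[1], strand,
                              cbind(sub$start, sub$end), tss_list = tss)
  }
  models
}

#' Write gene models (and optional transcript structures) as GTF
#'
#' Used by the simulator and for interchange. When per-transcript exon
#' structures are supplied they are written verbatim (one `exon` feature
#' per transcript exon); otherwise each union exon is written as a
#' single-transcript gene.
#'
#' @param transcripts Data frame with columns `gene_id`, `tx_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open exon records).
#' @param path Output path.
#' @export
write_annotation_gtf <- function(transcripts, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start + 1,
                              end = transcripts$end),
    strand = transcripts$strand)
  gr$type <- "exon"
  gr$source <- "silencescan"
  gr$gene_id <- transcripts$gene_id
  gr$transcript_id <- transcripts$tx_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Transcription start sites of a set of gene models
#'
#' @param models Named list of [gene_model()] objects.
#' @return Data frame with `gene_id`, `chrom`, `strand`, `tss` (one row
#'   per TSS; multi-TSS genes contribute several rows).
#' @export
tss_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               tss = m$tss_list, stringsAsFactors = FALSE)
  }))
}
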