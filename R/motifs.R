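#' Reverse complement of a DNA string
#'
#' Plain-character implementation (A/C/G/T/N, case preserved); cheap
#' enough to call once per candidate window in palindrome scans.
#'
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

#' EMSA probe sequences for the Twist2 and Igf2 ZBED6 binding sites
#'
#' Double-stranded oligonucleotide probes used to assay sequence-specific
#' ZBED6 binding in vitro: the wild-type Twist2 upstream site, its
#' single-point mutant (G-to-A in the GCTCG core), the core deletion,
#' the variant engineered to carry the Igf2-type CCTAGG palindrome, and
#' the validated Igf2 intron-3 site. ZBED6 binds WT, PAL and Igf2 but
#' not MUT or DEL; only Igf2 and PAL carry the palindrome.
#'
#' @return Named character vector
#'   (`twist2_wt`, `twist2_mut`, `twist2_del`, `twist2_pal`, `igf2_wt`).
#' @export
zbed6_probes <- function() {
  c(twist2_wt  = "TGGGCGCTCCCGCAGAGGCTCGCTGTGATGCCTAAGCT",
    twist2_mut = "TGGGCGCTCCCGCAGAGGCTCACTGTGATGCCTAAGCT",
    twist2_del = "TGGGCGCTCCCGCAGAGCTGTGATGCCTAAGCT",
    twist2_pal = "TGGGCGCTCCCGCCTAGGCTCGCTGTGATGCCTAAGCT",
    igf2_wt    = "CTTCGCCTAGGCTCGCAGCGCGGGAGCGA")
}

#' Scan for the core binding motif near peak summits
#'
#' Reports every occurrence of the core motif (default `GCTCG`, the
#' ZBED6 consensus; its reverse complement is also searched unless
#' `both_strands = FALSE`) whose start lies within `flank` bp of the
#' peak summit, boundaries inclusive. Each hit records its distance to
#' the summit and whether the extended 7-mer (`GGCTCGC`) covers it.
#'
#' @param peaks Peak data frame ([read_peaks()] columns).
#' @param genome Named `Biostrings::DNAStringSet`, plain named character
#'   vector of chromosome sequences, or FASTA path.
#' @param core Core motif (default `"GCTCG"`).
#' @param flank Maximum |motif start - summit| in bp (default 100).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @param extended Extended match pattern containing the core (default
#'   `"GGCTCGC"`); set `NULL` to skip.
#' @return Data frame of hits: `peak_id`, `chrom`, `start` (0-based
#'   start of the matched core on the forward strand), `strand`,
#'   `matched_seq` (equal to `core` on `+`, its reverse complement on
#'   `-`), `distance_to_summit`, `extended_match`.
#' @export
scan_motif <- function(peaks, genome, core = "GCTCG", flank = 100,
                       both_strands = TRUE, extended = "GGCTCGC") {
  genome <- as_genome(genome)
  k <- nchar(core)
  pats <- list(`+` = core)
  if (both_strands) {
    rc <- revcomp(core)
    if (!identical(rc, core)) pats[["-"]] <- rc
  }
  ext_off <- if (!is.null(extended)) {
    o <- regexpr(core, extended, fixed = TRUE)[1]
    if (o < 1) stop("extended pattern must contain the core")
    o - 1
  } else NA_integer_
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    seq <- genome[[chrom]]
    if (is.null(seq)) stop("chromosome ", chrom, " absent from genome")
    clen <- length(seq)
    lo <- max(0, peaks$summit[i] - flank)          # candidate start range
    hi <- min(clen - k, peaks$summit[i] + flank)
    if (lo > hi) next
    win <- as.character(Biostrings::subseq(seq, lo + 1, hi + k))
    for (strand in names(pats)) {
      starts <- lo + as.integer(
        Biostrings::start(Biostrings::matchPattern(pats[[strand]],
                                                   win))) - 1
      for (s in starts) {
        ext <- if (is.na(ext_off)) NA else {
          es <- if (strand == "+") s - ext_off else
            s - (nchar(extended) - k - ext_off)
          ee <- es + nchar(extended)
          if (es >= 0 && ee <= clen) {
            ctx <- as.character(Biostrings::subseq(seq, es + 1, ee))
            if (strand == "-") ctx <- revcomp(ctx)
            identical(ctx, extended)
          } else FALSE
        }
        hits[[length(hits) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], chrom = chrom, start = s,
          strand = strand, matched_seq = pats[[strand]],
          distance_to_summit = s - peaks$summit[i],
          extended_match = ext, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(peak_id = character(), chrom = character(),
                      start = numeric(), strand = character(),
                      matched_seq = character(),
                      distance_to_summit = numeric(),
                      extended_match = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$peak_id, out$start), , drop = FALSE]
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  # strip FASTA description after first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Score motif hits for evolutionary conservation
#'
#' Adds the arithmetic mean of the per-base conservation scores over the
#' matched core bases (`mean_conservation`; absent bases contribute 0,
#' so unscored regions never inflate the mean) and the `conserved` flag,
#' true when the mean is strictly greater than `threshold`.
#'
#' @param hits Data frame from [scan_motif()].
#' @param track A conservation [genome_track()].
#' @param threshold Strict lower bound for calling a hit conserved
#'   (default 0.90).
#' @return `hits` with `mean_conservation` and `conserved` appended.
#' @export
conservation_score <- function(hits, track, threshold = 0.90) {
  k <- nchar(hits$matched_seq)
  mc <- vapply(seq_len(nrow(hits)), function(i) {
    v <- track$values[[hits$chrom[i]]]
    if (is.null(v)) stop("chromosome ", hits$chrom[i], " absent from track")
    s <- hits$start[i]
    vals <- as.numeric(S4Vectors::window(v, s + 1, s + k[i]))
    sum(vals, na.rm = TRUE) / k[i]
  }, numeric(1))
  hits$mean_conservation <- if (nrow(hits)) mc else numeric(0)
  hits$conserved <- hits$mean_conservation > threshold
  hits
}

#' Detect a reverse-complement palindrome overlapping a motif hit
#'
#' Searches, within `max_span` bp of the matched core, for a window of
#' even length between `min_len` and `max_span` that equals its own
#' reverse complement and overlaps the core by at least one base (the
#' Igf2-type CCTAGG structure partially overlapping the GCTCG
#' consensus). Odd-length windows can never equal their reverse
#' complement and are not considered. Returns the longest qualifying
#' window, leftmost on ties.
#'
#' @param sequence Character scalar, the sequence context.
#' @param core_start,core_end 0-based half-open position of the matched
#'   core within `sequence`.
#' @param min_len Minimum palindrome length (default 6).
#' @param max_span Maximum palindrome length, and maximum distance from
#'   the core within which windows are considered (default 20).
#' @return List with `found` (flag; `NA` with a warning when no
#'   palindrome was found but the flanking context is too short to have
#'   fit even a minimum-length overlapping window, i.e. under
#'   `min_len - 1` bp on a side), `start`, `end` (0-based half-open) and
#'   `seq` of the located palindrome (`NA`s when none). A short probe
#'   with at least `min_len - 1` bp of context on both sides still gets
#'   a definite answer.
#' @export
detect_palindrome <- function(sequence, core_start, core_end,
                              min_len = 6, max_span = 20) {
  n <- nchar(sequence)
  stopifnot(core_start >= 0, core_end <= n, core_start < core_end)
  lo <- max(0, core_start - max_span)
  hi <- min(n, core_end + max_span)
  truncated <- core_start < (min_len - 1) || (n - core_end) < (min_len - 1)
  best <- NULL
  lens <- seq(min_len + (min_len %% 2), max_span, by = 2)
  for (L in rev(lens)) {                      # longest first
    starts <- seq.int(lo, hi - L)
    starts <- starts[starts + L > core_start & starts < core_end]
    if (length(starts) == 0) next
    for (s in starts) {                       # leftmost first
      w <- substr(sequence, s + 1, s + L)
      if (identical(w, revcomp(w))) { best <- c(s, s + L); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    if (truncated) {
      warning("context shorter than max_span; palindrome flag undefined")
      return(list(found = NA, start = NA_real_, end = NA_real_,
                  seq = NA_character_))
    }
    return(list(found = FALSE, start = NA_real_, end = NA_real_,
                seq = NA_character_))
  }
  list(found = TRUE, start = best[1], end = best[2],
       seq = substr(sequence, best[1] + 1, best[2]))
}

#' Annotate motif hits with the palindrome flag
#'
#' Extracts genomic context around each hit and applies
#' [detect_palindrome()]. Hits too close to a chromosome edge get an
#' `NA` flag with a warning.
#'
#' @param hits Data frame from [scan_motif()].
#' @param genome Genome as in [scan_motif()].
#' @inheritParams detect_palindrome
#' @return `hits` with logical `palindrome` and `palindrome_seq` columns.
#' @export
annotate_palindromes <- function(hits, genome, min_len = 6, max_span = 20) {
  genome <- as_genome(genome)
  res <- lapply(seq_len(nrow(hits)), function(i) {
    seq <- genome[[hits$chrom[i]]]
    k <- nchar(hits$matched_seq[i])
    lo <- max(0, hits$start[i] - max_span)
    hi <- min(length(seq), hits$start[i] + k + max_span)
    ctx <- as.character(Biostrings::subseq(seq, lo + 1, hi))
    detect_palindrome(ctx, hits$start[i] - lo, hits$start[i] + k - lo,
                      min_len = min_len, max_span = max_span)
  })
  hits$palindrome <- if (nrow(hits))
    vapply(res, function(r) r$found, logical(1)) else logical(0)
  hits$palindrome_seq <- if (nrow(hits))
    vapply(res, function(r) r$seq, character(1)) else character(0)
  hits
}

#' Associate peaks with genes by summit-to-TSS distance
#'
#' A peak is associated with a gene when the minimum over the gene's
#' TSS list of |summit - TSS| is at most `window_bp` (inclusive). A peak
#' may associate with several genes and vice versa.
#'
#' @param peaks Peak data frame.
#' @param models Named list of [gene_model()] objects.
#' @param window_bp Association window (default 5000; the 10-kb variant
#'   is `window_bp = 10000`).
#' @return Data frame `gene_id`, `peak_id`, `distance` (min over TSS),
#'   with `attr(, "window_bp")` recording the window used.
#' @export
associate_peaks_to_genes <- function(peaks, models, window_bp = 5000) {
  tss <- tss_table(models)
  out <- data.frame(gene_id = character(), peak_id = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(peaks) > 0 && !is.null(tss) && nrow(tss) > 0) {
    tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                     IRanges::IRanges(tss$tss + 1,
                                                      tss$tss + 1))
    pk_gr <- GenomicRanges::GRanges(
      peaks$chrom,
      IRanges::IRanges(pmax(0, peaks$summit - window_bp) + 1,
                       peaks$summit + window_bp + 1))
    ov <- GenomicRanges::findOverlaps(pk_gr, tss_gr)
    if (length(ov) > 0) {
      pi <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
      d <- abs(peaks$summit[pi] - tss$tss[ti])
      pair <- data.frame(gene_id = tss$gene_id[ti],
                         peak_id = peaks$peak_id[pi], distance = d,
                         stringsAsFactors = FALSE)
      # min distance over a gene's TSS list for each gene-peak pair
      key <- paste(pair$gene_id, pair$peak_id, sep = "\r")
      out <- pair[order(key, pair$distance), , drop = FALSE]
      out <- out[!duplicated(paste(out$gene_id, out$peak_id, sep = "\r")),
                 , drop = FALSE]
      out <- out[out$distance <= window_bp, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "window_bp") <- window_bp
  out
}
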