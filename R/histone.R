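#' Average signal footprint around anchor coordinates
#'
#' Sums per-base signal in fixed-width bins tiling
#' `[-half_window, half_window)` around each anchor and averages over
#' anchors. Minus-strand anchors are mirrored so that positive offsets
#' always point downstream. Anchors closer than `half_window` to a
#' chromosome edge (or on a chromosome absent from the track) are
#' dropped with a warning. Signal is scaled to reads-per-1e7 when the
#' track knows its `total_reads`.
#'
#' @param anchors Data frame with `chrom`, `pos` (0-based), `strand`
#'   (`"+"`/`"-"`; anything else treated as `"+"`).
#' @param track A signal [genome_track()].
#' @param half_window Half window in bp (default 1750, i.e. a 3.5-kb
#'   window).
#' @param bin Bin width in bp (default 50); must divide the window.
#' @param scale Apply the reads-per-1e7 factor (default TRUE).
#' @return List of class `footprint_profile`: `offsets` (bin left edges
#'   relative to the anchor), `mean_signal` (per-bin mean over anchors
#'   of the summed signal), `anchor_count`, `bin`, `half_window`,
#'   `scale_factor`.
#' @export
footprint <- function(anchors, track, half_window = 1750, bin = 50,
                      scale = TRUE) {
  stopifnot(nrow(anchors) >= 1, (2 * half_window) %% bin == 0)
  n_bins <- 2 * half_window / bin
  acc <- numeric(n_bins)
  kept <- 0
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]; pos <- anchors$pos[i]
    clen <- track$chrom_lengths[chrom]
    if (is.na(clen) || pos - half_window < 0 || pos + half_window > clen)
      next
    vals <- track_window_values(track, chrom, pos - half_window,
                                pos + half_window)
    if (identical(anchors$strand[i], "-")) vals <- rev(vals)
    acc <- acc + colSums(matrix(vals, nrow = bin))
    kept <- kept + 1
  }
  if (kept == 0) stop("all anchors dropped (chromosome edge or missing)")
  if (kept < nrow(anchors))
    warning(nrow(anchors) - kept, " anchor(s) dropped near chromosome edge")
  sf <- if (scale && is.finite(track$total_reads) && track$total_reads > 0)
    1e7 / track$total_reads else 1
  structure(list(offsets = seq(-half_window, half_window - bin, by = bin),
                 mean_signal = acc / kept * sf, anchor_count = kept,
                 bin = bin, half_window = half_window, scale_factor = sf),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat(sprintf("footprint_profile: %d anchors, %d bins of %d bp (+/- %d bp)\n",
              x$anchor_count, length(x$offsets), x$bin, x$half_window))
  invisible(x)
}

# strand-aware downstream window [tss, tss+window) on the coding strand,
# clipped to the chromosome; returns c(start, end), 0-based half-open
downstream_window <- function(tss, strand, window, chrom_len) {
  if (strand == "-") c(max(0, tss + 1 - window), tss + 1)
  else c(tss, min(chrom_len, tss + window))
}

#' Choose one TSS per gene by reference-track signal
#'
#' For multi-TSS genes, returns the TSS whose strand-aware downstream
#' window `[TSS, TSS + window)` has the highest summed signal in the
#' reference track (the promoter-mark control sample, e.g. H3K4me3);
#' single-TSS genes return theirs unchanged. Ties break to the smallest
#' genomic coordinate.
#'
#' @param models Named list of [gene_model()] objects.
#' @param reference_track Signal [genome_track()].
#' @param window Downstream window in bp (default 2000).
#' @return Named numeric vector of chosen TSS per gene.
#' @export
select_tss <- function(models, reference_track, window = 2000) {
  vapply(models, function(m) {
    tss <- m$tss_list
    if (length(tss) == 1) return(tss)
    clen <- reference_track$chrom_lengths[m$chrom]
    if (is.na(clen)) stop("chromosome ", m$chrom, " absent from track")
    cnt <- vapply(tss, function(t) {
      w <- downstream_window(t, m$strand, window, clen)
      if (w[1] >= w[2]) 0 else
        track_window_sum(reference_track, m$chrom, w[1], w[2])
    }, numeric(1))
    tss[order(-cnt, tss)][1]
  }, numeric(1))
}

#' Downstream-window counts and silenced/control ratios per gene
#'
#' Sums signal over the 2-kb (by default) window downstream of each
#' gene's chosen TSS in the silenced and control tracks of one histone
#' mark, and forms the per-gene ratio silenced/control normalised by a
#' global factor so that the non-DE gene set is centred at unity:
#' `ratio_g = (count_sil_g / count_ctl_g) *
#' (sum_nonDE count_ctl / sum_nonDE count_sil)`. Genes with a zero
#' control count get an `NA` ratio and are flagged.
#'
#' @param models Named list of [gene_model()] objects.
#' @param silenced,control Signal [genome_track()]s for one mark.
#' @param chosen_tss Named vector from [select_tss()]; defaults to each
#'   gene's single/first TSS when omitted.
#' @param window Downstream window in bp (default 2000).
#' @param non_de_genes Character vector of non-DE gene ids used for the
#'   normalisation factor.
#' @return Data frame `gene_id`, `chosen_tss`, `count_silenced`,
#'   `count_control`, `ratio`, `flagged`; the factor is in
#'   `attr(, "norm_factor")`.
#' @export
tss_window_counts <- function(models, silenced, control,
                              chosen_tss = NULL, window = 2000,
                              non_de_genes) {
  if (is.null(chosen_tss))
    chosen_tss <- vapply(models, function(m) m$tss_list[1], numeric(1))
  ids <- names(models)
  stopifnot(all(ids %in% names(chosen_tss)))
  cs <- cc <- rep(NA_real_, length(ids))
  for (j in seq_along(ids)) {
    m <- models[[j]]
    clen <- control$chrom_lengths[m$chrom]
    w <- downstream_window(chosen_tss[[m$gene_id]], m$strand, window, clen)
    if (w[1] >= w[2]) { cs[j] <- 0; cc[j] <- 0; next }
    cs[j] <- track_window_sum(silenced, m$chrom, w[1], w[2])
    cc[j] <- track_window_sum(control, m$chrom, w[1], w[2])
  }
  nd <- ids %in% non_de_genes
  if (!any(nd)) stop("no non-DE genes available for normalisation")
  if (sum(cs[nd]) == 0 || sum(cc[nd]) == 0)
    stop("zero total non-DE signal; cannot normalise")
  f <- sum(cc[nd]) / sum(cs[nd])
  ratio <- ifelse(cc > 0, cs / cc * f, NA_real_)
  out <- data.frame(gene_id = ids, chosen_tss = chosen_tss[ids],
                    count_silenced = cs, count_control = cc,
                    ratio = ratio, flagged = cc == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "norm_factor") <- f
  out
}

#' Top genes by normalised histone fold change
#'
#' Ranks genes by the normalised silenced/control ratio, descending,
#' ties broken by gene id (lexicographic), and returns the top `k`
#' (e.g. for export to an external GO-enrichment tool with the expressed
#' gene set as background). Genes with `NA` ratios are ineligible.
#'
#' @param gene_window_counts [tss_window_counts()] result.
#' @param k Number of genes (default 300).
#' @return Character vector of gene ids, length `min(k, eligible)`
#'   (with a warning when fewer than `k` are eligible).
#' @export
rank_by_fold_change <- function(gene_window_counts, k = 300) {
  g <- gene_window_counts[is.finite(gene_window_counts$ratio), ,
                          drop = FALSE]
  g <- g[order(-g$ratio, g$gene_id), , drop = FALSE]
  if (nrow(g) < k)
    warning("only ", nrow(g), " eligible genes for top-", k, " ranking")
  utils::head(g$gene_id, k)
}

#' Split peak anchors by the response of their associated genes
#'
#' Peaks associated (within the map's TSS window) with genes showing at
#' least `threshold`-fold up-regulation form the up anchor set; at least
#' `threshold`-fold down-regulation the down set (inclusive bounds).
#' The summits serve as anchors for footprint comparison.
#'
#' @param fc_table Data frame with `gene_id` and `M` (log2 fold change,
#'   silenced over control).
#' @param gene_peak_map [associate_peaks_to_genes()] result.
#' @param peaks Peak data frame (for summit coordinates).
#' @param threshold Fold-change threshold on the linear scale
#'   (default 2).
#' @return List of two anchor data frames (`up`, `down`) with `chrom`,
#'   `pos` (summit), `strand` (`"+"`; peaks are unstranded).
#' @export
group_targets_by_response <- function(fc_table, gene_peak_map, peaks,
                                      threshold = 2) {
  lfc <- log2(threshold)
  pick <- function(ids) {
    pk <- peaks[peaks$peak_id %in%
                  gene_peak_map$peak_id[gene_peak_map$gene_id %in% ids], ,
                drop = FALSE]
    data.frame(chrom = pk$chrom, pos = pk$summit,
               strand = rep("+", nrow(pk)), stringsAsFactors = FALSE)
  }
  list(up = pick(fc_table$gene_id[!is.na(fc_table$M) & fc_table$M >= lfc]),
       down = pick(fc_table$gene_id[!is.na(fc_table$M) &
                                      fc_table$M <= -lfc]))
}
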