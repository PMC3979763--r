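#' Gene expression in RPKM over union-exon gene models
#'
#' RPKM = reads per kilobase of gene model per million mapped reads:
#' `count / (exon_length_bp/1000) / (library_size/1e6)`. The library
#' size is the total mapped reads supplied with the count table, not the
#' column sum, since reads mapping outside gene models still count
#' toward sequencing depth.
#'
#' Genes present in the count table but lacking a gene model are
#' excluded with a warning.
#'
#' @param counts A [count_table()].
#' @param models Named list of [gene_model()] objects.
#' @return A data frame of class `expression_table`: `gene_id`,
#'   `exon_length_bp`, one RPKM column per sample.
#' @export
rpkm <- function(counts, models) {
  have <- counts$gene_ids %in% names(models)
  if (any(!have))
    warning(sum(!have), " gene(s) without a model excluded from RPKM")
  ids <- counts$gene_ids[have]
  len <- vapply(models[ids], `[[`, numeric(1), "exon_length_bp")
  if (any(len <= 0)) stop("gene model with non-positive exon length")
  m <- counts$counts[ids, , drop = FALSE]
  r <- sweep(m / (len / 1000), 2, counts$library_size / 1e6, "/")
  out <- data.frame(gene_id = ids, exon_length_bp = len, r,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "samples") <- counts$samples
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Flag expressed genes by an RPKM detection threshold
#'
#' A gene is detected when its RPKM reaches `threshold` (inclusive) in
#' at least one sample.
#'
#' @param expr An `expression_table` from [rpkm()].
#' @param threshold Detection threshold (default 1 RPKM).
#' @return The table with a logical `detected` column appended.
#' @export
detect_expressed <- function(expr, threshold = 1) {
  samples <- attr(expr, "samples")
  stopifnot(length(samples) >= 1)
  m <- as.matrix(expr[, samples, drop = FALSE])
  expr$detected <- apply(m, 1, max) >= threshold
  expr
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`; the fold change of the target
#' transcript in treated relative to control cells is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated Cycle thresholds in the
#'   treated condition for the target and reference gene.
#' @param ct_target_control,ct_ref_control Same for the control.
#' @return Fold change (vectorised).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be finite and positive")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
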