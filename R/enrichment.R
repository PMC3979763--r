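#' Build the DE-versus-binding-site 2x2 contingency table
#'
#' Columns are the selected DE genes (all, up only, or down only) and
#' the expressed non-DE genes; rows are genes with at least one
#' associated peak versus none. The universe is the caller's filtered
#' expressed gene set (e.g. detected genes present in the annotation
#' after removing small non-coding RNAs); genes outside it are ignored.
#' Non-DE genes are universe genes not called DE in either direction,
#' regardless of the `direction` selection.
#'
#' @param de_calls [call_de()] result.
#' @param gene_peak_map [associate_peaks_to_genes()] result.
#' @param universe Character vector of gene ids.
#' @param direction `"all"`, `"up"` or `"down"`.
#' @return 2x2 integer matrix of class `contingency_2x2`, rows
#'   `with_site`/`no_site`, columns `de`/`non_de`.
#' @export
build_contingency <- function(de_calls, gene_peak_map, universe,
                              direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  if (length(universe) == 0) stop("empty gene universe")
  de_all <- de_calls$gene_id[de_calls$status %in% c("up", "down")]
  de_sel <- if (direction == "all") de_all else
    de_calls$gene_id[de_calls$status == direction]
  de_sel <- intersect(de_sel, universe)
  non_de <- setdiff(universe, de_all)
  with_site <- unique(gene_peak_map$gene_id)
  m <- matrix(c(sum(de_sel %in% with_site),
                sum(!(de_sel %in% with_site)),
                sum(non_de %in% with_site),
                sum(!(non_de %in% with_site))),
              nrow = 2,
              dimnames = list(c("with_site", "no_site"),
                              c("de", "non_de")))
  structure(m, class = c("contingency_2x2", class(m)),
            direction = direction)
}

as_table_2x2 <- function(table) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2), all(m >= 0))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' `chi2 = sum (O - E)^2 / E` with expectations from the margins,
#' df = 1, two-tailed p from the upper chi-square tail. No continuity
#' correction by default (on the large-count tables this pipeline
#' produces, corrected and uncorrected p agree to the reported
#' precision).
#'
#' @param table 2x2 matrix (e.g. from [build_contingency()]).
#' @param continuity Apply the Yates correction (default FALSE).
#' @return List with `table`, `proportions` (with-site share per
#'   column), `chi2`, `df`, `p_two_tailed`, `odds_ratio` (= ad/bc).
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  m <- as_table_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in contingency table")
  ht <- stats::chisq.test(m, correct = continuity)
  if (any(ht$expected <= 0)) stop("non-positive expected cell")
  list(table = m,
       proportions = m[1, ] / colSums(m),
       chi2 = unname(ht$statistic), df = 1,
       p_two_tailed = ht$p.value,
       odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Default method sums hypergeometric probabilities of all tables (with
#' the observed margins) no more probable than the observed one; the
#' alternative `"doubling"` method doubles the smaller one-sided tail
#' (capped at 1).
#'
#' @param table 2x2 matrix.
#' @param method `"point"` (point-probability summation) or
#'   `"doubling"`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table, method = c("point", "doubling")) {
  method <- match.arg(method)
  m <- as_table_2x2(table)
  if (method == "point") return(stats::fisher.test(m)$p.value)
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lower <- stats::phyper(a, c1, n - c1, r1)
  upper <- stats::phyper(a - 1, c1, n - c1, r1, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney U test
#'
#' U with midranks for ties; the p-value is exact (by enumeration) when
#' both samples are tie-free and the smaller has at most `exact_max`
#' values, otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used (the correction roughly
#' quarters the worst-case error against the exact distribution at
#' small n).
#'
#' @param sample_a,sample_b Numeric vectors (each non-empty).
#' @param exact_max Largest min(n_a, n_b) for which the exact
#'   distribution is used (default 8).
#' @return List with `U` (for `sample_a`), `p_two_tailed`, `method`.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_max = 8) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  na <- length(sample_a)
  r <- rank(c(sample_a, sample_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(sample_a, sample_b)))
  use_exact <- !ties && min(na, length(sample_b)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = use_exact,
                       correct = TRUE))
  list(U = unname(U), p_two_tailed = min(1, ht$p.value),
       method = if (use_exact) "exact" else "normal_approx")
}
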