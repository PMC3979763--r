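#' MA-plot random-sampling differential-expression test
#'
#' Tests, per gene, whether a count `c1` out of `n1` library reads in
#' the silenced sample and `c2` out of `n2` in the control are
#' consistent with a common underlying expression proportion, under the
#' random-sampling (binomial) model. With `X = log2 c1`, `Y = log2 c2`,
#' `M = X - Y` and `A = (X + Y)/2`, the delta method gives
#' `X ~ N(log2(n1 p), (1 - p) / (n1 p ln^2 2))` (likewise `Y`), and
#' conditioning the resulting bivariate normal on `A = a` yields
#'
#' \deqn{E(M|A=a) = (\mu_X-\mu_Y) +
#'   2\frac{\sigma_X^2-\sigma_Y^2}{\sigma_X^2+\sigma_Y^2}
#'   \left(a - \frac{\mu_X+\mu_Y}{2}\right), \quad
#'   Var(M|A) = \frac{4\sigma_X^2\sigma_Y^2}{\sigma_X^2+\sigma_Y^2}.}
#'
#' The standardised statistic `z = (M - E(M|A)) / sqrt(Var(M|A))` gets a
#' two-sided normal p-value (no continuity correction).
#'
#' The unknown null proportion `p` is estimated, by default, from the
#' observed A-value itself: `p_hat = 2^A / sqrt(n1 n2)` (the geometric
#' mean of the two per-sample proportions), which is the self-consistent
#' choice for a statistic whose distribution is taken conditional on A
#' and tracks the exact conditional binomial test closely.
#' `phat = "pooled"` uses `(c1 + c2) / (n1 + n2)` instead.
#'
#' Zero handling: when both counts are 0 the gene is untested (`NA`
#' statistics); when exactly one is 0, 0.5 is substituted before logs
#' and the gene is flagged (`zero_substituted`), keeping M finite.
#'
#' @param c1,c2 Integer count vectors (silenced, control).
#' @param n1,n2 Library sizes (scalars), with `c1 <= n1`, `c2 <= n2`.
#' @param gene_id Optional gene identifiers.
#' @param phat `"conditional"` (default) or `"pooled"` null-proportion
#'   estimate.
#' @return Data frame with `gene_id`, `M`, `M_adj` (M minus the
#'   `log2(n1/n2)` depth offset, i.e. the library-size-normalised log2
#'   fold change), `A`, `p_hat`, `mu_M_given_A`, `var_M_given_A`, `z`,
#'   `p`, `tested`, `zero_substituted`. The depth offset is also stored
#'   in `attr(, "log2_depth_ratio")`.
#' @export
ma_test <- function(c1, c2, n1, n2, gene_id = NULL,
                    phat = c("conditional", "pooled")) {
  phat <- match.arg(phat)
  stopifnot(length(c1) == length(c2), length(n1) == 1, length(n2) == 1,
            n1 > 0, n2 > 0, all(c1 >= 0), all(c2 >= 0),
            all(c1 <= n1), all(c2 <= n2))
  if (is.null(gene_id)) gene_id <- paste0("g", seq_along(c1))
  tested <- c1 + c2 > 0
  zero_sub <- tested & (c1 == 0 | c2 == 0)
  x1 <- ifelse(c1 == 0, 0.5, c1)
  x2 <- ifelse(c2 == 0, 0.5, c2)

  M <- A <- ph <- EM <- VM <- z <- p <- rep(NA_real_, length(c1))
  i <- tested
  M[i] <- log2(x1[i]) - log2(x2[i])
  A[i] <- (log2(x1[i]) + log2(x2[i])) / 2
  ph[i] <- if (phat == "pooled") (x1[i] + x2[i]) / (n1 + n2)
           else 2^A[i] / sqrt(n1 * n2)
  ln2sq <- log(2)^2
  muX <- log2(n1 * ph[i]); muY <- log2(n2 * ph[i])
  vX <- (1 - ph[i]) / (n1 * ph[i] * ln2sq)
  vY <- (1 - ph[i]) / (n2 * ph[i] * ln2sq)
  EM[i] <- (muX - muY) + 2 * (vX - vY) / (vX + vY) * (A[i] - (muX + muY) / 2)
  VM[i] <- 4 * vX * vY / (vX + vY)
  z[i] <- (M[i] - EM[i]) / sqrt(VM[i])
  p[i] <- 2 * stats::pnorm(-abs(z[i]))

  out <- data.frame(gene_id = gene_id, M = M, M_adj = M - log2(n1 / n2),
                    A = A, p_hat = ph, mu_M_given_A = EM,
                    var_M_given_A = VM, z = z, p = p, tested = tested,
                    zero_substituted = zero_sub,
                    stringsAsFactors = FALSE)
  attr(out, "log2_depth_ratio") <- log2(n1 / n2)
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min_{j >= i} (p_(j) * m / j)` capped at 1, with `m` the number
#' of tested (non-`NA`) p-values; `NA` entries stay `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Composite two-timepoint differential-expression call
#'
#' A gene is called up- or down-regulated when all three gates hold:
#' (i) its day-2 BH q-value is below `fdr`; (ii) its day-2
#' library-size-normalised fold change reaches `fc`
#' (`|M_adj| >= log2(fc)`); (iii) day 2 and day 4 agree in direction
#' (`sign(M_adj)` equal and non-zero). The FDR gate uses day-2 p-values
#' only; day 4 contributes only its sign. Direction `up` means higher
#' expression in the silenced sample. Genes untested on either day are
#' `untested`; genes flagged for zero substitution remain eligible
#' (their M is finite) but carry the flag through.
#'
#' @param day2,day4 [ma_test()] result tables on a matched gene universe.
#' @param fdr FDR threshold (default 0.001, i.e. 0.1%).
#' @param fc Fold-change threshold (default 1.5).
#' @return Data frame with `gene_id`, `status`
#'   (`up`/`down`/`not_de`/`untested`), `M_day2`, `M_day4` (normalised
#'   scale), `q` (day-2 q-value), `zero_substituted`.
#' @export
call_de <- function(day2, day4, fdr = 0.001, fc = 1.5) {
  stopifnot(identical(day2$gene_id, day4$gene_id), fc >= 1)
  q <- bh_adjust(day2$p)
  tested <- day2$tested & day4$tested
  s2 <- sign(day2$M_adj); s4 <- sign(day4$M_adj)
  de <- tested & !is.na(q) & q < fdr &
    abs(day2$M_adj) >= log2(fc) & s2 == s4 & s2 != 0
  status <- ifelse(!tested, "untested",
                   ifelse(de & s2 > 0, "up",
                          ifelse(de & s2 < 0, "down", "not_de")))
  data.frame(gene_id = day2$gene_id, status = status,
             M_day2 = day2$M_adj, M_day4 = day4$M_adj, q = q,
             zero_substituted = day2$zero_substituted |
               day4$zero_substituted,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of per-gene fold changes across platforms/days
#'
#' Pearson `r` with the usual t-test p-value,
#' `t = r sqrt((n - 2) / (1 - r^2))`, two-sided. Non-finite pairs are
#' dropped; genes flagged for zero substitution should be excluded by
#' the caller before correlating.
#'
#' @param fc_a,fc_b Paired per-gene log2 fold changes.
#' @return List with `r`, `p`, `n` (pairs used). Zero variance in
#'   either vector yields `r = NA` with a warning.
#' @export
fold_change_correlation <- function(fc_a, fc_b) {
  stopifnot(length(fc_a) == length(fc_b))
  ok <- is.finite(fc_a) & is.finite(fc_b)
  a <- fc_a[ok]; b <- fc_b[ok]
  if (length(a) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(a)))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
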