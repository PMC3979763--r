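# Shared small simulation fixture, built once per test file.
.fixture_env <- new.env()

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 3, n_genes = 60, n_chroms = 2)
    .fixture_env$sim <- suppressWarnings(simulate_all(cfg))
    .fixture_env$cfg <- cfg
  }
  .fixture_env$sim
}

small_cfg <- function() {
  small_sim()
  .fixture_env$cfg
}

# exact two-sided conditional binomial p-value for (c1, c2) given
# c1 + c2, null proportion n1/(n1+n2): point-probability summation
exact_conditional_p <- function(c1, c2, n1, n2) {
  ct <- c1 + c2
  pr <- stats::dbinom(0:ct, ct, n1 / (n1 + n2))
  min(1, sum(pr[pr <= stats::dbinom(c1, ct, n1 / (n1 + n2)) * (1 + 1e-7)]))
}

# brute-force palindrome finder: every even window >= min_len and
# <= max_span inside [core_start - max_span, core_end + max_span),
# overlapping the core, equal to its own reverse complement
brute_palindrome <- function(seq, core_start, core_end,
                             min_len = 6, max_span = 20) {
  n <- nchar(seq)
  lo <- max(0, core_start - max_span)
  hi <- min(n, core_end + max_span)
  found <- list()
  for (s in lo:(hi - 1)) for (e in (s + 1):hi) {
    L <- e - s
    if (L < min_len || L > max_span || L %% 2 == 1) next
    if (s + L > core_start && s < core_end) {
      w <- substr(seq, s + 1, e)
      if (identical(w, revcomp(w))) found[[length(found) + 1]] <- c(s, e)
    }
  }
  found
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
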