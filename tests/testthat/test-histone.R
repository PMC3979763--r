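flat_track <- function(v, len = 10000, reads = NA) {
  genome_track(list(chr1 = rep(v, len)), "signal", total_reads = reads)
}

test_that("footprint of a constant field is flat at v * bin_width", {
  tr <- flat_track(2)
  an <- data.frame(chrom = "chr1", pos = 5000, strand = "+",
                   stringsAsFactors = FALSE)
  fp <- footprint(an, tr, half_window = 1750, bin = 50)
  expect_equal(length(fp$offsets), 70)           # 3.5 kb / 50 bp
  expect_equal(fp$mean_signal, rep(100, 70))
  expect_equal(fp$offsets[1], -1750)
})

test_that("single anchor reproduces the raw windowed signal", {
  set.seed(2)
  vals <- rpois(4000, 3)
  tr <- genome_track(list(chr1 = vals), "signal")
  an <- data.frame(chrom = "chr1", pos = 2000, strand = "+",
                   stringsAsFactors = FALSE)
  fp <- footprint(an, tr, half_window = 1000, bin = 100)
  manual <- colSums(matrix(vals[(2000 - 1000 + 1):(2000 + 1000)], 100))
  expect_equal(fp$mean_signal, manual)
})

test_that("footprint conserves total signal over anchors", {
  set.seed(20)
  vals <- rpois(20000, 2)
  tr <- genome_track(list(chr1 = vals), "signal")
  an <- data.frame(chrom = "chr1", pos = c(3000, 7000, 12000),
                   strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  fp <- footprint(an, tr, half_window = 500, bin = 50)
  window_sums <- vapply(an$pos, function(p)
    sum(vals[(p - 500 + 1):(p + 500)]), numeric(1))
  expect_equal(fp$anchor_count * sum(fp$mean_signal), sum(window_sums))
})

test_that("footprint is linear and respects strand mirroring", {
  set.seed(21)
  v1 <- rpois(8000, 2); v2 <- rpois(8000, 5)
  an <- data.frame(chrom = "chr1", pos = c(3000, 5000), strand = "+",
                   stringsAsFactors = FALSE)
  fa <- footprint(an, genome_track(list(chr1 = v1), "signal"), 1000, 50)
  fb <- footprint(an, genome_track(list(chr1 = v2), "signal"), 1000, 50)
  fab <- footprint(an, genome_track(list(chr1 = v1 + v2), "signal"),
                   1000, 50)
  expect_equal(fab$mean_signal, fa$mean_signal + fb$mean_signal)
  # flipping all strands reflects the profile about offset 0
  an_m <- an; an_m$strand <- "-"
  fm <- footprint(an_m, genome_track(list(chr1 = v1), "signal"), 1000, 50)
  expect_equal(fm$mean_signal, rev(fa$mean_signal))
})

test_that("joint scaling of values and total_reads leaves profiles unchanged", {
  set.seed(22)
  vals <- rpois(8000, 4)
  an <- data.frame(chrom = "chr1", pos = 4000, strand = "+",
                   stringsAsFactors = FALSE)
  f1 <- footprint(an, genome_track(list(chr1 = vals), "signal",
                                   total_reads = sum(vals)), 1000, 50)
  f2 <- footprint(an, genome_track(list(chr1 = vals * 5), "signal",
                                   total_reads = sum(vals) * 5), 1000, 50)
  expect_equal(f1$mean_signal, f2$mean_signal)
})

test_that("edge anchors are dropped with warning; all dropped errors", {
  tr <- flat_track(1, len = 3000)
  an <- data.frame(chrom = "chr1", pos = c(100, 1500),
                   strand = "+", stringsAsFactors = FALSE)
  expect_warning(fp <- footprint(an, tr, half_window = 1000, bin = 50),
                 "dropped")
  expect_equal(fp$anchor_count, 1)
  expect_error(
    suppressWarnings(footprint(an[1, ], tr, half_window = 1000,
                               bin = 50)),
    "all anchors")
})

test_that("TSS selection takes the argmax downstream window", {
  m <- gene_model("g", "chr1", "+", rbind(c(1000, 1500), c(3000, 3500)),
                  tss_list = c(1000, 3000))
  vals <- rep(0, 6000); vals[3001:3400] <- 10; vals[1001:1200] <- 1
  tr <- genome_track(list(chr1 = vals), "signal")
  expect_equal(unname(select_tss(list(g = m), tr, window = 2000)), 3000)
  # single-TSS genes pass through
  m1 <- gene_model("g1", "chr1", "+", rbind(c(100, 400)))
  expect_equal(unname(select_tss(list(g1 = m1), tr)), 100)
})

test_that("TSS choices equal brute-force per-TSS counting on the fixture", {
  sim <- small_sim()
  ref <- sim$histone$H3K4me3$control
  sel <- select_tss(sim$ann$models, ref, window = 2000)
  for (g in names(sim$ann$models)) {
    m <- sim$ann$models[[g]]
    cnt <- vapply(m$tss_list, function(t) {
      clen <- ref$chrom_lengths[[m$chrom]]
      w <- if (m$strand == "-") c(max(0, t + 1 - 2000), t + 1)
           else c(t, min(clen, t + 2000))
      sum(track_window_values(ref, m$chrom, w[1], w[2]))
    }, numeric(1))
    best <- m$tss_list[cnt == max(cnt)]
    expect_equal(unname(sel[g]), min(best))
  }
})

test_that("ratios are unity for identical tracks and depth-invariant", {
  sim <- small_sim()
  tr <- sim$histone$H3K9ac$control
  ids <- names(sim$ann$models)
  gwc <- tss_window_counts(sim$ann$models, tr, tr, non_de_genes = ids)
  expect_true(all(abs(gwc$ratio[!gwc$flagged] - 1) < 1e-12))
  # globally doubled silenced track: normalisation cancels the factor
  doubled <- genome_track(lapply(tr$values, function(v) v * 2),
                          "signal", total_reads = tr$total_reads * 2)
  gwc2 <- tss_window_counts(sim$ann$models, doubled, tr,
                            non_de_genes = ids)
  expect_true(all(abs(gwc2$ratio[!gwc2$flagged] - 1) < 1e-12))
})

test_that("top-k ranking matches a full sort with lexicographic ties", {
  gwc <- data.frame(gene_id = c("gB", "gA", "gC", "gD", "gE"),
                    chosen_tss = 0, count_silenced = 1,
                    count_control = 1,
                    ratio = c(2, 2, 5, NA, 1), flagged = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(rank_by_fold_change(gwc, k = 3), c("gC", "gA", "gB"))
  expect_equal(rank_by_fold_change(gwc, k = 1), "gC")
  expect_warning(top <- rank_by_fold_change(gwc, k = 10), "eligible")
  expect_equal(top, c("gC", "gA", "gB", "gE"))
})

test_that("response grouping uses inclusive two-fold bounds", {
  fc <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   M = c(1, 0.9, -1, NA), stringsAsFactors = FALSE)
  map <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    peak_id = c("p1", "p2", "p3", "p4"), distance = 0,
                    stringsAsFactors = FALSE)
  pk <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                   start = 0, end = 10, summit = (1:4) * 100,
                   height = 20, stringsAsFactors = FALSE)
  grp <- group_targets_by_response(fc, map, pk, threshold = 2)
  expect_equal(grp$up$pos, 100)      # M = 1 is exactly two-fold
  expect_equal(grp$down$pos, 300)
  # no gene passes: empty sets without error
  grp0 <- group_targets_by_response(fc, map, pk, threshold = 16)
  expect_equal(nrow(grp0$up), 0)
  expect_equal(nrow(grp0$down), 0)
})
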