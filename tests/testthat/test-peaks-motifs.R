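test_that("height filter is inclusive and order-preserving", {
  pk <- data.frame(peak_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(0, 100, 200), end = c(50, 150, 250),
                   summit = c(10, 110, 210), height = c(11, 12, 13),
                   stringsAsFactors = FALSE)
  expect_equal(filter_peaks(pk)$peak_id, c("b", "c"))
  expect_equal(nrow(filter_peaks(pk[0, ])), 0)
  set.seed(3)
  h <- sample(0:30, 1e4, replace = TRUE)
  pk2 <- data.frame(peak_id = as.character(seq_along(h)), chrom = "c",
                    start = 0, end = 10, summit = 5, height = h,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_peaks(pk2)), sum(h >= 12))
})

test_that("motif scan honours the inclusive summit window boundary", {
  seq <- paste0(strrep("A", 100), "GCTCG", strrep("A", 400))
  # motif start 100 sits exactly at summit - flank for summit 200
  pk <- data.frame(peak_id = c("in", "out"), chrom = c("c", "c"),
                   start = 0, end = nchar(seq),
                   summit = c(200, 201), height = 20,
                   stringsAsFactors = FALSE)
  hits <- scan_motif(pk, c(c = seq), flank = 100)
  expect_equal(hits$start[hits$peak_id == "in"], 100)
  # at summit 201 the motif start is one base beyond the window
  expect_equal(sum(hits$peak_id == "out"), 0)
})

test_that("motif scan equals brute-force substring enumeration", {
  set.seed(5)
  for (i in 1:100) {
    seq <- random_dna(400)
    summit <- sample(100:300, 1)
    pk <- data.frame(peak_id = "p", chrom = "c", start = 0,
                     end = 400, summit = summit, height = 20,
                     stringsAsFactors = FALSE)
    hits <- scan_motif(pk, c(c = seq), flank = 50)
    brute <- integer(0); brute_strand <- character(0)
    for (s in max(0, summit - 50):min(395, summit + 50)) {
      sub <- substr(seq, s + 1, s + 5)
      if (sub == "GCTCG") { brute <- c(brute, s)
                            brute_strand <- c(brute_strand, "+") }
      if (sub == revcomp("GCTCG")) { brute <- c(brute, s)
                                     brute_strand <- c(brute_strand, "-") }
    }
    o <- order(brute)
    expect_equal(hits$start, brute[o])
    expect_equal(hits$strand, brute_strand[o])
  }
})

test_that("scanning is strand-consistent under genome reverse complement", {
  set.seed(8)
  seq <- paste0(random_dna(180), "GGCTCGC", random_dna(60), "CGAGC",
                random_dna(150))
  L <- nchar(seq)
  pk <- data.frame(peak_id = "p", chrom = "c", start = 0, end = L,
                   summit = 200, height = 20, stringsAsFactors = FALSE)
  fwd <- scan_motif(pk, c(c = seq), flank = 150)
  pk_rc <- pk; pk_rc$summit <- L - 1 - 200
  rev <- scan_motif(pk_rc, c(c = revcomp(seq)), flank = 150)
  # mirrored positions and swapped strands
  expect_setequal(L - 5 - fwd$start, rev$start)
  expect_setequal(paste(L - 5 - fwd$start,
                        ifelse(fwd$strand == "+", "-", "+")),
                  paste(rev$start, rev$strand))
})

test_that("EMSA probes reproduce the published binding pattern", {
  pr <- zbed6_probes()
  pk <- data.frame(peak_id = names(pr), chrom = names(pr), start = 0,
                   end = nchar(pr), summit = floor(nchar(pr) / 2),
                   height = 20, stringsAsFactors = FALSE)
  hits <- scan_motif(pk, pr)
  with_core <- unique(hits$peak_id)
  expect_setequal(with_core, c("twist2_wt", "twist2_pal", "igf2_wt"))
  expect_true(all(hits$extended_match))
  pal <- vapply(with_core, function(nm) {
    h <- hits[hits$peak_id == nm, ]
    detect_palindrome(pr[[nm]], h$start, h$start + 5)$found
  }, logical(1))
  expect_setequal(names(pal)[pal], c("twist2_pal", "igf2_wt"))
})

test_that("conservation mean uses core bases only with strict threshold", {
  hit <- data.frame(peak_id = "p", chrom = "c", start = 10,
                    strand = "+", matched_seq = "GCTCG",
                    distance_to_summit = 0, extended_match = TRUE,
                    stringsAsFactors = FALSE)
  tr1 <- genome_track(list(c = rep(1, 30)), "conservation")
  expect_true(conservation_score(hit, tr1)$conserved)
  expect_equal(conservation_score(hit, tr1)$mean_conservation, 1)
  # mean exactly 0.90 is not conserved (strict >)
  tr2 <- genome_track(list(c = rep(0.9, 30)), "conservation")
  expect_false(conservation_score(hit, tr2)$conserved)
  # absent bases count as zero
  v <- rep(NA_real_, 30); v[11:13] <- 1
  tr3 <- genome_track(list(c = v), "conservation")
  expect_equal(conservation_score(hit, tr3)$mean_conservation, 3 / 5)
  # random tracks match independent per-base averaging
  set.seed(4)
  for (i in 1:20) {
    vals <- round(runif(30), 3)
    tr <- genome_track(list(c = vals), "conservation")
    expect_equal(conservation_score(hit, tr)$mean_conservation,
                 mean(vals[11:15]))
  }
})

test_that("palindrome detection matches exhaustive window enumeration", {
  set.seed(6)
  for (i in 1:300) {
    seq <- random_dna(60)
    core_start <- sample(20:35, 1)
    got <- detect_palindrome(seq, core_start, core_start + 5)
    brute <- brute_palindrome(seq, core_start, core_start + 5)
    expect_equal(got$found, length(brute) > 0)
    if (got$found) {
      lens <- vapply(brute, function(b) b[2] - b[1], numeric(1))
      best <- brute[lens == max(lens)]
      starts <- vapply(best, `[`, numeric(1), 1)
      expect_equal(got$start, min(starts))   # longest, leftmost
      expect_equal(got$end - got$start, max(lens))
    }
  }
})

test_that("odd windows never count and hexamer plants behave exhaustively", {
  # parity: an odd-length window cannot equal its reverse complement
  expect_false(identical("ACA", revcomp("ACA")))
  base <- paste0(strrep("A", 20), "GCTCG", strrep("A", 20))
  alphabet <- c("A", "C", "G", "T")
  hexamers <- apply(expand.grid(rep(list(alphabet), 6)), 1, paste,
                    collapse = "")
  is_pal <- hexamers == revcomp(hexamers)
  # plant each hexamer so it overlaps the core's first base
  planted <- vapply(hexamers, function(h) {
    s <- base
    substr(s, 16, 21) <- h
    detect_palindrome(s, 20, 25)$found
  }, logical(1))
  # every palindromic plant must be detected
  expect_true(all(planted[is_pal]))
  # non-palindromic plants may only fire via a chance window; verify
  # against brute force rather than assuming none
  for (h in sample(hexamers[!is_pal], 50)) {
    s <- base
    substr(s, 16, 21) <- h
    expect_equal(detect_palindrome(s, 20, 25)$found,
                 length(brute_palindrome(s, 20, 25)) > 0)
  }
})

test_that("insufficient context yields an undefined flag with warning", {
  expect_warning(res <- detect_palindrome("ACGCTCGA", 2, 7), "context")
  expect_true(is.na(res$found))
})

test_that("peak-gene association uses min TSS distance, inclusive window", {
  models <- list(
    gA = gene_model("gA", "chr1", "+", rbind(c(10000, 12000))),
    gB = gene_model("gB", "chr1", "-", rbind(c(30000, 31000))))
  pk <- data.frame(peak_id = c("p1", "p2", "p3"), chrom = "chr1",
                   start = c(10000, 4999, 25999) - 100,
                   end = c(10000, 4999, 25999) + 100,
                   summit = c(10000, 4999, 25999), height = 20,
                   stringsAsFactors = FALSE)
  map <- associate_peaks_to_genes(pk, models, window_bp = 5000)
  # p1 at gA's TSS; p2 at distance 5001 excluded; p3 exactly 5000 from
  # gB's minus-strand TSS (30999), inclusive
  expect_setequal(paste(map$gene_id, map$peak_id),
                  c("gA p1", "gB p3"))
  expect_equal(map$distance[map$peak_id == "p3"], 5000)
  expect_equal(map$distance[map$peak_id == "p1"], 0)
})

test_that("association map equals all-pairs brute force on the fixture", {
  sim <- small_sim()
  pk <- filter_peaks(sim$peaks_tracks$peaks)
  map <- associate_peaks_to_genes(pk, sim$ann$models, window_bp = 5000)
  brute <- list()
  for (g in names(sim$ann$models)) {
    m <- sim$ann$models[[g]]
    for (i in seq_len(nrow(pk))) {
      if (pk$chrom[i] != m$chrom) next
      d <- min(abs(pk$summit[i] - m$tss_list))
      if (d <= 5000)
        brute[[length(brute) + 1]] <- paste(g, pk$peak_id[i], d)
    }
  }
  expect_setequal(paste(map$gene_id, map$peak_id, map$distance),
                  unlist(brute))
})
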