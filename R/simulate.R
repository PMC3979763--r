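#' Configuration for the synthetic silencing experiment
#'
#' Bundles every knob of the generator. Defaults describe a compact but
#' realistic two-timepoint knockdown: 2,000 genes on 4 chromosomes,
#' log-normal baseline expression, 10% of genes with planted effects of
#' at least 2 on the log2 scale correlated across days, binomially
#' sampled counts at 1e6 mapped reads per sample, binding-site peaks
#' placed near up-regulated genes' TSS at an odds ratio of 3, GCTCG
#' cores planted within 100 bp of every summit, and promoter-mark
#' coverage bumps 120 bp downstream of TSS whose silenced-sample
#' amplitude is coupled to the planted expression change.
#'
#' @param seed Integer RNG seed; every generator derives its stream
#'   from it, so a fixed seed reproduces every output byte.
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (genes spread round-robin).
#' @param gene_spacing Distance between successive gene starts (bp).
#' @param baseline_log2_mean,baseline_log2_sd Log-normal baseline of
#'   relative expression, log2 scale.
#' @param expressed_mass Total proportion of library reads falling in
#'   gene models (the rest maps outside, so library size exceeds the
#'   count column sum).
#' @param de_fraction Fraction of genes with planted effects, in [0,1).
#' @param effect_size_log2 Minimum planted |log2 fold change|.
#' @param effect_size_spread Mean of the exponential tail added to the
#'   minimum effect size.
#' @param day_correlation Probability that the day-4 planted effect
#'   shares the day-2 sign.
#' @param library_sizes Named vector: `silenced_day2`, `control_day2`,
#'   `silenced_day4`, `control_day4`.
#' @param peak_prob_null Probability that a non-(up-regulated) gene gets
#'   a peak near its TSS.
#' @param peak_enrichment_odds Odds ratio of peak presence for planted
#'   up-regulated genes versus others (> 0; 1 = no association).
#' @param peak_tss_max_dist Maximum |summit - TSS| for planted peaks
#'   (bp; kept well inside the 5-kb association window).
#' @param motif_conserved_fraction Fraction of planted motifs given
#'   conservation above 0.9.
#' @param palindrome_fraction Fraction of planted motifs embedded in
#'   the Igf2-type CCTAGG palindrome context.
#' @param histone_marks Mark labels to simulate.
#' @param histone_baseline Background coverage per base.
#' @param histone_amplitude Bump height at an average-expression TSS.
#' @param histone_bump_sd Gaussian bump width (bp).
#' @param histone_bump_offset Bump centre downstream of TSS (bp).
#' @param histone_coupling Coupling of the silenced-sample bump to the
#'   planted log2 fold change (silenced amplitude is multiplied by
#'   `2^(coupling * log2FC)`); 0 decouples chromatin from expression.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_chroms = 4L,
                       gene_spacing = 8000L,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       expressed_mass = 0.5,
                       de_fraction = 0.1,
                       effect_size_log2 = 2,
                       effect_size_spread = 0.5,
                       day_correlation = 0.98,
                       library_sizes = c(silenced_day2 = 1e6,
                                         control_day2 = 1e6,
                                         silenced_day4 = 1e6,
                                         control_day4 = 1e6),
                       peak_prob_null = 0.25,
                       peak_enrichment_odds = 3,
                       peak_tss_max_dist = 1500,
                       motif_conserved_fraction = 0.5,
                       palindrome_fraction = 0.5,
                       histone_marks = c("H3K4me3", "H3K9ac"),
                       histone_baseline = 2,
                       histone_amplitude = 40,
                       histone_bump_sd = 400,
                       histone_bump_offset = 120,
                       histone_coupling = 1) {
  stopifnot(seed == round(seed), n_genes >= 0, n_chroms >= 1,
            gene_spacing >= 6000,
            de_fraction >= 0, de_fraction < 1,
            effect_size_log2 >= 0, expressed_mass > 0, expressed_mass <= 1,
            day_correlation >= 0, day_correlation <= 1,
            all(library_sizes > 0),
            peak_prob_null > 0, peak_prob_null < 1,
            peak_enrichment_odds > 0,
            motif_conserved_fraction >= 0, motif_conserved_fraction <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1)
  stopifnot(all(c("silenced_day2", "control_day2", "silenced_day4",
                  "control_day4") %in% names(library_sizes)))
  structure(as.list(environment()), class = "sim_config")
}

sim_margin <- 6000  # bp kept gene-free at chromosome ends

#' Simulate gene annotation with multi-transcript structures
#'
#' Places non-overlapping gene bodies at regular spacing (with jitter)
#' on both strands, gives each gene 2-5 exons and 1-3 transcripts built
#' from runs of those exons (so union-exon merging and multi-TSS
#' selection are exercised), and returns both the per-transcript exon
#' records (what a GTF stores) and the ground-truth union models.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (data frame for
#'   [write_annotation_gtf()]), `models` (named list of [gene_model()]),
#'   `chrom_lengths` (named vector).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_genes
  per_chrom <- if (n > 0) ceiling(n / config$n_chroms) else 0
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- stats::setNames(
    rep(per_chrom * config$gene_spacing + 2 * sim_margin, config$n_chroms),
    chroms)
  tx_rows <- list()
  models <- list()
  body_max <- min(4000, config$gene_spacing - 3500)
  for (i in seq_len(n)) {
    chrom <- chroms[((i - 1) %% config$n_chroms) + 1]
    slot <- (i - 1) %/% config$n_chroms
    gid <- sprintf("G%04d", i)
    body_start <- sim_margin + slot * config$gene_spacing +
      sample.int(500, 1)
    body_len <- sample(1500:body_max, 1)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:5, 1)
    # 2*n_ex - 2 interior cuts: exon k spans [cut_{2k-2}, cut_{2k-1})
    # with cut_0 = 0 and cut_{2n-1} = body_len
    cuts <- sort(sample(seq(100, body_len - 100, by = 20), 2 * n_ex - 2))
    ex_start <- body_start + c(0, cuts[seq(2, length(cuts), by = 2)])
    ex_end <- body_start + c(cuts[seq(1, length(cuts), by = 2)], body_len)
    n_tx <- sample(1:3, 1)
    tss <- numeric(0)
    for (t in seq_len(n_tx)) {
      # transcript 1 spans all exons; later ones drop leading/trailing
      a <- if (t == 1) 1 else sample.int(n_ex, 1)
      # sample(a:n_ex, 1) misbehaves when a == n_ex (length-1 x rule)
      b <- if (t == 1 || a == n_ex) n_ex else sample(a:n_ex, 1)
      tid <- sprintf("%s.t%d", gid, t)
      tx_rows[[length(tx_rows) + 1]] <- data.frame(
        gene_id = gid, tx_id = tid, chrom = chrom, strand = strand,
        start = ex_start[a:b], end = ex_end[a:b],
        stringsAsFactors = FALSE)
      tss <- c(tss, if (strand == "+") ex_start[a] else ex_end[b] - 1)
    }
    models[[gid]] <- gene_model(gid, chrom, strand,
                                cbind(ex_start, ex_end), tss_list = tss)
  }
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else
    data.frame(gene_id = character(), tx_id = character(),
               chrom = character(), strand = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  list(transcripts = transcripts, models = models,
       chrom_lengths = chrom_lengths)
}

#' Simulate the four-sample count table with planted fold changes
#'
#' Per sample and gene, counts are drawn `Binomial(library_size, p)`,
#' realising the random-sampling model the MA test assumes. Control
#' proportions come from the log-normal baseline; silenced-sample
#' proportions are multiplied by `2^(planted log2FC)` for the planted DE
#' genes (day-specific effects, sharing sign with probability
#' `day_correlation`). Should the proportions of a sample ever exceed 1
#' in total they are rescaled with a warning.
#'
#' @param config A [sim_config()].
#' @param models Models from [simulate_annotation()].
#' @return List with `counts` (a [count_table()], samples
#'   `silenced_day2`, `control_day2`, `silenced_day4`, `control_day4`)
#'   and `truth` (data frame `gene_id`, `p_base`, `is_de`, `direction`,
#'   `M_day2`, `M_day4`).
#' @export
simulate_counts <- function(config, models) {
  set.seed(config$seed + 202L)
  ids <- names(models)
  n <- length(ids)
  b <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  w <- 2^b
  p_base <- w / sum(w) * config$expressed_mass
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  direction <- numeric(n)
  M2 <- M4 <- numeric(n)
  if (n_de > 0) {
    direction[de_idx] <- sample(c(1, -1), n_de, replace = TRUE)
    mag2 <- config$effect_size_log2 +
      stats::rexp(n_de, rate = 1 / max(config$effect_size_spread, 1e-9))
    mag4 <- config$effect_size_log2 +
      stats::rexp(n_de, rate = 1 / max(config$effect_size_spread, 1e-9))
    same <- stats::rbinom(n_de, 1, config$day_correlation) * 2 - 1
    M2[de_idx] <- direction[de_idx] * mag2
    M4[de_idx] <- direction[de_idx] * same * mag4
  }
  props <- cbind(silenced_day2 = p_base * 2^M2,
                 control_day2 = p_base,
                 silenced_day4 = p_base * 2^M4,
                 control_day4 = p_base)
  for (s in colnames(props)) {
    tot <- sum(props[, s])
    if (tot > 1) {
      # rescale to 0.95, not 1: binomial draws stay valid and the
      # library size keeps its margin over the gene-count column sum
      warning("proportions for ", s, " sum to ", signif(tot, 3),
              "; rescaled")
      props[, s] <- props[, s] / tot * 0.95
    }
  }
  counts <- vapply(colnames(props), function(s) {
    stats::rbinom(n, config$library_sizes[[s]], props[, s])
  }, numeric(n))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(ids, colnames(props)))
  list(counts = count_table(counts, config$library_sizes),
       truth = data.frame(gene_id = ids, p_base = p_base,
                          is_de = seq_len(n) %in% de_idx,
                          direction = direction, M_day2 = M2,
                          M_day4 = M4, stringsAsFactors = FALSE))
}

#' Peak-to-gene assignment under the planted enrichment model
#'
#' Decides which genes receive a binding-site peak near their TSS:
#' planted up-regulated genes with probability `p_up` such that the
#' odds ratio versus all other genes equals `peak_enrichment_odds`;
#' everyone else with `peak_prob_null`. Factored out so the null
#' behaviour (odds 1) can be studied cheaply in calibration runs.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_counts()].
#' @return Logical vector along `truth$gene_id`.
#' @export
sim_assign_peaks <- function(config, truth) {
  q <- config$peak_prob_null / (1 - config$peak_prob_null)
  p_up <- config$peak_enrichment_odds * q /
    (1 + config$peak_enrichment_odds * q)
  is_up <- truth$is_de & truth$direction > 0
  stats::rbinom(nrow(truth), 1,
                ifelse(is_up, p_up, config$peak_prob_null)) == 1
}

# motif plant contexts: core GCTCG at the given offset within the plant
plant_pal <- "CCTAGGCTCGC"   # Igf2-type palindrome overlapping the core
plant_plain <- "GGCTCGC"     # extended 7-mer, no palindrome
plant_core_off <- c(pal = 5L, plain = 1L)

#' Simulate peaks, genome sequence and conservation track
#'
#' Generates a random genome, assigns peaks to genes per
#' [sim_assign_peaks()], places each summit within
#' `peak_tss_max_dist` of a (randomly chosen) TSS of its gene, plants a
#' GCTCG core within 100 bp of every summit (embedded in the CCTAGG
#' palindrome context for a configured fraction, on a random strand),
#' and writes per-base conservation above 0.9 over a configured
#' fraction of the planted cores (low scores over the rest; background
#' bases carry no data). Sub-threshold decoy peaks (height < 12) with
#' no planted structure are added for the height filter to remove.
#' Random background sequence may of course contain chance motif or
#' palindrome occurrences of its own.
#'
#' @param config A [sim_config()].
#' @param ann [simulate_annotation()] result.
#' @param truth Truth table from [simulate_counts()].
#' @return List with `genome` (`DNAStringSet`), `peaks` (data frame),
#'   `motifs` (truth: `peak_id`, `gene_id`, `motif_start`, `strand`,
#'   `palindrome`, `conserved`), `conservation` (a
#'   `conservation_track`), `has_peak` (logical along genes).
#' @export
simulate_peaks_and_tracks <- function(config, ann, truth) {
  set.seed(config$seed + 303L)
  chrom_lengths <- ann$chrom_lengths
  genome <- lapply(chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  })
  has_peak <- sim_assign_peaks(config, truth)
  rows <- list(); motif_rows <- list()
  cons_runs <- lapply(chrom_lengths, function(...)
    list(start = numeric(0), end = numeric(0), score = numeric(0)))
  for (j in which(has_peak)) {
    gid <- truth$gene_id[j]
    m <- ann$models[[gid]]
    tss <- if (length(m$tss_list) > 1) sample(m$tss_list, 1) else
      m$tss_list
    clen <- chrom_lengths[[m$chrom]]
    summit <- min(max(sim_margin %/% 2,
                      tss + sample(-config$peak_tss_max_dist:
                                     config$peak_tss_max_dist, 1)),
                  clen - sim_margin %/% 2)
    pid <- paste0("pk_", gid)
    height <- 12 + stats::rpois(1, 25)
    rows[[length(rows) + 1]] <- data.frame(
      peak_id = pid, chrom = m$chrom,
      start = summit - sample(120:280, 1),
      end = summit + sample(120:280, 1),
      summit = summit, height = height, stringsAsFactors = FALSE)
    # plant the core with its start within 100 bp of the summit
    pal <- stats::runif(1) < config$palindrome_fraction
    plant <- if (pal) plant_pal else plant_plain
    off <- plant_core_off[[if (pal) "pal" else "plain"]]
    core_start <- summit + sample(-80:80, 1)
    plant_start <- core_start - off
    minus <- stats::runif(1) < 0.5
    seqs <- if (minus) revcomp(plant) else plant
    substr(genome[[m$chrom]], plant_start + 1,
           plant_start + nchar(plant)) <- seqs
    hit_start <- if (minus)
      plant_start + nchar(plant) - off - 5L else core_start
    conserved <- stats::runif(1) < config$motif_conserved_fraction
    sc <- if (conserved) stats::runif(1, 0.92, 1.0) else
      stats::runif(1, 0.2, 0.6)
    cr <- cons_runs[[m$chrom]]
    cons_runs[[m$chrom]] <- list(start = c(cr$start, plant_start - 3),
                                 end = c(cr$end, plant_start +
                                           nchar(plant) + 3),
                                 score = c(cr$score, round(sc, 3)))
    motif_rows[[length(motif_rows) + 1]] <- data.frame(
      peak_id = pid, gene_id = gid, motif_start = hit_start,
      strand = if (minus) "-" else "+", palindrome = pal,
      conserved = conserved, stringsAsFactors = FALSE)
  }
  # decoy peaks below the height-12 filter
  n_decoy <- max(0L, round(0.15 * length(rows)))
  for (d in seq_len(n_decoy)) {
    chrom <- names(chrom_lengths)[sample.int(length(chrom_lengths), 1)]
    summit <- sample(seq(sim_margin, chrom_lengths[[chrom]] - sim_margin),
                     1)
    rows[[length(rows) + 1]] <- data.frame(
      peak_id = paste0("decoy_", d), chrom = chrom,
      start = summit - 150, end = summit + 150, summit = summit,
      height = sample(3:11, 1), stringsAsFactors = FALSE)
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(), chrom = character(),
               start = numeric(), end = numeric(), summit = numeric(),
               height = numeric(), stringsAsFactors = FALSE)
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(peak_id = character(), gene_id = character(),
               motif_start = numeric(), strand = character(),
               palindrome = logical(), conserved = logical(),
               stringsAsFactors = FALSE)
  cons_values <- lapply(names(chrom_lengths), function(chrom) {
    cr <- cons_runs[[chrom]]
    rle_from_runs(cr$start, cr$end, cr$score, chrom_lengths[[chrom]],
                  NA_real_)
  })
  names(cons_values) <- names(chrom_lengths)
  list(genome = Biostrings::DNAStringSet(unlist(genome)),
       peaks = peaks, motifs = motifs,
       conservation = genome_track(cons_values, kind = "conservation"),
       has_peak = has_peak)
}

#' Simulate histone-mark coverage tracks
#'
#' Coverage is `Poisson(baseline + bumps)` per base, where each TSS of
#' an expressed gene contributes a Gaussian bump centred
#' `histone_bump_offset` bp downstream (strand-aware) with amplitude
#' proportional to the gene's relative expression (multi-TSS genes get
#' random per-TSS weights, so one TSS dominates). In silenced-sample
#' tracks the amplitude is additionally multiplied by
#' `2^(histone_coupling * planted log2FC)`.
#'
#' @param config A [sim_config()].
#' @param ann [simulate_annotation()] result.
#' @param truth Truth table from [simulate_counts()].
#' @return Nested list `tracks[[mark]][[condition]]` of
#'   `signal_track`s, conditions `silenced` and `control`.
#' @export
simulate_histone_coverage <- function(config, ann, truth) {
  set.seed(config$seed + 404L)
  chrom_lengths <- ann$chrom_lengths
  rel <- truth$p_base / mean(truth$p_base)
  half_support <- 3 * config$histone_bump_sd
  offs <- seq(-half_support, half_support)
  shape <- exp(-offs^2 / (2 * config$histone_bump_sd^2))
  # per-gene, per-TSS planted amplitudes (shared across marks/conditions)
  plan <- lapply(seq_along(ann$models), function(j) {
    m <- ann$models[[j]]
    wts <- stats::runif(length(m$tss_list), 0.3, 1)
    wts[which.max(wts)] <- 1
    list(model = m, amp = config$histone_amplitude * rel[j] * wts,
         fc = 2^(config$histone_coupling * truth$M_day2[j]))
  })
  base_lambda <- lapply(chrom_lengths, function(len)
    rep(config$histone_baseline, len))
  build <- function(silenced) {
    lambda <- lapply(base_lambda, identity)
    for (pl in plan) {
      m <- pl$model
      mult <- if (silenced) pl$fc else 1
      for (t in seq_along(m$tss_list)) {
        centre <- m$tss_list[t] +
          if (m$strand == "+") config$histone_bump_offset else
            -config$histone_bump_offset
        idx <- centre + offs
        ok <- idx >= 0 & idx < chrom_lengths[[m$chrom]]
        lambda[[m$chrom]][idx[ok] + 1] <-
          lambda[[m$chrom]][idx[ok] + 1] + pl$amp[t] * mult * shape[ok]
      }
    }
    values <- lapply(lambda, function(lam)
      S4Vectors::Rle(stats::rpois(length(lam), lam)))
    genome_track(values, kind = "signal",
                 total_reads = sum(vapply(values, sum, numeric(1))))
  }
  tracks <- lapply(stats::setNames(config$histone_marks,
                                   config$histone_marks),
                   function(mark) list(silenced = build(TRUE),
                                       control = build(FALSE)))
  tracks
}

#' Run every generator and write all files
#'
#' Emits `annotation.gtf`, `counts.tsv`, `truth.tsv`, `peaks.bed`,
#' `genome.fa`, `conservation.bg` and `<mark>_<condition>.bg` under
#' `dir`, and returns the in-memory objects.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return List with `ann`, `counts`, `truth`, `peaks_tracks`,
#'   `histone`.
#' @export
simulate_all <- function(config, dir = NULL) {
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(config, ann$models)
  pt <- simulate_peaks_and_tracks(config, ann, cnt$truth)
  ht <- simulate_histone_coverage(config, ann, cnt$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation_gtf(ann$transcripts, file.path(dir, "annotation.gtf"))
    write_counts(cnt$counts, file.path(dir, "counts.tsv"))
    utils::write.table(cnt$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_peaks(pt$peaks, file.path(dir, "peaks.bed"))
    Biostrings::writeXStringSet(pt$genome, file.path(dir, "genome.fa"))
    write_track(pt$conservation, file.path(dir, "conservation.bg"))
    for (mark in names(ht))
      for (cond in names(ht[[mark]]))
        write_track(ht[[mark]][[cond]],
                    file.path(dir, sprintf("%s_%s.bg", mark, cond)))
  }
  list(ann = ann, counts = cnt$counts, truth = cnt$truth,
       peaks_tracks = pt, histone = ht)
}
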