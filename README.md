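# silencescan

Computational readout of a transcription-factor knockdown experiment,
built around the ZBED6 silencing design in mouse C2C12 myoblasts:
RNA-seq differential expression between silenced and control cells at
two timepoints, association of ChIP-seq binding-site peaks with the
regulated genes, conserved GCTCG-core motif and palindrome scanning
around peak summits, and histone-modification profiling around
transcription start sites. A seeded synthetic-data generator emulates
the study's statistical structure with known ground truth, so every
stage of the pipeline can be validated end to end without the original
sequencing data.

## Who this is for

Analysts re-running or stress-testing a TF-knockdown readout: two
conditions, pooled replicates (no within-condition dispersion
estimate), gene-level counts, MACS-style peak calls, per-base
conservation scores and histone-mark coverage tracks.

## The statistics at the core

**MA-plot random-sampling test.** For a gene with counts `c1` (silenced,
library `n1`) and `c2` (control, library `n2`), let `X = log2 c1`,
`Y = log2 c2`, `M = X − Y`, `A = (X + Y)/2`. Under binomial ("random
sampling") count noise with a common proportion `p`, the delta method
gives `X ≈ N(log2(n1 p), (1 − p)/(n1 p ln²2))`, likewise `Y`, and
conditioning the bivariate normal on the observed `A`:

    E(M | A = a)  = (μX − μY) + 2 (σX² − σY²)/(σX² + σY²) · (a − (μX + μY)/2)
    Var(M | A)    = 4 σX² σY² / (σX² + σY²)

`z = (M − E(M|A)) / sqrt(Var(M|A))` gets a two-sided normal p-value.
The null proportion is estimated from the conditioning variable itself,
`p̂ = 2^A / sqrt(n1 n2)`, which keeps the statistic aligned with the
exact conditional binomial test (see the methods vignette). A gene is
called differentially expressed when its day-2 Benjamini–Hochberg
q-value is below 0.001, its library-size-normalised fold change is at
least 1.5, and day 2 and day 4 agree in direction.

**Downstream:** RPKM over union-exon gene models with an inclusive
1-RPKM detection threshold; peak height ≥ 12 filtering; GCTCG scans
within 100 bp of summits with phastCons-style mean conservation > 0.90
(strict); reverse-complement palindrome detection overlapping the core;
peak–gene association within 5 kb (or 10 kb) of the nearest TSS;
chi-square / Fisher / Mann–Whitney enrichment statistics; 3.5-kb
footprints and 2-kb downstream-of-TSS silenced/control ratios
normalised to the non-DE gene set.

## Worked example

```r
library(silencescan)

cfg <- sim_config(seed = 1)            # 2,000 genes, 10% planted DE
ann <- simulate_annotation(cfg)
cnt <- simulate_counts(cfg, ann$models)
ct  <- cnt$counts

d2 <- ma_test(ct$counts[, "silenced_day2"], ct$counts[, "control_day2"],
              ct$library_size[["silenced_day2"]],
              ct$library_size[["control_day2"]], gene_id = ct$gene_ids)
d4 <- ma_test(ct$counts[, "silenced_day4"], ct$counts[, "control_day4"],
              ct$library_size[["silenced_day4"]],
              ct$library_size[["control_day4"]], gene_id = ct$gene_ids)
calls <- call_de(d2, d4, fdr = 0.001, fc = 1.5)
table(calls$status)
#>   down not_de     up
#>     96   1809     95

de <- calls$gene_id[calls$status %in% c("up", "down")]
planted <- cnt$truth$gene_id[cnt$truth$is_de]
mean(planted %in% de)      # sensitivity on planted truth
#> [1] 0.955
mean(!(de %in% planted))   # empirical false-discovery proportion
#> [1] 0
```

191 of the 200 planted genes are recalled with no false positives:
the q < 0.001 day-2 gate, the 1.5-fold gate and the day-2/day-4
direction gate together control the false-discovery proportion well
below the nominal 0.1% FDR, at the cost of the handful of planted genes
whose day-4 effect flipped sign or whose expression is too shallow at a
10^6-read library.

Peak enrichment on the same simulation:

```r
pt  <- simulate_peaks_and_tracks(cfg, ann, cnt$truth)
map <- associate_peaks_to_genes(filter_peaks(pt$peaks), ann$models,
                                window_bp = 5000)
expr <- detect_expressed(rpkm(ct, ann$models))
tab <- build_contingency(calls, map, expr$gene_id[expr$detected], "up")
chi_square_2x2(tab)$p_two_tailed
#> [1] 1.595062e-11
```

The planted odds-3 association of binding sites with up-regulated genes
is detected decisively.

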