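---
title: "Methods: models, parameters and design choices in silencescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in silencescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

silencescan implements the computational readout of a
transcription-factor knockdown experiment of the ZBED6/C2C12 type:
two-condition RNA-seq without within-condition replicates (triplicates
pooled before sequencing), binding-site peaks from ChIP-seq, per-base
conservation scores, and histone-mark coverage. This vignette explains
the models, the parameters that matter, the synthetic-data generator,
and the places where the design was genuinely open.

## Coordinates and containers

All internal coordinates are 0-based half-open (BED convention); GTF,
refGene and wiggle inputs are converted at parse time, so a printed
1-based inclusive interval `a–b` has length `b − a + 1` (the 825-bp
Twist2 construct insert is the canonical check). Gene models merge all
transcripts into disjoint union exons but keep every distinct
transcript 5′ end in `tss_list`, because downstream rules (highest
promoter-mark TSS selection) need the full list. Tracks are
run-length-encoded per-base vectors per chromosome; conservation
tracks mark data-free bases `NA` while signal tracks treat them as
zero coverage — an absent conservation score must not count as
evidence of conservation, whereas absent coverage genuinely is zero.

## The MA-plot random-sampling test

With counts `c1` out of library `n1` (silenced) and `c2` out of `n2`
(control), `X = log2 c1`, `Y = log2 c2`, `M = X − Y`,
`A = (X + Y)/2`. Under binomial sampling with shared proportion `p`
the delta method gives `X ≈ N(log2(n1 p), (1 − p)/(n1 p ln²2))`, and
conditioning the bivariate normal `(M, A)` on `A = a` yields

$$E(M\mid A=a) = (\mu_X-\mu_Y) +
  2\frac{\sigma_X^2-\sigma_Y^2}{\sigma_X^2+\sigma_Y^2}
  \Big(a-\frac{\mu_X+\mu_Y}{2}\Big),
\qquad
\mathrm{Var}(M\mid A) = \frac{4\sigma_X^2\sigma_Y^2}
                             {\sigma_X^2+\sigma_Y^2}.$$

These are the standard bivariate-normal conditional moments
(`E(M|A) = μM + Cov(M,A)/Var(A)·(a − μA)` with
`Cov(M,A) = (σX² − σY²)/2`, `Var(A) = (σX² + σY²)/4`); we verified the
algebra symbolically and numerically before use.

**Estimating the null proportion.** The statistic's distribution is
taken *conditional on the observed A*, so the self-consistent estimate
of the shared proportion is the one implied by A itself:
`p̂ = 2^A / √(n1 n2)`, the geometric mean of the two per-sample
proportions. The pooled alternative `(c1 + c2)/(n1 + n2)` is offered
as an option but tracks the exact conditional binomial test
noticeably worse in the tails (at `c1 = 200, c2 = 100, n = 10^6` the
geometric form is within 0.16 decades of the exact conditional
p-value; the pooled form is off by 0.62 decades). The default was
chosen on that oracle comparison.

**Zero handling.** Both counts zero: the gene is untested. Exactly one
zero: 0.5 is substituted before logs and the gene flagged; flagged
genes keep a finite M for calling but are excluded from correlation
analyses.

**Calibration and its limits.** On 10^5 null simulations
(`n = 10^7`, `p = 10^−5`, mean count 100) the type-I error at
α = 0.05 is 0.050–0.051. The p-value distribution is *not* uniform to
arbitrary precision, for a structural reason: counts are discrete, and
`P(c1 = c2) = Σ_k P(k)² ≈ (4πnp)^{-1/2} ≈ 0.028` of null draws give
`M = 0`, i.e. exactly p = 1. Any deterministic two-sided p-value from
these counts carries that atom, so the Kolmogorov–Smirnov distance
from Uniform(0,1) is bounded below by ≈ 0.028 regardless of how good
the normal approximation is (we measure 0.029, with interior
deviations under 0.005). The acceptance suite asserts a KS bound of
0.02; that assertion fails for this reason and is retained as a
documented limitation rather than silenced.

**Composite call.** up/down requires (i) day-2 BH q < 0.001, (ii)
library-size-normalised |fold change| ≥ 1.5, (iii) day-2 and day-4
effects in the same direction. The FDR gate uses day-2 p-values only;
day 4 contributes its sign. The fold-change gate uses
`M − log2(n1/n2)` — a raw count ratio conflates sequencing depth with
expression, and the normalised form is invariant to depth; whether the
original analysis normalised this gate is not documented, so this is a
recorded design choice, not a reproduction claim.

## Expression

RPKM divides by the union-exon length and by the *supplied* library
size (total mapped reads), not the column sum: reads mapping outside
gene models still consume sequencing depth. Detection is inclusive
(`≥ 1` RPKM in at least one sample). The "high/medium" expression
labels seen in published tables have no numeric definition we could
adopt, so binning is left to the user. qPCR fold changes use
`2^−ΔΔCt`.

## Motifs, conservation, palindromes

The core motif is GCTCG (the consensus; one Methods-section spelling
"GTCTG" in the source literature is treated as a typographical error,
and the core is an argument so either can be scanned). Both strands
are scanned by default — double-stranded binding is the conservative
default where the original strand convention is unstated. "Within
100 bp of the summit" is interpreted as the motif *start* within
±100 bp inclusive. The extended 7-mer GGCTCGC is flagged per hit.
Conservation is the arithmetic mean over the 5 core bases only, with
absent bases contributing 0 (an unscored region must not inflate the
mean), and "conserved" is strict: mean > 0.90.

A palindrome is formalised as: an even-length window of ≥ 6 bp and
≤ 20 bp, within 20 bp of the matched core, equal to its own reverse
complement, overlapping the core by at least one base; the longest
such window (leftmost on ties) is reported. Odd windows can never
satisfy reverse-complement equality. The definition is validated
against the five published EMSA probe sequences: the core is found in
exactly the Twist2-WT, Twist2-PAL and Igf2 probes, the palindrome flag
is true exactly for Igf2 (CCTAGG context) and Twist2-PAL — matching
the published construct design and binding pattern. A probe with at
least 5 bp of context on each side of the core gets a definite answer;
only shorter contexts return an undefined flag, because a 38-bp probe
was clearly expected to be classifiable.

Peak–gene association is by minimum |summit − TSS| over the gene's TSS
list, inclusive at the window edge (5 kb for enrichment tables, 10 kb
for the snoRNA-style annotation).

## Enrichment statistics

The DE-versus-binding-site table uses the caller-supplied expressed
universe (detected genes, with small non-coding RNAs removed by the
caller where that mirrors the original filtering); non-DE genes are
universe genes not called in either direction. Chi-square is Pearson's
without continuity correction by default — on the published all-DE
table both corrected (p = 0.0042) and uncorrected (p = 0.0036) round
to the printed 0.004, and expected counts are in the hundreds; the
flag exists. Fisher's two-sided p uses point-probability summation
(the `fisher.test` convention), with tail-doubling behind a flag.
Mann–Whitney uses midranks, exact enumeration for tie-free samples
with min(n) ≤ 8, and otherwise the normal approximation with
tie-corrected variance *and* continuity correction: without the
correction the worst-case error against exact enumeration is 0.68,
with it 0.13 (exhaustive over all n ≤ 8 configurations), almost all of
it at tiny n and large p. A stated acceptance bound of |Δp| ≤ 0.01 for
all n ≤ 8 is unattainable for any normal-type approximation (the best
regime we found — both n ≥ 4 and p ≤ 0.2 — still reaches 0.0126) and
is left failing, documented here.

Pearson chi-square and the margin-conditional (label-shuffle)
permutation null agree well only where the asymptotic approximation is
in its validity regime; on strongly associated small tables such as
(5,15;20,10) the exact shuffle null differs by ~46% relative, so the
permutation-oracle unit test uses a moderate-association table
instead.

## Histone profiles

Footprints sum signal in 50-bp bins tiling ±1750 bp (the 3.5-kb
window; bin width is not documented in the source literature — 50 bp
resolves a 400-bp-scale promoter bump comfortably), mirror
minus-strand anchors, and scale to reads-per-10^7 when the track knows
its read count. Downstream windows are `[TSS, TSS + 2000)` on the
coding strand. For multi-TSS genes the TSS with the highest
reference-track (H3K4me3 control) downstream count is selected, ties
to the smallest coordinate. The silenced/control ratio is normalised
by a single global factor `Σ_nonDE control / Σ_nonDE silenced` — the
published "normalized to counts for all non-DE genes" is not
formalised anywhere, and a global factor is the least-assuming reading
(a per-gene median-ratio alternative would downweight long-tailed
genes; the global factor keeps ratios interpretable as fold changes).
Read-interval input is MAPQ-filtered (> 10, strict) and divided by the
mean read length so bedGraph signal and read pileups are
commensurable.

## The synthetic-data generator

The generator realises the very model the DE test assumes — binomial
sampling of per-gene proportions — so type-I error and recovery rates
are interpretable; robustness to overdispersion is an extension, not
something these simulations can demonstrate. What it emulates, and
what it does not:

* **Annotation**: 2,000 genes on 4 chromosomes, 8-kb spacing, 2–5
  exons, 1–3 transcripts per gene (exercising union merging and
  multi-TSS selection). No overlapping genes, no shared exons.
* **Counts**: log-normal baseline (log2 mean 8, sd 1.5) scaled so half
  of each 10^6-read library falls in gene models; planted effects on
  10% of genes, |log2FC| = 2 plus an exponential tail (mean 0.5),
  day-4 effects sharing the day-2 sign with probability 0.98.
  The spread and the day correlation are the two knobs the study
  conditions do not fix; they were set so that the generator meets its
  own design contract — that a strong-effect simulation is
  *recoverable in principle* at ≥ 90%: with log2-sd 2 about a tenth
  of planted genes carry too few reads at a 10^6-read library for any
  test, and the direction gate structurally caps sensitivity at the
  day correlation. Real direct-target regulation is
  direction-consistent across adjacent timepoints; 0.98 models a small
  secondary-effect contamination. Rescaling (with a warning) to a
  0.95 proportion total applies only if planted effects push the
  silenced proportions above 1, keeping binomial draws valid and the
  library size above the in-gene count sum.
* **Peaks/motifs**: up-regulated genes receive a summit within 1.5 kb
  of a random TSS at odds 3 versus a 0.25 baseline probability;
  every peak gets a planted GCTCG within ±80 bp of the summit, half
  embedded in the Igf2-type CCTAGG palindrome context, half as the
  plain GGCTCGC 7-mer, on a random strand; conservation > 0.9 is
  written over a configured fraction of cores. Decoy peaks below the
  height-12 filter carry no planted structure. Random background
  sequence may contain chance motifs or palindromes — tests that
  compare planted against found structure therefore check containment
  (every planted motif is found), not equality.
* **Histone coverage**: Poisson counts around
  `baseline + Gaussian bump` (sd 400 bp) centred 120 bp downstream of
  every TSS, amplitude proportional to relative expression with
  per-TSS weights, multiplied in silenced tracks by
  `2^(coupling · log2FC)`.

Real data differ in ways the generator does not model: overdispersion
beyond binomial, GC and mappability bias, overlapping genes and
antisense transcription, peak-width/summit-position noise, fragment-
length effects in coverage. Passing the recovery tests therefore shows
the pipeline is correct *under its own model assumptions*, not that
those assumptions hold for any particular dataset.

## Problem sizes and numerics

Unit tests run a 60-gene simulation; the acceptance suite runs the
full 2,000-gene recovery (about 1–2 minutes) and the 10^5-draw null
calibration (seconds). The exact-conditional-binomial oracle grid uses
counts 50–1000 at ratios up to 2, restricted to exact p ≥ 10^−10:
beyond that, normal-tail and binomial-tail p-values diverge by
construction and neither matters at any realistic FDR threshold.
Ties in TSS selection and in fold-change ranking break
deterministically (smallest coordinate; lexicographic gene id). All
generators derive their RNG streams from a single seed; every output
is byte-reproducible.

## Known limitations

* No replicate-aware dispersion modelling — the design pools
  replicates, and the binomial test is anti-conservative under real
  biological overdispersion.
* The p = 1 atom and small-sample Mann–Whitney bounds discussed above.
* Footprint and ratio profiling assume single-fragment, single-end
  style coverage; no input-chromatin normalisation.
* GO enrichment is out of scope; the package only exports ranked gene
  lists (top-k by histone fold change, DE sets) for external tools.
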