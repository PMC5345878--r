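---
title: "Landmark-anchored chromatin profiles and splicing-linked statistics"
author: "metachrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-anchored chromatin profiles and splicing-linked statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachrom)
```

## The analysis problem

Short histone H2A variants such as H2A.B (mouse H2A.B.3) destabilize
nucleosomes and are deposited on active genes in the testis and brain —
at the transcription start site (TSS) and, within gene bodies, on exons
and their flanking intronic sequence. Whether this deposition merely
tracks transcription or carries information about splicing is a
quantitative question: one must relate a ChIP-seq signal, positioned at
base-pair resolution around genomic landmarks, to per-gene expression
and per-exon inclusion, while controlling the obvious confounder that
highly included exons tend to sit in highly expressed genes.

`metachrom` implements that analysis as a reusable pipeline:

1. paired-end fragments &rarr; per-base coverage tracks, RPM-normalized
   (`compute_coverage()`, `normalize_rpm()`);
2. strand-oriented signal matrices anchored at the TSS, the intron–exon
   boundary (splice acceptor) or the exon–intron boundary (donor)
   (`anchored_matrix()`), with mean profiles and pointwise 95% bands
   (`mean_profile()`), stratification into expression / signal /
   inclusion classes (`stratify_anchors()`, `bin_by_inclusion()`),
   metagene scaling (`metagene_scale()`) and rank-group heatmaps
   (`heatmap_groups()`);
3. the positional statistics: a per-base linear model of the ChIP/input
   ratio against log expression (`slope_profile()`), windowed positional
   Pearson correlation between two tracks (`positional_correlation()`),
   expression-matched subsampling (`matched_subsample()`), windowed mean
   comparison with a significance test (`window_mean_compare()`), and
   positional gene-set enrichment around the TSS (`positional_gsea()`);
4. RNA-IP (CLIP) processing: control subtraction, boundary-anchored RNA
   profiles with peak localization, and the ChIP-overlap fraction at a
   minimum read coverage (`subtract_control()`,
   `rnaip_boundary_profile()`, `overlap_fraction()`);
5. expression utilities: TPM, gene-family pool fractions, tissue
   expression ratios and the qChIP 2^-&Delta;&Delta;Ct calculator.

Everything runs on plain text formats (BED12/GTF, fragment BED,
bedGraph, TSV) and on data produced by the package's own synthetic
generator, so each stage is testable without external downloads.

## Coordinates, units and conventions

All internal coordinates are 0-based half-open; conversions happen only
at I/O (GTF is 1-based inclusive, BED 0-based half-open). Coverage at a
base is the number of spanning fragments containing it; RPM is coverage
scaled by $10^6/\text{library size}$, where the library size counts
fragments (one mate pair collapses to one fragment). Anchored matrices
are strand-oriented: positive offsets always point 5'&rarr;3' along the
transcript, and windows that run off a chromosome are *missing*, never
zero-filled — zero-filling would bias profiles of genes near contig
edges.

An intron–exon anchor sits on the first exonic base of an internal exon
(the splice acceptor side); an exon–intron anchor on the first intronic
base after it (donor side). First and last exons contribute no boundary
anchors. On the minus strand the genomic positions mirror accordingly;
a mirror-image genome with flipped strands yields identical profiles
(this is a tested invariant).

## The slope model

For each offset $d$ relative to the intron–exon boundary, let
$r_a(d)$ be the ratio of ChIP to input signal at anchor $a$, formed from
mean RPM in a 20-bp sliding window centred on $d$ with a pseudocount
$\varepsilon$ on both sides:

$$ r_a(d) = \frac{\overline{\mathrm{chip}}_a(d) + \varepsilon}
                 {\overline{\mathrm{input}}_a(d) + \varepsilon}. $$

At every offset an ordinary least-squares line
$r_a(d) = \alpha(d) + \beta(d)\,\log_2(\mathrm{TPM}_a + 1)$ is fitted
across anchors, and $\beta(d)$ with its standard error is reported. A
larger $\beta$ over exonic offsets than intronic offsets means exons
gain the variant faster than introns as genes activate. Columns are fit
independently via the normal equations, which the tests cross-check
against `lm()`.

Defaults: window 20 bp (truncated, not padded, at matrix edges),
$\varepsilon = 0.1$ RPM, log base 2. The source analyses specify "log
expression" without a base or zero-handling rule; base 2 and the +1
pseudocount are this package's documented choices, and because the
slope is reported per offset rather than compared across bases the
choice of base only rescales $\beta$ globally.

## Positional correlation

Two anchored matrices are compared by, at each 50-bp window position
tiling the flank, averaging each track over the window per anchor,
transforming $\log_2(x + \varepsilon)$, and taking the Pearson
correlation across anchors. The statistic is symmetric in the two
tracks and invariant to positive rescaling of either (the log turns a
scale factor into an additive shift). Windows where either vector is
constant give a missing value rather than a spurious correlation.

## Matched subsampling

Cassette (alternatively spliced) exons are a small minority
(the generator default is 13.4%), and their host genes are not
expression-matched to constitutive exons. `matched_subsample()` splits
the target set's $\log_2(\mathrm{TPM}+1)$ values into 20 quantile bins
and samples, without replacement and under an explicit seed, the same
number of pool records per bin; bins with a shortfall borrow from the
nearest bins with a warning. The subset size always equals the target
size, and on skewed pools the Kolmogorov–Smirnov distance between
subset and target log-expression stays below 0.1 in the tests.

## RNA-IP processing

The RNA-IP control (a parallel library on a variant that does not bind
RNA) is removed by per-base subtraction of RPM tracks, clipped at zero
so the result remains a valid coverage-like signal; the treatment of
negative differences is this package's choice, as a subtraction rule
alone does not define one. The overlap fraction asks how much of the
ChIP signal lies under RNA-IP-covered bases: within gene bodies plus
1-kb promoters, bases with at least `min_cov = 30` raw RNA-IP reads
qualify, and the default statistic is the fraction of ChIP
fragment-bases falling on qualifying bases. Because "covers X% of
reads" is ambiguous between reads and bases, a fragment-counting mode
(`mode = "fragment"`) is provided; the base mode is the default. The
fraction is monotone non-increasing in `min_cov`, another tested
invariant.

## Class schemes

* Expression: genes with TPM &lt; 0.1 are `repressed`; the rest split
  into rank tertiles `low`/`medium`/`high`. The four class names come
  from the analysis being reproduced; the numeric cutoffs are package
  choices (flagged here because only the class names are specified
  upstream).
* Signal level: quartiles (`very_low` … `high`) of mean signal in a
  scoring window — offsets &minus;75..&minus;25 for TSS-level ranking,
  0..+150 into the exon for gene-body ranking (typical exons are
  50–200 bp).
* Inclusion: right-closed bins (0,0.2], (0.2,0.4], (0.4,0.6],
  (0.6,1.0], with inclusion exactly 0 folded into `very_low`.

Ties rank deterministically in anchor order, so stratification is
reproducible.

## The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate a toy genome of
non-overlapping multi-exon genes (exon lengths lognormal with median
140 bp, clamped to 60–400 bp, matching the 50–200 bp range typical of
mouse exons; introns ~900 bp), a repressed/expressed TPM mixture (25%
repressed, lognormal otherwise), cassette calls at rate 13.4% with
Beta(2,2) inclusion, and Poisson-sampled fragment libraries
(lengths N(147, 15), centre jitter N(0, 20)) for three ChIP tracks plus
exon-restricted RNA-IP reads.

The structure the generator emulates:

* positioned exonic nucleosomes flanked by depleted linkers, with the
  input (total nucleosome) occupancy *decreasing* with expression;
* a variant-containing nucleosome at ~&minus;50 bp from the TSS whose
  amplitude grows with expression, and exclusion of the variant from
  the +1 nucleosome (footprint 150–300 bp downstream of the TSS);
* an asymmetric variant depletion around exons, deeper on the acceptor
  side, with the variant nucleosome shifted toward the donor edge;
* RNA-IP reads confined to exons, peaking 65 bp inside the exon from
  the acceptor (proportionally closer for short exons), at a rate
  proportional to TPM, over a uniform control background;
* optionally, a coupling `kappa` that scales cassette-exon variant
  occupancy by $1 + \kappa(\psi - 0.5)$, producing inclusion-ordered
  profiles when switched on and none when `kappa = 0`.

**Ratio-scale parameterisation.** The headline estimand is the slope of
the measured ChIP/input ratio versus $\log_2(\mathrm{TPM}+1)$, and the
measurement pipeline smooths per-base intensities with the
fragment-length box, the centre jitter and the 20-bp analysis window.
A slope written directly into per-base amplitudes would therefore *not*
be the slope the estimator sees: kernel mixing shrinks exonic effects
toward intronic ones (exons are barely wider than a fragment), and RPM
normalization rescales the ratio by the two libraries' total
intensities. The generator instead defines `beta_exon` and
`beta_intron` on the measured scale: `build_truth()` computes, from the
realized genome, the expected window-averaged RPM ratio at an exonic
evaluation band (+63..+77, around the typical exon centre) and an
intronic band (&minus;507..&minus;493, mid-intron) through the exact
smoothing kernels — including the first-order ratio-of-counts bias at
the configured depth — and solves a small linear system (with a short
fixed-point loop for the library-size coupling) for the per-base
coefficients that make the expected fitted slope equal the configured
values. The truth object records both the base-level coefficients and
the measured-scale targets; recovery tests compare fitted slopes to the
targets at those bands. The null configuration (`sim_config_null()`)
zeroes *every* expression coupling, including the input occupancy slope
and the TSS amplitude slope, because a non-flat input makes the ratio
weakly expression-dependent through kernel mixing even with no variant
coupling — that would not be a null.

For correlation recovery a dedicated paired-track generator
(`simulate_paired_tracks()`) plants a bivariate-lognormal exonic
amplitude with latent correlation $\rho$ and independent 50-bp intronic
blocks; at the default depth the Poisson attenuation of the measured
log-window-mean correlation is a few percent, well inside the
recovery tolerance.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: mappability and GC bias, duplicate
reads, MNase sequence preference, linker phasing beyond the modelled
depletion dips, overlapping genes and alternative TSSs, isoform
mixtures, and any sequence-level effects (reads are intervals, not
sequences). Conclusions from the tests concern the correctness of the
estimators, not biological effect sizes.

## Numerical choices and degenerate inputs

* Pseudocount 0.1 RPM in ratios and log transforms; zero-handling is
  otherwise unspecified upstream.
* Sliding windows truncate at matrix edges; off-chromosome positions
  are missing and excluded from window means.
* 95% bands are pointwise normal approximations
  ($\pm 1.96\,s/\sqrt{n}$), not bootstrap.
* The TSS-versus-boundary mean comparison uses Welch's two-sided
  t-test on per-region means by default (the upstream analysis reports
  a P-value without naming a test); a Wilcoxon option exists.
* Positional gene-set enrichment uses a one-sided Wilcoxon rank-sum
  per 50-bp window with Benjamini–Hochberg correction across
  window &times; set; sets with fewer than 5 joined genes are skipped.
* Heatmap groups: 100 contiguous rank groups, earlier groups take the
  remainder; fewer anchors than groups degrade to one row per anchor.
* Degenerate cases error early and loudly: empty anchor sets, zero
  library sizes, double RPM normalization, unsorted or overlapping
  bedGraph input (reported with the offending line), constant
  expression, single-region comparisons.

## Problem sizes in the test suite

The shipped tests run the full recovery analyses at reduced but
representative scale, chosen so the suite completes quickly on one
CPU: 300 genes &times; 20 replicate simulations at 2&times;10^5
fragments per library for slope recovery; 5 replicates of 150 genes
for the null; 8 replicates of 500 anchors for correlation recovery;
10^5 RNA-IP reads for peak localization; 50 randomized instances for
the coverage oracle. `scripts/acceptance.R` re-runs the same analyses
from scratch under a caller-supplied seed and writes the headline
numbers as JSON.

## Limitations

The dense per-chromosome track representation targets toy and
synthetic genomes (tens of megabases at most); a production run on a
full mammalian genome would want an Rle or disk-backed store behind the
same interfaces. BAM parsing, duplicate marking and alignment are
assumed to have happened upstream; inclusion fractions are an input
(produced externally by a splicing caller), not computed here.
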