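# metachrom

Landmark-anchored chromatin signal profiles and splicing-linked
positional statistics, for epigenomics analyses that relate a histone
variant's ChIP-seq signal to transcription and exon inclusion.

Short H2A variants (H2A.B / mouse H2A.B.3) destabilize nucleosomes and
are deposited on active genes — at the transcription start site and on
exons at intron–exon boundaries — where their occupancy tracks both
expression and splicing outcomes. Quantifying that requires a family of
positional statistics computed at base-pair resolution around genomic
landmarks, with careful control of the expression confound. `metachrom`
implements the full pipeline on plain-text formats (BED12/GTF, fragment
BED, bedGraph, TSV), driven by a ground-truth synthetic-data generator
so every stage is testable without downloads.

## What it computes

* **Coverage**: paired-end fragments → per-base coverage, RPM
  normalization (`reads per bp per million mapped`), bedGraph I/O.
* **Anchored profiles**: strand-oriented signal matrices around the
  TSS, intron–exon (acceptor) and exon–intron (donor) boundaries; mean
  profiles with pointwise 95% bands; stratification into expression,
  signal-level and inclusion (PSI) classes; metagene scaling to a 0–1
  axis; 100-group rank heatmaps.
* **The slope model**: at each offset `d` around the boundary, fit
  across anchors

  `ratio(d) = alpha(d) + beta(d) * log2(TPM + 1)`,

  where `ratio` is the ChIP/input RPM ratio in a 20-bp sliding window
  (pseudocount 0.1). `beta(d)` larger over exons than introns means
  exons gain the variant preferentially on activation.
* **Positional correlation**: Pearson correlation of log window-mean
  coverage (50-bp windows) between two tracks, per distance from the
  boundary.
* **Expression-matched subsampling** of constitutive exons to a
  cassette-exon target set (20 quantile bins, seeded, without
  replacement).
* **RNA-IP / CLIP**: control-library subtraction (clipped at zero),
  boundary-anchored RNA profiles with peak localization, and the
  fraction of ChIP signal under RNA-IP-covered bases (≥ 30 reads/base
  within gene bodies + 1-kb promoters).
* **Positional gene-set enrichment**: per 50-bp window around the TSS,
  one-sided Wilcoxon rank-sum of in-set versus out-of-set coverage
  ranks, BH-corrected across windows × sets.
* **Expression utilities**: TPM, gene-family pool fractions, tissue
  expression ratios, and qChIP `2^-ddCt` enrichment with replicate SD.
* **Synthetic data**: positioned exonic nucleosomes with depleted
  linkers, occupancy coupled to `log2(TPM+1)` per track (negative for
  input, positive for the variant, parameterised on the measured
  ChIP/input-ratio scale), a TSS nucleosome at −50 bp with +1-nucleosome
  exclusion, exon-restricted CLIP reads peaking 65 bp inside the exon,
  cassette exons at 13.4% with Beta-distributed inclusion, and a truth
  object sufficient to predict every expected profile.

## Worked example

Simulate an experiment with exonic ratio slope 0.4 and intronic slope
0.1, then recover them:

```r
library(metachrom)

cfg <- sim_config(n_genes = 200, beta_exon = 0.4, beta_intron = 0.1)
sim <- simulate_experiment(cfg, seed = 1)

sizes <- sim$genome$chrom_sizes
chip  <- normalize_rpm(compute_coverage(sim$fragments$variant, sizes))
input <- normalize_rpm(compute_coverage(sim$fragments$input, sizes))

anchors <- extract_anchors(sim$genome$models, "intron_exon")
expr <- expression_vector(sim$genome$expression)

sl <- slope_profile(anchored_matrix(chip, anchors, 1000, 1000),
                    anchored_matrix(input, anchors, 1000, 1000),
                    expr, window = 20, pseudocount = 0.1)
subset(sl, offset %in% c(-500, 0, 70, 500))
#>      offset      slope      stderr   n
#> 501    -500 0.10122969 0.002406263 895
#> 1001      0 0.29726852 0.009309365 895
#> 1071     70 0.40206552 0.013599528 895
#> 1501    500 0.07884605 0.003407121 895

mean(sl$slope[sl$offset %in% sim$truth$eval_exon_band])    # 0.402
mean(sl$slope[sl$offset %in% sim$truth$eval_intron_band])  # 0.101
```

The fitted slope is ~0.40 at the exon centre (offset +70), ~0.10 in
the flanking introns (offsets ±500), and intermediate at the boundary
itself, where the 20-bp window and fragment smoothing mix the two
regimes — exons gain signal faster than introns as expression rises,
at the configured rates.

A command-line wrapper covers the same stages
(`inst/scripts/metachrom`):

```sh
metachrom simulate --n-genes 100 --seed 1 --out sim/
metachrom coverage --fragments sim/variant.bed --chrom-sizes sim/chrom.sizes \
                   --rpm --out variant.bedgraph
metachrom slope    --chip variant.bedgraph --input input.bedgraph \
                   --chrom-sizes sim/chrom.sizes --genes sim/genes.bed12 \
                   --expression sim/expression.tsv --out slope.tsv
```

`run_pipeline()` chains simulation, coverage, profiles, slope,
correlation, subsampling and RNA-IP into one seeded, byte-reproducible
run with a checksum manifest.

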