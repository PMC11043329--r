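# mnasequant

Quantitative MNase-seq analysis of promoter nucleosome repositioning, with
a companion broad-peak ChIP-seq caller.

## The problem

During a cell-state transition (the motivating system is C2C12 myoblasts
differentiating into myotubes), promoter nucleosomes need not be gained or
lost in bulk — they can be *repositioned*: a nucleosome slides toward the
3' end, builds up at a repressive position, or is evicted from the
transcription start site. Genome-browser views of MNase-seq make such
changes easy to describe and hard to test. `mnasequant` implements a
statistical pipeline that asks, for an a priori defined *group* of genes
(lineage-specific marker sets instead of gene-ontology terms), whether
nucleosome occupancy changed *significantly* at each base pair of the
promoter.

## The method

Promoters are the windows `[-3000, +1000)` bp around each TSS, handled in
a strand-aware TSS-anchored frame at 1-bp resolution, with no smoothing.

1. **Coverage.** Aligned paired-end fragments are size-selected to the
   mononucleosome band (130–200 bp inclusive) and only the 3 bases at each
   fragment center are counted (`c = floor((start + end - 1)/2)`).
2. **Normalisation.** For gene *x*,
   `normalized count[p] = count[p] / Σ count[x]`, so every promoter has
   equal weight; the repositioning statistic is the per-base difference
   `Δ[p] = normalized_myotube[p] − normalized_control[p]`, which sums to 0.
3. **Testing.** At each of the 4000 offsets, a two-sided paired t-test
   across the genes of a group (default α = 0.05 per 1-bp window;
   Benjamini–Hochberg adjustment available).
4. **Regions.** Runs of significant same-sign offsets are merged (gap
   ≤ 25 bp, width ≥ 10 bp) and classified: a mass-balanced loss→gain lobe
   pair is a `downstream_shift`, gain→loss an `upstream_shift`, isolated
   gain a `buildup`, isolated loss a `loss`.
5. **Modelling & comparison.** Two-peak spans are fit with a sum of two
   Lorentzians, multi-peak spans with an integral-preserving smoothing
   spline; groups are compared by Pearson correlation of their mean
   Δ-profiles over the called regions (|R| > 0.7 flagged strong).
6. **ChIP.** Binding values are input-subtracted normalised coverage;
   sites are seeded where the value exceeds the window mean + 4 SD,
   extended to the mean + 1 SD envelope, and validated across replicate
   libraries.

A seeded synthetic-data generator (`synthetic_spec()`,
`simulate_dataset()`) plants nucleosome arrays, shift/loss/build-up
perturbations and ChIP enrichment boxes with known ground truth, so every
stage is testable end to end.

## Worked example

```r
library(mnasequant)
cfg <- run_config(spec = demo_spec(seed = 1), p_adjust = "BH",
                  out_dir = "demo_out")
res <- run_pipeline(cfg)
res$regions
```

```
  label start_offset end_offset width direction    mean_delta   classification unit
1     A        -2501      -2401   101      loss -0.0003803195 downstream_shift    1
2     B        -2381      -2291    91      gain  0.0003943503 downstream_shift    1
3     C        -2100      -2001   100      gain  0.0004897135          buildup    2
4     D         -640       -526   115      loss -0.0003465719 downstream_shift    3
5     E         -517       -396   122      gain  0.0003001029 downstream_shift    3
6     F           -4         20    25      loss -0.0003194328             loss    4
7     G          524        640   117      loss -0.0003483270 downstream_shift    5
8     H          654        737    84      gain  0.0004119381 downstream_shift    5
```

The demo generator plants five repositioning events in the skeletal-group
myotube promoters; the pipeline reports eight significant regions that
classify into exactly those five units: three downstream shifts (paired
loss/gain lobes, units 1, 3 and 5), one build-up near −2 kb (unit 2) and
one narrow nucleosome loss straddling the TSS (unit 4). `mean_delta` is in
normalised-count units (each promoter's total signal is 1). Alongside,
`res$correlations` holds the group-by-group Pearson matrices per region,
`res$chip$census` the count of genes per group with a validated 4σ
binding site, and `res$files` the paths of the written report tables.

A thin command-line wrapper is installed at
`inst/cli/mnasequant.R` (`simulate` and `run` subcommands).

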