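---
title: "Quantifying promoter nucleosome repositioning from MNase-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter nucleosome repositioning from MNase-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnasequant)
```

## The model

MNase digestion leaves nucleosome-protected fragments; in a titrated
digest the library is a mixture of mononucleosomes (~150 bp) and residual
dinucleosomes (~300 bp). `mnasequant` treats the promoter of each gene as
a fixed 4000-bp window, `[-3000, +1000)` around the TSS in a strand-aware
frame (offset 0 is the TSS base; on minus-strand genes the frame mirrors
around the TSS so upstream/downstream are transcriptional). Size-selected
fragments (130–200 bp, bounds inclusive — "between" is read inclusively
and both bounds are exposed as configuration) contribute only the 3 bases
at their center, `c = floor((start + end - 1)/2)`; the left-of-middle
convention for even-length fragments is arbitrary but fixed, so results
are reproducible.

Per-promoter coverage is normalised to its own sum,

$$v_x[p] = \frac{c_x[p]}{\sum_{q} c_x[q]},$$

so each gene carries equal weight regardless of sequencing depth or local
mappability, and the per-gene repositioning statistic is the difference of
normalised profiles, $\Delta_x[p] = v_x^{myo}[p] - v_x^{ctrl}[p]$, which
sums to zero by construction: the statistic sees mass *moved*, not mass
gained. Genome-size (1×-depth) normalisation is available for track
comparability but cancels out of every downstream quantity; tests assert
that applying it before or after window extraction changes nothing.

The group-level test is deliberately simple and smoothing-free: at every
offset, a two-sided paired t-test of $\Delta_x[p]$ across the $n$ genes of
an a priori group (lineage marker sets rather than ontology terms; the
packaged configuration has 12 skeletal-muscle-specific, 9 common-muscle,
6 heart-muscle-specific and 26 non-muscle genes). The test is paired
within genes, across conditions; replicate-level pairing is not modelled.

### Zero-variance offsets

With discrete counts two degenerate cases arise. If all paired
differences are exactly zero the offset is null and gets $p = 1$. If the
differences are identical but non-zero the t statistic is formally
infinite; rather than reporting $p = 0$ the offset is flagged
`degenerate` and included in the significance mask, so the pathology is
visible instead of silently extreme.

## Region calling and classification

Significant offsets of a common difference sign are merged into regions,
bridging internal gaps of at most `max_gap = 25` bp — but never across an
opposite-sign significant offset — and regions narrower than
`min_width = 10` bp are dropped. Neither parameter has a principled
universal value; the defaults were chosen so that a biologically real but
narrow (~16 bp) TSS-proximal loss region survives calling, and both are
exposed in the configuration.

Classification reads the region pattern the way a chromatin biologist
would: a loss lobe followed within `pair_distance = 300` bp by a gain
lobe is one nucleosome moving toward the gene's 3' end
(`downstream_shift`); the reverse order is an `upstream_shift`; isolated
gains and losses are `buildup` and `loss`. Two refinements make the rule
robust on noisy masks. Pairing looks ahead past intervening
same-direction regions, and two lobes only pair when their integrated
differences are mass-balanced (the smaller $|\bar\Delta \times width|$
must be at least `balance_frac = 0.25` of the larger): a genuine shift
relocates conserved signal mass, so a strong build-up should not be
re-labelled a shift because a marginal opposite blip sits nearby. Paired
lobes share a `unit` id, so one shift counts as one repositioning event.

### Multiple testing, honestly

The pipeline's default is the per-1-bp uncorrected α = 0.05. That choice
maximises fidelity to the headline procedure, but its consequence should
be understood: 4000 tests at 5% produce ~200 false-positive offsets per
group, and with a 25-bp bridge these chain into spurious
minimum-width regions — on null data the caller reports dozens of small
regions, not zero. The planted-truth recovery tests and the packaged
benchmark therefore score region *sets* with the Benjamini–Hochberg
option enabled (`p_adjust = "BH"`), under which the demo's five planted
events are recovered exactly and the false-discovery background
disappears. Detection of individual true regions works under either
setting; counting regions cleanly requires the correction. Both modes are
one flag apart, and the uncorrected default remains for procedural
fidelity.

## Difference-profile regression

For visual overlay and effect summarisation the group-mean Δ-profile is
fit with a "best-fit model" curve chosen by a coarse peak count (local
extrema of the 50-bp-binned span):

* **≤ 2 peaks: sum of two Lorentzians.**
  $y = b + \sum_{k=1,2} A_k / (1 + ((x - x_{0k})/\gamma_k)^2)$ with signed
  amplitudes, centers in bp and half-widths $\gamma_k > 0$. Least squares
  via Levenberg–Marquardt with a deterministic multi-start grid: centers
  seeded at the largest-|y| coarse extrema (plus the global extremes of a
  finer binning, which catches lobes at the span boundary), amplitudes at
  the signal values there, half-widths over {25, 50, 100} bp. The best
  single-Lorentzian fit is embedded as a candidate with $A_2 = 0$, which
  guarantees the nested-model inequality (two-component RSS never exceeds
  one-component RSS) on every input. The fit is translation-invariant and
  recovers noiseless planted parameters to well under 1%.
* **> 2 peaks: constrained smoothing spline.** A cubic smoothing spline
  (GCV-chosen λ by default) post-constrained to preserve the data's
  integral by a constant shift — Δ-profiles must keep their ~0 total.
  "Constrained" is an interpretation fixed by this package; a
  non-negativity clamp for occupancy profiles is available behind a flag.
* **Fourier diagnostic.** `dominant_frequency()` reports the largest
  non-DC spectral component; on unsmoothed 1-bp difference profiles the
  power never concentrates (the dominant period is the observation window
  itself) and the signal is flagged as having no periodic structure —
  which is exactly why spectral smoothing is not used for regression
  here.

Fitting can be run over region-local spans (the default in the pipeline,
±100 bp around each classified unit) or the whole promoter; the span
choice is reported alongside the parameters.

## Group comparison

Pearson's R between group-mean Δ-profiles, restricted to each called
region of a designated reference group (default: the skeletal group's
regions) and, for contrast, over the whole 4000-bp window; |R| > 0.7 is
flagged strong. Zero-variance spans yield missing values rather than
fabricated correlations. On the demo data the whole-promoter correlations
are near zero while region-restricted ones are strong — regional
coherence with global independence.

## The 4σ ChIP caller

For chromatin-binding proteins whose broad peaks defeat narrow-peak
callers, binding values are computed per gene window as
$b[p] = v^{IP}[p] - v^{input}[p]$ (both sum-normalised, so depth cancels
and the values sum to 0), and the threshold statistics are the mean and
SD *of the per-offset values across the full 4-kb window* — the one
reading under which "the SD of the sum" is well defined. Seeds are
offsets with $b[p] > \mu + 4\sigma$; each site is the maximal run above
$\mu + 1\sigma$ containing a seed (the extension multiplier is
configurable; seed-only mode exists). The rule is affine-invariant, and
on i.i.d. Gaussian nulls its seed rate matches the analytic one-sided
tail beyond 4 SD (≈ 3.17 × 10⁻⁵; the package reports the corresponding
confidence as `sigma_confidence(4)` = 99.997%, which exceeds the 99.8%
conventionally quoted for this threshold).

Two caveats are documented deliberately. First, real binding values are
not homoscedastic: their variance scales with local chromatin intensity,
so the window-global σ under-states the noise at nucleosome dyads and the
seed rule is anticonservative there. Second, for that reason a site is
only *validated* when called independently in both replicate libraries —
spurious exceedances are narrow and positionally random and rarely
reproduce, while genuine broad sites always do. With two replicates the
demo's background census drops from every gene to a small minority, and
every planted site survives.

Downstream reports: per-group/condition censuses of genes with ≥ 1
validated site (a gene counts once), retention of control sites in
myotubes (≥ 1 bp intersection on the same gene), summed Δ nucleosome
content under each site, and site positions relative to the TSS and the
called regions (500-bp histogram).

## What the generator emulates — and what it does not

`synthetic_spec()` fixes the study conditions for all tests:

* nucleosome arrays phased on the TSS, 190-bp mean spacing, 20-bp
  per-dyad jitter (drawn once per gene, so the two conditions of a gene
  share one architecture — the paired design is real), 30-bp occupancy
  SD, and a phase placing one dyad just downstream of the TSS (+10) as a
  +1 nucleosome;
* a fragment-length mixture of 95% mononucleosomes N(165, 10²) and 5%
  dinucleosomes N(330, 20²), emulating a digest in which dinucleosomes
  are almost fully digested; the size filter then removes the
  dinucleosome mode;
* multinomial sampling of fragment centers from the per-bp intensity
  (counting noise), 5000 fragments per promoter and condition by default
  — per-bp center coverage ≈ 3.8, a deeply covered promoter;
* perturbations applied to the myotube intensity of an affected group:
  `shift` relocates all intensity in a region by δ bp, `loss`/`buildup`
  scale it by a factor — sharp-edged by construction, so planted
  boundaries are meaningful ground truth;
* ChIP enrichment boxes multiplying the IP intensity by a fold inside an
  interval, input following the MNase architecture, two replicate
  library pairs per condition.

The generator does **not** emulate mappability and GC artefacts,
digestion-bias or sequence-dependent MNase preference, biological
architecture diversity across genes beyond phase jitter, batch effects
between replicates, or genome-scale background outside the promoter
windows. Passing tests therefore demonstrate the pipeline's statistical
correctness and its recovery of planted effects under honest noise — not
robustness to every artefact of real libraries.

## Numerical choices and problem sizes

All randomness flows from one integer seed through per-gene,
per-condition, per-replicate derived streams, making full runs
byte-identical. Default problem sizes used by the test suite (the
package's own choices): null calibration uses 12 genes × 4000 offsets ×
20 replicates; the 4σ null uses 10⁷ simulated offsets; planted-effect
recovery uses 100 seeded runs of 12 genes; Lorentzian recovery uses 100
noisy fits at noise SD = 0.1 × amplitude. Region-set benchmarks run the
packaged `demo_spec()` (four groups at the study sizes, five planted
events, ChIP boxes 2–3 kb upstream).

Degenerate inputs are handled explicitly rather than crashing: zero-sum
promoters are flagged and excluded from testing with a warning,
zero-variance ChIP windows call no sites, single-group runs skip the
between-group stages, and a flat profile counts zero nucleosomes.
Nucleosome counting (10-bp binning, 120-bp minimum separation, 10%
height threshold) is kept fully separate from the Δ pipeline, which never
smooths.

## Known limitations

* The uncorrected per-bp default cannot by itself produce a short clean
  region list (see the multiple-testing section); region-set claims
  should use the BH mask or stricter α.
* One TSS per gene; no isoform logic, no genome-wide scanning beyond the
  configured promoters, no HMM/Poisson-mixture positional modelling —
  the method's point is to stay close to the raw counts.
* The 4σ caller inherits the heteroscedasticity caveat above; replicate
  validation mitigates but does not remove it.
* Group membership is taken purely from configuration; with N between 6
  and 26 genes per group, power differs visibly between groups, and
  region boundaries for build-ups taper with the occupancy bell rather
  than tracking the perturbed interval exactly.
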