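---
title: "Models and methods behind scduoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scduoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scduoqc` evaluates paired single-cell DNA/RNA preparations. This vignette
documents the statistical models, the synthetic-data generator that stands
in for sequencing data, the numerical conventions, and the design choices
made where the problem left the design open. Nothing here asserts an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate and format conventions

All intervals are 0-based half-open internally; VCF positions (1-based)
are converted on read and write. Strand is ignored throughout — every
bin- and region-level statistic here is unstranded. SAM flag bits used are
0x4 (unmapped), 0x2 (properly paired) and 0x400 (duplicate). Alignment
fraction is over all reads; duplication, proper-pairing and
mate-on-other-chromosome fractions are over *mapped* reads, a choice that
had to be made because the usual figure legends do not state denominators.

## Coverage uniformity

Whole-genome amplification from a single cell's two template copies
produces locus-dependent gain that is *spatially correlated*: neighboring
regions are over- or under-amplified together. Three complementary
statistics quantify this.

**Bin-to-bin CV** uses the sample (n−1) standard deviation over the mean.
Pure Poisson sampling at depth d gives CV ≈ 1/√d, so excess CV is
amplification bias.

**Lorenz curve.** Bins sorted ascending by count; x = cumulative genome
fraction, y = cumulative read fraction, anchored at (0,0); area by the
trapezoidal rule. Perfect uniformity is the diagonal (AUC = 1/2);
concentrating all reads in one of n bins leaves a single triangle of area
1/(2n). The curve is computed from per-bin read counts as a proxy for
mapped bases — at fixed read length the two are proportional. AUC strictly
decreases under any mean-preserving transfer from a poorer to a richer
bin, which the property tests exercise with random transfers.

**Power spectrum.** Per chromosome, the relative-depth signal
x_b = c_b/c̄ − 1 is Fourier transformed and psd_k = |X_k|²/N is reported at
frequency k/(N·bin_size), k = 1..N−1. This convention is chosen so the
Parseval identity Σ psd = N·var(x) is *exact* (machine precision), giving
the tests a closed-form anchor. No windowing or detrending beyond mean
removal is applied; spectra are computed per chromosome (never on the
genome concatenation, which would inject spurious power at junctions),
interpolated to the longest chromosome's frequency grid, and averaged.
The scalar summary is the mean power at frequencies above 1/500 kb, i.e.
genomic length scales finer than 500 kb. That band is empty unless bins
are finer than 250 kb (Nyquist = 1/(2·bin_size)); the function returns NA
in that case rather than silently changing the band, and synthetic PSD
analyses in this package use 10-kb bins.

## The synthetic generator: a stated world

The generator emulates what the analyses must distinguish, with every
parameter either fixed by the emulated setting or chosen once and
documented here.

**WGS counts.** Per cell, counts are Poisson(depth · cn_b/2 · bias_b)
with log bias an AR(1) Gaussian process per chromosome, mean-centered so
bias is depth-neutral. `bias_sigma` is the **innovation** (conditional)
standard deviation, so the marginal sd is bias_sigma/√(1−ρ²). This
parametrization was a deliberate choice: with marginal sd held fixed, an
AR(1) spectrum is monotone decreasing in frequency, so raising ρ can only
*remove* power from any band excluding zero frequency — no parameter
setting could make correlated bias raise the fine-scale PSD summary. With
innovation sd fixed, raising ρ adds power at every scale, most strongly at
coarse scales, which is the qualitative signature of WGA bias the
uniformity statistics are built to detect. Defaults bias_sigma = 0.3,
bias_rho = 0.5 are calibration choices (the emulated protocols' bias
spectra are not quantitatively characterized), giving CV ≈ 0.4–0.5 at
500 reads/bin — single-cell-WGA-like, clearly worse than the Poisson
floor, while bulk-like data is recovered by bias_sigma = 0.

**scRNA counts.** Gene g in cell c is Poisson(lib_c · p_g) thinned by a
gene-level Bernoulli with detection probability
logit⁻¹(slope · (log μ − midpoint)) — the standard logistic-dropout
picture in which weakly expressed genes fail to be captured. Library
sizes are lognormal with sd 0.3 (a typical cell-to-cell spread; the
lognormal mean is offset so E[lib] is the nominal size). ERCC spike-ins
pass through the same library-size and Poisson noise but are never
dropout-thinned: they are exogenous standards added in equal amounts to
each cell, and their input–output correlation is exactly what the
calibration metric measures.

**SNV calls.** Each cell's set is a Bernoulli(sensitivity) thinning of
the planted truth plus Poisson(fp_rate) false positives at random
non-truth positions. The plug-in expectation for bulk concordance,
|T|·s / (|T|·s + E[FP]), is verified by simulation in the tests.

**Contamination.** A Binomial(n, rate) subset of the RNA fraction's reads
(exonic-enriched by construction) moves into the DNA fraction, and vice
versa; total reads are conserved. Contaminant reads are duplicate-marked
with probability 0.25 and baseline reads with 0.0066 — the two duplication
regimes observed for unseparated versus separated preparations — so the
coding-region duplication rate responds to contamination just as the
exonic fraction does.

**Reproducibility.** A single master seed expands to per-cell substreams
via a fixed affine map mod 2³¹−1 (computed in double precision to avoid
32-bit overflow), so cell i's data are independent of n_cells and all
outputs are bit-identical across runs. The determinism criterion tests
this end-to-end, including the full pipeline's summary file.

What a green test does *not* establish: the generator has no GC bias, no
mappability structure, no sequencing-error model, no UMIs, no
base-resolution reads, and dropout acts on genes rather than reads. Green
acceptance means the *statistics and algorithms* are correct on data whose
generating process is known — not that the defaults reproduce any
particular instrument's noise.

## Copy-number profiling

Per-cell counts are normalized to log2(c_b/c̄) over usable (positive)
bins; zero-count bins are masked. Each profile is normalized to its own
mean — relative copy number, appropriate to a setting with no matched
normal. Optional GC correction divides counts by their GC-decile median
(off by default; the emulated data carry no GC structure).

**Segmentation** is circular binary segmentation: for the current
segment, maximize over boundary pairs (i, j) the statistic
|mean(i,j] − mean(complement)| · √(n₁n₂/n), and accept the split if the
observed maximum exceeds the (1−α) quantile of the same maximum under
within-segment permutation; recurse on the up-to-three resulting pieces.
Numerical choices:

- The known-variance z form is used instead of the pooled-variance t.
  The segment's residual scale is a constant factor within a segment and
  cancels between observed and permuted statistics, while avoiding the
  0/0 degeneracy of a pooled sd on noiseless steps. A constant segment
  has statistic 0 and is never split.
- An arc and its complement define the same partition and the same
  statistic; the exhaustive-oracle tests therefore compare canonical cut
  sets, not (i, j) labels.
- Permutation testing stops early once rejection is certain (the
  exceedance count passes α(n_perm+1)−1), with the permutation stream
  seeded from `cbs_params` for bit-reproducibility.
- No "undo"/pruning pass is applied: at desk scale with the effect sizes
  of interest (|Δlog2| ≥ 0.4) it changes nothing; noted as an extension
  point.
- Masked bins are excluded from all statistics and assigned afterwards to
  the enclosing segment on their right (the first segment absorbs leading
  masked bins and the last absorbs trailing ones), keeping segments a
  partition of all bins.
- min_width defaults to 3 bins; α = 0.01 and n_perm = 1000 by default,
  with n_perm lowered (100–200) in replicated simulations for speed —
  stated wherever done.

Clustering of profiles uses Euclidean distance with Ward linkage
(`hclust(method = "ward.D2")`), dropping bins masked in any profile; two
singletons merge at exactly their Euclidean distance, which the tests
assert as the Ward base case.

## RNA metrics

Gene detection is raw count ≥ 1 (configurable; the emulated protocol's
exact rule is not public). Normalization for correlations, binning and
cell-cycle scoring is log2(CPM+1) — standard, monotone, and
desk-verifiable. Saturation subsampling is multivariate hypergeometric
(without replacement) and *nested across depths within a replicate*, so
each replicate's detection curve is monotone by construction, while each
depth's marginal distribution remains exact. The analytic
with-replacement curve Σ(1−(1−p_g)^n) anchors the Monte-Carlo test at
large counts. Body coverage takes per-transcript coverage vectors on a
0–100 percentile grid (computing coverage from alignments is out of
scope), ranks transcripts by expression, and averages the top/middle/
bottom class of 1000 (middle = ranks ⌊(n−1000)/2⌋+1 …+1000), normalizing
to the class maximum. Housekeeping selection takes the k = 8 lowest-CV
genes among the top decile by mean, ties broken by gene id; the cell
filter requires a configurable number of them detected. Cell-cycle calls
are argmax of mean per-phase marker z-scores with an `unassigned` outcome
when the top two scores are within `tie_tol` — a deliberately transparent
classifier; marker lists (e.g. a 874-gene cell-cycle panel) are an input.

## Integration

Genes map to the single bin containing their TSS — an unambiguous
partition. Expression is binned per cell and then averaged across cells
(cell-averaging after binning; the alternative order was open and this
one was fixed as the default). The dosage correlation uses CBS segment
means on the DNA side by default (raw log2 mode available): segment means
are the denoised copy-number estimate, and correlating them against
binned expression is the cleaner test of a dosage effect. The bulk
regression draws n cells without replacement, fits OLS with intercept
across genes, and reports adjusted R² = 1−(1−R²)(G−1)/(G−k−1) where k is
the rank actually used (collinear columns are dropped with a warning).
SNV concordance is directional — the fraction of *cell* calls present in
bulk — matching the verification framing, not a symmetric Jaccard index.
qPCR recovery is efficiency^(Cp_ref − Cp_fraction) with efficiency 2
(perfect doubling) by default.

## Pipeline and configuration

The `run` pipeline executes simulate → genome-qc → cnv → rna-qc →
integrate, writing per-stage TSVs, a `summary.json` and a log with
version and seed. All randomness flows from the config seed; no stage
reads the wall clock. Configuration is JSON only — no YAML parser is a
declared dependency of this package, and one format suffices.

## Known limitations

- CBS is O(n²) per split search; fine for ≤ a few thousand bins per
  chromosome, not for base-resolution data.
- The generator's contamination acts on annotated read tables, not
  sequences; alignment-level artifacts of chimeric libraries are not
  modeled.
- GC correction is offered but untested against real GC structure (the
  generator produces none).
- Absolute (integer) copy-number calling, sub-bin breakpoint refinement
  and allele-specific CNV are out of scope.
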