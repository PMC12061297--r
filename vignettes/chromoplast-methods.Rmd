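---
title: "Methods: chromatin packing, plasticity and heterogeneity analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin packing, plasticity and heterogeneity analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(chromoplast)
```

`chromoplast` implements the quantitative core of a multi-omic view of
cancer-stem-cell (CSC) transcriptional plasticity: label-free chromatin
packing imaging, bulk-RNA plasticity statistics, single-cell heterogeneity,
and CUT&Tag peak analytics. This vignette explains the models, the
parameters that matter, and the design choices taken where the underlying
procedures leave the design open.

## 1. PWS imaging: from spectral cubes to D_n

Partial wave spectroscopic (PWS) microscopy records a 3D image cube
I(&lambda;, x, y) of backscattered intensity, together with a reference cube
from a cell-free region of the dish. Nanoscale chromatin density
fluctuations modulate the spectrum pixel by pixel, so the sample standard
deviation of the reference-normalized spectrum at each pixel, &sigma;(x, y),
encodes the local chromatin packing scaling exponent D (genomic length
N &prop; R^D for a mass-fractal packing domain). The analysis chain is:

1. zero-phase Butterworth low-pass along the wavelength axis
   (`butterworth_lowpass()`, default order 2, cutoff 0.2 cycles/sample) to
   suppress high-frequency illumination noise. Defaults are configurable;
   the filter is applied forward-backward with mean removal and
   odd-reflection padding so constants pass exactly and edge transients do
   not contaminate the 86-plane record;
2. elementwise division by the reference cube (`normalize_reference()`);
3. the per-pixel spectral standard deviation (`spectral_sigma()`);
4. inversion through a calibration model to D_a(x, y) (`sigma_to_d()`), and
5. the nuclear average D_n over a nucleus mask (`nuclear_dn()`).

**The calibration is pluggable by design.** The closed-form &sigma; &harr; D
mapping depends on a priori optical instrument parameters and on the assumed
chromatin density autocorrelation function, which live outside this package.
`calibration_model()` therefore accepts any strictly increasing family on an
open D domain (default (1, 3)); linear `sigma = b (D - 1)` with b = 0.05 on
normalized-intensity scale is the shipped default, and every test of the
imaging chain is calibration-family independent (round trips, monotonicity,
scale invariance). Absolute D values on real cubes depend on supplying the
instrument's own calibration. Pixels that invert outside the domain are
clipped to the domain edge and counted — never dropped — so masked averages
keep their pixel counts.

Population comparison (`compare_populations()`) uses Welch's unpaired,
unequal-variance t-test against the control group, with the significance
threshold 0.05/N for N groups, and reports group means normalized to the
control mean.

**What the generator emulates.** `gen_pws_cube()` plants a known D map: the
per-pixel fluctuation is a sum of low-frequency sinusoids standardized to
unit sample sd and scaled by calib.forward(D), plus additive white Gaussian
measurement noise (default 5% of signal). Placing the D-encoding power well
below the filter cutoff is deliberate: the analysis filter then passes the
signal essentially unchanged while attenuating roughly half of the white
noise power, mirroring the role of the filter on real LED-illuminated
cubes. What this does *not* emulate: real optics (coherence volumes,
point-spread functions), spatially correlated nuclear texture, or the
instrument's true calibration — recovery tests demonstrate the pipeline's
correctness, not instrument accuracy. Simulated nuclei use 24 × 24-pixel
cubes with an elliptical mask and 30 nuclei per group at D_n means
2.34 (CSC-like) and 2.05 (non-CSC-like), sd 0.1 — the regime the package
targets; these sizes keep a full two-group recovery under half a minute on
one core.

## 2. Transcriptional plasticity from bulk RNA-seq

The plasticity analysis follows a fixed order of operations
(`tpm_from_counts()`, `clean_expression()`, `lfc_gate()`,
`quantile_response()`, `lowest_decile_lfc()`):

1. TPM from counts and gene lengths; every sample sums to 10^6;
2. cleaning, in exactly this order: remove ERCC spike-ins and NaN genes,
   renormalize each sample to 10^6, remove genes with a zero in **any**
   sample, then average replicates. The cleaned table is zero-free, so log2
   fold changes need no pseudocount (one is available for user data);
3. a |log2FC| &ge; 1 gate between control and stressor-treated samples. The
   gate operates on genes — the upstream object is a gene table — with the
   threshold configurable;
4. response curves: genes binned into baseline-expression quantiles (rank
   bins, sizes differing by at most one, ties broken by gene id), mean
   change per bin with SEM. Whether the change is a TPM difference or an
   LFC is selectable (`delta =`); the default is the TPM difference;
5. the lowest-decile analysis: deciles are formed over the *gated* genes of
   a chosen source group, the lowest decile extracted, and the LFC of those
   genes evaluated in every response pair. Each distribution is summarized
   by mean, sd, a Gaussian KDE (Scott bandwidth, 512-point grid) and the
   sample bimodality coefficient b = (skewness&sup2; + 1)/kurtosis with the
   uniform-reference threshold 0.555: a Gaussian gives 1/3, a symmetric
   well-separated mixture approaches 1. The coefficient makes the visual
   "bimodal vs unimodal" read-out reproducible; it is a screening statistic,
   not a test.

**Generator.** `gen_bulk_expression()` draws negative-binomial counts
(dispersion 0.1) with baseline expression log-uniform over four decades —
wide enough that decile binning is non-degenerate and low-baseline genes
still have expected counts &ge; 10, keeping zero-driven gene loss rare. The
lowest baseline decile of the CSC-like cell type carries a symmetric
two-component LFC mixture (&plusmn;2, component sd 0.5, 50/50 weights); the
non-CSC-like lowest decile carries a single positive-mean LFC (+2, sd 0.5).
The mixture means are config; the procedures upstream describe the CSC
response only qualitatively ("bimodal" vs "mostly upregulated"), and
&plusmn;2 with sd 0.5 gives a population-level bimodality coefficient near
0.8 against 1/3 for the unimodal arm — separated enough that measurement
noise, the fold-change gate and decile re-selection leave the
classification correct in &ge;95% of seeded runs. Real bulk data differ in
ways the generator does not model: library-composition effects, correlated
genes, batch structure.

## 3. Intercellular heterogeneity from single cells

`qc_filter()` applies the standard single-cell gates in a fixed order:
genes detected in &ge;3 cells are kept, then cells are dropped when they
have fewer than 200 detected features, fewer than 20,000 or more than
100,000 total reads (both boundary values are kept), or a mitochondrial
fraction of 15% **or more** ("MT"-prefixed genes). The boundary conventions
are part of the contract and are tested at the exact threshold values.
`lognorm_hvg_scale()` log-normalizes (scale factor 10^4), ranks genes by
standardized variance around a loess mean–variance trend (the standard
VST-style fit), and centers/scales the top 2000 with clipping at ±10.
`pca_embed()` returns the first 20 SVD-based components with a
deterministic sign convention.

The heterogeneity statistic is the **radius of genomic space**

Rc = sqrt( (1/N) &Sigma;_i || r_i − r&#772; ||&sup2; ),

the RMS distance of cells from their centroid in a 3D expression embedding.
For an isotropic Gaussian cloud E[Rc&sup2;] = 3&sigma;&sup2;(N−1)/N, which
the tests use as a closed-form oracle. Rc is translation- and
rotation-invariant and scales linearly with the coordinates. Two readings
of the statistic circulate — an enclosing-sphere radius and the RMS
formula; the RMS formula governs this implementation.

The 3D embedding itself is a pluggable contract: any function from the PC
matrix to 3 coordinates can be used. A deterministic fallback
(`embed_pca3()`, the first three PCs) ships so that no test or pipeline
depends on a stochastic t-SNE. Because conditions differ in cell count,
`radius_of_genomic_space()` reports three equalization modes: `none`,
seeded `subsample` to the smallest condition (default for comparisons), and
`weights` (per-cell weights 1/N_condition, which equal `none` within a
single condition and matter only for pooled estimates); the exact weighting
mechanics upstream are unstated, so all three are exposed.

## 4. Chromatin-mark peak analytics

All interval work uses 0-based half-open (BED) coordinates at the surface
and GenomicRanges internally.

- `gate_differential()` keeps peaks with p strictly below `p_max`. Default
  0.1 (the per-chromosome analysis inclusion rule); an adjusted-p gate at
  0.05 is available via the arguments, since both rules appear in the
  source procedures.
- `per_chromosome_density()` **merges** overlapping intervals before
  summation, so density = merged bp / chromosome length is always in
  [0, 1] and merging is idempotent; "total segment length" without merging
  would double-count overlapping differential peaks. chrX is excluded by
  default, reflecting its distinct heterochromatin regulation.
- `density_regression()` is OLS of one mark's density on the other across
  chromosomes; R&sup2; is the squared Pearson correlation.
- `assign_peaks_to_tss()` associates a peak with a gene iff it overlaps the
  promoter window [TSS − 2 kb, TSS + 2 kb) by &ge;1 bp; a peak may serve
  multiple genes; strand does not move the window. `call_poised()`
  intersects the H3K4me3 and H3K27me3 gene sets ("poised"/bivalent genes)
  and reports per-cell-type counts and the fold ratio.
- `annotate_peak_features()` classifies each peak by its midpoint with the
  fixed priority promoter &gt; exon &gt; intron &gt; intergenic (the
  upstream annotator is unnamed, so the rule is stated rather than
  inherited).
- `promoter_signal_matrix()` computes per-gene, per-bin (default 50 bp over
  ±2 kb) mean coverage in two conditions and log2((A + 1)/(B + 1)); rows of
  minus-strand genes are reversed so all rows read 5'&rarr;3'.
  `cluster_promoters()` runs Lloyd k-means (default K = 6) with a fixed
  seed and 10 random restarts, keeping the best inertia — restarts rather
  than k-means++ initialization, which base R does not provide; with 10
  restarts on signal matrices of this size the best-inertia solution is
  stable across seeds in practice.

**Peak generator.** `gen_peaks()` constructs, per chromosome and mark,
non-overlapping sorted intervals whose summed length equals the target
density to within 1 bp (multinomial splits of the covered and uncovered
basepairs). Cross-mark per-chromosome densities are drawn bivariate normal
with correlation &rho; (default 0.82, mean 0.10, sd 0.02 — comfortably
inside (0, 1) so no clipping distorts the correlation). The toy genome is
22 autosomes (5–20 Mb) plus chrX. `gen_annotation()` places TSSs in
peak-free regions and then appends promoter-proximal peaks so that exactly
the planted gene set is bivalent; because of that augmentation it returns
the updated mark sets alongside the annotation.

## 5. Numerical conventions and degenerate inputs

- Deciles/quantiles are rank bins with sizes differing by at most one;
  ties break by stable gene-id order.
- A constant response in `density_regression()` yields R&sup2; = 0 (the
  0/0 case is resolved to "no variance explained").
- Empty masks, empty deciles, all-zero samples, non-invertible
  calibrations, cells that all fail QC, and peaks beyond chromosome ends
  are rejected with informative errors, not silently repaired.
- Every generator takes a seed, restores the caller's RNG state, and is
  byte-reproducible for a fixed configuration.

## 6. Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything from code:
60 simulated nuclei (24 × 24 × 86 cubes), 4000-gene bulk tables across 8
samples with 200 seeded replicate runs, 5000-point embeddings, 500
replicate peak-density regressions on the 23-chromosome toy genome, and
100-cell matrices. These sizes were chosen so each stage's sampling error
sits well below the effect sizes being recovered while a full run stays in
the minutes range on a single core.

## 7. Known limitations

- Absolute D quantification requires the instrument calibration; the
  package validates the pipeline around any monotone calibration, not the
  optics.
- The bimodality coefficient is threshold-based; borderline mixtures
  (small separation, unequal weights) can fall on either side of 0.555.
- t-SNE is intentionally not bundled; Rc values depend on the embedding
  supplied, and only the embedding-independent properties of Rc are
  guaranteed here.
- The synthetic single-cell generator plants clean, well-separated QC
  violations; it does not model ambient RNA, doublet expression profiles,
  or depth-dependent dropout beyond multinomial sampling.
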