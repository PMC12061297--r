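# chromoplast

Analytics linking nanoscale **chromatin packing** to **transcriptional
plasticity and heterogeneity** in cancer-stem-cell (CSC) biology. The
package implements, as tested reusable R functions, the four quantitative
pipelines such a study needs, plus a seeded synthetic-data generator with
planted ground truth so every stage can be validated without any external
download.

## What it computes

1. **PWS imaging → chromatin packing scaling.** A partial wave
   spectroscopic (PWS) image cube I(λ, x, y) is low-pass filtered along
   wavelength, normalized by a cell-free reference cube, and reduced to the
   per-pixel spectral standard deviation σ(x, y), which a strictly monotone
   calibration inverts to the local packing scaling map D_a(x, y)
   (mass-fractal exponent: genomic length N ∝ R^D). Averaging over the
   nucleus gives D_n; groups are compared with Welch's unequal-variance
   t-test at a 0.05/N threshold.
2. **Transcriptional plasticity (bulk RNA-seq).** TPM normalization,
   ERCC/NaN/zero cleaning with replicate averaging, |log2FC| ≥ 1 gating,
   baseline-quantile response curves (mean change ± SEM per decile of
   baseline expression), and lowest-decile log2FC distributions summarized
   by Gaussian KDE and the sample bimodality coefficient
   b = (skew² + 1)/kurtosis (threshold 0.555).
3. **Intercellular heterogeneity (scRNA-seq).** QC (20k–100k reads, <15%
   mitochondrial, ≥200 features, genes in ≥3 cells), log-normalization,
   variable-feature scaling, a 20-component PCA contract, and the **radius
   of genomic space** Rc = √( (1/N) Σᵢ ‖rᵢ − r̄‖² ) on a 3D embedding, with
   seeded subsampling to equalize condition sizes.
4. **Chromatin-mark (CUT&Tag) peak analytics.** Differential-peak gating,
   per-chromosome mark density (merged bp / chromosome length, chrX
   excluded), cross-mark density regression (R² = squared Pearson r),
   poised/bivalent gene calling (H3K4me3 ∩ H3K27me3 within ±2 kb of the
   TSS, half-open windows), peak feature annotation, and promoter log2FC
   signal matrices with seeded k-means (K = 6) clustering.

## Worked example

Simulate two nuclear populations at true mean D_n 2.34 (CSC-like) vs 2.05
(non-CSC-like), 30 nuclei each, 5% spectral noise, and recover the group
difference from the cubes alone:

```r
library(chromoplast)

cfg <- sim_config(seed = 101)
sim <- gen_pws_nuclei(cfg)
dn  <- vapply(sim$nuclei, function(n) pws_dn(n$cube, n$mask, cfg$calib)$d_n, 0)
compare_populations(split(dn, sim$truth$group), control_label = "ALDHneg")
#>     group  n  mean_dn      sd_dn normalized_mean t_statistic       df      p_value significant
#> 1 ALDHneg 30 2.035149 0.10243996        1.000000          NA       NA           NA       FALSE
#> 2 ALDHpos 30 2.330799 0.08356057        1.145272    12.24937 55.74917 1.915522e-17        TRUE
```

The recovered means sit within a few thousandths of the planted values and
the Welch test is significant far below the 0.05/2 threshold. The same
generator-recovery pattern runs for every module, e.g. the radius of
genomic space against its closed form:

```r
e <- gen_embedding(5000, sigma = 1, seed = 11)
radius_of_genomic_space(e)$rc   # 1.7232, vs sqrt(3) = 1.7321 expected
```

and the per-chromosome density regression against a planted cross-mark
correlation:

```r
cfg <- sim_config(seed = 20001)          # planted rho = 0.82
gp  <- gen_peaks(cfg)
d   <- per_chromosome_density(gp$peaks, cfg$chrom_sizes)
density_regression(d[d$mark == "H3K4me3", ], d[d$mark == "H3K27me3", ])$r_squared
#> 0.6505  (22 autosomes; the long-run mean over 500 seeds is ~0.67 = rho^2)
```

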