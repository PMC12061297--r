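test_that("generated cubes encode D exactly when noiseless, and are seed-deterministic", {
  cal <- calibration_model()
  g <- gen_pws_cube(matrix(2.0, 5, 4), matrix(1, 5, 4), cal,
                    noise_sd = 0, seed = 2)
  sig <- spectral_sigma(normalize_reference(g$cube))
  expect_lt(max(abs(sig - cal$forward(2.0))), 1e-12)
  # determinism: same seed identical, different seed different
  g2 <- gen_pws_cube(matrix(2.0, 5, 4), matrix(1, 5, 4), cal, 0, seed = 2)
  g3 <- gen_pws_cube(matrix(2.0, 5, 4), matrix(1, 5, 4), cal, 0, seed = 3)
  expect_identical(g$cube$intensities, g2$cube$intensities)
  expect_false(identical(g$cube$intensities, g3$cube$intensities))
  # rejection of out-of-domain D and shape mismatch
  expect_error(gen_pws_cube(matrix(3.5, 2, 2), matrix(1, 2, 2), cal), "domain")
  expect_error(gen_pws_cube(matrix(2, 2, 2), matrix(1, 3, 2), cal), "shape")
})

test_that("noisy cubes at the CSC-like mean recover D_n within 0.02", {
  cal <- calibration_model()
  errs <- vapply(1:30, function(i) {
    g <- gen_pws_cube(matrix(2.34, 10, 10), matrix(1, 10, 10), cal,
                      noise_sd = 0.05 * cal$forward(2.34), seed = 100 + i)
    pws_dn(g$cube, g$mask, cal)$d_n - 2.34
  }, 0)
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(max(abs(errs)), 0.02)
})

test_that("bulk generator plants decile effects and flags exactly the planted genes", {
  cfg <- sim_config(seed = 42, n_genes = 1000)
  b <- gen_bulk_expression(cfg)
  k <- floor(cfg$n_genes / 10)
  expect_equal(sum(b$truth$planted_ALDHpos), k)
  expect_equal(sum(b$truth$planted_ALDHneg), k)
  expect_equal(sum(b$truth$planted_ALDHpos & b$truth$planted_ALDHneg), 0L)
  # planted CSC-like true LFCs form a bimodal mixture
  expect_gt(bimodality_coefficient(
    b$truth$true_lfc_ALDHpos[b$truth$planted_ALDHpos]), 0.555)
  # null data: measured |LFC| >= 1 retains ~no genes
  cfg0 <- sim_config(seed = 43, n_genes = 1000, dispersion = 0.01)
  b0 <- gen_bulk_expression(cfg0, effect_scale = 0)
  cl0 <- clean_expression(tpm_from_counts(b0$counts, b0$gene_lengths), b0$samples)
  g0 <- lfc_gate(cl0$tpm[, "ALDHpos_control"], cl0$tpm[, "ALDHpos_cisplatin"])
  expect_lt(mean(g0$retained), 0.01)
  expect_error(gen_bulk_expression(sim_config(n_genes = 50)), "deciles")
})

test_that("embedding generator matches its closed-form radius expectation", {
  e <- gen_embedding(5000, sigma = 1, seed = 1)
  rc <- radius_of_genomic_space(e)$rc
  expect_lt(abs(rc - sqrt(3)) / sqrt(3), 0.02)   # E[Rc^2] = 3 sigma^2 (n-1)/n
  # degenerate sigma = 0: all points identical, Rc = 0
  e0 <- gen_embedding(10, sigma = 0, seed = 1)
  expect_equal(radius_of_genomic_space(e0)$rc, 0)
  # doubling sigma doubles Rc in expectation
  r1 <- radius_of_genomic_space(gen_embedding(3000, 1, seed = 2))$rc
  r2 <- radius_of_genomic_space(gen_embedding(3000, 2, seed = 3))$rc
  expect_lt(abs(r2 / r1 - 2), 0.1)
  expect_error(gen_embedding(1, 1), ">= 2")
})

test_that("peak generator hits target densities within 1 bp, sorted and in range", {
  cfg <- sim_config(seed = 9, chrom_sizes = c(chr1 = 1e6, chr2 = 2e6))
  tgt <- data.frame(chrom = c("chr1", "chr2"), mark = "H3K4me3",
                    density = c(0.10, 0.25))
  gp <- gen_peaks(cfg, tgt)
  pk <- gp$peaks$H3K4me3
  for (i in seq_len(nrow(tgt))) {
    p <- pk[pk$chrom == tgt$chrom[i], ]
    expect_true(all(diff(p$start) > 0))
    expect_true(all(p$start < p$end))
    expect_true(all(p$start >= 0 & p$end <= cfg$chrom_sizes[[tgt$chrom[i]]]))
    # non-overlapping, so plain sum == merged sum
    expect_true(all(p$end[-nrow(p)] <= p$start[-1]))
    expect_lte(abs(sum(p$end - p$start) -
                     tgt$density[i] * cfg$chrom_sizes[[tgt$chrom[i]]]), 1)
  }
  expect_error(gen_peaks(cfg, transform(tgt, density = 1.5)), "\\[0, 1\\]")
  # determinism
  gp2 <- gen_peaks(cfg, tgt)
  expect_identical(gp, gp2)
})

test_that("planted density correlation is recovered by the regression in distribution", {
  # 120 seeded replicates through gen_peaks vs a direct bivariate-normal oracle
  reps <- 120
  r2 <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(seed = 5000 + i)
    gp <- gen_peaks(cfg)
    d <- per_chromosome_density(gp$peaks, cfg$chrom_sizes)
    density_regression(d[d$mark == "H3K4me3", ],
                       d[d$mark == "H3K27me3", ])$r_squared
  }, 0)
  set.seed(77)
  oracle <- replicate(3000, {
    z1 <- rnorm(22); z2 <- 0.82 * z1 + sqrt(1 - 0.82^2) * rnorm(22)
    cor(z1, z2)^2
  })
  se <- sd(oracle) * sqrt(1 / reps + 1 / length(oracle))
  expect_lt(abs(mean(r2) - mean(oracle)), 1.96 * se + 0.01)
  # null: rho = 0 gives small R^2 matching the null simulation
  r2_0 <- vapply(1:60, function(i) {
    cfg <- sim_config(seed = 8000 + i, planted_rho = 0)
    gp <- gen_peaks(cfg)
    d <- per_chromosome_density(gp$peaks, cfg$chrom_sizes)
    density_regression(d[d$mark == "H3K4me3", ],
                       d[d$mark == "H3K27me3", ])$r_squared
  }, 0)
  # E[R^2] under the null with n chromosomes is 1/(n-1) = 1/21
  expect_lt(abs(mean(r2_0) - 1 / 21), 0.035)
})

test_that("annotation generator plants exactly the bivalent set", {
  cfg <- sim_config(seed = 13, planted_poised = c("g2", "g7", "g11"))
  ga <- gen_annotation(cfg, n_genes = 12)
  asn <- list(H3K4me3 = assign_peaks_to_tss(ga$marks$H3K4me3, ga$annotation),
              H3K27me3 = assign_peaks_to_tss(ga$marks$H3K27me3, ga$annotation))
  called <- call_poised(list(sim = asn))$poised$sim
  expect_identical(called, sort(c("g2", "g7", "g11")))
  # non-poised genes carry at most one mark in the window
  both <- asn$H3K4me3$assigned & asn$H3K27me3$assigned
  expect_identical(sort(asn$H3K4me3$gene_id[both]), sort(c("g2", "g7", "g11")))
  # empty planted set -> empty call
  cfg0 <- sim_config(seed = 13, planted_poised = character())
  ga0 <- gen_annotation(cfg0, n_genes = 6)
  asn0 <- list(H3K4me3 = assign_peaks_to_tss(ga0$marks$H3K4me3, ga0$annotation),
               H3K27me3 = assign_peaks_to_tss(ga0$marks$H3K27me3, ga0$annotation))
  expect_length(call_poised(list(sim = asn0))$poised$sim, 0)
  # impossible placement is rejected
  tiny <- sim_config(seed = 1, chrom_sizes = c(chr1 = 10000))
  expect_error(gen_annotation(tiny, n_genes = 12), "too short")
})

test_that("single-cell generator plants QC failures that brute force confirms", {
  cfg <- sim_config(seed = 21, n_cells = 100)
  s <- gen_single_cell(cfg)
  expect_equal(sum(!s$truth$pass), 10L)
  q <- qc_filter(s$counts)
  expect_equal(ncol(q$counts), 90L)
  expect_identical(sort(colnames(q$counts)), sort(s$truth$cell[s$truth$pass]))
  # brute-force re-application of the three thresholds on the filtered genes
  gk <- rowSums(s$counts > 0) >= 3
  m <- s$counts[gk, ]
  reads <- colSums(m)
  mito <- colSums(m[startsWith(rownames(m), "MT"), ]) / reads
  feats <- colSums(m > 0)
  brute <- reads >= 20000 & reads <= 100000 & mito < 0.15 & feats >= 200
  expect_equal(ncol(q$counts), sum(brute))
  # zero mito everywhere -> no mito removals
  s0 <- s$counts; s0[startsWith(rownames(s0), "MT"), ] <- 0L
  expect_equal(qc_filter(s0)$report$removed_high_mito, 0L)
})
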