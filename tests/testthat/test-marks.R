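test_that("differential gating is strictly below the threshold", {
  pk <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                   end = c(50, 150, 250, 350),
                   p_value = c(0.05, 0.09, 0.10, 0.2))
  g <- gate_differential(pk, p_max = 0.1)
  expect_equal(nrow(g), 2L)                 # 0.10 is excluded (strict <)
  expect_equal(attr(g, "report")$n_kept, 2L)
  expect_equal(nrow(gate_differential(pk, p_max = 1.01)), 4L)
  expect_equal(nrow(gate_differential(pk[0, ], p_max = 0.1)), 0L)
  expect_error(gate_differential(pk[, 1:3], 0.1), "p_value")
})

test_that("per-chromosome density merges overlaps and excludes chrX", {
  sizes <- c(chr1 = 1e6, chrX = 5e5)
  one <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  d <- per_chromosome_density(one, sizes)
  expect_equal(d$density[d$chrom == "chr1"], 0.1)
  # overlapping [0,100) + [50,150) merge to 150 bp, matching the brute oracle
  ov <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150))
  d2 <- per_chromosome_density(ov, sizes)
  expect_equal(d2$merged_bp[d2$chrom == "chr1"], 150)
  expect_equal(d2$merged_bp[d2$chrom == "chr1"],
               brute_merged_bp(ov$start, ov$end))
  # merging is idempotent: re-measuring the same set changes nothing
  expect_equal(per_chromosome_density(ov, sizes), d2)
  # chrX present in the peaks but absent from the output
  px <- data.frame(chrom = c("chr1", "chrX"), start = 0, end = 100)
  dx <- per_chromosome_density(px, sizes)
  expect_false("chrX" %in% dx$chrom)
  # peaks beyond the chromosome end are rejected by name
  bad <- data.frame(chrom = "chr1", start = 999950, end = 1000050)
  expect_error(per_chromosome_density(bad, sizes), "chr1:999950")
})

test_that("density regression equals squared Pearson correlation", {
  a <- data.frame(chrom = paste0("chr", 1:10), mark = "A",
                  density = seq(0.05, 0.25, length.out = 10))
  b2 <- a; b2$density <- 2 * a$density; b2$mark <- "B"
  r <- density_regression(a, b2)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  bc <- a; bc$density <- 0.1
  expect_equal(density_regression(a, bc)$r_squared, 0)
  set.seed(6)
  brand <- a; brand$density <- runif(10)
  rr <- density_regression(a, brand)
  expect_equal(rr$r_squared, cor(a$density, brand$density)^2, tolerance = 1e-12)
  expect_error(density_regression(bc, a), "zero variance")
  expect_error(density_regression(a[1:2, ], b2[1:2, ]), ">= 3")
})

test_that("TSS assignment follows the half-open 2 kb window convention", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000)
  # overlapping the window by 500 bp -> assigned
  inpk <- data.frame(chrom = "chr1", start = 11500, end = 12500)
  expect_true(assign_peaks_to_tss(inpk, ann)$assigned)
  # starting exactly at TSS + 2000 (half-open window end) -> not assigned
  edge <- data.frame(chrom = "chr1", start = 12000, end = 13000)
  expect_false(assign_peaks_to_tss(edge, ann)$assigned)
  # ending exactly at TSS - 2000 (half-open peak end) -> not assigned
  left <- data.frame(chrom = "chr1", start = 7000, end = 8000)
  expect_false(assign_peaks_to_tss(left, ann)$assigned)
  # one bp further right -> assigned
  left1 <- data.frame(chrom = "chr1", start = 7000, end = 8001)
  expect_true(assign_peaks_to_tss(left1, ann)$assigned)
})

test_that("TSS assignment matches a brute-force all-pairs oracle on a 12-gene fixture", {
  set.seed(12)
  ann <- data.frame(gene_id = paste0("g", 1:12), chrom = rep(c("chr1", "chr2"), 6),
                    strand = "+", tss = sort(sample(5000:200000, 12)))
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                   start = sample(0:200000, 40))
  pk$end <- pk$start + sample(200:3000, 40, replace = TRUE)
  got <- assign_peaks_to_tss(pk, ann)
  want <- vapply(seq_len(12), function(i)
    brute_tss_overlap(pk, ann$chrom[i], ann$tss[i]), TRUE)
  expect_equal(got$assigned, want)
  # invariant to peak order
  got2 <- assign_peaks_to_tss(pk[sample(40), ], ann)
  expect_equal(got2, got)
})

test_that("poised calling is a set intersection with counts and fold ratio", {
  ann <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1", strand = "+",
                    tss = seq(10000, 260000, by = 50000))
  win_peak <- function(genes) data.frame(
    chrom = rep("chr1", length(genes)),
    start = ann$tss[match(genes, ann$gene_id)] - 100,
    end = ann$tss[match(genes, ann$gene_id)] + 100)
  mk <- function(k4g, k27g) list(
    H3K4me3 = assign_peaks_to_tss(win_peak(k4g), ann),
    H3K27me3 = assign_peaks_to_tss(win_peak(k27g), ann))
  asn <- list(CSC = mk(c("g1", "g2", "g3", "g4"), c("g2", "g3", "g5")),
              nonCSC = mk(c("g1", "g2"), c("g2", "g6")))
  pc <- call_poised(asn)
  expect_identical(pc$poised$CSC, c("g2", "g3"))       # brute intersection
  expect_identical(pc$poised$nonCSC, "g2")
  expect_identical(pc$shared, "g2")
  expect_equal(unname(pc$counts), c(2L, 1L))
  expect_equal(pc$fold_ratio, 2)
  # no K27 assignments -> empty poised set
  empty <- mk(c("g1", "g2"), character(0))
  expect_length(call_poised(list(x = empty))$poised$x, 0)
  # gene relabeling commutes with the call
  ann2 <- ann; ann2$gene_id <- paste0("x", 12:7)
  relab <- setNames(ann2$gene_id, ann$gene_id)
  pk2 <- list(CSC = list(
    H3K4me3 = assign_peaks_to_tss(win_peak(c("g1", "g2", "g3", "g4")), ann2),
    H3K27me3 = assign_peaks_to_tss(win_peak(c("g2", "g3", "g5")), ann2)))
  pc2 <- call_poised(pk2)
  expect_identical(pc2$poised$CSC, sort(unname(relab[c("g2", "g3")])))
})

test_that("peak features are classified by midpoint with fixed priority", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 10000, end = 30000, tss = 10000)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(10000, 20000), end = c(12500, 21000))
  gm <- list(genes = genes, exons = exons)
  pk <- data.frame(chrom = "chr1",
                   start = c(9000, 15000, 20100, 50000),
                   end = c(9800, 16000, 20500, 51000))
  cls <- annotate_peak_features(pk, gm)
  expect_equal(as.character(cls$category),
               c("promoter", "intron", "exon", "intergenic"))
  # promoter wins over exon at the TSS (priority)
  tssp <- data.frame(chrom = "chr1", start = 10100, end = 10300)
  expect_equal(as.character(annotate_peak_features(tssp, gm)$category), "promoter")
  expect_equal(sum(cls$fractions), 1)
})

test_that("promoter signal matrices compute binned log2 ratios, strand-aware", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000, 50000))
  covb <- data.frame(chrom = "chr1", start = 0, end = 100000, value = 2)
  # A == B -> all zeros
  m0 <- promoter_signal_matrix(covb, covb, ann)
  expect_true(all(m0 == 0))
  expect_equal(dim(m0), c(2L, 80L))
  # A = 3B, pseudocount 0 -> all bins log2(3)
  cova <- covb; cova$value <- 6
  m3 <- promoter_signal_matrix(cova, covb, ann, pseudocount = 0)
  expect_equal(unname(m3), matrix(log2(3), 2, 80), tolerance = 1e-12,
               ignore_attr = TRUE)
  # minus-strand bins are the reverse of the plus-strand computation
  ramp <- data.frame(chrom = "chr1", start = seq(0, 99000, 1000),
                     end = seq(1000, 100000, 1000),
                     value = seq_len(100))
  annp <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 50000)
  annm <- transform(annp, strand = "-")
  mp <- promoter_signal_matrix(ramp, covb, annp, pseudocount = 0)
  mm <- promoter_signal_matrix(ramp, covb, annm, pseudocount = 0)
  expect_equal(unname(mm[1, ]), rev(unname(mp[1, ])))
  # off-contig promoters are skipped with a warning
  annoff <- rbind(annp, data.frame(gene_id = "g2", chrom = "chr9",
                                   strand = "+", tss = 1000))
  expect_warning(mo <- promoter_signal_matrix(ramp, covb, annoff), "skipped")
  expect_equal(nrow(mo), 1L)
})

test_that("k-means promoter clustering recovers planted blocks and metaplots", {
  set.seed(3)
  blockA <- matrix(rnorm(40 * 20, 5), 40, 20)
  blockB <- matrix(rnorm(40 * 20, -5), 40, 20)
  mat <- rbind(blockA, blockB)
  rownames(mat) <- paste0("g", 1:80)
  cl <- cluster_promoters(mat, k = 2, seed = 9)
  # perfect partition of well-separated blocks (ARI = 1)
  truth <- rep(1:2, each = 40)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  } else {
    expect_equal(length(unique(cl$labels[1:40])), 1L)
    expect_equal(length(unique(cl$labels[41:80])), 1L)
  }
  # k = 1: single cluster, metaplot = column means
  c1 <- cluster_promoters(mat, k = 1, seed = 9)
  expect_equal(unname(c1$metaplot[1, ]), unname(colMeans(mat)))
  # seed determinism and k > rows rejection
  expect_equal(cluster_promoters(mat, k = 2, seed = 9)$labels, cl$labels)
  expect_error(cluster_promoters(mat, k = 100, seed = 1), "exceeds")
})
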