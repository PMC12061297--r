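## Synthetic-data generators with planted ground truth. Every input the
## pipeline consumes can be generated here, seeded and deterministic, so all
## downstream stages are testable without any external download. Each
## generator returns its ground truth alongside the data; recovery tests
## consume only the data and compare against the truth.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators. Defaults reproduce the
#' study conditions the pipeline targets: two flow-sorted populations
#' (CSC-like "ALDHpos" vs non-CSC-like "ALDHneg") with nuclear packing scaling
#' D_n centered at 2.34 and 2.05 (sd 0.1), spectral cubes on the 515-685 nm /
#' 2 nm grid, a toy genome of 22 autosomes plus chrX, a planted cross-mark
#' per-chromosome density correlation of 0.82, and a 100-cell single-cell
#' matrix with planted QC failures.
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param n_nuclei_per_group nuclei per population for PWS simulations.
#' @param true_dn_means named numeric, per-group true mean D_n.
#' @param true_dn_sd between-nucleus sd of D_n.
#' @param cube_shape integer triple (nlambda, nx, ny).
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param calib a [calibration_model()].
#' @param noise_frac spectral measurement noise, as a fraction of the
#'   D-encoded spectral sigma (default 0.05).
#' @param n_genes bulk genes (>= 100 so deciles are non-degenerate).
#' @param n_cells single-cell count.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp),
#'   0-based half-open coordinates throughout.
#' @param planted_rho planted across-chromosome density correlation between
#'   two marks, in \[-1, 1\].
#' @param planted_poised character vector of gene ids to make bivalent.
#' @param lfc_mu,lfc_sd,lfc_weights CSC-like lowest-decile log2 fold-change
#'   mixture: component means +/- `lfc_mu`, component sd `lfc_sd`, weights
#'   `lfc_weights`.
#' @param lfc_mu_unimodal non-CSC-like lowest-decile LFC mean (single
#'   positive-mean component, sd `lfc_sd`).
#' @param dispersion negative-binomial dispersion of bulk counts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_nuclei_per_group = 30L,
                       true_dn_means = c(ALDHpos = 2.34, ALDHneg = 2.05),
                       true_dn_sd = 0.1,
                       cube_shape = c(86L, 24L, 24L),
                       wavelengths = seq(515, 685, by = 2),
                       calib = calibration_model(),
                       noise_frac = 0.05,
                       n_genes = 4000L,
                       n_cells = 100L,
                       chrom_sizes = default_chrom_sizes(),
                       planted_rho = 0.82,
                       planted_poised = c("g1", "g2"),
                       lfc_mu = 2, lfc_sd = 0.5, lfc_weights = c(0.5, 0.5),
                       lfc_mu_unimodal = 2,
                       dispersion = 0.1) {
  n_nuclei_per_group <- as_count(n_nuclei_per_group, "n_nuclei_per_group")
  n_genes <- as_count(n_genes, "n_genes")
  n_cells <- as_count(n_cells, "n_cells")
  check_that(length(cube_shape) == 3L && all(cube_shape >= 1),
             "cube_shape must be (nlambda, nx, ny), all positive")
  check_that(cube_shape[1] == length(wavelengths),
             "cube_shape[1] must equal length(wavelengths)")
  check_that(all(diff(wavelengths) > 0), "wavelengths must be strictly increasing")
  check_that(abs(planted_rho) <= 1, "planted_rho must be in [-1, 1]")
  check_that(all(chrom_sizes > 0) && !is.null(names(chrom_sizes)),
             "chrom_sizes must be a named positive vector")
  check_that(true_dn_sd >= 0 && noise_frac >= 0 && dispersion > 0,
             "true_dn_sd, noise_frac must be >= 0 and dispersion > 0")
  stopifnot(inherits(calib, "calibration_model"))
  structure(list(
    seed = as.integer(seed),
    n_nuclei_per_group = n_nuclei_per_group,
    true_dn_means = true_dn_means, true_dn_sd = true_dn_sd,
    cube_shape = as.integer(cube_shape), wavelengths = as.numeric(wavelengths),
    calib = calib, noise_frac = noise_frac,
    n_genes = n_genes, n_cells = n_cells,
    chrom_sizes = chrom_sizes, planted_rho = planted_rho,
    planted_poised = planted_poised,
    lfc_mu = lfc_mu, lfc_sd = lfc_sd, lfc_weights = lfc_weights,
    lfc_mu_unimodal = lfc_mu_unimodal, dispersion = dispersion
  ), class = "sim_config")
}

#' Default toy genome: 22 autosomes plus chrX
#'
#' Down-scaled chromosome lengths (5-20 Mb, decreasing) sufficient for
#' per-chromosome density analytics; chrX is present so its downstream
#' exclusion is exercised.
#'
#' @return named numeric vector of chromosome sizes in bp.
#' @export
default_chrom_sizes <- function() {
  sizes <- round(seq(2e7, 5e6, length.out = 22))
  names(sizes) <- paste0("chr", 1:22)
  c(sizes, chrX = 1.2e7)
}

## ---------------------------------------------------------------------------
## PWS cubes

#' Generate a PWS spectral cube encoding a known D map
#'
#' Builds a reference-normalized cube whose per-pixel spectral standard
#' deviation equals `calib$forward(d_map)` exactly (before noise), then adds
#' i.i.d. Gaussian measurement noise and multiplies by a smooth positive
#' reference spectrum. The D-encoding fluctuation is synthesized from
#' low-frequency sinusoids (in-band for the default order-2 / cutoff-0.2
#' Butterworth analysis filter) and standardized to unit sample sd per pixel,
#' so the noiseless round trip through [spectral_sigma()] is exact.
#'
#' @param d_map nx x ny matrix of true packing scaling values, inside
#'   `calib$domain` (open interval).
#' @param mask binary matrix, same shape, marking the nucleus.
#' @param calib a [calibration_model()].
#' @param noise_sd additive noise sd on the normalized intensity (absolute;
#'   e.g. `0.05 * calib$forward(2.34)` for 5% of signal).
#' @param wavelengths wavelength grid (nm).
#' @param seed integer seed.
#' @return list: `cube` (a [spectral_cube()] with reference), `mask`,
#'   `truth` (list with `d_map`, `sigma_map`).
#' @export
gen_pws_cube <- function(d_map, mask, calib = calibration_model(),
                         noise_sd = 0, wavelengths = seq(515, 685, by = 2),
                         seed = 1L) {
  check_that(is.matrix(d_map), "d_map must be a matrix")
  check_that(identical(dim(mask), dim(d_map)), "mask shape must match d_map")
  dom <- calib$domain
  check_that(all(d_map > dom[1] & d_map < dom[2]),
             "d_map values must lie inside the calibration domain (%g, %g)",
             dom[1], dom[2])
  nl <- length(wavelengths)
  nx <- nrow(d_map); ny <- ncol(d_map)
  npix <- nx * ny
  sigma_map <- calib$forward(d_map)
  with_seed(seed, {
    ## in-band fluctuation: 3 low-frequency sinusoids with random phase and
    ## amplitude per pixel, standardized to sample mean 0 / sample sd 1
    t <- seq_len(nl) - 1L
    freqs <- c(0.02, 0.035, 0.05)
    s <- matrix(0, nl, npix)
    for (f in freqs) {
      amp <- stats::runif(npix, 0.5, 1.5)
      ph <- stats::runif(npix, 0, 2 * pi)
      s <- s + sin(outer(2 * pi * f * t, ph, "+")) * rep(amp, each = nl)
    }
    s <- sweep(s, 2L, colMeans(s))
    sds <- sqrt(colSums(s^2) / (nl - 1L))
    s <- sweep(s, 2L, sds, "/")
    norm <- 1 + sweep(s, 2L, as.vector(sigma_map), "*")
    if (noise_sd > 0) norm <- norm + stats::rnorm(nl * npix, sd = noise_sd)
    ## smooth positive reference spectrum, common to all pixels
    ref_spec <- 1000 * exp(-((wavelengths - mean(wavelengths)) / 120)^2)
    ref <- array(rep(ref_spec, npix), dim = c(nl, nx, ny))
    intens <- array(norm, dim = c(nl, nx, ny)) * ref
    intens[intens < 0] <- 0
    list(cube = spectral_cube(intens, wavelengths = wavelengths, reference = ref),
         mask = mask != 0,
         truth = list(d_map = d_map, sigma_map = sigma_map))
  })
}

#' Simulate PWS nuclei for several populations
#'
#' Draws per-nucleus true D_n ~ Normal(group mean, sd), builds one cube per
#' nucleus via [gen_pws_cube()] (constant D inside an elliptical nuclear
#' mask, with measurement noise `noise_frac * sigma(D)`), and returns the
#' cubes with the planted truth.
#'
#' @param cfg a [sim_config()].
#' @return list: `nuclei` (list of `gen_pws_cube()` results), `truth`
#'   (data.frame: group, nucleus, true_dn).
#' @export
gen_pws_nuclei <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- names(cfg$true_dn_means)
  nx <- cfg$cube_shape[2]; ny <- cfg$cube_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  mask <- outer(seq_len(nx), seq_len(ny), function(i, j)
    ((i - cx) / (0.4 * nx))^2 + ((j - cy) / (0.4 * ny))^2 <= 1)
  truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, nucleus = seq_len(cfg$n_nuclei_per_group),
               true_dn = NA_real_, stringsAsFactors = FALSE)
  }))
  truth$true_dn <- with_seed(cfg$seed, {
    unlist(lapply(groups, function(g)
      stats::rnorm(cfg$n_nuclei_per_group, cfg$true_dn_means[[g]], cfg$true_dn_sd)))
  })
  dom <- cfg$calib$domain
  truth$true_dn <- pmin(pmax(truth$true_dn, dom[1] + 1e-3), dom[2] - 1e-3)
  nuclei <- lapply(seq_len(nrow(truth)), function(i) {
    dn <- truth$true_dn[i]
    d_map <- matrix(dn, nx, ny)
    gen_pws_cube(d_map, mask, calib = cfg$calib,
                 noise_sd = cfg$noise_frac * cfg$calib$forward(dn),
                 wavelengths = cfg$wavelengths,
                 seed = cfg$seed + 1000L + i)
  })
  list(nuclei = nuclei, truth = truth)
}

## ---------------------------------------------------------------------------
## Bulk expression

#' Generate a two-condition, two-cell-type bulk expression table
#'
#' Negative-binomial counts for `cfg$n_genes` genes in two cell types
#' (CSC-like "ALDHpos", non-CSC-like "ALDHneg") under control and cisplatin,
#' two replicates each (8 samples). Baseline expression (TPM scale) is
#' log-uniform over four decades so decile binning is non-degenerate. Genes in
#' the lowest baseline decile of the CSC-like type carry a symmetric
#' two-component log2 fold-change mixture (means +/- `lfc_mu`); the lowest
#' baseline decile of the non-CSC-like type (excluding CSC-planted genes)
#' carries a single positive-mean LFC. All other genes have true LFC 0.
#'
#' @param cfg a [sim_config()] (`n_genes >= 100`).
#' @param effect_scale multiply all planted LFCs by this factor (0 = null
#'   data).
#' @return list: `counts` (gene x sample integer matrix), `gene_lengths`
#'   (named, bp), `samples` (data.frame: sample, cell_type, treatment,
#'   replicate), `truth` (data.frame: gene_id, baseline ALDHpos/ALDHneg TPM,
#'   planted flags and true LFCs per cell type).
#' @export
gen_bulk_expression <- function(cfg, effect_scale = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  check_that(cfg$n_genes >= 100L, "n_genes < 100: deciles degenerate")
  ng <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(ng))
  with_seed(cfg$seed, {
    lengths <- round(stats::runif(ng, 500, 5000))
    names(lengths) <- gene_id
    ## true baseline expression per cell type, TPM scale, 4 decades
    base <- list(
      ALDHpos = 10^stats::runif(ng, log10(20), log10(2e5)),
      ALDHneg = 10^stats::runif(ng, log10(20), log10(2e5)))
    k <- floor(ng / 10)
    planted_pos <- order(base$ALDHpos)[seq_len(k)]
    cand <- setdiff(order(base$ALDHneg), planted_pos)
    planted_neg <- cand[seq_len(k)]
    lfc <- list(ALDHpos = numeric(ng), ALDHneg = numeric(ng))
    comp <- sample(c(-1, 1), k, replace = TRUE,
                   prob = cfg$lfc_weights / sum(cfg$lfc_weights))
    lfc$ALDHpos[planted_pos] <- stats::rnorm(k, comp * cfg$lfc_mu, cfg$lfc_sd)
    lfc$ALDHneg[planted_neg] <- stats::rnorm(k, cfg$lfc_mu_unimodal, cfg$lfc_sd)
    lfc$ALDHpos <- lfc$ALDHpos * effect_scale
    lfc$ALDHneg <- lfc$ALDHneg * effect_scale
    samples <- expand.grid(replicate = 1:2,
                           treatment = c("control", "cisplatin"),
                           cell_type = c("ALDHpos", "ALDHneg"),
                           stringsAsFactors = FALSE)[, 3:1]
    samples$sample <- with(samples, paste(cell_type, treatment, replicate, sep = "_"))
    counts <- matrix(0L, ng, nrow(samples),
                     dimnames = list(gene_id, samples$sample))
    size <- 1 / cfg$dispersion
    for (j in seq_len(nrow(samples))) {
      ct <- samples$cell_type[j]
      mu <- base[[ct]] * (lengths / 1000)
      if (samples$treatment[j] == "cisplatin") mu <- mu * 2^lfc[[ct]]
      counts[, j] <- stats::rnbinom(ng, mu = mu, size = size)
    }
    truth <- data.frame(
      gene_id = gene_id,
      baseline_ALDHpos = base$ALDHpos, baseline_ALDHneg = base$ALDHneg,
      planted_ALDHpos = seq_len(ng) %in% planted_pos,
      planted_ALDHneg = seq_len(ng) %in% planted_neg,
      true_lfc_ALDHpos = lfc$ALDHpos, true_lfc_ALDHneg = lfc$ALDHneg,
      stringsAsFactors = FALSE)
    list(counts = counts, gene_lengths = lengths, samples = samples,
         truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Embeddings

#' Generate an isotropic 3D Gaussian embedding
#'
#' Test input for the radius-of-genomic-space statistic: `n` i.i.d. points
#' from an isotropic 3D normal with per-axis sd `sigma`. E\[Rc^2\] =
#' 3 sigma^2 (n-1)/n.
#'
#' @param n number of points (>= 2).
#' @param sigma per-axis standard deviation (>= 0; 0 gives coincident points).
#' @param seed integer seed.
#' @param condition condition label attached to all points.
#' @return data.frame: cell, condition, x, y, z.
#' @export
gen_embedding <- function(n, sigma = 1, seed = 1L, condition = "sim") {
  n <- as_count(n, "n", min = 2L)
  check_that(is.numeric(sigma) && length(sigma) == 1L && sigma >= 0,
             "sigma must be a single value >= 0")
  with_seed(seed, {
    m <- matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
    data.frame(cell = sprintf("c%05d", seq_len(n)), condition = condition,
               x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
  })
}

## ---------------------------------------------------------------------------
## Peaks, densities, annotation

#' Draw correlated per-chromosome target densities for two marks
#'
#' Bivariate normal densities (mean `mu`, sd `sd`) with correlation `rho`
#' across chromosomes; defaults keep all draws well inside (0, 1).
#'
#' @param chroms chromosome names.
#' @param rho target correlation in \[-1, 1\].
#' @param mu,sd marginal mean and sd of the densities.
#' @param seed integer seed.
#' @param marks length-2 mark names.
#' @return data.frame: chrom, mark, density (long format).
#' @export
gen_correlated_densities <- function(chroms, rho, mu = 0.10, sd = 0.02,
                                     seed = 1L, marks = c("H3K4me3", "H3K27me3")) {
  check_that(abs(rho) <= 1, "rho must be in [-1, 1]")
  check_that(length(marks) == 2L, "exactly two marks")
  n <- length(chroms)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    d1 <- pmin(pmax(mu + sd * z1, 1e-4), 0.999)
    d2 <- pmin(pmax(mu + sd * z2, 1e-4), 0.999)
    rbind(data.frame(chrom = chroms, mark = marks[1], density = d1,
                     stringsAsFactors = FALSE),
          data.frame(chrom = chroms, mark = marks[2], density = d2,
                     stringsAsFactors = FALSE))
  })
}

#' Generate peak sets hitting exact per-chromosome densities
#'
#' For each (chromosome, mark) target density, places sorted, non-overlapping
#' intervals (0-based half-open, within \[0, chrom_size)) whose total length
#' equals `round(density * chrom_size)` exactly, i.e. within 1 bp of the
#' target per chromosome. If `target_densities` is omitted, densities for
#' H3K4me3/H3K27me3 are drawn on the autosomes with correlation
#' `cfg$planted_rho` via [gen_correlated_densities()].
#'
#' @param cfg a [sim_config()] (chromosome sizes, seed, planted_rho).
#' @param target_densities data.frame (chrom, mark, density) or NULL.
#' @param mean_peak_bp average peak length used to choose peak counts.
#' @return list: `peaks` (named list of mark -> data.frame(chrom, start, end)),
#'   `truth` (the target density table).
#' @export
gen_peaks <- function(cfg, target_densities = NULL, mean_peak_bp = 5000) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- cfg$chrom_sizes
  if (is.null(target_densities)) {
    autos <- names(sizes)[names(sizes) != "chrX"]
    target_densities <- gen_correlated_densities(
      autos, rho = cfg$planted_rho, seed = cfg$seed)
  }
  check_that(all(c("chrom", "mark", "density") %in% names(target_densities)),
             "target_densities needs columns chrom, mark, density")
  check_that(all(target_densities$density >= 0 & target_densities$density <= 1),
             "densities must be in [0, 1]")
  check_that(all(target_densities$chrom %in% names(sizes)),
             "target chrom absent from chrom_sizes")
  peaks <- with_seed(cfg$seed + 7L, {
    out <- list()
    for (i in seq_len(nrow(target_densities))) {
      chrom <- target_densities$chrom[i]
      mark <- target_densities$mark[i]
      L <- sizes[[chrom]]
      total <- round(target_densities$density[i] * L)
      if (total == 0L) next
      npk <- max(1L, min(round(total / mean_peak_bp), floor(total)))
      ## peak lengths: positive, summing to total
      lens <- as.vector(stats::rmultinom(1L, total - npk, rep(1, npk))) + 1L
      ## gaps: nonnegative, summing to L - total, npk + 1 of them
      gaps <- as.vector(stats::rmultinom(1L, L - total, rep(1, npk + 1L)))
      starts <- cumsum(c(gaps[1L], lens[-npk] + gaps[2:npk]))
      df <- data.frame(chrom = chrom, start = starts, end = starts + lens,
                       stringsAsFactors = FALSE)
      out[[mark]] <- rbind(out[[mark]], df)
    }
    out
  })
  peaks <- lapply(peaks, function(df) df[order(df$chrom, df$start), , drop = FALSE])
  list(peaks = peaks, truth = target_densities)
}

#' Generate a gene annotation with planted bivalent (poised) genes
#'
#' Places TSSs in peak-free regions of the toy genome (farther than the
#' promoter window from every existing H3K4me3/H3K27me3 peak), then appends
#' promoter-proximal peaks so that exactly the `cfg$planted_poised` genes
#' carry both marks within the +/- `window` bp TSS window; the remaining
#' genes cycle through H3K4me3-only, H3K27me3-only and unmarked. Because
#' peaks are appended, the (augmented) mark sets are returned alongside the
#' annotation.
#'
#' @param cfg a [sim_config()].
#' @param marks named list of mark data.frames (chrom, start, end) to augment;
#'   must contain "H3K4me3" and "H3K27me3" entries (possibly empty).
#' @param n_genes number of genes to place (>= number of planted poised).
#' @param window promoter half-width in bp (default 2000).
#' @return list: `annotation` (data.frame gene_id, chrom, strand, tss),
#'   `marks` (augmented named list), `truth` (list: poised, k4_only, k27_only,
#'   unmarked).
#' @export
gen_annotation <- function(cfg, marks = list(H3K4me3 = NULL, H3K27me3 = NULL),
                           n_genes = 12L, window = 2000L) {
  stopifnot(inherits(cfg, "sim_config"))
  n_genes <- as_count(n_genes, "n_genes")
  gene_id <- sprintf("g%d", seq_len(n_genes))
  poised <- cfg$planted_poised
  check_that(all(poised %in% gene_id),
             "planted_poised must be a subset of generated gene ids g1..g%d", n_genes)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  k4 <- if (is.null(marks$H3K4me3)) empty else marks$H3K4me3
  k27 <- if (is.null(marks$H3K27me3)) empty else marks$H3K27me3
  occupied <- rbind(k4[c("chrom", "start", "end")], k27[c("chrom", "start", "end")])
  spacing <- 6L * window            # TSS-to-TSS distance; windows never interact
  sizes <- cfg$chrom_sizes
  ## find peak-free TSS slots, walking chromosomes in order
  slots <- list()
  for (chrom in names(sizes)) {
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    gr_occ <- if (nrow(occ)) {
      GenomicRanges::reduce(GenomicRanges::GRanges(
        rep(chrom, nrow(occ)),
        IRanges::IRanges(start = occ$start + 1, end = occ$end)))
    } else GenomicRanges::GRanges()
    cand <- seq(from = 2L * window, to = sizes[[chrom]] - 2L * window,
                by = spacing)
    if (!length(cand)) next
    cand_gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = pmax(1, cand - 3L * window),
                              end = cand + 3L * window))
    hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(cand_gr, gr_occ))
    free <- cand[!(seq_along(cand) %in% hits)]
    if (length(free))
      slots[[chrom]] <- data.frame(chrom = chrom, tss = free,
                                   stringsAsFactors = FALSE)
    if (sum(vapply(slots, nrow, integer(1))) >= n_genes) break
  }
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_genes)
    stop(sprintf("chromosomes too short to place %d genes %d bp apart",
                 n_genes, spacing))
  slots <- slots[seq_len(n_genes), , drop = FALSE]
  strand <- with_seed(cfg$seed + 11L,
                      sample(c("+", "-"), n_genes, replace = TRUE))
  annotation <- data.frame(gene_id = gene_id, chrom = slots$chrom,
                           strand = strand, tss = slots$tss,
                           stringsAsFactors = FALSE)
  ## assign mark classes: planted poised first, others cycle through classes
  rest <- setdiff(gene_id, poised)
  cls <- setNames(rep(c("k4_only", "k27_only", "unmarked"),
                      length.out = length(rest)), rest)
  add_k4 <- empty; add_k27 <- empty
  for (i in seq_len(n_genes)) {
    g <- gene_id[i]; tss <- annotation$tss[i]; chrom <- annotation$chrom[i]
    if (g %in% poised) {
      add_k4 <- rbind(add_k4, data.frame(chrom = chrom, start = tss - 700,
                                         end = tss - 200, stringsAsFactors = FALSE))
      add_k27 <- rbind(add_k27, data.frame(chrom = chrom, start = tss + 200,
                                           end = tss + 900, stringsAsFactors = FALSE))
    } else if (cls[[g]] == "k4_only") {
      add_k4 <- rbind(add_k4, data.frame(chrom = chrom, start = tss - 500,
                                         end = tss + 100, stringsAsFactors = FALSE))
    } else if (cls[[g]] == "k27_only") {
      add_k27 <- rbind(add_k27, data.frame(chrom = chrom, start = tss + 100,
                                           end = tss + 800, stringsAsFactors = FALSE))
    }
  }
  out_marks <- list(
    H3K4me3 = rbind(k4[c("chrom", "start", "end")], add_k4),
    H3K27me3 = rbind(k27[c("chrom", "start", "end")], add_k27))
  out_marks <- lapply(out_marks, function(df)
    df[order(df$chrom, df$start), , drop = FALSE])
  truth <- list(poised = sort(poised),
                k4_only = names(cls)[cls == "k4_only"],
                k27_only = names(cls)[cls == "k27_only"],
                unmarked = names(cls)[cls == "unmarked"])
  list(annotation = annotation, marks = out_marks, truth = truth)
}

## ---------------------------------------------------------------------------
## Single-cell matrices

#' Generate a single-cell count matrix with planted QC failures
#'
#' Library sizes of passing cells are log-normal within the accepted read
#' range; a planted number of cells violate each QC rule (library < 20000,
#' library > 100000, mitochondrial fraction >= 0.15, detected features
#' < 200). Mitochondrial genes carry the "MT-" prefix. Per-cell reads are
#' multinomial over the cell's expressed gene set, with the mitochondrial
#' probability mass set to the cell's target mito fraction.
#'
#' @param cfg a [sim_config()] (`n_cells`).
#' @param n_genes total genes including mitochondrial.
#' @param n_mito number of "MT-" genes.
#' @param n_fail named integer vector with entries `low_reads`, `high_reads`,
#'   `high_mito`, `low_features` (planted violations, disjoint cells).
#' @return list: `counts` (gene x cell integer matrix), `truth` (data.frame:
#'   cell, category, reads, target_mito, expected failure flags).
#' @export
gen_single_cell <- function(cfg, n_genes = 1000L, n_mito = 10L,
                            n_fail = c(low_reads = 3L, high_reads = 2L,
                                       high_mito = 3L, low_features = 2L)) {
  stopifnot(inherits(cfg, "sim_config"))
  n_cells <- cfg$n_cells
  n_genes <- as_count(n_genes, "n_genes", min = 300L)
  check_that(all(c("low_reads", "high_reads", "high_mito", "low_features")
                 %in% names(n_fail)), "n_fail needs all four rule entries")
  n_bad <- sum(n_fail)
  check_that(n_bad < n_cells, "more planted failures than cells")
  genes <- c(sprintf("MT-%d", seq_len(n_mito)),
             sprintf("gene%04d", seq_len(n_genes - n_mito)))
  with_seed(cfg$seed + 23L, {
    category <- c(rep(names(n_fail), times = n_fail),
                  rep("pass", n_cells - n_bad))
    category <- sample(category)       # shuffle cell order
    cells <- sprintf("cell%03d", seq_len(n_cells))
    reads <- numeric(n_cells); mito_t <- numeric(n_cells)
    nexpr <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      reads[i] <- switch(category[i],
        low_reads = round(stats::runif(1, 5000, 15000)),
        high_reads = round(stats::runif(1, 110000, 160000)),
        ## passing range, kept clear of both 20k and 100k boundaries
        round(min(max(exp(stats::rnorm(1, log(45000), 0.25)), 21000), 98000)))
      mito_t[i] <- if (category[i] == "high_mito")
        stats::runif(1, 0.20, 0.35) else stats::runif(1, 0.02, 0.08)
      nexpr[i] <- if (category[i] == "low_features") 150L else n_genes
    }
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    base_w <- stats::rgamma(n_genes, shape = 0.8)   # shared gene weights
    for (i in seq_len(n_cells)) {
      expressed <- seq_len(nexpr[i])               # first nexpr genes (incl MT)
      w <- base_w[expressed]
      is_mt <- expressed <= n_mito
      p <- numeric(length(expressed))
      p[is_mt] <- mito_t[i] * base_w[expressed[is_mt]] / sum(base_w[expressed[is_mt]])
      p[!is_mt] <- (1 - mito_t[i]) * w[!is_mt] / sum(w[!is_mt])
      counts[expressed, i] <- as.vector(stats::rmultinom(1L, reads[i], p))
    }
    mito_real <- colSums(counts[seq_len(n_mito), , drop = FALSE]) / colSums(counts)
    truth <- data.frame(
      cell = cells, category = category, reads = colSums(counts),
      mito_fraction = mito_real,
      n_features = colSums(counts > 0),
      fail_reads_low = colSums(counts) < 20000,
      fail_reads_high = colSums(counts) > 100000,
      fail_mito = mito_real >= 0.15,
      fail_features = colSums(counts > 0) < 200,
      stringsAsFactors = FALSE)
    truth$pass <- !(truth$fail_reads_low | truth$fail_reads_high |
                      truth$fail_mito | truth$fail_features)
    list(counts = counts, truth = truth)
  })
}
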