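## Intercellular transcriptional heterogeneity: single-cell QC, log
## normalization / HVG / scaling, a PCA contract, and the radius-of-genomic-
## space statistic on 3D embeddings.

#' Single-cell quality-control filter
#'
#' Applies, in order: a gene filter (keep genes detected in at least
#' `min_cells_per_gene` cells), then cell filters on the gene-filtered
#' matrix: cells with fewer than `min_features` detected genes are removed;
#' cells with fewer than `min_reads` or more than `max_reads` total reads are
#' removed (both boundary values are kept); cells with a mitochondrial
#' fraction of `max_mito` **or more** are removed. Mitochondrial genes are
#' identified by the `mito_prefix` on their ids.
#'
#' @param counts gene x cell integer matrix with dimnames.
#' @param min_features minimum detected genes per cell (default 200).
#' @param min_cells_per_gene minimum cells per gene (default 3).
#' @param min_reads,max_reads accepted library-size range (defaults 20000 and
#'   100000, inclusive).
#' @param max_mito mitochondrial-fraction cutoff, removal at >= (default 0.15).
#' @param mito_prefix gene-id prefix marking mitochondrial genes
#'   (default "MT").
#' @return list: `counts` (filtered matrix), `report` (list with per-rule
#'   removal counts and the per-cell metrics table `cells`).
#' @export
qc_filter <- function(counts, min_features = 200L, min_cells_per_gene = 3L,
                      min_reads = 20000, max_reads = 100000,
                      max_mito = 0.15, mito_prefix = "MT") {
  check_that(is.matrix(counts) && !is.null(rownames(counts)) &&
               !is.null(colnames(counts)), "counts must have dimnames")
  check_that(all(counts >= 0), "counts must be nonnegative")
  gene_keep <- rowSums(counts > 0) >= min_cells_per_gene
  m <- counts[gene_keep, , drop = FALSE]
  reads <- colSums(m)
  feats <- colSums(m > 0)
  is_mt <- startsWith(rownames(m), mito_prefix)
  mito <- if (any(is_mt)) colSums(m[is_mt, , drop = FALSE]) / pmax(reads, 1)
          else rep(0, ncol(m))
  fail_feat <- feats < min_features
  fail_low <- reads < min_reads
  fail_high <- reads > max_reads
  fail_mito <- mito >= max_mito
  keep <- !(fail_feat | fail_low | fail_high | fail_mito)
  cells <- data.frame(cell = colnames(m), total_reads = unname(reads),
                      n_features = unname(feats), mito_fraction = unname(mito),
                      genes_per_umi = unname(feats / pmax(reads, 1)),
                      fail_features = unname(fail_feat),
                      fail_reads_low = unname(fail_low),
                      fail_reads_high = unname(fail_high),
                      fail_mito = unname(fail_mito),
                      pass = unname(keep), stringsAsFactors = FALSE)
  report <- list(
    n_genes_in = nrow(counts), n_genes_kept = nrow(m),
    n_cells_in = ncol(m), n_cells_kept = sum(keep),
    removed_low_features = sum(fail_feat),
    removed_low_reads = sum(fail_low),
    removed_high_reads = sum(fail_high),
    removed_high_mito = sum(fail_mito),
    cells = cells)
  if (!any(keep)) {
    stop(sprintf(paste0(
      "no cells survive QC (low features: %d, low reads: %d, ",
      "high reads: %d, high mito: %d of %d cells)"),
      report$removed_low_features, report$removed_low_reads,
      report$removed_high_reads, report$removed_high_mito, ncol(m)))
  }
  list(counts = m[, keep, drop = FALSE], report = report)
}

#' Log-normalize, select highly variable genes, and scale
#'
#' Per cell: x -> ln(1 + count / total * scale_factor). Highly variable genes
#' are ranked by standardized variance (observed log-normalized variance
#' divided by the value expected at the gene's mean, from a loess fit of
#' log10 variance on log10 mean). The top `n_hvg` genes are centered and
#' scaled to unit variance, with scaled values clipped at +/- `clip`.
#'
#' @param counts gene x cell matrix (QC-filtered).
#' @param scale_factor library-size scale factor (default 1e4).
#' @param n_hvg number of variable genes to keep (default 2000, capped at the
#'   number of non-constant genes).
#' @param clip clipping bound for scaled values (default 10).
#' @return list: `scaled` (HVG x cell matrix, rows mean 0 / sd 1 before
#'   clipping), `hvg` (gene ids), `lognorm` (full log-normalized matrix).
#' @export
lognorm_hvg_scale <- function(counts, scale_factor = 1e4, n_hvg = 2000L,
                              clip = 10) {
  check_that(is.matrix(counts) && all(counts >= 0), "counts must be nonnegative")
  tot <- colSums(counts)
  check_that(all(tot > 0), "cells with zero totals present; run qc_filter first")
  ln <- log1p(sweep(counts, 2L, tot, "/") * scale_factor)
  mu <- rowMeans(ln)
  v <- apply(ln, 1L, stats::var)
  ok <- v > 0
  if (!any(ok)) stop("all genes constant: no variable features exist")
  ## expected variance at each mean, from a loess mean-variance trend
  lv <- log10(v[ok]); lm10 <- log10(mu[ok] + 1e-12)
  fit <- if (sum(ok) >= 10) {
    stats::loess(lv ~ lm10, span = 0.5, degree = 2)$fitted
  } else lv * 0 + mean(lv)
  std_var <- lv - fit                      # log-scale standardized variance
  n_hvg <- min(as_count(n_hvg, "n_hvg"), sum(ok))
  hvg <- names(sort(std_var, decreasing = TRUE))[seq_len(n_hvg)]
  sc <- ln[hvg, , drop = FALSE]
  sc <- (sc - rowMeans(sc)) / apply(sc, 1L, stats::sd)
  sc[sc > clip] <- clip
  sc[sc < -clip] <- -clip
  list(scaled = sc, hvg = hvg, lognorm = ln)
}

#' PCA embedding of scaled expression
#'
#' SVD-based principal components of cells in HVG space with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive). Explained variance is non-increasing by construction.
#'
#' @param scaled HVG x cell matrix from [lognorm_hvg_scale()].
#' @param n_components number of PCs (default 20, capped at the data rank).
#' @return list: `coords` (cell x n_components matrix, columns PC1..),
#'   `loadings` (gene x n_components), `explained_variance` (vector).
#' @export
pca_embed <- function(scaled, n_components = 20L) {
  check_that(is.matrix(scaled), "scaled must be a matrix")
  x <- t(scaled)                            # cells x genes
  n_components <- as_count(n_components, "n_components")
  check_that(n_components <= min(dim(x)),
             "n_components (%d) exceeds min(cells, genes) = %d",
             n_components, min(dim(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rank_eff <- sum(pc$sdev > 1e-10)
  if (rank_eff < n_components)
    stop(sprintf("degenerate rank: only %d non-null dimensions for %d requested PCs",
                 rank_eff, n_components))
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  loads <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ## deterministic sign: largest-|loading| entry of each PC positive
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(loads[, j]))
    if (loads[i, j] < 0) {
      loads[, j] <- -loads[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coords = coords, loadings = loads,
       explained_variance = pc$sdev[seq_len(n_components)]^2)
}

#' Deterministic 3D embedding fallback
#'
#' Any function mapping a cell x PC matrix to 3D coordinates can serve as the
#' embedding step (e.g. a 3D t-SNE). This deterministic fallback simply takes
#' the first three PCs, so tests and pipelines never depend on a stochastic
#' embedding.
#'
#' @param pcs cell x component matrix (>= 3 columns).
#' @return cell x 3 matrix with columns x, y, z.
#' @export
embed_pca3 <- function(pcs) {
  check_that(is.matrix(pcs) && ncol(pcs) >= 3L, "need at least 3 components")
  out <- pcs[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Radius of genomic space
#'
#' The intercellular transcriptional heterogeneity statistic: per condition,
#' Rc = sqrt( (1/N) * sum_i || r_i - r_mean ||^2 ) over the N cells' 3D
#' embedding coordinates. Rc is invariant to rigid rotation and translation
#' and scales linearly with the coordinates.
#'
#' Because conditions differ in cell count, three equalization modes are
#' reported: `none` uses all cells; `subsample` (seeded) draws the smallest
#' condition's cell count from every condition without replacement;
#' `weights` computes the weighted centroid and weighted mean squared
#' distance with per-cell weights proportional to 1/N_condition (identical to
#' `none` within a single condition; it matters when conditions are pooled).
#'
#' @param embedding data.frame with columns `condition`, `x`, `y`, `z` (e.g.
#'   from [gen_embedding()] or [embed_pca3()] plus labels).
#' @param equalize `"none"`, `"subsample"` or `"weights"`.
#' @param seed seed for `subsample`.
#' @return data.frame: condition, n_cells, n_used, rc, equalize, seed.
#' @export
#' @examples
#' e <- gen_embedding(5000, sigma = 1, seed = 1)
#' radius_of_genomic_space(e)$rc  # ~ sqrt(3)
radius_of_genomic_space <- function(embedding,
                                    equalize = c("none", "subsample", "weights"),
                                    seed = 1L) {
  equalize <- match.arg(equalize)
  check_that(all(c("condition", "x", "y", "z") %in% names(embedding)),
             "embedding needs columns condition, x, y, z")
  coords <- as.matrix(embedding[, c("x", "y", "z")])
  check_that(all(is.finite(coords)), "non-finite coordinates in embedding")
  conds <- split(seq_len(nrow(embedding)), embedding$condition)
  check_that(all(vapply(conds, length, integer(1)) >= 2L),
             "every condition needs >= 2 cells")
  n_min <- min(vapply(conds, length, integer(1)))
  rc_of <- function(m) {
    ctr <- colMeans(m)
    sqrt(mean(rowSums((m - matrix(ctr, nrow(m), 3L, byrow = TRUE))^2)))
  }
  rows <- with_seed(seed, lapply(names(conds), function(cn) {
    idx <- conds[[cn]]
    used <- switch(equalize,
                   none = idx,
                   weights = idx,     # equal weights within a condition
                   subsample = sort(sample(idx, n_min)))
    data.frame(condition = cn, n_cells = length(idx), n_used = length(used),
               rc = rc_of(coords[used, , drop = FALSE]),
               equalize = equalize, seed = as.integer(seed),
               stringsAsFactors = FALSE)
  }))
  do.call(rbind, rows)
}
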