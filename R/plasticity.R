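## Intracellular transcriptional plasticity: TPM normalization, cleaning,
## log2 fold-change gating, baseline-quantile response curves, and
## lowest-decile fold-change density summaries.

#' TPM normalization from raw counts
#'
#' Transcripts per million: per-gene count rates `count / length_kb-free`
#' are renormalized per sample so every column sums to 1e6. Accounts for both
#' sequencing depth and gene length.
#'
#' @param counts gene x sample numeric matrix with rownames (gene ids).
#' @param lengths named numeric vector of gene lengths (bp), covering all
#'   genes, all > 0.
#' @return gene x sample TPM matrix, columns summing to 1e6.
#' @export
#' @examples
#' tpm_from_counts(matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'                 c(a = 1000, b = 2000))  # both 5e5
tpm_from_counts <- function(counts, lengths) {
  check_that(is.matrix(counts) && !is.null(rownames(counts)),
             "counts must be a matrix with gene-id rownames")
  check_that(!anyDuplicated(rownames(counts)), "duplicate gene ids in counts")
  check_that(all(rownames(counts) %in% names(lengths)),
             "lengths missing for some genes")
  len <- lengths[rownames(counts)]
  check_that(all(len > 0), "gene lengths must be > 0")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot <= 0))
    stop(sprintf("zero total rate in sample(s): %s",
                 paste(colnames(counts)[tot <= 0], collapse = ", ")))
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Clean a TPM table for plasticity analysis
#'
#' Applies, in this exact order: (1) drop spike-in genes (ids starting with
#' `ercc_prefix`) and genes with any NaN/NA value; (2) renormalize every
#' sample to sum 1 and rescale to 1e6 (TPM); (3) drop genes with a value of 0
#' in any sample; (4) average replicates within each (cell_type, treatment)
#' condition.
#'
#' @param tpm gene x sample matrix (TPM scale).
#' @param samples data.frame with columns `sample`, `cell_type`, `treatment`,
#'   `replicate`; `sample` must match `colnames(tpm)`.
#' @param ercc_prefix spike-in id prefix (default "ERCC").
#' @return list: `tpm` (gene x condition matrix, columns named
#'   `<cell_type>_<treatment>`, replicates averaged), `attrition` (data.frame
#'   of per-stage gene removals).
#' @export
clean_expression <- function(tpm, samples, ercc_prefix = "ERCC") {
  check_that(is.matrix(tpm) && !is.null(rownames(tpm)), "tpm must be a named matrix")
  check_that(all(c("sample", "cell_type", "treatment", "replicate") %in% names(samples)),
             "samples needs columns sample, cell_type, treatment, replicate")
  check_that(setequal(colnames(tpm), samples$sample),
             "colnames(tpm) must match samples$sample")
  tpm <- tpm[, samples$sample, drop = FALSE]
  n0 <- nrow(tpm)
  is_ercc <- startsWith(rownames(tpm), ercc_prefix)
  has_na <- apply(tpm, 1L, function(x) any(is.na(x)))
  keep1 <- !is_ercc & !has_na
  tpm <- tpm[keep1, , drop = FALSE]
  if (nrow(tpm) == 0L) stop("all genes removed at the ERCC/NaN stage")
  ## renormalize to transcript fractions, then back to TPM
  tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
  any_zero <- apply(tpm, 1L, function(x) any(x == 0))
  tpm <- tpm[!any_zero, , drop = FALSE]
  attrition <- data.frame(
    stage = c("input", "ercc", "nan", "zero_in_any_sample", "retained"),
    n_removed = c(0L, sum(is_ercc), sum(has_na & !is_ercc), sum(any_zero), 0L),
    stringsAsFactors = FALSE)
  if (nrow(tpm) == 0L) {
    msg <- paste(sprintf("%s: %d", attrition$stage, attrition$n_removed),
                 collapse = "; ")
    stop("all genes removed during cleaning (", msg, ")")
  }
  ## average replicates within condition
  cond <- paste(samples$cell_type, samples$treatment, sep = "_")
  uc <- unique(cond)
  avg <- vapply(uc, function(cn)
    rowMeans(tpm[, samples$sample[cond == cn], drop = FALSE]),
    numeric(nrow(tpm)))
  attrition$n_removed[attrition$stage == "retained"] <- 0L
  attr_total <- sum(attrition$n_removed)
  stopifnot(attr_total == n0 - nrow(tpm))
  list(tpm = avg, attrition = attrition)
}

#' Log2 fold-change gate
#'
#' Computes per-gene log2(treated / baseline) on cleaned (zero-free) TPM and
#' retains genes with |LFC| >= `min_abs_lfc`.
#'
#' @param baseline,treated named numeric vectors over the same gene set
#'   (cleaned TPM; zeros are an error — they indicate cleaning was skipped).
#' @param min_abs_lfc retention threshold (default 1).
#' @param pseudocount added to both numerator and denominator (default 0; the
#'   cleaned table is zero-free so none is needed).
#' @return data.frame: gene_id, baseline, treated, lfc, retained (logical).
#' @export
lfc_gate <- function(baseline, treated, min_abs_lfc = 1, pseudocount = 0) {
  check_that(!is.null(names(baseline)) && setequal(names(baseline), names(treated)),
             "baseline and treated must be named over the same gene set")
  treated <- treated[names(baseline)]
  if (pseudocount == 0 && any(baseline == 0 | treated == 0))
    stop("zero expression values present; clean the table first or set a pseudocount")
  lfc <- log2((treated + pseudocount) / (baseline + pseudocount))
  data.frame(gene_id = names(baseline), baseline = unname(baseline),
             treated = unname(treated), lfc = unname(lfc),
             retained = abs(lfc) >= min_abs_lfc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Baseline-quantile response curve
#'
#' Groups genes into `n_quantiles` equal-size rank bins of baseline
#' expression (ties broken by stable gene-id order) and reports, per bin, the
#' mean baseline expression, the mean change in expression after treatment,
#' and its standard error of the mean.
#'
#' @param baseline,treated named numeric vectors over the same genes.
#' @param n_quantiles number of bins (default 10).
#' @param delta `"difference"` (treated - baseline, default) or `"lfc"`
#'   (log2 ratio).
#' @return data.frame: quantile (1 = lowest baseline), n_genes,
#'   mean_baseline, mean_delta, sem_delta.
#' @export
quantile_response <- function(baseline, treated, n_quantiles = 10L,
                              delta = c("difference", "lfc")) {
  delta <- match.arg(delta)
  n_quantiles <- as_count(n_quantiles, "n_quantiles", min = 2L)
  check_that(!is.null(names(baseline)) && setequal(names(baseline), names(treated)),
             "baseline and treated must be named over the same gene set")
  check_that(length(baseline) >= n_quantiles,
             "need at least n_quantiles (%d) genes", n_quantiles)
  treated <- treated[names(baseline)]
  ord <- order(baseline, names(baseline))       # stable tie-break by gene id
  bin <- quantile_bins(length(baseline), n_quantiles)
  d <- switch(delta,
              difference = treated - baseline,
              lfc = log2(treated / baseline))
  out <- do.call(rbind, lapply(seq_len(n_quantiles), function(q) {
    idx <- ord[bin == q]
    dv <- d[idx]
    data.frame(quantile = q, n_genes = length(idx),
               mean_baseline = mean(baseline[idx]),
               mean_delta = mean(dv),
               sem_delta = stats::sd(dv) / sqrt(length(dv)))
  }))
  out
}

## rank -> quantile bin labels with sizes differing by at most one gene
quantile_bins <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Lowest-decile fold-change distributions across response pairs
#'
#' The paper's lowest-percentile analysis: within the `source` pair, genes
#' are gated at |LFC| >= `min_abs_lfc`, the surviving genes are ranked by
#' baseline (control) expression in the source group, and the lowest decile
#' is extracted. The log2 fold change of exactly those genes is then computed
#' in every supplied response pair, and each LFC distribution is summarized
#' by its mean, sd, sample bimodality coefficient (threshold 0.555; see
#' [bimodality_coefficient()]) and a Gaussian kernel density estimate on a
#' fixed grid.
#'
#' @param source name of the pair (in `pairs`) whose baseline defines the
#'   gate and the decile.
#' @param pairs named list; each element is a list/data.frame with named
#'   numeric vectors `baseline` and `treated` over a common gene set.
#' @param n_quantiles decile count (default 10; the lowest bin is used).
#' @param min_abs_lfc gate threshold applied in the source pair (default 1).
#' @param grid_n KDE grid size (default 512).
#' @param bw KDE bandwidth rule (default Scott's, via `bw = "nrd"`).
#' @return list: `genes` (lowest-decile gene ids), `summaries` (data.frame:
#'   pair, n, mean, sd, bimodality), `kde` (data.frame: pair, x, density),
#'   `lfc` (data.frame: pair, gene_id, lfc).
#' @export
lowest_decile_lfc <- function(source, pairs, n_quantiles = 10L,
                              min_abs_lfc = 1, grid_n = 512L, bw = "nrd") {
  check_that(source %in% names(pairs), "source '%s' not found in pairs", source)
  src <- pairs[[source]]
  gate <- lfc_gate(src$baseline, src$treated, min_abs_lfc = min_abs_lfc)
  kept <- gate[gate$retained, , drop = FALSE]
  if (nrow(kept) < n_quantiles)
    stop("too few genes pass the fold-change gate to form deciles")
  ord <- order(kept$baseline, kept$gene_id)
  bin <- quantile_bins(nrow(kept), n_quantiles)
  decile_genes <- kept$gene_id[ord[bin == 1L]]
  if (!length(decile_genes)) stop("lowest decile empty after gating")
  lfc_rows <- list(); sum_rows <- list(); kde_rows <- list()
  for (pn in names(pairs)) {
    p <- pairs[[pn]]
    check_that(all(decile_genes %in% names(p$baseline)) &&
                 all(decile_genes %in% names(p$treated)),
               "pair '%s' is missing lowest-decile genes", pn)
    lf <- log2(p$treated[decile_genes] / p$baseline[decile_genes])
    lfc_rows[[pn]] <- data.frame(pair = pn, gene_id = decile_genes,
                                 lfc = unname(lf), stringsAsFactors = FALSE)
    dens <- stats::density(lf, bw = bw, n = grid_n)
    kde_rows[[pn]] <- data.frame(pair = pn, x = dens$x, density = dens$y,
                                 stringsAsFactors = FALSE)
    sum_rows[[pn]] <- data.frame(
      pair = pn, n = length(lf), mean = mean(lf), sd = stats::sd(lf),
      bimodality = bimodality_coefficient(lf), stringsAsFactors = FALSE)
  }
  list(genes = decile_genes,
       summaries = do.call(rbind, sum_rows),
       kde = do.call(rbind, kde_rows),
       lfc = do.call(rbind, lfc_rows))
}
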