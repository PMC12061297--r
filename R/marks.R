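## CUT&Tag peak analytics: differential-peak gating, per-chromosome mark
## density and cross-mark regression, poised (bivalent) promoter calling,
## peak feature annotation, and promoter log2FC signal matrices with k-means
## clustering. Coordinates are 0-based half-open (BED dialect) at the module
## surface; GenomicRanges (1-based closed) is used internally.

## 0-based half-open data.frame -> GRanges
peaks_to_granges <- function(peaks, chrom_sizes = NULL) {
  check_that(all(c("chrom", "start", "end") %in% names(peaks)),
             "peaks need columns chrom, start, end")
  check_that(all(peaks$start < peaks$end), "peak start must be < end")
  if (!is.null(chrom_sizes)) {
    check_that(all(peaks$chrom %in% names(chrom_sizes)),
               "peak chromosome absent from chrom_sizes")
    over <- peaks$end > chrom_sizes[peaks$chrom]
    if (any(over)) {
      i <- which(over)[1]
      stop(sprintf("peak %s:%d-%d extends beyond chromosome length %d",
                   peaks$chrom[i], peaks$start[i], peaks$end[i],
                   chrom_sizes[[peaks$chrom[i]]]))
    }
  }
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

#' Gate differential peaks on significance
#'
#' Retains peaks with p-value strictly below `p_max`. The default 0.1 follows
#' the per-chromosome analysis inclusion rule; an adjusted-p column can be
#' gated at 0.05 instead via the arguments.
#'
#' @param peaks data.frame (chrom, start, end, p_value, ...).
#' @param p_max strict upper bound on the p-value (default 0.1).
#' @param p_column column holding the p-value (default "p_value"; e.g.
#'   "p_adj" for adjusted values).
#' @return the retained rows, with attribute `"report"` (list: n_in, n_kept,
#'   p_max, p_column).
#' @export
gate_differential <- function(peaks, p_max = 0.1, p_column = "p_value") {
  check_that(p_column %in% names(peaks),
             "peaks lack a '%s' column; cannot gate on significance", p_column)
  p <- peaks[[p_column]]
  check_that(!anyNA(p), "missing p-values present")
  out <- peaks[p < p_max, , drop = FALSE]
  attr(out, "report") <- list(n_in = nrow(peaks), n_kept = nrow(out),
                              p_max = p_max, p_column = p_column)
  out
}

#' Per-chromosome mark density
#'
#' Merges overlapping intervals per chromosome (so a basepair is never
#' counted twice and density cannot exceed 1), sums the merged lengths, and
#' normalizes by chromosome length: density = sum(bp_mark) / chrom_length.
#' chrX is excluded by default, owing to its distinct heterochromatin
#' regulation.
#'
#' @param peaks named list of mark -> data.frame (chrom, start, end), or a
#'   single data.frame (then `mark_name` labels it).
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param exclude chromosomes to drop (default "chrX").
#' @param mark_name label used when `peaks` is a single data.frame.
#' @return data.frame: chrom, mark, merged_bp, chrom_length, density.
#' @export
per_chromosome_density <- function(peaks, chrom_sizes, exclude = "chrX",
                                   mark_name = "mark") {
  if (is.data.frame(peaks)) peaks <- stats::setNames(list(peaks), mark_name)
  keep_chroms <- setdiff(names(chrom_sizes), exclude)
  rows <- list()
  for (mk in names(peaks)) {
    gr <- GenomicRanges::reduce(peaks_to_granges(peaks[[mk]], chrom_sizes))
    bp <- tapply(GenomicRanges::width(gr),
                 as.character(GenomicRanges::seqnames(gr)), sum)
    for (chrom in keep_chroms) {
      m <- if (chrom %in% names(bp)) bp[[chrom]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, mark = mk, merged_bp = m,
        chrom_length = chrom_sizes[[chrom]],
        density = m / chrom_sizes[[chrom]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cross-mark per-chromosome density regression
#'
#' Ordinary least squares of mark B's per-chromosome density on mark A's,
#' across the chromosomes shared by both tables. R^2 equals the squared
#' Pearson correlation.
#'
#' @param table_a,table_b outputs of [per_chromosome_density()] (one mark
#'   each).
#' @return list: slope, intercept, r_squared, n_chrom.
#' @export
density_regression <- function(table_a, table_b) {
  shared <- intersect(table_a$chrom, table_b$chrom)
  check_that(length(shared) >= 3L,
             "need >= 3 shared chromosomes, have %d", length(shared))
  a <- table_a$density[match(shared, table_a$chrom)]
  b <- table_b$density[match(shared, table_b$chrom)]
  check_that(stats::var(a) > 0, "zero variance in predictor densities")
  fit <- stats::lm(b ~ a)
  r2 <- if (stats::var(b) == 0) 0 else stats::cor(a, b)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_chrom = length(shared))
}

#' Assign peaks to genes by TSS proximity
#'
#' A peak is associated with a gene iff it overlaps the promoter window
#' \[TSS - window, TSS + window) (0-based half-open) by at least 1 bp. A peak
#' may be assigned to multiple genes; strand does not alter the window.
#'
#' @param peaks data.frame (chrom, start, end), 0-based half-open.
#' @param annotation data.frame (gene_id, chrom, strand, tss), tss 0-based.
#' @param window promoter half-width in bp (default 2000).
#' @return data.frame: gene_id, n_peaks, assigned (logical).
#' @export
assign_peaks_to_tss <- function(peaks, annotation, window = 2000L) {
  check_that(all(c("gene_id", "chrom", "tss") %in% names(annotation)),
             "annotation needs columns gene_id, chrom, tss")
  check_that(!anyDuplicated(annotation$gene_id), "duplicate gene ids")
  check_that(all(annotation$tss >= 0), "TSS coordinates must be >= 0")
  win0 <- pmax(annotation$tss - window, 0)          # 0-based half-open window
  win1 <- annotation$tss + window
  win_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(start = win0 + 1, end = win1))
  n <- if (nrow(peaks)) {
    pk_gr <- peaks_to_granges(peaks)
    GenomicRanges::countOverlaps(win_gr, pk_gr, minoverlap = 1L)
  } else rep(0L, nrow(annotation))
  data.frame(gene_id = annotation$gene_id, n_peaks = n, assigned = n > 0,
             stringsAsFactors = FALSE)
}

#' Call poised (bivalent) genes
#'
#' Genes associated with both the active H3K4me3 mark and the repressive
#' H3K27me3 mark near their TSS are "poised". Given per-cell-type mark
#' assignments (from [assign_peaks_to_tss()]), returns each cell type's
#' poised gene set, the shared set, counts, and the fold ratio between the
#' two cell types.
#'
#' @param assignments named list, one element per cell type; each element is
#'   a list with components `H3K4me3` and `H3K27me3`, the assignment tables
#'   over a common annotation.
#' @return list: `poised` (named list of gene-id vectors), `shared`
#'   (character), `counts` (named integer), `fold_ratio` (first / second cell
#'   type, NA when the denominator set is empty).
#' @export
call_poised <- function(assignments) {
  check_that(is.list(assignments) && length(assignments) >= 1L &&
               !is.null(names(assignments)), "assignments must be a named list")
  poised <- lapply(assignments, function(a) {
    check_that(all(c("H3K4me3", "H3K27me3") %in% names(a)),
               "each cell type needs H3K4me3 and H3K27me3 assignments")
    check_that(setequal(a$H3K4me3$gene_id, a$H3K27me3$gene_id),
               "assignments built on different annotations")
    k4 <- a$H3K4me3$gene_id[a$H3K4me3$assigned]
    k27 <- a$H3K27me3$gene_id[a$H3K27me3$assigned]
    sort(intersect(k4, k27))
  })
  if (length(assignments) >= 2L) {
    unis <- lapply(assignments, function(a) sort(unique(a$H3K4me3$gene_id)))
    check_that(length(Reduce(intersect, unis)) > 0L,
               "cell-type assignments use disjoint annotations")
  }
  shared <- if (length(poised) >= 2L) Reduce(intersect, poised) else poised[[1]]
  counts <- vapply(poised, length, integer(1))
  fold <- if (length(counts) >= 2L && counts[2] > 0)
    unname(counts[1] / counts[2]) else NA_real_
  list(poised = poised, shared = shared, counts = counts, fold_ratio = fold)
}

#' Classify peaks by genomic feature
#'
#' Each peak is assigned one category by its midpoint with fixed priority
#' promoter > exon > intron > intergenic. Promoter windows are TSS +/-
#' `window`; introns are within a gene span but outside its exons.
#'
#' @param peaks data.frame (chrom, start, end), 0-based half-open.
#' @param gene_models list with `genes` (data.frame gene_id, chrom, strand,
#'   start, end, tss) and `exons` (data.frame gene_id, chrom, start, end),
#'   0-based half-open.
#' @param window promoter half-width (default 2000).
#' @return list: `category` (factor per peak), `fractions` (named numeric).
#' @export
annotate_peak_features <- function(peaks, gene_models, window = 2000L) {
  check_that(all(c("genes", "exons") %in% names(gene_models)),
             "gene_models needs 'genes' and 'exons' tables")
  lv <- c("promoter", "exon", "intron", "intergenic")
  if (!nrow(peaks))
    return(list(category = factor(character(), levels = lv),
                fractions = stats::setNames(rep(NA_real_, 4), lv)))
  mid0 <- floor((peaks$start + peaks$end) / 2)      # 0-based midpoint
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid0 + 1, mid0 + 1))
  g <- gene_models$genes
  prom_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(g$tss - window, 0) + 1, g$tss + window))
  span_gr <- peaks_to_granges(g)
  exon_gr <- peaks_to_granges(gene_models$exons)
  in_prom <- GenomicRanges::countOverlaps(mid_gr, prom_gr) > 0
  in_exon <- GenomicRanges::countOverlaps(mid_gr, exon_gr) > 0
  in_span <- GenomicRanges::countOverlaps(mid_gr, span_gr) > 0
  cat <- rep("intergenic", nrow(peaks))
  cat[in_span] <- "intron"
  cat[in_exon] <- "exon"
  cat[in_prom] <- "promoter"
  cat <- factor(cat, levels = lv)
  list(category = cat, fractions = table(cat) / length(cat))
}

## binned mean coverage over fixed-width windows, from a bedGraph data.frame
binned_coverage <- function(cov, chrom, win_start, win_end, bin) {
  nbins <- (win_end - win_start) / bin
  cc <- cov[cov$chrom == chrom, , drop = FALSE]
  out <- numeric(nbins)
  if (!nrow(cc)) return(out)
  ## coverage Rle over [win_start, win_end) in local coordinates
  s <- pmax(cc$start, win_start)
  e <- pmin(cc$end, win_end)
  keep <- e > s
  if (!any(keep)) return(out)
  rng <- IRanges::IRanges(start = s[keep] + 1 - win_start,
                          end = e[keep] - win_start)
  rle <- IRanges::coverage(rng, weight = cc$value[keep],
                           width = win_end - win_start)
  v <- IRanges::Views(rle, start = seq(1, by = bin, length.out = nbins),
                      width = bin)
  IRanges::viewMeans(v)
}

#' Promoter log2 fold-change signal matrix
#'
#' For each gene, computes per-bin mean coverage in two conditions over the
#' promoter window TSS +/- `window`, then the matrix of
#' log2((A + pseudocount) / (B + pseudocount)). Rows are oriented 5' to 3'
#' (bins of minus-strand genes are reversed).
#'
#' @param cov_a,cov_b bedGraph-style data.frames (chrom, start, end, value),
#'   0-based half-open.
#' @param annotation data.frame (gene_id, chrom, strand, tss).
#' @param window promoter half-width (default 2000).
#' @param bin bin width in bp; must divide `2 * window` (default 50).
#' @param pseudocount added to both coverages (default 1).
#' @return gene x bin matrix of log2 fold changes, with attribute
#'   `"n_skipped"` (genes whose window ran off the annotated contigs; these
#'   are dropped with a warning).
#' @export
promoter_signal_matrix <- function(cov_a, cov_b, annotation, window = 2000L,
                                   bin = 50L, pseudocount = 1) {
  check_that((2L * window) %% bin == 0L, "bin must divide the window evenly")
  nbins <- 2L * window / bin
  contigs <- union(cov_a$chrom, cov_b$chrom)
  off <- !(annotation$chrom %in% contigs) | (annotation$tss - window < 0)
  if (any(off))
    warning(sprintf("%d gene(s) skipped: promoter window off-contig", sum(off)))
  ann <- annotation[!off, , drop = FALSE]
  m <- matrix(NA_real_, nrow(ann), nbins,
              dimnames = list(ann$gene_id,
                              paste0("bin", seq_len(nbins))))
  for (i in seq_len(nrow(ann))) {
    ws <- ann$tss[i] - window; we <- ann$tss[i] + window
    a <- binned_coverage(cov_a, ann$chrom[i], ws, we, bin)
    b <- binned_coverage(cov_b, ann$chrom[i], ws, we, bin)
    lfc <- log2((a + pseudocount) / (b + pseudocount))
    if (identical(ann$strand[i], "-")) lfc <- rev(lfc)
    m[i, ] <- lfc
  }
  attr(m, "n_skipped") <- sum(off)
  m
}

#' K-means clustering of promoter signal matrices
#'
#' Lloyd's algorithm with `nstart` random restarts under a fixed seed; the
#' best-inertia solution is kept. Returns per-cluster metaplot means (the
#' per-bin average profile of each cluster).
#'
#' @param mat gene x bin matrix (e.g. from [promoter_signal_matrix()]).
#' @param k number of clusters (default 6; must be <= rows).
#' @param seed RNG seed.
#' @param nstart random restarts (default 10).
#' @param iter_max Lloyd iteration cap (default 100).
#' @return list: `labels` (named integer vector), `metaplot` (k x bin
#'   matrix), `inertia` (total within-cluster sum of squares), `sizes`.
#' @export
cluster_promoters <- function(mat, k = 6L, seed = 1L, nstart = 10L,
                              iter_max = 100L) {
  check_that(is.matrix(mat) && !anyNA(mat), "mat must be a complete matrix")
  k <- as_count(k, "k")
  check_that(k <= nrow(mat), "k (%d) exceeds number of rows (%d)", k, nrow(mat))
  km <- with_seed(seed,
    stats::kmeans(mat, centers = k, nstart = nstart, iter.max = iter_max,
                  algorithm = "Lloyd"))
  meta <- km$centers
  rownames(meta) <- paste0("cluster", seq_len(k))
  list(labels = stats::setNames(km$cluster, rownames(mat)),
       metaplot = meta, inertia = km$tot.withinss, sizes = km$size)
}
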