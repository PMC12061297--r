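## Readers and writers for the plain-text formats the pipeline touches:
## BED-like peak files (with optional p_value/direction columns), counts TSV,
## MatrixMarket triplets, chromosome sizes, and gene annotations. All
## coordinates on disk are 0-based half-open (BED dialect).

#' Read a BED-like peak file
#'
#' Expects >= 3 tab-separated columns (chrom, start, end), with optional
#' further columns `name`, `p_value` and `direction` (mapped by header when a
#' `#`- or `chrom`-headed line is present, else by position). Malformed lines
#' (start >= end, non-numeric coordinates) are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @return data.frame: chrom, start, end and any optional columns.
#' @export
read_bed <- function(path) {
  check_that(file.exists(path), "cannot read '%s': no such file", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  header <- NULL
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (startsWith(lines[1], "#") || identical(tolower(first[1]), "chrom")) {
    header <- sub("^#\\s*", "", lines[1])
    header <- strsplit(header, "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(rows)
  check_that(all(ncol >= 3L),
             "line(s) %s have fewer than 3 tab-separated columns",
             paste(utils::head(which(ncol < 3L), 5L), collapse = ", "))
  nc <- min(ncol)
  cols <- if (!is.null(header)) header[seq_len(nc)]
          else c("chrom", "start", "end", "name", "p_value", "direction")[seq_len(min(nc, 6L))]
  mat <- t(vapply(rows, function(r) r[seq_len(nc)], character(nc)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  bad_num <- which(is.na(df$start) | is.na(df$end))
  if (length(bad_num))
    stop(sprintf("non-numeric coordinates on line(s): %s",
                 paste(utils::head(bad_num, 5L), collapse = ", ")))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("start >= end on line(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if ("p_value" %in% names(df)) df$p_value <- as.numeric(df$p_value)
  df
}

#' Write peaks as BED
#'
#' @param peaks data.frame with chrom, start, end and optional extra columns.
#' @param path destination; written atomically (temp file + rename).
#' @param header write a `#`-prefixed header line naming the columns.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, header = TRUE) {
  check_that(all(c("chrom", "start", "end") %in% names(peaks)),
             "peaks need columns chrom, start, end")
  tmp <- paste0(path, ".tmp")
  cols <- lapply(peaks, function(x)
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE)
    else as.character(x))
  body <- do.call(paste, c(cols, list(sep = "\t")))
  hdr <- if (header) paste0("#", paste(names(peaks), collapse = "\t"))
  writeLines(c(hdr, body), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a counts table (TSV or MatrixMarket triplet)
#'
#' TSV: first column gene ids, remaining columns numeric counts per sample.
#' MatrixMarket: `path` is the `.mtx` file; row and column names are read
#' from sibling files (`genes`/`features` and `barcodes`/`samples`, `.tsv`),
#' or passed explicitly. Duplicate ids are rejected by name.
#'
#' @param path TSV or .mtx path.
#' @param genes_path,cells_path optional explicit paths to the row/column
#'   name files for MTX input.
#' @return numeric matrix (genes x samples/cells) with dimnames; integer
#'   counts are preserved exactly.
#' @export
read_counts <- function(path, genes_path = NULL, cells_path = NULL) {
  check_that(file.exists(path), "cannot read '%s': no such file", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    find_side <- function(given, names) {
      if (!is.null(given)) return(given)
      for (n in names) {
        p <- file.path(dir, n)
        if (file.exists(p)) return(p)
      }
      stop(sprintf("no %s file found beside '%s'", names[1], path))
    }
    gp <- find_side(genes_path, c("genes.tsv", "features.tsv"))
    cp <- find_side(cells_path, c("barcodes.tsv", "samples.tsv", "cells.tsv"))
    rn <- readLines(gp); cn <- readLines(cp)
    check_that(length(rn) == nrow(m) && length(cn) == ncol(m),
               "dimension mismatch between matrix and name files")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    rn <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  storage.mode(m) <- "double"
  m
}

#' Write a counts matrix as TSV
#'
#' @param counts matrix with dimnames.
#' @param path destination (atomic write).
#' @param id_column name of the leading id column (default "gene_id").
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_column = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom, size (no header).
#' @return named numeric vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2L, "chrom sizes file needs two columns")
  sizes <- as.numeric(df[[2]])
  check_that(!anyNA(sizes) && all(sizes > 0), "chromosome sizes must be positive")
  stats::setNames(sizes, df[[1]])
}

#' Read a minimal gene annotation (gene_id, chrom, strand, tss)
#'
#' @param path TSV with a header; tss is 0-based.
#' @return data.frame gene_id, chrom, strand, tss.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_that(all(c("gene_id", "chrom", "strand", "tss") %in% names(df)),
             "annotation needs columns gene_id, chrom, strand, tss")
  check_that(!anyDuplicated(df$gene_id), "duplicate gene ids in annotation")
  df$tss <- as.numeric(df$tss)
  df
}
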