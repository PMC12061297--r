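# Shared fixtures and brute-force oracles, built in code at test time.

# tiny cube with per-pixel spectra given as a list of vectors (column-major)
make_cube <- function(spectra, nx, ny, wavelengths = NULL, reference = NULL) {
  nl <- length(spectra[[1]])
  if (is.null(wavelengths)) wavelengths <- seq(515, by = 2, length.out = nl)
  arr <- array(unlist(spectra), dim = c(nl, nx, ny))
  spectral_cube(arr, wavelengths = wavelengths, reference = reference)
}

# brute-force per-pixel sample sd across the wavelength axis
brute_sigma <- function(arr) {
  d <- dim(arr)
  out <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) out[i, j] <- sd(arr[, i, j])
  out
}

# brute-force interval oracle: is any peak within [tss - w, tss + w) (0-based
# half-open) overlapping the peak interval [start, end) by >= 1 bp?
brute_tss_overlap <- function(peaks, chrom, tss, w = 2000) {
  any(peaks$chrom == chrom &
        peaks$start < tss + w &
        peaks$end > tss - w)
}

# brute-force merged basepair total of possibly-overlapping intervals
brute_merged_bp <- function(starts, ends) {
  pos <- sort(unique(c(starts, ends)))
  covered <- 0
  for (k in seq_len(length(pos) - 1)) {
    if (any(starts <= pos[k] & ends >= pos[k + 1]))
      covered <- covered + (pos[k + 1] - pos[k])
  }
  covered
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# cleaned two-pair plasticity input from a bulk simulation
bulk_pairs <- function(cfg) {
  b <- gen_bulk_expression(cfg)
  tpm <- tpm_from_counts(b$counts, b$gene_lengths)
  cl <- clean_expression(tpm, b$samples)
  mk <- function(ct) list(baseline = cl$tpm[, paste0(ct, "_control")],
                          treated = cl$tpm[, paste0(ct, "_cisplatin")])
  list(pairs = list(ALDHpos = mk("ALDHpos"), ALDHneg = mk("ALDHneg")),
       clean = cl, truth = b$truth)
}
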