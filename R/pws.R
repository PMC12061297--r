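## PWS (partial wave spectroscopy) image analysis: spectral image cube ->
## per-pixel chromatin packing scaling map D_a(x, y) -> nuclear average D_n ->
## population comparison.

#' Construct a spectral image cube
#'
#' A PWS acquisition is a 3D image cube I(lambda, x, y) of backscatter
#' intensities plus a same-shape reference cube captured in a cell-free region
#' of the dish. The default wavelength grid is 515-685 nm in 2 nm steps
#' (86 planes).
#'
#' @param intensities numeric array, nlambda x nx x ny, nonnegative.
#' @param wavelengths strictly increasing numeric vector (nm), length nlambda.
#' @param reference numeric array with the same shape as `intensities`, or
#'   `NULL` if the cube is already reference-normalized.
#' @return a `spectral_cube` object (list with `intensities`, `wavelengths`,
#'   `reference`).
#' @export
spectral_cube <- function(intensities,
                          wavelengths = seq(515, 685, by = 2),
                          reference = NULL) {
  check_that(is.array(intensities) && length(dim(intensities)) == 3L,
             "intensities must be a 3D array (nlambda x nx x ny)")
  check_that(!anyNA(intensities) && all(intensities >= 0),
             "intensities must be nonnegative and NA-free")
  check_that(length(wavelengths) == dim(intensities)[1],
             "length(wavelengths) must equal dim(intensities)[1]")
  check_that(all(diff(wavelengths) > 0), "wavelengths must be strictly increasing")
  if (!is.null(reference)) {
    check_that(identical(dim(reference), dim(intensities)),
               "reference must have the same shape as intensities")
    check_that(!anyNA(reference), "reference must be NA-free")
  }
  structure(list(intensities = intensities,
                 wavelengths = as.numeric(wavelengths),
                 reference = reference),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("spectral_cube: %d wavelengths (%.0f-%.0f nm), %d x %d pixels, %s reference\n",
              d[1], min(x$wavelengths), max(x$wavelengths), d[2], d[3],
              if (is.null(x$reference)) "no" else "with"))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter along the wavelength axis
#'
#' Reduces high-frequency noise (e.g. from LED illumination) in each pixel's
#' spectrum. The filter is applied forward-backward (zero phase), so the DC
#' gain is exactly 1 and in-band signal is passed with negligible distortion
#' while broadband noise is attenuated.
#'
#' @param cube a [spectral_cube()].
#' @param order filter order (>= 1); default 2.
#' @param cutoff normalized cutoff frequency in cycles/sample, in (0, 0.5);
#'   default 0.2.
#' @return a `spectral_cube` with filtered intensities (reference, if present,
#'   is filtered identically).
#' @export
butterworth_lowpass <- function(cube, order = 2L, cutoff = 0.2) {
  stopifnot(inherits(cube, "spectral_cube"))
  check_that(cutoff > 0 && cutoff < 0.5,
             "cutoff must be in (0, 0.5) cycles/sample, got %g", cutoff)
  order <- as_count(order, "order")
  nl <- dim(cube$intensities)[1]
  ## filtfilt needs > 3 * filter length samples to initialize its edges
  minlen <- 3L * (2L * order + 1L)
  check_that(nl >= minlen,
             "cube has %d wavelength planes; order-%d zero-phase filtering needs >= %d",
             nl, order, minlen)
  bf <- signal::butter(order, 2 * cutoff, type = "low")
  ## forward-backward filtering with mean removal and odd-reflection padding,
  ## so constants pass exactly and edge transients stay out of the record
  pad <- min(minlen, nl - 1L)
  zphase <- function(x) {
    n <- length(x)
    mu <- mean(x)
    xc <- x - mu
    pre <- 2 * xc[1] - xc[(pad + 1):2]
    post <- 2 * xc[n] - xc[(n - 1):(n - pad)]
    ext <- c(pre, xc, post)
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    y[(pad + 1):(pad + n)] + mu
  }
  filt_planes <- function(arr) {
    d <- dim(arr)
    flat <- matrix(arr, nrow = d[1])        # columns are pixels
    out <- apply(flat, 2L, zphase)
    array(out, dim = d)
  }
  out <- cube
  out$intensities <- filt_planes(cube$intensities)
  if (!is.null(cube$reference)) out$reference <- filt_planes(cube$reference)
  out
}

#' Normalize a cube by its cell-free reference
#'
#' Divides the intensity cube elementwise by the reference cube, removing the
#' source spectrum and the per-pixel illumination profile. `cube == reference`
#' yields all ones.
#'
#' @param cube a [spectral_cube()] with a reference, or an intensity array.
#' @param reference reference array; taken from `cube$reference` if missing.
#' @return a `spectral_cube` whose intensities are the ratio and whose
#'   `reference` slot is `NULL` (already applied).
#' @export
normalize_reference <- function(cube, reference = NULL) {
  if (inherits(cube, "spectral_cube")) {
    if (is.null(reference)) reference <- cube$reference
    intens <- cube$intensities
    wl <- cube$wavelengths
  } else {
    intens <- cube
    wl <- seq_len(dim(intens)[1])
  }
  check_that(!is.null(reference), "no reference cube supplied")
  check_that(identical(dim(reference), dim(intens)),
             "reference shape does not match cube shape")
  bad <- which(reference <= 0)
  if (length(bad)) {
    idx <- arrayInd(utils::head(bad, 5L), dim(reference))
    stop(sprintf(
      "reference has %d non-positive values; first offending (lambda,x,y) indices: %s",
      length(bad),
      paste(apply(idx, 1L, paste, collapse = ","), collapse = "; ")))
  }
  spectral_cube(intens / reference, wavelengths = wl, reference = NULL)
}

#' Per-pixel spectral standard deviation map
#'
#' The core PWS observable: for each (x, y) pixel, the sample standard
#' deviation of the (reference-normalized) intensity across wavelengths.
#'
#' @param cube a reference-normalized [spectral_cube()] or a 3D array.
#' @return nx x ny numeric matrix of sample standard deviations.
#' @export
spectral_sigma <- function(cube) {
  arr <- if (inherits(cube, "spectral_cube")) cube$intensities else cube
  check_that(is.array(arr) && length(dim(arr)) == 3L, "need a 3D cube")
  check_that(dim(arr)[1] >= 2L, "need at least 2 wavelength planes")
  check_that(!anyNA(arr), "cube contains NA planes; refusing to compute sigma")
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1])
  mu <- colMeans(flat)
  ss <- colSums(flat^2) - d[1] * mu^2
  ss[ss < 0] <- 0                      # numerical guard
  matrix(sqrt(ss / (d[1] - 1L)), nrow = d[2], ncol = d[3])
}

#' Convert a spectral-sigma map to a chromatin packing scaling map
#'
#' Applies the inverse calibration elementwise: D_a(x, y) =
#' `calib$inverse(sigma(x, y))`. Values that invert outside the calibration
#' domain are clipped to the domain edges and counted in a QC report (never
#' silently dropped, so masked averages keep their pixel counts).
#'
#' @param sigma_map numeric matrix of nonnegative spectral standard deviations.
#' @param calib a [calibration_model()].
#' @return a list: `d_map` (matrix), `clip_fraction` (scalar), `n_clipped_low`,
#'   `n_clipped_high`.
#' @export
sigma_to_d <- function(sigma_map, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  check_that(is.matrix(sigma_map) && all(sigma_map >= 0, na.rm = TRUE),
             "sigma_map must be a nonnegative matrix")
  d <- calib$inverse(sigma_map)
  lo <- d < calib$domain[1]
  hi <- d > calib$domain[2]
  d[lo] <- calib$domain[1]
  d[hi] <- calib$domain[2]
  list(d_map = d,
       clip_fraction = (sum(lo, na.rm = TRUE) + sum(hi, na.rm = TRUE)) / length(d),
       n_clipped_low = sum(lo, na.rm = TRUE),
       n_clipped_high = sum(hi, na.rm = TRUE))
}

#' Nuclear-average chromatin packing scaling D_n
#'
#' Arithmetic mean of the D_a(x, y) map over the nuclear mask.
#'
#' @param d_map numeric matrix (D_a map).
#' @param mask logical/0-1 matrix of the same shape; must select >= 1 pixel.
#' @return scalar D_n.
#' @export
nuclear_dn <- function(d_map, mask) {
  check_that(is.matrix(d_map), "d_map must be a matrix")
  check_that(identical(dim(mask), dim(d_map)), "mask shape must match d_map")
  mask <- mask != 0
  check_that(any(mask), "mask is empty: no nuclear pixels to average")
  vals <- d_map[mask]
  check_that(all(is.finite(vals)), "d_map has non-finite values inside the mask")
  mean(vals)
}

#' Full cube -> D_n pipeline for one nucleus
#'
#' Convenience wrapper chaining [butterworth_lowpass()],
#' [normalize_reference()], [spectral_sigma()], [sigma_to_d()] and
#' [nuclear_dn()].
#'
#' @param cube a [spectral_cube()] with reference.
#' @param mask nuclear mask matrix (nx x ny); default all pixels.
#' @param calib a [calibration_model()].
#' @param filter_order,filter_cutoff Butterworth settings; set
#'   `filter_order = NULL` to skip filtering.
#' @return list: `d_n`, `d_map`, `sigma_map`, `clip_fraction`, `n_pixels`.
#' @export
pws_dn <- function(cube, mask = NULL, calib = calibration_model(),
                   filter_order = 2L, filter_cutoff = 0.2) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!is.null(filter_order))
    cube <- butterworth_lowpass(cube, order = filter_order, cutoff = filter_cutoff)
  norm <- if (is.null(cube$reference)) cube else normalize_reference(cube)
  sig <- spectral_sigma(norm)
  inv <- sigma_to_d(sig, calib)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(sig), ncol(sig))
  list(d_n = nuclear_dn(inv$d_map, mask),
       d_map = inv$d_map,
       sigma_map = sig,
       clip_fraction = inv$clip_fraction,
       n_pixels = sum(mask != 0))
}

#' Compare nuclear D_n between cell populations
#'
#' Welch's unpaired, unequal-variance t-test of each group against the control
#' group, with a Bonferroni-style significance threshold of 0.05 / N where N is
#' the number of groups. Group means are also reported normalized to the
#' control-group mean (control = 1 exactly).
#'
#' @param groups named list of numeric vectors of per-nucleus D_n values; each
#'   group needs >= 3 nuclei.
#' @param control_label name of the control group in `groups`.
#' @param alpha base significance level before the 0.05/N division
#'   (default 0.05).
#' @return a data.frame with one row per group: `group`, `n`, `mean_dn`,
#'   `sd_dn`, `normalized_mean`, `t_statistic`, `df`, `p_value`,
#'   `significant` (at `alpha / N`), plus attribute `"alpha_adjusted"`.
#' @export
compare_populations <- function(groups, control_label, alpha = 0.05) {
  check_that(is.list(groups) && !is.null(names(groups)) && length(groups) >= 2L,
             "groups must be a named list with >= 2 groups")
  check_that(control_label %in% names(groups),
             "control_label '%s' not found among groups", control_label)
  n_per <- vapply(groups, length, integer(1))
  check_that(all(n_per >= 3L), "every group needs >= 3 nuclei")
  zero_var <- vapply(groups, function(g) stats::var(g) == 0, logical(1))
  if (any(zero_var & n_per < 2L))
    stop("group with zero variance and fewer than 2 observations")
  ctrl <- groups[[control_label]]
  n_groups <- length(groups)
  alpha_adj <- alpha / n_groups
  rows <- lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    if (lab == control_label) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(g, ctrl, var.equal = FALSE)
    }
    data.frame(group = lab, n = length(g),
               mean_dn = mean(g), sd_dn = stats::sd(g),
               normalized_mean = mean(g) / mean(ctrl),
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value,
               significant = !is.na(tt$p.value) && tt$p.value < alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "control") <- control_label
  out
}
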