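#' DFT bins covering the analysis band
#'
#' Returns the 0-based discrete-Fourier bin indices k (0 < k <= T/2) whose
#' frequency k/(T * tr_s) falls in the closed band. For T = 150 frames at
#' TR = 2 s the resolution is 1/300 Hz and the 0.01-0.08 Hz band covers
#' bins 3..24 — 22 bins.
#'
#' @param nt number of time points.
#' @param tr_s repetition time, seconds.
#' @param band_hz length-2 numeric, band edges in Hz (inclusive).
#' @return integer vector of bin indices.
#' @export
alff_band_bins <- function(nt, tr_s, band_hz) {
  bins <- band_bin_indices(nt, tr_s, band_hz)
  bins[bins < nt / 2]                          # ALFF excludes the Nyquist bin
}

#' ALFF of a single voxel time series
#'
#' The series is Fourier-transformed; the single-sided amplitude at bin k
#' (0 < k < T/2) is (2/T) |X_k|, so a unit-amplitude sinusoid sitting
#' exactly on a bin has amplitude 1. ALFF is the mean of these amplitudes
#' over the bins whose frequency lies in the closed band. The constant (DC)
#' component is excluded, so a constant series has ALFF 0.
#'
#' @param x numeric vector, the (detrended) series; length >= 16.
#' @param tr_s repetition time, seconds.
#' @param band_hz length-2 numeric, band edges in Hz.
#' @return non-negative scalar amplitude.
#' @export
alff_voxel <- function(x, tr_s, band_hz = c(0.01, 0.08)) {
  nt <- length(x)
  if (nt < 16L) stop("series too short for a spectral estimate (need >= 16)")
  bins <- alff_band_bins(nt, tr_s, band_hz)
  if (length(bins) == 0L)
    stop(sprintf("no DFT bins in band (%g, %g) Hz at T = %d, TR = %g s",
                 band_hz[1L], band_hz[2L], nt, tr_s))
  amp <- (2 / nt) * Mod(stats::fft(x)[bins + 1L])
  mean(amp)
}

#' Voxel-wise ALFF map
#'
#' Applies [alff_voxel()] to every in-mask voxel of a preprocessed 4D
#' series (vectorised over voxels); out-of-mask voxels are 0.
#'
#' @param series a [bold_series()] or 4D array, preprocessed.
#' @param mask 3D logical array, same grid.
#' @param tr_s repetition time, seconds (taken from `series` if absent).
#' @param band_hz length-2 numeric, band edges in Hz.
#' @return an `alff_map` object: list with `values` (3D array), `mask`,
#'   `band_hz`, `standardized` (FALSE), `affine` (if known).
#' @export
alff_map <- function(series, mask, tr_s = NULL, band_hz = c(0.01, 0.08)) {
  if (inherits(series, "bold_series")) {
    if (is.null(tr_s)) tr_s <- series$tr_s
    affine <- series$affine
    arr <- series$data
  } else {
    if (is.null(tr_s)) stop("tr_s required when series is a bare array")
    affine <- NULL
    arr <- series
  }
  d <- dim(arr)
  if (!identical(dim(mask), d[1:3]))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match series grid ", paste(d[1:3], collapse = "x"))
  nt <- d[4L]
  bins <- alff_band_bins(nt, tr_s, band_hz)
  if (length(bins) == 0L) stop("no DFT bins in band")
  idx <- which(mask)
  m <- t(matrix(arr, prod(d[1:3]), nt)[idx, , drop = FALSE])  # T x V
  b <- band_basis(nt, tr_s, band_hz)
  pair <- b$keep < nt / 2                     # ALFF excludes Nyquist
  a_re <- crossprod(b$C[, pair, drop = FALSE], m)
  a_im <- crossprod(b$S[, pair, drop = FALSE], m)
  amp <- (2 / nt) * sqrt(a_re^2 + a_im^2)
  vals <- array(0, dim = d[1:3])
  vals[idx] <- colMeans(amp)
  structure(list(values = vals, mask = mask, band_hz = band_hz,
                 standardized = FALSE, affine = affine),
            class = "alff_map")
}

#' @export
print.alff_map <- function(x, ...) {
  cat(sprintf("<alff_map> %s, band %g-%g Hz, %s, %d mask voxels\n",
              paste(dim(x$values), collapse = "x"),
              x$band_hz[1L], x$band_hz[2L],
              if (x$standardized) "standardized" else "raw",
              sum(x$mask)))
  invisible(x)
}

#' Standardize an ALFF map by its global mean
#'
#' Divides every in-mask voxel by the in-mask mean, so that the
#' standardized map averages exactly 1 over the mask; out-of-mask voxels
#' remain 0. This removes inter-subject global amplitude scale.
#'
#' @param map an `alff_map` (or a bare 3D array with `mask` supplied).
#' @param mask 3D logical array; defaults to the map's own mask.
#' @return a standardized `alff_map` (or 3D array for array input).
#' @export
standardize_alff <- function(map, mask = NULL) {
  arr_in <- !inherits(map, "alff_map")
  vals <- if (arr_in) map else map$values
  if (is.null(mask)) {
    if (arr_in) stop("mask required for bare-array input")
    mask <- map$mask
  }
  g <- mean(vals[mask])
  if (!is.finite(g) || g <= 0)
    stop("in-mask mean ALFF is not positive (", g, "); cannot standardize")
  out <- vals
  out[mask] <- vals[mask] / g
  if (arr_in) return(out)
  map$values <- out
  map$standardized <- TRUE
  map
}

#' Mean standardized ALFF over a region of interest
#'
#' @param map an `alff_map` (typically standardized) or 3D array.
#' @param roi integer vector of linear voxel indices, an n x 3 index
#'   matrix, or a logical array — all on the map's grid.
#' @return scalar mean over the ROI voxels.
#' @export
regional_mean_alff <- function(map, roi) {
  vals <- if (inherits(map, "alff_map")) map$values else map
  idx <- roi_linear_indices(roi, dim(vals))
  if (length(idx) == 0L) stop("ROI is empty")
  mean(vals[idx])
}

# Accept ROI as linear indices, an n x 3 voxel-index matrix, or a logical
# array, and return linear indices.
roi_linear_indices <- function(roi, dims) {
  if (is.logical(roi)) {
    stopifnot(identical(dim(roi), dims))
    which(roi)
  } else if (is.matrix(roi)) {
    stopifnot(ncol(roi) == 3L)
    as.integer(roi[, 1L] + dims[1L] * (roi[, 2L] - 1L) +
               dims[1L] * dims[2L] * (roi[, 3L] - 1L))
  } else {
    as.integer(roi)
  }
}
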