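#' Preprocessing parameters
#'
#' Defaults follow a standard resting-state ALFF protocol: drop the first 5
#' frames (magnetisation equilibration), exclude subjects whose head motion
#' exceeds 1 mm translation or 1 degree rotation on any axis, smooth with an
#' 8 mm FWHM isotropic Gaussian, and band-pass filter to 0.01-0.08 Hz.
#'
#' @param n_discard number of initial frames to drop.
#' @param max_translation_mm subject-exclusion bound on |translation|, mm.
#' @param max_rotation_deg subject-exclusion bound on |rotation|, degrees.
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum, mm.
#' @param band_hz length-2 numeric, pass-band edges in Hz (inclusive).
#' @return a list of class `preprocess_params`.
#' @export
preprocess_params <- function(n_discard = 5L, max_translation_mm = 1.0,
                              max_rotation_deg = 1.0, fwhm_mm = 8.0,
                              band_hz = c(0.01, 0.08)) {
  stopifnot(n_discard >= 0L, max_translation_mm > 0, max_rotation_deg > 0,
            fwhm_mm >= 0, length(band_hz) == 2L,
            band_hz[1L] > 0, band_hz[1L] < band_hz[2L])
  structure(list(n_discard = as.integer(n_discard),
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 fwhm_mm = fwhm_mm, band_hz = band_hz),
            class = "preprocess_params")
}

#' Discard initial (dummy) volumes
#'
#' Removes the first `n_discard` frames of a 4D acquisition; the remaining
#' frames are untouched. With the default 155 acquired frames and
#' `n_discard = 5`, 150 frames survive.
#'
#' @param series a [bold_series()] or 4D array.
#' @param n_discard non-negative integer, frames to drop.
#' @return the same type as `series`, shortened by `n_discard` frames.
#' @export
discard_initial_volumes <- function(series, n_discard = 5L) {
  arr <- if (inherits(series, "bold_series")) series$data else series
  nt <- dim(arr)[4L]
  if (n_discard < 0L) stop("n_discard must be non-negative")
  if (nt <= n_discard)
    stop("series has ", nt, " frames; cannot discard ", n_discard)
  if (n_discard == 0L) return(series)
  out <- arr[, , , (n_discard + 1L):nt, drop = FALSE]
  if (inherits(series, "bold_series")) {
    series$data <- out
    series
  } else out
}

#' Screen a motion trace for subject exclusion
#'
#' A subject fails if any translation column exceeds `max_translation_mm`
#' in absolute value at any frame, or any rotation column exceeds
#' `max_rotation_deg` — strictly greater than, so a peak of exactly 1 mm
#' passes under the default bounds. Screening is subject-level (include or
#' exclude), not frame censoring.
#'
#' @param motion_trace T x 6 matrix: translations mm, then rotations deg.
#' @param params a [preprocess_params()].
#' @return list with `pass` (logical), `offending_frames` (integer vector),
#'   `max_translation_mm`, `max_rotation_deg` observed.
#' @export
screen_motion <- function(motion_trace, params = preprocess_params()) {
  if (!is.matrix(motion_trace) || ncol(motion_trace) != 6L)
    stop("motion trace must be a matrix with 6 columns")
  tr_bad <- abs(motion_trace[, 1:3, drop = FALSE]) > params$max_translation_mm
  ro_bad <- abs(motion_trace[, 4:6, drop = FALSE]) > params$max_rotation_deg
  bad <- rowSums(tr_bad) > 0L | rowSums(ro_bad) > 0L
  list(pass = !any(bad),
       offending_frames = which(bad),
       max_translation_mm = max(abs(motion_trace[, 1:3])),
       max_rotation_deg = max(abs(motion_trace[, 4:6])))
}

# 1D smoothing operator with replicate-nearest boundary: row i holds the
# normalised Gaussian weights that produce smoothed value i, with
# out-of-range taps folded onto the nearest edge sample.
.gaussian_operator <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  taps <- (-half):half
  w <- exp(-taps^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + taps, 1L), n)
    for (t in seq_along(taps)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Convolves each frame with a separable isotropic Gaussian of
#' sigma = FWHM / (2 sqrt(2 ln 2)) (in mm, scaled by the voxel size), using
#' replicate-nearest boundary handling so constant images stay constant.
#' `fwhm_mm = 0` is the identity.
#'
#' @param series a [bold_series()], 4D array, or 3D array (single frame).
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @return smoothed data of the same type and shape.
#' @export
spatial_smooth <- function(series, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  arr <- if (inherits(series, "bold_series")) series$data else series
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  if (fwhm_mm == 0) return(series)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(arr)
  K1 <- .gaussian_operator(d[1L], sigma)
  K2 <- .gaussian_operator(d[2L], sigma)
  K3 <- .gaussian_operator(d[3L], sigma)
  x <- if (nd == 3L) array(arr, dim = c(d, 1L)) else arr
  dd <- dim(x)
  # axis 1
  x <- array(K1 %*% matrix(x, dd[1L]), dim = dd)
  # axis 2
  x <- aperm(x, c(2L, 1L, 3L, 4L))
  x <- array(K2 %*% matrix(x, dd[2L]), dim = dd[c(2L, 1L, 3L, 4L)])
  x <- aperm(x, c(2L, 1L, 3L, 4L))
  # axis 3
  x <- aperm(x, c(3L, 1L, 2L, 4L))
  x <- array(K3 %*% matrix(x, dd[3L]), dim = dd[c(3L, 1L, 2L, 4L)])
  x <- aperm(x, c(2L, 3L, 1L, 4L))
  out <- if (nd == 3L) array(x, dim = d) else x
  if (inherits(series, "bold_series")) {
    series$data <- out
    series
  } else out
}

#' Remove a linear trend from time series
#'
#' Subtracts the least-squares fit of an intercept plus linear term from
#' each series; residuals are orthogonal to both regressors.
#'
#' @param x numeric vector (one series) or T x V matrix (series in columns).
#' @return detrended data of the same shape.
#' @export
detrend_linear <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1L) else x
  nt <- nrow(m)
  if (nt < 3L) stop("need at least 3 time points to detrend")
  t_c <- seq_len(nt) - (nt + 1) / 2           # centred time, orthogonal to 1
  beta <- crossprod(t_c, m) / sum(t_c^2)
  out <- m - rep(colMeans(m), each = nt) - outer(t_c, drop(beta))
  if (vec) drop(out) else out
}

# 0-based DFT bin indices k (0 < k <= floor(T/2)) whose frequency k/(T*tr)
# lies in the closed band; a tiny tolerance absorbs floating-point edges.
band_bin_indices <- function(nt, tr_s, band_hz) {
  k <- seq_len(floor(nt / 2))
  f <- k / (nt * tr_s)
  tol <- 1e-9
  k[f >= band_hz[1L] - tol & f <= band_hz[2L] + tol]
}

# Real DFT basis restricted to the in-band bins, memoised per
# (T, TR, band): C[t, k] = cos(2 pi k t / T), S[t, k] = sin(2 pi k t / T)
# (t 0-based), with per-bin weights 2/T (1/T at the self-conjugate Nyquist
# bin). Projection with these weights reproduces the ideal
# frequency-domain filter; |X_k| = sqrt((C'x)^2 + (S'x)^2). Working on a
# handful of bins via BLAS products is much faster than full FFTs at
# awkward series lengths.
.basis_cache <- new.env(parent = emptyenv())
band_basis <- function(nt, tr_s, band_hz) {
  key <- paste(nt, tr_s, band_hz[1L], band_hz[2L], sep = "|")
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  keep <- band_bin_indices(nt, tr_s, band_hz)
  t0 <- seq_len(nt) - 1
  ang <- outer(t0, 2 * pi * keep / nt)
  out <- list(keep = keep,
              C = cos(ang), S = sin(ang),
              w = ifelse(keep == nt / 2, 1 / nt, 2 / nt))
  .basis_cache[[key]] <- out
  out
}

#' Ideal band-pass filter
#'
#' Brick-wall frequency-domain filter: discrete Fourier coefficients whose
#' frequency lies in the closed band `[low, high]` are retained (together
#' with their conjugate bins) and every other coefficient, including DC, is
#' zeroed; the inverse transform is returned. Real input yields real
#' output, and the filter is idempotent by construction.
#'
#' @param x numeric vector or T x V matrix (series in columns).
#' @param band_hz length-2 numeric, pass-band edges in Hz.
#' @param tr_s sampling interval (repetition time), seconds.
#' @return filtered data of the same shape.
#' @export
bandpass_filter <- function(x, band_hz, tr_s) {
  nyquist <- 1 / (2 * tr_s)
  if (band_hz[1L] <= 0 || band_hz[2L] > nyquist + 1e-12 ||
      band_hz[1L] >= band_hz[2L])
    stop(sprintf("band (%g, %g) Hz must lie within (0, Nyquist = %g] Hz",
                 band_hz[1L], band_hz[2L], nyquist))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1L) else x
  nt <- nrow(m)
  b <- band_basis(nt, tr_s, band_hz)
  if (length(b$keep) == 0L) return(x * 0)
  out <- b$C %*% (b$w * crossprod(b$C, m)) +
         b$S %*% (b$w * crossprod(b$S, m))
  if (vec) drop(out) else out
}

#' Apply the full temporal/spatial preprocessing chain to one subject
#'
#' Stages in order: discard dummy frames, smooth spatially, remove the
#' voxel-wise linear trend, band-pass filter. Motion screening is a
#' separate subject-level decision (see [screen_motion()]); call it on the
#' motion trace before investing in the volume processing.
#'
#' @param series a [bold_series()].
#' @param params a [preprocess_params()].
#' @param voxel_size_mm isotropic voxel size in mm (from the grid).
#' @param bandpass if `FALSE`, stop after detrending (the ALFF band average
#'   makes the filter a no-op for ALFF itself; connectivity analyses filter).
#' @return a preprocessed `bold_series`.
#' @export
preprocess_bold <- function(series, params = preprocess_params(),
                            voxel_size_mm, bandpass = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  out <- discard_initial_volumes(series, params$n_discard)
  out <- spatial_smooth(out, params$fwhm_mm, voxel_size_mm)
  d <- dim(out$data)
  m <- matrix(out$data, prod(d[1:3]), d[4L])
  m <- t(detrend_linear(t(m)))
  if (bandpass) m <- t(bandpass_filter(t(m), params$band_hz, out$tr_s))
  out$data <- array(m, dim = d)
  out
}
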