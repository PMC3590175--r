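#' Resolve a spherical seed ROI on the analysis grid
#'
#' Collects every in-mask voxel whose centre lies within `diameter_mm / 2`
#' (inclusive) of the given world-space centre. On a 3 mm isotropic grid a
#' 6 mm-diameter sphere centred on a voxel centre resolves to 7 voxels:
#' the centre plus its six face neighbours. A diameter of 0 selects the
#' single voxel whose centre coincides with (or, strictly, lies at
#' distance 0 from) the centre.
#'
#' @param center_mm length-3 world coordinate, mm.
#' @param diameter_mm sphere diameter, mm (default 6).
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `seed_roi`: list with `center_mm`, `diameter_mm`, `voxels`
#'   (linear indices), `ijk` (n x 3 voxel indices).
#' @export
resolve_sphere <- function(center_mm, diameter_mm = 6, mask, affine) {
  stopifnot(length(center_mm) == 3L, diameter_mm >= 0)
  dims <- dim(mask)
  idx <- which(mask)
  ijk <- arrayInd(idx, dims)
  xyz <- voxel_to_world(ijk, affine)
  d2 <- (xyz[, 1L] - center_mm[1L])^2 + (xyz[, 2L] - center_mm[2L])^2 +
        (xyz[, 3L] - center_mm[3L])^2
  inside <- d2 <= (diameter_mm / 2)^2 + 1e-9
  if (!any(inside))
    stop(sprintf("sphere at (%g, %g, %g) mm, diameter %g mm, contains no mask voxels",
                 center_mm[1L], center_mm[2L], center_mm[3L], diameter_mm))
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm,
                 voxels = idx[inside], ijk = ijk[inside, , drop = FALSE]),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat(sprintf("<seed_roi> centre (%g, %g, %g) mm, diameter %g mm, %d voxels\n",
              x$center_mm[1L], x$center_mm[2L], x$center_mm[3L],
              x$diameter_mm, length(x$voxels)))
  invisible(x)
}

#' Peak group-difference voxel within a search region
#'
#' The world coordinate of the voxel with the largest |t| inside the
#' region; ties resolve to the smallest voxel index, so the answer is
#' deterministic.
#'
#' @param stat a `stat_map`.
#' @param region search region: linear indices, n x 3 index matrix, or
#'   logical array on the map grid.
#' @return length-3 world coordinate in mm.
#' @export
peak_difference_voxel <- function(stat, region) {
  stopifnot(inherits(stat, "stat_map"))
  idx <- roi_linear_indices(region, dim(stat$t))
  idx <- idx[stat$mask[idx] & !is.na(stat$t[idx])]
  if (length(idx) == 0L) stop("search region is empty")
  peak <- idx[which.max(abs(stat$t[idx]))]
  voxel_to_world(arrayInd(peak, dim(stat$t))[1L, ], stat$affine)
}

#' Mean time series over a seed ROI
#'
#' @param series a [bold_series()] or 4D array.
#' @param roi a `seed_roi` (or linear voxel indices).
#' @return numeric vector of length T.
#' @export
extract_seed_series <- function(series, roi) {
  arr <- if (inherits(series, "bold_series")) series$data else series
  d <- dim(arr)
  vox <- if (inherits(roi, "seed_roi")) roi$voxels
         else roi_linear_indices(roi, d[1:3])
  m <- matrix(arr, prod(d[1:3]), d[4L])[vox, , drop = FALSE]
  colMeans(m)
}

#' Regress nuisance covariates out of time series
#'
#' Replaces each series by the residual of an ordinary least-squares fit
#' on an intercept plus the six rigid-body motion parameters; residuals
#' are orthogonal to the design. Collinear design columns are dropped
#' with a warning (QR rank detection).
#'
#' @param x numeric vector or T x V matrix (series in columns).
#' @param motion T x 6 motion trace (or any T x k nuisance matrix).
#' @return residuals of the same shape as `x`.
#' @export
regress_out_nuisance <- function(x, motion) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1L) else x
  motion <- as.matrix(motion)
  if (nrow(motion) != nrow(m))
    stop("motion trace has ", nrow(motion), " rows but series has ",
         nrow(m), " time points")
  design <- cbind(1, motion)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_cols <- qrd$pivot[(qrd$rank + 1L):ncol(design)]
    warning("rank-deficient nuisance design; dropping column(s) ",
            paste(drop_cols - 1L, collapse = ", "))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  out <- m - design %*% qr.coef(qrd, m)
  if (vec) drop(out) else out
}

#' Subject-level seed correlation map
#'
#' Pearson correlation of the (nuisance-regressed) seed series with every
#' in-mask voxel series. Zero-variance voxels (or a zero-variance seed)
#' get r = 0, with the count reported in a warning.
#'
#' @param seed_series numeric vector of length T.
#' @param series a [bold_series()] or 4D array of the same length.
#' @param mask 3D logical array.
#' @return an `fc_map`: list with `values` (3D array of r), `space`
#'   (`"r"`), `mask`, `affine` if known.
#' @export
fc_map_subject <- function(seed_series, series, mask) {
  arr <- if (inherits(series, "bold_series")) series$data else series
  affine <- if (inherits(series, "bold_series")) series$affine else NULL
  d <- dim(arr)
  stopifnot(identical(dim(mask), d[1:3]), length(seed_series) == d[4L])
  idx <- which(mask)
  m <- matrix(arr, prod(d[1:3]), d[4L])[idx, , drop = FALSE]
  s <- seed_series - mean(seed_series)
  ss <- sqrt(sum(s^2))
  mc <- m - rowMeans(m)
  denom <- ss * sqrt(rowSums(mc^2))
  r <- ifelse(denom > 0, as.numeric(mc %*% s) / denom, 0)
  nz <- sum(denom == 0)
  if (nz > 0L) warning(nz, " zero-variance voxel(s); r set to 0")
  out <- array(0, dim = d[1:3])
  out[idx] <- r
  structure(list(values = out, space = "r", mask = mask, affine = affine),
            class = "fc_map")
}

#' Fisher z-transformation and its inverse
#'
#' z = atanh(r) = 0.5 log((1 + r) / (1 - r)). Correlations at or beyond
#' |r| = 1 (a seed's own voxels) are clipped to 1 - 1e-7 in magnitude with
#' a warning so the transform stays finite.
#'
#' @param r correlations (any numeric shape, or an `fc_map`).
#' @param z Fisher z values.
#' @return transformed values of the same shape; an `fc_map` input
#'   returns an `fc_map` with `space = "z"`.
#' @export
fisher_z <- function(r) {
  if (inherits(r, "fc_map")) {
    stopifnot(r$space == "r")
    vals <- r$values
    vals[r$mask] <- fisher_z(vals[r$mask])
    r$values <- vals
    r$space <- "z"
    return(r)
  }
  clip <- abs(r) >= 1 - 1e-15
  if (any(clip, na.rm = TRUE)) {
    warning(sum(clip, na.rm = TRUE),
            " correlation(s) at |r| >= 1 clipped before Fisher transform")
    r[which(clip)] <- sign(r[which(clip)]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Within- and between-group statistics on Fisher-z connectivity maps
#'
#' Within each group, a one-sample t map against zero identifies voxels
#' with consistent seed correlation; between groups, a pooled-variance
#' two-sample t map (group B minus group A) tests connectivity
#' differences. The between-group map feeds [cluster_report()] with
#' either AlphaSim cluster-extent or Bonferroni voxel-level correction.
#'
#' @param z_maps list of subject `fc_map`s in z space (or 3D arrays).
#' @param groups character vector of `"A"` / `"B"` labels, one per map.
#' @param mask 3D logical array.
#' @param affine optional 4x4 matrix.
#' @return list with `within` (list `A`, `B` of one-sample `stat_map`s)
#'   and `between` (two-sample `stat_map`).
#' @export
group_fc_maps <- function(z_maps, groups, mask, affine = NULL) {
  stopifnot(length(z_maps) == length(groups),
            all(groups %in% c("A", "B")))
  vals <- lapply(z_maps, function(m)
    if (inherits(m, "fc_map")) m$values else m)
  A <- vals[groups == "A"]
  B <- vals[groups == "B"]
  if (length(A) < 2L || length(B) < 2L)
    stop("need >= 2 subjects per group")
  list(within = list(A = one_sample_t_map(A, mask, affine),
                     B = one_sample_t_map(B, mask, affine)),
       between = two_sample_t_map(A, B, mask, affine))
}

#' Full single-subject seed connectivity analysis
#'
#' Convenience wrapper implementing the standard order of operations:
#' extract the seed mean series, regress the motion parameters out of the
#' seed series and out of every voxel series, correlate, and Fisher
#' z-transform.
#'
#' @param series a preprocessed [bold_series()].
#' @param roi a `seed_roi`.
#' @param motion T x 6 motion trace aligned with `series` (already
#'   truncated to the retained frames).
#' @param mask 3D logical array.
#' @return an `fc_map` in z space.
#' @export
seed_connectivity_subject <- function(series, roi, motion, mask) {
  arr <- if (inherits(series, "bold_series")) series$data else series
  d <- dim(arr)
  seed <- regress_out_nuisance(extract_seed_series(series, roi), motion)
  idx <- which(mask)
  m <- t(matrix(arr, prod(d[1:3]), d[4L])[idx, , drop = FALSE])
  m <- regress_out_nuisance(m, motion)
  resid <- array(0, dim = d)
  tmp <- matrix(0, prod(d[1:3]), d[4L])
  tmp[idx, ] <- t(m)
  resid[] <- tmp
  rs <- if (inherits(series, "bold_series")) {
    series$data <- resid
    series
  } else resid
  fisher_z(fc_map_subject(seed, rs, mask))
}
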