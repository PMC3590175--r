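#' Axis-aligned RAS affine for a synthetic grid
#'
#' Builds the 4x4 voxel-to-world affine used throughout the package for
#' simulated data: axes aligned with RAS world axes, isotropic voxels of
#' `voxel_size_mm`, and the grid centre at the world origin (0, 0, 0) mm.
#' The affine follows the NIfTI convention and maps *0-based* voxel indices
#' to mm; use [voxel_to_world()] / [world_to_voxel()] to convert the 1-based
#' indices R arrays use.
#'
#' @param dims integer vector of length 3, grid dimensions in voxels.
#' @param voxel_size_mm positive scalar, isotropic voxel edge in mm.
#' @return a 4x4 numeric matrix.
#' @export
grid_affine <- function(dims, voxel_size_mm) {
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size_mm > 0)
  aff <- diag(c(rep(voxel_size_mm, 3L), 1))
  aff[1:3, 4L] <- -voxel_size_mm * (dims - 1) / 2
  aff
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps 1-based voxel indices (as used to subscript R
#' arrays) to world mm via a NIfTI affine (which is defined on 0-based
#' indices); `world_to_voxel()` is the inverse, rounding to the nearest
#' voxel.
#'
#' @param ijk numeric matrix (n x 3) or length-3 vector of 1-based indices.
#' @param xyz numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return an n x 3 matrix (or length-3 vector for vector input).
#' @export
voxel_to_world <- function(ijk, affine) {
  v <- !is.matrix(ijk)
  if (v) ijk <- matrix(ijk, nrow = 1L)
  out <- cbind(ijk - 1, 1) %*% t(affine[1:3, , drop = FALSE])
  if (v) out[1L, ] else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(xyz, affine) {
  v <- !is.matrix(xyz)
  if (v) xyz <- matrix(xyz, nrow = 1L)
  inv <- solve(affine)
  out <- round(cbind(xyz, 1) %*% t(inv[1:3, , drop = FALSE])) + 1
  storage.mode(out) <- "integer"
  if (v) out[1L, ] else out
}

#' Neighbourhood offsets for 3D cluster connectivity
#'
#' @param connectivity one of 6 (faces), 18 (faces + edges), 26 (full cube).
#' @return an m x 3 integer matrix of index offsets.
#' @keywords internal
neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26, got ", connectivity)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1L,
    "18" = rowSums(abs(g)) <= 2L,
    "26" = rep(TRUE, nrow(g)))
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

# Brett's piecewise-affine MNI -> Talairach mapping: one linear map for
# z >= 0 and one for z < 0; both agree at z = 0 so the mapping is continuous.
.brett_above <- matrix(c(
  0.9900, 0.0000,  0.0000,
  0.0000, 0.9688,  0.0460,
  0.0000, -0.0485, 0.9189), 3L, 3L, byrow = TRUE)
.brett_below <- matrix(c(
  0.9900, 0.0000,  0.0000,
  0.0000, 0.9688,  0.0420,
  0.0000, -0.0485, 0.8390), 3L, 3L, byrow = TRUE)

#' Convert MNI coordinates to Talairach-Tournoux coordinates
#'
#' Applies the conventional piecewise-linear mapping (separate matrices for
#' the volume above and below the AC-PC plane, z >= 0 and z < 0) between the
#' MNI template frame and the Talairach and Tournoux atlas frame.
#' `talairach_to_mni()` inverts it.
#'
#' @param xyz length-3 vector or n x 3 matrix of mm coordinates.
#' @return coordinates of the same shape in the target frame.
#' @export
mni_to_talairach <- function(xyz) {
  v <- !is.matrix(xyz)
  if (v) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  out <- xyz
  up <- xyz[, 3L] >= 0
  if (any(up))  out[up, ]  <- xyz[up, , drop = FALSE] %*% t(.brett_above)
  if (any(!up)) out[!up, ] <- xyz[!up, , drop = FALSE] %*% t(.brett_below)
  if (v) out[1L, ] else out
}

#' @rdname mni_to_talairach
#' @export
talairach_to_mni <- function(xyz) {
  v <- !is.matrix(xyz)
  if (v) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  inv_above <- solve(.brett_above)
  inv_below <- solve(.brett_below)
  out <- xyz %*% t(inv_above)
  # branch is decided by the sign of z in MNI space, i.e. after inversion
  below <- out[, 3L] < 0
  if (any(below)) out[below, ] <- xyz[below, , drop = FALSE] %*% t(inv_below)
  if (v) out[1L, ] else out
}
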