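#' Two-tailed Student-t critical value
#'
#' The value q with P(|T_df| > q) = alpha. At alpha = 0.01 and df = 28
#' this is 2.7633, the voxel threshold printed on standard resting-state
#' group-difference maps.
#'
#' @param alpha_two_tailed two-tailed tail probability in (0, 1].
#' @param df degrees of freedom (>= 1).
#' @return positive scalar threshold.
#' @export
t_critical <- function(alpha_two_tailed, df) {
  if (!is.finite(alpha_two_tailed) || alpha_two_tailed <= 0 ||
      alpha_two_tailed > 1)
    stop("alpha must be in (0, 1], got ", alpha_two_tailed)
  if (!is.finite(df) || df < 1) stop("df must be >= 1, got ", df)
  stats::qt(1 - alpha_two_tailed / 2, df)
}

#' Bonferroni voxel-level t threshold
#'
#' Family-wise-error control by Bonferroni over the in-mask voxels:
#' the two-tailed critical value at `alpha / n_voxels`.
#'
#' @param alpha family-wise two-tailed alpha.
#' @param df degrees of freedom.
#' @param n_voxels number of in-mask voxels tested.
#' @return positive scalar threshold.
#' @export
bonferroni_t_threshold <- function(alpha, df, n_voxels) {
  stopifnot(n_voxels >= 1)
  t_critical(alpha / n_voxels, df)
}

# Stack subject maps into an (in-mask voxels) x (subjects) matrix.
as_map_matrix <- function(maps, mask) {
  idx <- which(mask)
  if (is.array(maps) && length(dim(maps)) == 4L) {
    stopifnot(identical(dim(maps)[1:3], dim(mask)))
    return(matrix(maps, prod(dim(mask)), dim(maps)[4L])[idx, , drop = FALSE])
  }
  stopifnot(is.list(maps), length(maps) >= 1L)
  vapply(maps, function(m) {
    v <- if (inherits(m, "alff_map")) m$values else m
    stopifnot(identical(dim(v), dim(mask)))
    v[idx]
  }, numeric(length(idx)))
}

#' Voxel-wise two-sample t map
#'
#' Pooled-variance (Student) two-sample t at every in-mask voxel, with
#' df = nA + nB - 2 and sign convention group B minus group A — so with
#' controls as A and patients as B, negative t means reduced in patients.
#' Voxels with zero pooled variance get t = 0 (their count is reported
#' with a warning).
#'
#' @param mapsA,mapsB subject maps per group: a list of 3D arrays /
#'   `alff_map`s, or a 4D array stacked over subjects.
#' @param mask 3D logical array.
#' @param affine optional 4x4 voxel-to-world matrix carried into reports.
#' @return a `stat_map`: list with `t` (3D array, 0 outside mask), `df`,
#'   `n_per_group`, `mask`, `affine`.
#' @export
two_sample_t_map <- function(mapsA, mapsB, mask, affine = NULL) {
  A <- as_map_matrix(mapsA, mask)
  B <- as_map_matrix(mapsB, mask)
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2L || nB < 2L) stop("need >= 2 subjects per group")
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  df <- nA + nB - 2L
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tval <- ifelse(se > 0, (mB - mA) / se, 0)
  nzv <- sum(se == 0)
  if (nzv > 0L)
    warning(nzv, " in-mask voxel(s) with zero pooled variance; t set to 0")
  out <- array(0, dim = dim(mask))
  out[mask] <- tval
  structure(list(t = out, df = df, n_per_group = c(A = nA, B = nB),
                 mask = mask, affine = affine),
            class = "stat_map")
}

#' Voxel-wise one-sample t map against zero
#'
#' Used for within-group connectivity maps: t = mean / (sd / sqrt(n)) at
#' each in-mask voxel, df = n - 1. Zero-variance voxels are masked out
#' (set to `NA`) with a warning.
#'
#' @param maps subject maps (list of 3D arrays or 4D array).
#' @param mask 3D logical array.
#' @param affine optional 4x4 matrix.
#' @return a `stat_map` with possible `NA` at degenerate voxels.
#' @export
one_sample_t_map <- function(maps, mask, affine = NULL) {
  M <- as_map_matrix(maps, mask)
  n <- ncol(M)
  if (n < 2L) stop("need >= 2 subjects")
  mu <- rowMeans(M)
  sd_ <- sqrt(rowSums((M - mu)^2) / (n - 1L))
  tval <- ifelse(sd_ > 0, mu / (sd_ / sqrt(n)), NA_real_)
  if (anyNA(tval))
    warning(sum(is.na(tval)),
            " in-mask voxel(s) with zero variance masked out")
  out <- array(0, dim = dim(mask))
  out[mask] <- tval
  structure(list(t = out, df = n - 1L, n_per_group = c(n = n),
                 mask = mask, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, df = %d, |t| range %.3f-%.3f in mask\n",
              paste(dim(x$t), collapse = "x"), x$df,
              min(abs(x$t[x$mask]), na.rm = TRUE),
              max(abs(x$t[x$mask]), na.rm = TRUE)))
  invisible(x)
}

#' Label connected clusters in a 3D binary map
#'
#' Connected-component labelling under 6- (faces), 18- (faces + edges) or
#' 26- (full cube) connectivity. Components are returned ordered by
#' decreasing size, ties broken by smallest linear voxel index, so the
#' labelling is deterministic.
#'
#' @param bin 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return list of integer vectors of linear voxel indices, one per
#'   cluster.
#' @export
label_clusters <- function(bin, connectivity = 6L) {
  offs <- neighbor_offsets(connectivity)
  dims <- dim(bin)
  stopifnot(length(dims) == 3L)
  idx <- which(bin)
  if (length(idx) == 0L) return(list())
  lab <- array(0L, dims)
  m <- nrow(offs)
  clusters <- list()
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    lab[v] <- cur
    members <- v
    frontier <- v
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, dims)
      nb <- co[rep(seq_len(nrow(co)), each = m), , drop = FALSE] +
            offs[rep(seq_len(m), nrow(co)), , drop = FALSE]
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1L] + dims[1L] * (nb[, 2L] - 1L) +
                    dims[1L] * dims[2L] * (nb[, 3L] - 1L))
      lin <- lin[bin[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      members <- c(members, lin)
      frontier <- lin
    }
    clusters[[cur]] <- sort(members)
  }
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, `[`, integer(1L), 1L)
  clusters[order(-sizes, firsts)]
}

#' Monte-Carlo (AlphaSim-style) minimum cluster extent
#'
#' Estimates the smallest cluster size k such that, under the null, the
#' probability that a thresholded smooth noise map contains any cluster of
#' at least k voxels is at most `corrected_alpha`. Each iteration fills
#' the volume with unit Gaussian noise, smooths it to the analysis FWHM,
#' re-standardises the in-mask values to zero mean / unit variance,
#' applies the two-tailed voxel threshold, and records the largest
#' connected cluster.
#'
#' @param mask 3D logical array.
#' @param fwhm_mm smoothing kernel FWHM, mm (0 = independent voxels).
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param voxel_p two-tailed voxel-level p threshold.
#' @param corrected_alpha family-wise alpha to control.
#' @param n_iter Monte-Carlo iterations (>= 1000 for production use).
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `k_min`, `max_cluster_sizes` (length `n_iter`),
#'   `mean_suprathreshold_voxels`, `z_threshold`, and the call parameters.
#' @export
alphasim_min_extent <- function(mask, fwhm_mm, voxel_size_mm, voxel_p,
                                corrected_alpha = 0.05, n_iter = 1000L,
                                connectivity = 6L, seed = NULL) {
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must be in (0, 1)")
  if (corrected_alpha <= 0 || corrected_alpha > 1)
    stop("corrected_alpha must be in (0, 1]")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  zc <- stats::qnorm(1 - voxel_p / 2)
  dims <- dim(mask)
  idx <- which(mask)
  max_sizes <- integer(n_iter)
  n_supra <- integer(n_iter)
  bin <- array(FALSE, dims)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(dims)), dims)
    if (fwhm_mm > 0)
      noise <- spatial_smooth(noise, fwhm_mm, voxel_size_mm)
    v <- noise[idx]
    v <- (v - mean(v)) / stats::sd(v)
    supra <- abs(v) > zc
    n_supra[it] <- sum(supra)
    if (n_supra[it] == 0L) { max_sizes[it] <- 0L; next }
    bin[] <- FALSE
    bin[idx[supra]] <- TRUE
    cl <- label_clusters(bin, connectivity)
    max_sizes[it] <- max(lengths(cl))
  }
  # smallest k with P(max cluster >= k) <= corrected_alpha
  k <- 1L
  while (mean(max_sizes >= k) > corrected_alpha) k <- k + 1L
  list(k_min = k, max_cluster_sizes = max_sizes,
       mean_suprathreshold_voxels = mean(n_supra),
       z_threshold = zc, voxel_p = voxel_p,
       corrected_alpha = corrected_alpha, fwhm_mm = fwhm_mm,
       connectivity = connectivity, n_iter = n_iter)
}

#' Cluster report from a thresholded statistic map
#'
#' Thresholds a [two_sample_t_map()] two-tailed at `t_crit`, labels
#' positive and negative suprathreshold voxels separately, keeps clusters
#' of at least `k_min` voxels, and reports each surviving cluster's peak
#' (the voxel of maximum |t|, ties broken by lexicographically smallest
#' voxel index) in world mm together with the peak t, cluster size and
#' sign. Rows are ordered by decreasing cluster size.
#'
#' @param stat a `stat_map`.
#' @param t_crit two-tailed voxel threshold (e.g. [t_critical()] output).
#' @param k_min minimum cluster extent in voxels (clusters of size
#'   >= `k_min` survive; an AlphaSim "cluster > k" rule corresponds to
#'   `k_min = k + 1`).
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param exclude optional voxels to drop before labelling (linear
#'   indices, n x 3 index matrix, or logical array) — e.g. the seed sphere
#'   in a connectivity contrast.
#' @param seed_label optional label copied into the report's `seed`
#'   column.
#' @return data.frame with columns `seed`, `x_mm`, `y_mm`, `z_mm`,
#'   `peak_t`, `cluster_size`, `sign` (possibly 0 rows).
#' @export
cluster_report <- function(stat, t_crit, k_min, connectivity = 6L,
                           exclude = NULL, seed_label = NA_character_) {
  stopifnot(inherits(stat, "stat_map"), t_crit > 0, k_min >= 1)
  tmap <- stat$t
  keep <- stat$mask & !is.na(tmap)
  if (!is.null(exclude))
    keep[roi_linear_indices(exclude, dim(tmap))] <- FALSE
  rows <- list()
  for (sgn in c(1, -1)) {
    bin <- keep & (sgn * tmap > t_crit)
    cl <- label_clusters(bin, connectivity)
    cl <- cl[lengths(cl) >= k_min]
    for (vox in cl) {
      peak <- vox[which.max(sgn * tmap[vox])]   # which.max: first = smallest
      xyz <- if (!is.null(stat$affine))
        voxel_to_world(arrayInd(peak, dim(tmap))[1L, ], stat$affine)
      else as.numeric(arrayInd(peak, dim(tmap))[1L, ])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed_label, x_mm = xyz[1L], y_mm = xyz[2L], z_mm = xyz[3L],
        peak_t = tmap[peak], cluster_size = length(vox),
        sign = as.integer(sgn),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L)
    data.frame(seed = character(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric(), peak_t = numeric(),
               cluster_size = integer(), sign = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  out[order(-out$cluster_size, out$x_mm, out$y_mm, out$z_mm), ,
      drop = FALSE]
}

#' Write a cluster report as TSV
#'
#' @param report a [cluster_report()] data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
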