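#' Monte-Carlo calibration and recovery studies
#'
#' These drivers run the full analysis chain (simulate, preprocess, ALFF,
#' group statistics, connectivity, clinical association) over many
#' independently seeded synthetic cohorts, and summarise how often the
#' chain (a) stays silent when nothing is planted and (b) recovers what
#' was planted. They are the package's empirical calibration evidence.
#'
#' `study_alff_null()` runs no-effect cohorts and reports the fraction of
#' replicates whose corrected ALFF cluster report is empty (the family-wise
#' specificity of the corrected map).
#'
#' `study_alff_recovery()` plants a band-amplitude region (ratio 1.5 by
#' default) and reports how often a surviving cluster of the right sign
#' peaks inside the planted region.
#'
#' `study_fc_recovery()` plants a seed-target shared signal (mixing weight
#' 0.8 vs 0.2) and reports how often the between-group connectivity
#' report recovers the target region.
#'
#' `study_assoc_power()` plants the negative amplitude-duration coupling
#' (the `"clinical"` preset) and reports how often the partial
#' correlation (controlling age, education, nicotine) is negative and
#' significant at p < 0.05.
#'
#' The Monte-Carlo cluster threshold is computed once per study from the
#' shared mask and reused across replicates (the null distribution does
#' not depend on the data).
#'
#' @param n_replicates number of independent cohorts.
#' @param grid_dims simulation grid (voxels).
#' @param n_per_group subjects per group.
#' @param fwhm_mm smoothing kernel FWHM, mm.
#' @param voxel_p voxel-level two-tailed p threshold.
#' @param corrected_alpha family-wise alpha for the cluster correction.
#' @param n_iter Monte-Carlo iterations for the cluster-extent null.
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @param ... further arguments to [simulation_preset()].
#' @return a data.frame with one row per replicate plus study-level
#'   attributes (`k_min`, `t_crit`); see each function's `detected` /
#'   `empty` / `significant` column.
#' @name studies
NULL

# Standardized ALFF maps for every (or a subset of) cohort subjects.
.cohort_alff <- function(co, pp, vs, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(co$subjects) else subset
  maps <- lapply(idx, function(i)
    standardize_alff(alff_map(
      preprocess_bold(co$subjects[[i]]$bold, pp, voxel_size_mm = vs),
      co$mask, band_hz = pp$band_hz)))
  names(maps) <- co$manifest$subject[idx]
  maps
}

# Is any report row of the expected sign peaked inside the planted region?
.report_hits <- function(report, center_mm, radius_mm, sign_expected) {
  if (nrow(report) == 0L) return(FALSE)
  d <- sqrt((report$x_mm - center_mm[1L])^2 +
            (report$y_mm - center_mm[2L])^2 +
            (report$z_mm - center_mm[3L])^2)
  any(d <= radius_mm + 1e-9 & report$sign == sign_expected)
}

#' @rdname studies
#' @export
study_alff_null <- function(n_replicates = 20L,
                            grid_dims = c(24L, 24L, 18L),
                            n_per_group = c(15L, 17L),
                            fwhm_mm = 8, voxel_p = 0.01,
                            corrected_alpha = 0.05, n_iter = 1000L,
                            seed = 1L, ...) {
  cfg0 <- simulation_preset("null", grid_dims = grid_dims, seed = seed,
                            n_per_group = n_per_group, ...)
  mask <- make_brain_mask(cfg0)
  vs <- cfg0$voxel_size_mm
  null_dist <- alphasim_min_extent(mask, fwhm_mm, vs, voxel_p,
                                   corrected_alpha, n_iter,
                                   seed = seed)
  pp <- preprocess_params(fwhm_mm = fwhm_mm)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- simulation_preset("null", grid_dims = grid_dims,
                             seed = seed + r, n_per_group = n_per_group,
                             ...)
    co <- generate_cohort(cfg)
    maps <- .cohort_alff(co, pp, vs)
    st <- two_sample_t_map(maps[co$manifest$group == "A"],
                           maps[co$manifest$group == "B"], mask,
                           co$affine)
    rep_ <- cluster_report(st, t_critical(voxel_p, st$df),
                           null_dist$k_min)
    data.frame(replicate = r, empty = nrow(rep_) == 0L,
               n_clusters = nrow(rep_), max_abs_t = max(abs(st$t)))
  })
  out <- do.call(rbind, rows)
  attr(out, "k_min") <- null_dist$k_min
  out
}

#' @rdname studies
#' @export
study_alff_recovery <- function(n_replicates = 25L,
                                grid_dims = c(16L, 16L, 12L),
                                n_per_group = c(15L, 17L),
                                fwhm_mm = 8, voxel_p = 0.01,
                                corrected_alpha = 0.05, n_iter = 1000L,
                                seed = 1L, ...) {
  cfg0 <- simulation_preset("amplitude", grid_dims = grid_dims,
                            seed = seed, n_per_group = n_per_group, ...)
  mask <- make_brain_mask(cfg0)
  vs <- cfg0$voxel_size_mm
  roi <- cfg0$effect_rois[[1L]]
  sign_expected <- if (roi$amplitude_ratio >= 1) 1L else -1L
  null_dist <- alphasim_min_extent(mask, fwhm_mm, vs, voxel_p,
                                   corrected_alpha, n_iter, seed = seed)
  pp <- preprocess_params(fwhm_mm = fwhm_mm)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- simulation_preset("amplitude", grid_dims = grid_dims,
                             seed = seed + r, n_per_group = n_per_group,
                             ...)
    co <- generate_cohort(cfg)
    maps <- .cohort_alff(co, pp, vs)
    st <- two_sample_t_map(maps[co$manifest$group == "A"],
                           maps[co$manifest$group == "B"], mask,
                           co$affine)
    rep_ <- cluster_report(st, t_critical(voxel_p, st$df),
                           null_dist$k_min)
    data.frame(replicate = r,
               detected = .report_hits(rep_, roi$center_mm, roi$radius_mm,
                                       sign_expected),
               n_clusters = nrow(rep_))
  })
  out <- do.call(rbind, rows)
  attr(out, "k_min") <- null_dist$k_min
  out
}

#' @rdname studies
#' @export
study_fc_recovery <- function(n_replicates = 25L,
                              grid_dims = c(16L, 16L, 12L),
                              n_per_group = c(15L, 17L),
                              fwhm_mm = 8, voxel_p = 0.01,
                              corrected_alpha = 0.05, n_iter = 1000L,
                              seed = 1L, ...) {
  cfg0 <- simulation_preset("connectivity", grid_dims = grid_dims,
                            seed = seed, n_per_group = n_per_group, ...)
  mask <- make_brain_mask(cfg0)
  vs <- cfg0$voxel_size_mm
  eff <- cfg0$connectivity_effects[[1L]]
  sign_expected <- if (eff$weight[["B"]] >= eff$weight[["A"]]) 1L else -1L
  null_dist <- alphasim_min_extent(mask, fwhm_mm, vs, voxel_p,
                                   corrected_alpha, n_iter, seed = seed)
  pp <- preprocess_params(fwhm_mm = fwhm_mm)
  affine <- grid_affine(grid_dims, vs)
  roi <- resolve_sphere(eff$seed_center_mm, 6, mask, affine)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- simulation_preset("connectivity", grid_dims = grid_dims,
                             seed = seed + r, n_per_group = n_per_group,
                             ...)
    co <- generate_cohort(cfg)
    z_maps <- lapply(co$subjects, function(s) {
      prep <- preprocess_bold(s$bold, pp, voxel_size_mm = vs)
      seed_connectivity_subject(
        prep, roi, s$motion[(pp$n_discard + 1L):nrow(s$motion), ], mask)
    })
    gs <- group_fc_maps(z_maps, co$manifest$group, mask, co$affine)
    rep_ <- cluster_report(gs$between,
                           t_critical(voxel_p, gs$between$df),
                           null_dist$k_min, exclude = roi$voxels)
    data.frame(replicate = r,
               detected = .report_hits(rep_, eff$target_center_mm,
                                       eff$radius_mm, sign_expected),
               n_clusters = nrow(rep_))
  })
  out <- do.call(rbind, rows)
  attr(out, "k_min") <- null_dist$k_min
  out
}

#' @rdname studies
#' @export
study_assoc_power <- function(n_replicates = 50L,
                              grid_dims = c(16L, 16L, 12L),
                              n_per_group = c(2L, 17L),
                              fwhm_mm = 8, seed = 1L, ...) {
  pp <- preprocess_params(fwhm_mm = fwhm_mm)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- simulation_preset("clinical", grid_dims = grid_dims,
                             seed = seed + r, n_per_group = n_per_group,
                             ...)
    co <- generate_cohort(cfg)
    isB <- which(co$manifest$group == "B")
    maps <- .cohort_alff(co, pp, cfg$voxel_size_mm, subset = isB)
    roi <- cfg$effect_rois[[1L]]
    vox <- resolve_sphere(roi$center_mm, 2 * roi$radius_mm, co$mask,
                          co$affine)$voxels
    res <- alff_use_association(maps, vox,
                                co$manifest[isB, , drop = FALSE],
                                use_vars = "duration")
    data.frame(replicate = r, r_partial = res$r_partial[1L],
               p = res$p[1L],
               significant = res$p[1L] < 0.05 & res$r_partial[1L] < 0)
  })
  do.call(rbind, rows)
}
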