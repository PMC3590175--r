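#' Configuration for the synthetic two-group BOLD cohort simulator
#'
#' Defines the generative model for a two-group resting-state cohort on a
#' common grid. Each voxel's series is a band-limited Gaussian fluctuation
#' (white noise ideally filtered to `band_hz`, matching the analysis
#' filter), scaled by a region amplitude factor that differs between groups
#' inside planted effect ROIs, plus AR(1) scanner noise and a random linear
#' drift. Seed/target voxel pairs of a planted connectivity effect
#' additionally mix in a common latent band-limited signal with a
#' group-specific weight. Defaults mirror a 3 T resting-state acquisition:
#' TR 2 s, 155 acquired frames (5 min 10 s), 15 + 17 subjects,
#' 0.01-0.08 Hz fluctuations on a 3 mm grid.
#'
#' @param grid_dims integer 3-vector, grid size in voxels (each >= 8).
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param tr_s repetition time, seconds.
#' @param n_volumes_acquired frames acquired per subject (before dummies
#'   are discarded downstream).
#' @param n_per_group integer 2-vector, subjects in group A (controls) and
#'   group B (patients).
#' @param band_hz pass band of the fluctuation signal, Hz.
#' @param signal_sd standard deviation of the band-limited fluctuation.
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param ar1_coef lag-1 autocorrelation of the noise, in [0, 1).
#' @param drift_slope_sd SD of the per-voxel linear drift slope, signal
#'   units per frame.
#' @param effect_rois list of planted amplitude effects, each a list with
#'   `center_mm` (length-3), `radius_mm`, `amplitude_ratio` (group B
#'   amplitude relative to group A; 1 = no effect).
#' @param connectivity_effects list of planted connectivity effects, each a
#'   list with `seed_center_mm`, `target_center_mm`, `radius_mm`, and
#'   `weight` (named numeric `c(A = , B = )`, shared-signal mixing weight
#'   per group, each in [0, 1]).
#' @param motion_step_mm,motion_step_deg per-frame step SD of the
#'   random-walk motion trace (translations mm, rotations degrees).
#' @param inject_motion_violator if `TRUE`, one subject per cohort gets a
#'   motion spike exceeding the 1 mm screen (for testing exclusion).
#' @param duration_roi index into `effect_rois` of the region whose
#'   subject-level amplitude couples to drug-use duration in group B
#'   (`NA` for none).
#' @param use_alff_rho latent correlation between the duration-coupled
#'   region amplitude and drug-use duration/dose (applied with negative
#'   sign: longer use, lower amplitude).
#' @param amp_subject_cv between-subject coefficient of variation of the
#'   duration-coupled region amplitude in group B.
#' @param seed integer RNG seed for the whole cohort.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(grid_dims = c(24L, 24L, 18L),
                              voxel_size_mm = 3,
                              tr_s = 2,
                              n_volumes_acquired = 155L,
                              n_per_group = c(15L, 17L),
                              band_hz = c(0.01, 0.08),
                              signal_sd = 1,
                              noise_sd = 1,
                              ar1_coef = 0.3,
                              drift_slope_sd = 0.005,
                              effect_rois = list(),
                              connectivity_effects = list(),
                              motion_step_mm = 0.02,
                              motion_step_deg = 0.02,
                              inject_motion_violator = FALSE,
                              duration_roi = NA_integer_,
                              use_alff_rho = 0.8,
                              amp_subject_cv = 0.3,
                              seed = 1L) {
  stopifnot(length(grid_dims) == 3L, voxel_size_mm > 0, tr_s > 0,
            length(n_per_group) == 2L,
            length(band_hz) == 2L, band_hz[1L] > 0,
            band_hz[1L] < band_hz[2L],
            band_hz[2L] <= 1 / (2 * tr_s) + 1e-12,
            signal_sd >= 0, noise_sd >= 0,
            ar1_coef >= 0, ar1_coef < 1,
            motion_step_mm > 0, motion_step_deg > 0,
            use_alff_rho >= 0, use_alff_rho <= 1, amp_subject_cv >= 0)
  if (any(grid_dims < 8L))
    stop("degenerate grid: every dimension must be >= 8 voxels")
  if (n_volumes_acquired * tr_s < 1 / band_hz[1L])
    stop("scan too short: need at least one full cycle of ",
         band_hz[1L], " Hz (", 1 / band_hz[1L], " s)")
  for (e in effect_rois)
    stopifnot(length(e$center_mm) == 3L, e$radius_mm > 0,
              e$amplitude_ratio >= 0)
  for (e in connectivity_effects)
    stopifnot(length(e$seed_center_mm) == 3L,
              length(e$target_center_mm) == 3L, e$radius_mm > 0,
              all(c("A", "B") %in% names(e$weight)),
              all(e$weight >= 0), all(e$weight <= 1))
  structure(list(grid_dims = as.integer(grid_dims),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes_acquired = as.integer(n_volumes_acquired),
                 n_per_group = as.integer(n_per_group),
                 band_hz = band_hz, signal_sd = signal_sd,
                 noise_sd = noise_sd, ar1_coef = ar1_coef,
                 drift_slope_sd = drift_slope_sd,
                 effect_rois = effect_rois,
                 connectivity_effects = connectivity_effects,
                 motion_step_mm = motion_step_mm,
                 motion_step_deg = motion_step_deg,
                 inject_motion_violator = inject_motion_violator,
                 duration_roi = duration_roi,
                 use_alff_rho = use_alff_rho,
                 amp_subject_cv = amp_subject_cv,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Preset simulation configurations for calibration and recovery studies
#'
#' Four named study conditions on the reference grid:
#' `"null"` — no planted effects (groups exchangeable by construction);
#' `"amplitude"` — one 6 mm-radius region with a pure 1.5x group-B
#' band-amplitude ratio (no subject-level spread), the group-detection
#' condition;
#' `"connectivity"` — a seed/target region pair sharing a latent signal with
#' weight 0.8 in group B versus 0.2 in group A;
#' `"clinical"` — the amplitude region plus subject-level amplitude spread
#' coupled to drug-use duration (latent correlation 0.8), the
#' association condition. The spread that creates the coupling also
#' inflates group-B variance, so the pure-ratio and coupled conditions
#' are deliberately separate presets: each study plants exactly the
#' effect it measures.
#'
#' @param effect one of `"null"`, `"amplitude"`, `"connectivity"`,
#'   `"clinical"`.
#' @param grid_dims grid size in voxels.
#' @param seed cohort RNG seed.
#' @param ... further arguments passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
simulation_preset <- function(effect = c("null", "amplitude",
                                         "connectivity", "clinical"),
                              grid_dims = c(24L, 24L, 18L), seed = 1L, ...) {
  effect <- match.arg(effect)
  # centers scale with the grid so presets remain inside the ellipsoidal
  # mask on smaller grids
  sc <- min(grid_dims / c(24, 24, 18))
  roi_center <- c(9, 12, 3) * sc
  seed_center <- c(9, 12, 3) * sc
  target_center <- c(-12, -15, 3) * sc
  amp_roi <- list(list(center_mm = roi_center, radius_mm = 6,
                       amplitude_ratio = 1.5))
  args <- switch(effect,
    null = list(),
    amplitude = list(effect_rois = amp_roi),
    clinical = list(effect_rois = amp_roi, duration_roi = 1L),
    connectivity = list(
      connectivity_effects = list(list(seed_center_mm = seed_center,
                                       target_center_mm = target_center,
                                       radius_mm = 6,
                                       weight = c(A = 0.2, B = 0.8)))))
  do.call(simulation_config,
          c(list(grid_dims = grid_dims, seed = seed), args, list(...)))
}

#' Ellipsoidal brain mask for a simulation grid
#'
#' A centred axis-aligned ellipsoid with semi-axes 0.45 of each grid
#' dimension — nonempty, strictly inside the volume, and symmetric about
#' the grid centre (which the simulation affine places at the world
#' origin).
#'
#' @param config a [simulation_config()] (or an integer 3-vector of grid
#'   dims).
#' @return 3D logical array.
#' @export
make_brain_mask <- function(config) {
  dims <- if (inherits(config, "simulation_config")) config$grid_dims
          else as.integer(config)
  if (any(dims < 8L)) stop("degenerate grid: every dimension must be >= 8")
  ctr <- (dims + 1) / 2
  semi <- 0.45 * dims
  i <- (seq_len(dims[1L]) - ctr[1L]) / semi[1L]
  j <- (seq_len(dims[2L]) - ctr[2L]) / semi[2L]
  k <- (seq_len(dims[3L]) - ctr[3L]) / semi[3L]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  r2 <= 1
}

# Resolve the simulator's geometry once: mask, affine, world coordinates of
# every voxel, and linear-index voxel sets of every planted region.
sim_geometry <- function(config) {
  mask <- make_brain_mask(config)
  affine <- grid_affine(config$grid_dims, config$voxel_size_mm)
  dims <- config$grid_dims
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  xyz <- voxel_to_world(ijk, affine)
  sphere <- function(center, radius) {
    d2 <- (xyz[, 1L] - center[1L])^2 + (xyz[, 2L] - center[2L])^2 +
          (xyz[, 3L] - center[3L])^2
    idx <- which(d2 <= radius^2 + 1e-9)
    if (length(idx) == 0L)
      stop("planted region at (", paste(center, collapse = ", "),
           ") mm resolves to no voxels")
    if (!all(mask[idx]))
      stop("planted region at (", paste(center, collapse = ", "),
           ") mm is not fully inside the brain mask")
    idx
  }
  rois <- lapply(config$effect_rois,
                 function(e) sphere(e$center_mm, e$radius_mm))
  conn <- lapply(config$connectivity_effects, function(e)
    list(seed = sphere(e$seed_center_mm, e$radius_mm),
         target = sphere(e$target_center_mm, e$radius_mm)))
  list(mask = mask, affine = affine, rois = rois, conn = conn)
}

# Band-limited unit-variance Gaussian signal, synthesised directly in the
# frequency domain: independent complex-Gaussian coefficients on the
# in-band bins (conjugate-symmetric), zero elsewhere — the distribution of
# white noise ideally filtered to the band. Scaled by the theoretical
# (not empirical) SD so planted amplitude ratios are exact in expectation
# and identical across voxels.
.band_signal <- function(nt, ncol, tr_s, band_hz) {
  b <- band_basis(nt, tr_s, band_hz)
  pair <- b$keep < nt / 2                      # skip Nyquist self-conjugate
  C <- b$C[, pair, drop = FALSE]
  S <- b$S[, pair, drop = FALSE]
  nk <- ncol(C)
  A <- matrix(stats::rnorm(nk * ncol), nk, ncol)
  B <- matrix(stats::rnorm(nk * ncol), nk, ncol)
  (C %*% A - S %*% B) / sqrt(nk)
}

#' Generate one synthetic subject
#'
#' Draws a full 4D acquisition plus motion trace for one subject under the
#' configured generative model. All randomness comes from `seed`, so a
#' repeated call is bit-identical.
#'
#' @param config a [simulation_config()].
#' @param group `"A"` (control) or `"B"` (patient).
#' @param seed integer RNG seed for this subject.
#' @param latent_u subject-level standard-normal latent scaling the
#'   duration-coupled region amplitude (group B only; drawn by
#'   [generate_cohort()]).
#' @param motion_violator force a suprathreshold motion spike.
#' @param geometry optional precomputed [sim_geometry] (an optimisation for
#'   cohort generation).
#' @return list with `bold` (a [bold_series()]) and `motion` (T x 6 matrix).
#' @export
generate_subject <- function(config, group, seed, latent_u = 0,
                             motion_violator = FALSE, geometry = NULL) {
  if (!group %in% c("A", "B")) stop("unknown group label: ", group)
  if (is.null(geometry)) geometry <- sim_geometry(config)
  set.seed(as.integer(seed))
  dims <- config$grid_dims
  nv <- prod(dims)
  nt <- config$n_volumes_acquired

  # voxel-wise amplitude factors
  amp <- rep(1, nv)
  for (r in seq_along(geometry$rois)) {
    f <- if (group == "B") config$effect_rois[[r]]$amplitude_ratio else 1
    if (group == "B" && !is.na(config$duration_roi) &&
        r == config$duration_roi)
      f <- f * max(0.2, 1 + config$amp_subject_cv * latent_u)
    amp[geometry$rois[[r]]] <- f
  }

  sig <- .band_signal(nt, nv, config$tr_s, config$band_hz)
  for (e in seq_along(geometry$conn)) {
    w <- unname(config$connectivity_effects[[e]]$weight[group])
    vox <- c(geometry$conn[[e]]$seed, geometry$conn[[e]]$target)
    shared <- .band_signal(nt, 1L, config$tr_s, config$band_hz)
    sig[, vox] <- sqrt(1 - w^2) * sig[, vox, drop = FALSE] +
      w * matrix(shared, nt, length(vox))
  }
  x <- sig * rep(config$signal_sd * amp, each = nt)

  if (config$noise_sd > 0) {
    phi <- config$ar1_coef
    innov <- matrix(stats::rnorm(nt * nv,
                                 sd = config$noise_sd * sqrt(1 - phi^2)),
                    nt, nv)
    if (phi > 0) {
      # stationary start: x_0 ~ N(0, noise_sd), then the AR(1) recursion
      prev <- stats::rnorm(nv, sd = config$noise_sd)
      for (t in seq_len(nt)) {
        prev <- phi * prev + innov[t, ]
        innov[t, ] <- prev
      }
    }
    x <- x + innov
  }
  if (config$drift_slope_sd > 0) {
    slope <- stats::rnorm(nv, sd = config$drift_slope_sd)
    x <- x + outer(seq_len(nt) - (nt + 1) / 2, slope)
  }

  step_sd <- rep(c(config$motion_step_mm, config$motion_step_deg),
                 each = 3L)
  steps <- sweep(matrix(stats::rnorm(nt * 6L), nt, 6L), 2L, step_sd, `*`)
  motion <- apply(steps, 2L, cumsum)
  if (motion_violator) {
    frame <- sample.int(nt, 1L)
    motion[frame, 1L] <- motion[frame, 1L] + 1.5   # 1.5 mm spike
  }
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm",
                        "rx_deg", "ry_deg", "rz_deg")

  bold <- bold_series(array(t(x), dim = c(dims, nt)),
                      tr_s = config$tr_s, affine = geometry$affine)
  list(bold = bold, motion = motion)
}

#' Generate a full synthetic cohort
#'
#' Draws both groups with per-subject seeds derived from the cohort seed,
#' synthesises demographics (age, education, nicotine) matched between
#' groups and, for group B, drug-use duration (81.5 +/- 33.9 months) and
#' daily dose (0.71 +/- 0.35 g/day) truncated at zero, with duration and
#' dose coupled negatively to the duration-region amplitude latent. When
#' `out_dir` is given, every subject's 4D volume (`.nii.gz`) and motion
#' trace are written there together with `manifest.tsv` and
#' `ground_truth.json`; otherwise the subject data are returned in memory.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `manifest` (data.frame), `ground_truth` (list),
#'   `mask`, `affine`, and — when `out_dir` is `NULL` — `subjects`
#'   (list of [generate_subject()] results).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (any(config$n_per_group < 2L))
    stop("need at least 2 subjects per group for group statistics")
  geometry <- sim_geometry(config)
  n <- sum(config$n_per_group)
  groups <- rep(c("A", "B"), config$n_per_group)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  nB <- config$n_per_group[2L]

  # demographics emulating a matched two-group study
  age <- c(stats::rnorm(config$n_per_group[1L], 34.3, 7.3),
           stats::rnorm(nB, 33.9, 6.3))
  education <- pmax(0, c(stats::rnorm(config$n_per_group[1L], 10.6, 2.4),
                         stats::rnorm(nB, 10.2, 2.8)))
  nicotine <- pmax(0, c(stats::rnorm(config$n_per_group[1L], 18.3, 2.1),
                        stats::rnorm(nB, 20.0, 6.1)))

  u <- stats::rnorm(nB)                       # amplitude latent, group B
  rho <- config$use_alff_rho
  mix <- function(rho) rho * u + sqrt(1 - rho^2) * stats::rnorm(nB)
  duration <- pmax(0, 81.5 - 33.9 * mix(rho))
  dose <- pmax(0.01, 0.71 - 0.35 * mix(rho))

  violator <- if (config$inject_motion_violator)
    sample.int(n, 1L) else 0L

  ids <- sprintf("sub-%s%02d", groups,
                 c(seq_len(config$n_per_group[1L]), seq_len(nB)))
  manifest <- data.frame(
    subject = ids, group = groups, age = round(age, 1),
    education = round(education, 1), nicotine = round(nicotine, 1),
    duration = c(rep(NA_real_, config$n_per_group[1L]), round(duration, 1)),
    dose = c(rep(NA_real_, config$n_per_group[1L]), round(dose, 2)),
    bold_path = NA_character_, motion_path = NA_character_,
    stringsAsFactors = FALSE)

  subjects <- vector("list", n)
  uB <- rep(0, n); uB[groups == "B"] <- u
  for (i in seq_len(n)) {
    subj <- generate_subject(config, groups[i], seed = subject_seeds[i],
                             latent_u = uB[i],
                             motion_violator = i == violator,
                             geometry = geometry)
    if (is.null(out_dir)) {
      subjects[[i]] <- subj
    } else {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      bp <- file.path(out_dir, paste0(ids[i], "_bold.nii.gz"))
      mp <- file.path(out_dir, paste0("rp_", ids[i], ".txt"))
      write_bold(subj$bold, bp)
      write_motion(subj$motion, mp)
      manifest$bold_path[i] <- bp
      manifest$motion_path[i] <- mp
    }
  }

  ground_truth <- list(
    seed = config$seed,
    effect_rois = lapply(config$effect_rois, function(e)
      list(center_mm = e$center_mm, radius_mm = e$radius_mm,
           amplitude_ratio = e$amplitude_ratio)),
    connectivity_effects = lapply(config$connectivity_effects, function(e)
      list(seed_center_mm = e$seed_center_mm,
           target_center_mm = e$target_center_mm, radius_mm = e$radius_mm,
           weight = as.list(e$weight),
           z_delta_sign = sign(e$weight[["B"]] - e$weight[["A"]]))),
    duration_roi = config$duration_roi,
    use_alff_rho = config$use_alff_rho)

  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    jsonlite::write_json(ground_truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_map(geometry$mask + 0, geometry$affine,
              file.path(out_dir, "mask.nii.gz"))
  }

  out <- list(manifest = manifest, ground_truth = ground_truth,
              mask = geometry$mask, affine = geometry$affine,
              config = config)
  if (is.null(out_dir)) out$subjects <- subjects else out$dir <- out_dir
  out
}
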