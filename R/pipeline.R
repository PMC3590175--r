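#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where data come from (a
#' simulation config, or a directory holding a cohort written by
#' [generate_cohort()]), preprocessing parameters, the group-statistics
#' settings, seed handling for the connectivity stage, and the RNG seed
#' that drives the Monte-Carlo cluster calibration.
#'
#' @param sim a [simulation_config()] (ignored when `input_dir` is given).
#' @param input_dir optional directory with `manifest.tsv`, `mask.nii.gz`
#'   and per-subject files, as written by [generate_cohort()].
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param preprocess a [preprocess_params()].
#' @param voxel_p two-tailed voxel-level p threshold for group maps.
#' @param corrected_alpha family-wise alpha for the cluster correction.
#' @param n_iter Monte-Carlo iterations for [alphasim_min_extent()].
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param correction `"alphasim"` (cluster extent) or `"bonferroni"`
#'   (voxel level) for the connectivity contrast.
#' @param seed_source `"ground_truth"` (sphere centres from the
#'   simulator's planted regions) or `"peaks"` (centres from the ALFF
#'   group-difference report).
#' @param seed_diameter_mm connectivity seed sphere diameter, mm.
#' @param rng_seed RNG seed for the Monte-Carlo null.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            input_dir = NULL, out_dir = NULL,
                            preprocess = preprocess_params(),
                            voxel_p = 0.01, corrected_alpha = 0.05,
                            n_iter = 1000L, connectivity = 6L,
                            correction = c("alphasim", "bonferroni"),
                            seed_source = c("ground_truth", "peaks"),
                            seed_diameter_mm = 6, rng_seed = 1L) {
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 preprocess = preprocess, voxel_p = voxel_p,
                 corrected_alpha = corrected_alpha,
                 n_iter = as.integer(n_iter),
                 connectivity = as.integer(connectivity),
                 correction = match.arg(correction),
                 seed_source = match.arg(seed_source),
                 seed_diameter_mm = seed_diameter_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

# Load a cohort either from disk (generate_cohort output directory) or by
# simulating it in memory.
.load_cohort <- function(config) {
  if (!is.null(config$input_dir)) {
    dirp <- config$input_dir
    manifest <- read_manifest(file.path(dirp, "manifest.tsv"))
    mk <- read_map(file.path(dirp, "mask.nii.gz"))
    gt_path <- file.path(dirp, "ground_truth.json")
    gt <- if (file.exists(gt_path)) {
      g <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
      g$effect_rois <- lapply(g$effect_rois, function(e)
        list(center_mm = unlist(e$center_mm),
             radius_mm = unlist(e$radius_mm),
             amplitude_ratio = unlist(e$amplitude_ratio)))
      g$connectivity_effects <- lapply(g$connectivity_effects, function(e)
        list(seed_center_mm = unlist(e$seed_center_mm),
             target_center_mm = unlist(e$target_center_mm),
             radius_mm = unlist(e$radius_mm),
             weight = unlist(e$weight)))
      g
    } else NULL
    subjects <- lapply(seq_len(nrow(manifest)), function(i)
      list(bold = read_bold(manifest$bold_path[i]),
           motion = read_motion(manifest$motion_path[i])))
    list(manifest = manifest, mask = mk$values > 0.5, affine = mk$affine,
         ground_truth = gt, subjects = subjects,
         voxel_size_mm = sqrt(sum(mk$affine[1:3, 1L]^2)))
  } else {
    co <- generate_cohort(config$sim)
    co$voxel_size_mm <- config$sim$voxel_size_mm
    co
  }
}

#' Run the full resting-state analysis pipeline
#'
#' Stages, in order: cohort simulation or ingestion; motion screening
#' (subject-level exclusion); temporal/spatial preprocessing; voxel-wise
#' standardized ALFF; two-sample ALFF group comparison with Monte-Carlo
#' cluster-extent correction and a cluster report; seed-based
#' connectivity from 6 mm spheres with motion regression and Fisher z;
#' within- and between-group connectivity statistics per seed; and the
#' partial-correlation association of regional ALFF with drug-use
#' history. Reruns with the same configuration (and seeds) reproduce all
#' numeric outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list with `manifest`, `mask`, `affine`, `alff_maps`
#'   (standardized, named by subject), `alff_stat` (`stat_map`),
#'   `t_crit`, `k_min`, `alff_report`, `fc_reports` (one per seed, rbound),
#'   `fc_stats` (per-seed [group_fc_maps()] output), `association`,
#'   `demographics`, `excluded` (subjects failing the motion screen).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  say("stage: cohort")
  co <- .load_cohort(config)
  mask <- co$mask; affine <- co$affine
  vs <- co$voxel_size_mm
  pp <- config$preprocess

  say("stage: motion screen")
  screen <- lapply(co$subjects, function(s) screen_motion(s$motion, pp))
  pass <- vapply(screen, `[[`, logical(1L), "pass")
  excluded <- co$manifest$subject[!pass]
  if (length(excluded) > 0L)
    warning("excluded for excess head motion: ",
            paste(excluded, collapse = ", "))
  keep <- which(pass)
  manifest <- co$manifest[keep, , drop = FALSE]
  groups <- manifest$group
  if (sum(groups == "A") < 2L || sum(groups == "B") < 2L)
    stop("fewer than 2 subjects per group after motion screening")

  say("stage: preprocess + ALFF")
  n <- length(keep)
  alff_maps <- vector("list", n)
  series_fc <- vector("list", n)
  motion_fc <- vector("list", n)
  for (i in seq_len(n)) {
    s <- co$subjects[[keep[i]]]
    prep <- preprocess_bold(s$bold, pp, voxel_size_mm = vs)
    am <- alff_map(prep, mask, band_hz = pp$band_hz)
    alff_maps[[i]] <- standardize_alff(am)
    series_fc[[i]] <- prep
    motion_fc[[i]] <- s$motion[(pp$n_discard + 1L):nrow(s$motion), ,
                               drop = FALSE]
  }
  names(alff_maps) <- manifest$subject

  say("stage: ALFF group statistics")
  A <- alff_maps[groups == "A"]
  B <- alff_maps[groups == "B"]
  alff_stat <- two_sample_t_map(A, B, mask, affine)
  t_crit <- t_critical(config$voxel_p, alff_stat$df)
  null_dist <- alphasim_min_extent(mask, pp$fwhm_mm, vs, config$voxel_p,
                                   config$corrected_alpha, config$n_iter,
                                   config$connectivity,
                                   seed = config$rng_seed)
  k_min <- null_dist$k_min
  alff_report <- cluster_report(alff_stat, t_crit, k_min,
                                config$connectivity)

  say("stage: seed connectivity")
  seed_centers <- if (config$seed_source == "ground_truth") {
    if (is.null(co$ground_truth) ||
        length(co$ground_truth$effect_rois) == 0L) list()
    else lapply(co$ground_truth$effect_rois,
                function(e) unlist(e$center_mm))
  } else if (nrow(alff_report) > 0L) {
    lapply(seq_len(nrow(alff_report)), function(i)
      c(alff_report$x_mm[i], alff_report$y_mm[i], alff_report$z_mm[i]))
  } else list()

  fc_stats <- list()
  fc_reports <- list()
  for (si in seq_along(seed_centers)) {
    lab <- sprintf("seed%02d", si)
    roi <- resolve_sphere(seed_centers[[si]], config$seed_diameter_mm,
                          mask, affine)
    z_maps <- lapply(seq_len(n), function(i)
      seed_connectivity_subject(series_fc[[i]], roi, motion_fc[[i]], mask))
    gs <- group_fc_maps(z_maps, groups, mask, affine)
    fc_stats[[lab]] <- gs
    thr <- if (config$correction == "bonferroni")
      bonferroni_t_threshold(0.05, gs$between$df, sum(mask))
    else t_critical(config$voxel_p, gs$between$df)
    km <- if (config$correction == "bonferroni") 1L else k_min
    fc_reports[[lab]] <- cluster_report(gs$between, thr, km,
                                        config$connectivity,
                                        exclude = roi$voxels,
                                        seed_label = lab)
  }
  fc_report <- if (length(fc_reports) > 0L) do.call(rbind, fc_reports)
               else cluster_report(alff_stat, t_crit, .Machine$integer.max)

  say("stage: clinical association")
  demographics <- demographic_tests(manifest = manifest)
  association <- NULL
  assoc_roi <- if (!is.null(co$ground_truth) &&
                   length(co$ground_truth$effect_rois) > 0L) {
    e <- co$ground_truth$effect_rois[[1L]]
    resolve_sphere(unlist(e$center_mm), 2 * e$radius_mm, mask,
                   affine)$voxels
  } else if (nrow(alff_report) > 0L) {
    resolve_sphere(c(alff_report$x_mm[1L], alff_report$y_mm[1L],
                     alff_report$z_mm[1L]),
                   config$seed_diameter_mm, mask, affine)$voxels
  } else NULL
  if (!is.null(assoc_roi) && sum(manifest$group == "B") >= 7L)
    association <- alff_use_association(alff_maps, assoc_roi, manifest)

  out <- list(manifest = manifest, mask = mask, affine = affine,
              alff_maps = alff_maps, alff_stat = alff_stat,
              t_crit = t_crit, k_min = k_min,
              null_dist = null_dist, alff_report = alff_report,
              fc_stats = fc_stats, fc_report = fc_report,
              association = association, demographics = demographics,
              excluded = excluded, config = config)

  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, t0)
  out
}

# Persist maps, reports and a provenance record under config$out_dir.
.write_pipeline_outputs <- function(res, t0) {
  dirp <- res$config$out_dir
  if (!dir.exists(dirp)) dir.create(dirp, recursive = TRUE)
  for (id in names(res$alff_maps))
    write_map(res$alff_maps[[id]]$values, res$affine,
              file.path(dirp, paste0(id, "_malff.nii.gz")))
  write_map(res$alff_stat$t, res$affine,
            file.path(dirp, "alff_tmap.nii.gz"))
  write_cluster_report(res$alff_report,
                       file.path(dirp, "alff_clusters.tsv"))
  write_cluster_report(res$fc_report, file.path(dirp, "fc_clusters.tsv"))
  utils::write.table(res$demographics,
                     file.path(dirp, "demographics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$association))
    utils::write.table(res$association,
                       file.path(dirp, "alff_use_association.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  cfg_file <- tempfile(fileext = ".json")
  cfg_json <- jsonlite::serializeJSON(res$config)
  writeLines(cfg_json, cfg_file)
  prov <- list(package = "restalff",
               version = as.character(utils::packageVersion("restalff")),
               config_md5 = unname(tools::md5sum(cfg_file)),
               started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
               finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               k_min = res$k_min, t_crit = res$t_crit,
               excluded = res$excluded)
  jsonlite::write_json(prov, file.path(dirp, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(cfg_json, file.path(dirp, "config.json"))
  invisible(dirp)
}
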