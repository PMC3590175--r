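test_that("t_critical reproduces tabulated and limiting values", {
  expect_equal(t_critical(0.01, 28), 2.7633, tolerance = 5e-4)
  expect_equal(t_critical(0.01, 30), 2.75, tolerance = 5e-4)
  expect_equal(t_critical(0.05, 1e6), 1.95996, tolerance = 1e-4)
  expect_equal(t_critical(1, 10), 0)
  expect_error(t_critical(0, 10), "alpha")
  expect_error(t_critical(0.05, 0), "df")
})

test_that("bonferroni threshold grows with the voxel count", {
  expect_equal(bonferroni_t_threshold(0.05, 30, 1), t_critical(0.05, 30))
  expect_gt(bonferroni_t_threshold(0.05, 30, 1000),
            bonferroni_t_threshold(0.05, 30, 10))
})

test_that("two-sample t map equals a per-voxel scalar t.test loop", {
  set.seed(40)
  dims <- c(6L, 5L, 4L)
  mask <- array(TRUE, dims); mask[1, 1, 1] <- FALSE
  A <- lapply(1:5, function(i) array(rnorm(prod(dims)), dims))
  B <- lapply(1:7, function(i) array(rnorm(prod(dims), 0.2), dims))
  st <- two_sample_t_map(A, B, mask)
  expect_identical(st$df, 10L)

  for (v in which(mask)[c(1, 20, 77, 100)]) {
    a <- vapply(A, `[`, numeric(1), v)
    b <- vapply(B, `[`, numeric(1), v)
    tt <- stats::t.test(b, a, var.equal = TRUE)
    expect_equal(st$t[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_identical(st$t[1, 1, 1], 0)            # outside mask

  # identical groups give t = 0; label swap negates the map
  expect_true(all(two_sample_t_map(A, A[1:5], mask)$t == 0))
  st_swap <- two_sample_t_map(B, A, mask)
  expect_equal(st_swap$t, -st$t, tolerance = 1e-12)
})

test_that("zero pooled variance yields t = 0 with a warning", {
  dims <- c(4L, 4L, 3L)
  mask <- array(TRUE, dims)
  flatA <- lapply(1:3, function(i) array(1, dims))
  flatB <- lapply(1:3, function(i) array(1, dims))
  expect_warning(st <- two_sample_t_map(flatA, flatB, mask),
                 "zero pooled variance")
  expect_true(all(st$t == 0))
})

test_that("cluster labelling handles face and corner adjacency", {
  dims <- c(5L, 5L, 5L)
  face <- array(FALSE, dims)
  face[2, 2, 2] <- face[3, 2, 2] <- TRUE        # share a face
  for (conn in c(6L, 18L, 26L))
    expect_length(label_clusters(face, conn), 1L)

  corner <- array(FALSE, dims)
  corner[2, 2, 2] <- corner[3, 3, 3] <- TRUE    # share only a corner
  expect_length(label_clusters(corner, 6L), 2L)
  expect_length(label_clusters(corner, 18L), 2L)
  expect_length(label_clusters(corner, 26L), 1L)

  edge <- array(FALSE, dims)
  edge[2, 2, 2] <- edge[3, 3, 2] <- TRUE        # share an edge
  expect_length(label_clusters(edge, 6L), 2L)
  expect_length(label_clusters(edge, 18L), 1L)

  expect_error(label_clusters(face, 10L), "connectivity")
  expect_length(label_clusters(array(FALSE, dims), 6L), 0L)
})

test_that("cluster labelling agrees with an independent flood fill", {
  set.seed(41)
  for (rep in 1:4) {
    bin <- array(runif(512) < 0.25, c(8L, 8L, 8L))
    for (conn in c(6L, 18L, 26L)) {
      got <- label_clusters(bin, conn)
      want <- flood_fill_components(bin, conn)
      expect_identical(length(got), length(want))
      # same partition: compare sorted member sets
      key <- function(cl) paste(vapply(cl, paste, "", collapse = ","))
      expect_setequal(key(got), key(want))
    }
  }
})

test_that("alphasim null matches the binomial expectation without smoothing", {
  mask <- array(TRUE, c(20L, 20L, 10L))         # 4000 independent voxels
  res <- alphasim_min_extent(mask, fwhm_mm = 0, voxel_size_mm = 3,
                             voxel_p = 0.01, corrected_alpha = 0.05,
                             n_iter = 2000L, seed = 7)
  expect_equal(res$mean_suprathreshold_voxels, 40, tolerance = 3 / 40)
})

test_that("alphasim extent is deterministic, monotone, and trivial at alpha 1", {
  mask <- make_brain_mask(c(14L, 14L, 10L))
  r1 <- alphasim_min_extent(mask, 8, 3, 0.01, 0.05, n_iter = 300L,
                            seed = 5)
  r2 <- alphasim_min_extent(mask, 8, 3, 0.01, 0.05, n_iter = 300L,
                            seed = 5)
  expect_identical(r1$k_min, r2$k_min)
  expect_identical(r1$max_cluster_sizes, r2$max_cluster_sizes)

  # stricter voxel threshold cannot need a larger extent (same seed)
  r_strict <- alphasim_min_extent(mask, 8, 3, 0.001, 0.05, n_iter = 300L,
                                  seed = 5)
  expect_lte(r_strict$k_min, r1$k_min)

  r_triv <- alphasim_min_extent(mask, 8, 3, 0.01, 1.0, n_iter = 50L,
                                seed = 5)
  expect_identical(r_triv$k_min, 1L)

  expect_error(alphasim_min_extent(mask, 8, 3, 1.5, 0.05), "voxel_p")
})

test_that("cluster report applies threshold, extent and tie rules", {
  dims <- c(10L, 10L, 8L)
  mask <- array(TRUE, dims)
  affine <- grid_affine(dims, 3)
  tmap <- array(0, dims)
  tmap[2:4, 2:4, 2:4] <- 5                      # 27-voxel positive block
  tmap[7:8, 7:8, 6] <- -6                       # 4-voxel negative block
  st <- structure(list(t = tmap, df = 30L, mask = mask, affine = affine),
                  class = "stat_map")

  rep_all <- cluster_report(st, t_crit = 2.75, k_min = 1L)
  expect_identical(nrow(rep_all), 2L)
  expect_identical(rep_all$sign, c(1L, -1L))
  expect_identical(rep_all$cluster_size, c(27L, 4L))
  # tie on |t| inside the block resolves to the smallest voxel index (2,2,2)
  expect_equal(unlist(rep_all[1, c("x_mm", "y_mm", "z_mm")]),
               voxel_to_world(c(2, 2, 2), affine),
               ignore_attr = TRUE)

  # extent rule: a 10-voxel cluster dies under k_min = 16
  small <- array(0, dims); small[1:10, 1, 1] <- 5
  st2 <- structure(list(t = small, df = 30L, mask = mask, affine = affine),
                   class = "stat_map")
  expect_identical(nrow(cluster_report(st2, 2.75, 16L)), 0L)
  expect_identical(nrow(cluster_report(st2, 2.75, 10L)), 1L)

  # exclusion removes seed voxels before labelling
  rep_ex <- cluster_report(st, 2.75, 1L,
                           exclude = which(tmap > 0))
  expect_identical(nrow(rep_ex), 1L)
  expect_identical(rep_ex$sign, -1L)

  # report round-trips through TSV
  td <- withr::local_tempdir()
  p <- write_cluster_report(rep_all, file.path(td, "r.tsv"))
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(back$cluster_size, rep_all$cluster_size)
})

test_that("one-sample t maps flag zero-variance voxels", {
  dims <- c(4L, 4L, 3L)
  mask <- array(TRUE, dims)
  maps <- lapply(1:4, function(i) array(rnorm(prod(dims), 1), dims))
  st <- one_sample_t_map(maps, mask)
  expect_identical(st$df, 3L)
  v <- which(mask)[5]
  x <- vapply(maps, `[`, numeric(1), v)
  expect_equal(st$t[v], unname(stats::t.test(x)$statistic),
               tolerance = 1e-10)

  same <- lapply(1:4, function(i) array(2, dims))
  expect_warning(st0 <- one_sample_t_map(same, mask), "zero variance")
  expect_true(all(is.na(st0$t[mask])))
})
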