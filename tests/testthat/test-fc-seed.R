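test_that("sphere resolution matches geometric enumeration", {
  dims <- c(15L, 15L, 15L)
  mask <- array(TRUE, dims)
  affine <- grid_affine(dims, 3)

  # centre on a voxel centre, diameter 6 on a 3 mm grid: the centre plus
  # its six face neighbours (distance exactly 3.0 mm, inclusive)
  roi <- resolve_sphere(c(0, 0, 0), 6, mask, affine)
  expect_length(roi$voxels, 7L)
  d <- sqrt(rowSums(voxel_to_world(roi$ijk, affine)^2))
  expect_true(all(d <= 3 + 1e-9))

  # diameter 0 selects the single coincident voxel
  roi0 <- resolve_sphere(c(0, 0, 0), 0, mask, affine)
  expect_length(roi0$voxels, 1L)
  expect_equal(voxel_to_world(roi0$ijk[1, ], affine), c(0, 0, 0))

  # brute-force scan oracle at an off-centre point
  ctr <- c(4, -2, 5); dia <- 9
  roi2 <- resolve_sphere(ctr, dia, mask, affine)
  want <- integer(0)
  for (v in seq_len(prod(dims))) {
    xyz <- voxel_to_world(arrayInd(v, dims)[1, ], affine)
    if (sum((xyz - ctr)^2) <= (dia / 2)^2) want <- c(want, v)
  }
  expect_setequal(roi2$voxels, want)

  # respects the mask and rejects empty results
  mask2 <- array(FALSE, dims); mask2[1, 1, 1] <- TRUE
  expect_error(resolve_sphere(c(0, 0, 0), 6, mask2, affine),
               "no mask voxels")
})

test_that("peak difference voxel is the argmax with deterministic ties", {
  dims <- c(8L, 8L, 6L)
  mask <- array(TRUE, dims)
  affine <- grid_affine(dims, 3)
  tmap <- array(0, dims)
  tmap[3, 4, 2] <- -7; tmap[5, 5, 3] <- 6.5
  st <- structure(list(t = tmap, df = 20L, mask = mask, affine = affine),
                  class = "stat_map")

  expect_equal(peak_difference_voxel(st, which(mask)),
               voxel_to_world(c(3, 4, 2), affine))   # largest |t|

  # restricted search region
  region <- array(FALSE, dims); region[5:6, 5:6, 3] <- TRUE
  expect_equal(peak_difference_voxel(st, region),
               voxel_to_world(c(5, 5, 3), affine))

  # exact tie: smallest voxel index wins
  tmap2 <- array(0, dims); tmap2[2, 2, 2] <- 5; tmap2[6, 6, 4] <- 5
  st2 <- structure(list(t = tmap2, df = 20L, mask = mask, affine = affine),
                   class = "stat_map")
  expect_equal(peak_difference_voxel(st2, which(mask)),
               voxel_to_world(c(2, 2, 2), affine))

  expect_error(peak_difference_voxel(st, integer(0)), "empty")
})

test_that("seed series extraction is the enumerated frame-wise mean", {
  set.seed(50)
  dims <- c(6L, 6L, 4L); nt <- 20L
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  mask <- array(TRUE, dims)
  affine <- grid_affine(dims, 3)
  roi <- resolve_sphere(c(1.5, 1.5, 0), 7, mask, affine)

  got <- extract_seed_series(arr, roi)
  want <- rep(0, nt)
  for (v in roi$voxels) {
    ijk <- arrayInd(v, dims)
    want <- want + arr[ijk[1], ijk[2], ijk[3], ]
  }
  expect_equal(got, want / length(roi$voxels), tolerance = 1e-12)

  one <- structure(list(voxels = roi$voxels[1]), class = "seed_roi")
  ijk <- arrayInd(roi$voxels[1], dims)
  expect_equal(extract_seed_series(arr, one),
               arr[ijk[1], ijk[2], ijk[3], ])
})

test_that("nuisance regression matches the normal-equations oracle", {
  set.seed(51)
  for (rep in 1:5) {
    motion <- matrix(rnorm(20 * 6), 20, 6)
    y <- matrix(rnorm(20 * 3), 20, 3)
    res <- regress_out_nuisance(y, motion)
    X <- cbind(1, motion)
    beta <- solve(t(X) %*% X, t(X) %*% y)      # brute-force normal equations
    expect_equal(res, y - X %*% beta, tolerance = 1e-8)
    expect_lt(max(abs(t(X) %*% res)), 1e-8)    # orthogonality
  }

  # zero motion: the six degenerate columns drop, leaving the intercept,
  # so the residual is the demeaned series
  y1 <- rnorm(20)
  expect_warning(r0 <- regress_out_nuisance(y1, matrix(0, 20, 6)),
                 "rank-deficient")
  expect_equal(r0, y1 - mean(y1), tolerance = 1e-10)

  # a series equal to a motion column is annihilated
  motion <- matrix(rnorm(20 * 6), 20, 6)
  expect_lt(max(abs(regress_out_nuisance(motion[, 3], motion))), 1e-10)

  expect_warning(regress_out_nuisance(rnorm(20),
                                      cbind(motion, motion[, 1])),
                 "rank-deficient")
  expect_error(regress_out_nuisance(rnorm(10), motion), "time points")
})

test_that("subject correlation maps match the scalar correlation oracle", {
  set.seed(52)
  dims <- c(6L, 5L, 4L); nt <- 30L
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  mask <- array(TRUE, dims)
  seed_series <- rnorm(nt)
  v1 <- which(mask)[3]; ijk <- arrayInd(v1, dims)
  arr[ijk[1], ijk[2], ijk[3], ] <- seed_series          # r = +1
  v2 <- which(mask)[10]; ijk2 <- arrayInd(v2, dims)
  arr[ijk2[1], ijk2[2], ijk2[3], ] <- -2 * seed_series  # r = -1

  fc <- fc_map_subject(seed_series, arr, mask)
  expect_equal(fc$values[v1], 1, tolerance = 1e-12)
  expect_equal(fc$values[v2], -1, tolerance = 1e-12)
  for (v in which(mask)[c(5, 17, 40)]) {
    ijk <- arrayInd(v, dims)
    expect_equal(fc$values[v],
                 stats::cor(seed_series, arr[ijk[1], ijk[2], ijk[3], ]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(fc$values[mask]) <= 1))

  flat <- arr; flat[2, 2, 2, ] <- 3
  expect_warning(fc0 <- fc_map_subject(seed_series, flat, mask),
                 "zero-variance")
  expect_identical(fc0$values[2, 2, 2], 0)
})

test_that("Fisher z transform: closed form, oddness, round trip, clipping", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.999, 0.999, length.out = 41)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))               # monotone
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("seed ROI averaging commutes with nuisance regression", {
  set.seed(53)
  dims <- c(6L, 6L, 4L); nt <- 40L
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  mask <- array(TRUE, dims)
  affine <- grid_affine(dims, 3)
  motion <- matrix(rnorm(nt * 6, sd = 0.1), nt, 6)
  roi <- resolve_sphere(c(0, 0, 0), 6, mask, affine)

  # regress the averaged series
  a <- regress_out_nuisance(extract_seed_series(arr, roi), motion)
  # average the regressed series
  m <- matrix(arr, prod(dims), nt)[roi$voxels, , drop = FALSE]
  b <- rowMeans(regress_out_nuisance(t(m), motion))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("group connectivity maps recover planted deltas and antisymmetry", {
  cfg <- tiny_config(n_per_group = c(4L, 4L), seed = 61,
    connectivity_effects = list(list(seed_center_mm = c(3, 3, 0),
                                     target_center_mm = c(-6, -6, 0),
                                     radius_mm = 4,
                                     weight = c(A = 0.1, B = 0.9))))
  geom <- restalff:::sim_geometry(cfg)
  co <- generate_cohort(cfg)
  pp <- preprocess_params(fwhm_mm = 0)
  roi <- resolve_sphere(c(3, 3, 0), 8, geom$mask, geom$affine)

  z_maps <- lapply(seq_along(co$subjects), function(i) {
    s <- co$subjects[[i]]
    prep <- preprocess_bold(s$bold, pp, voxel_size_mm = 3)
    seed_connectivity_subject(prep, roi,
                              s$motion[6:nrow(s$motion), ], geom$mask)
  })
  gs <- group_fc_maps(z_maps, co$manifest$group, geom$mask, geom$affine)
  expect_identical(gs$between$df, 6L)
  expect_identical(gs$within$A$df, 3L)

  # planted target connectivity is higher in group B
  tgt <- geom$conn[[1]]$target
  expect_gt(mean(gs$between$t[tgt]), 2)

  # label swap negates the between-group map
  gs_swap <- group_fc_maps(z_maps,
                           ifelse(co$manifest$group == "A", "B", "A"),
                           geom$mask, geom$affine)
  expect_equal(gs_swap$between$t, -gs$between$t, tolerance = 1e-12)
})
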