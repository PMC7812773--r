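test_that("planted retinotopic maps are contralateral with linear layouts", {
  mL <- make_mesh(6, 9, spacing = 2, hemisphere = "L")
  mR <- make_mesh(6, 9, spacing = 2, hemisphere = "R")
  gL <- make_retinotopic_map(mL, ecc_range = c(0.5, 8))
  gR <- make_retinotopic_map(mR, ecc_range = c(0.5, 8))
  expect_true(all(gL$x0 >= 0))   # left hemisphere -> right hemifield
  expect_true(all(gR$x0 <= 0))
  expect_equal(range(gL$ecc), c(0.5, 8))
  # neighboring vertices along the eccentricity axis differ by span/(cols-1)
  expect_equal(gL$ecc[2] - gL$ecc[1], 7.5 / 8)
  expect_equal(diff(gL$ecc[1:9]), rep(7.5 / 8, 8))
  # pRF size grows linearly with eccentricity
  fit <- stats::lm(sigma ~ ecc, data = gL)
  expect_equal(unname(stats::coef(fit)), c(0.2, 0.2), tolerance = 1e-10)
  expect_error(make_retinotopic_map(cf_mesh(matrix(0, 1, 3)[0, ],
                                            matrix(0L, 0, 3), "L")),
               "grid mesh")
})

test_that("bar apertures sweep contiguous strips and wedges cover the disk", {
  ap <- make_aperture("bar", field_radius = 8, n_frames = 80, grid_res = 41)
  for (k in c(5, 25, 45, 70)) {
    fr <- ap$frames[, , k]
    on <- which(fr > 0)
    expect_gt(length(on), 0)
    # ON pixels of a bar frame lie within one strip of the bar width
    px <- rep(ap$x, each = 41)[on]
    py <- rep(ap$y, times = 41)[on]
    spread <- min(diff(range(px)), diff(range(py)))
    expect_lte(spread, 2 + 0.5)  # bar width (r/4) plus one pixel
  }
  wg <- make_aperture("wedge", field_radius = 8, n_frames = 64, grid_res = 41)
  covered <- apply(wg$frames, c(1, 2), sum)
  gx <- matrix(wg$x, 41, 41, byrow = TRUE)
  gy <- matrix(wg$y, 41, 41)
  in_disk <- gx^2 + gy^2 <= 8^2
  expect_true(all(covered[in_disk] > 0))  # full rotation covers the disk

  pad <- make_aperture("bar", n_frames = 40, grid_res = 21, pad_frames = 5)
  expect_true(all(pad$frames[, , c(1:5, 36:40)] == 0))
  expect_error(make_aperture("spiral"), "arg")
})

test_that("zero-noise stimulated sources equal the pRF model prediction", {
  cfg <- synthetic_config(mesh_rows = 4, mesh_cols = 5, noise_sd = 0,
                          source_global = 0, n_runs = 2,
                          n_timepoints_per_run = 60, aperture_grid_res = 41)
  mesh <- make_mesh(4, 5, cfg$vertex_spacing, "L")
  gt <- make_retinotopic_map(mesh, cfg$ecc_range, cfg$angle_range,
                             cfg$prf_sigma_intercept, cfg$prf_sigma_slope)
  ap <- make_aperture("bar", cfg$field_radius, 60, 41)
  runs <- simulate_source(mesh, gt, cfg, aperture = ap)
  for (v in c(1, 10, 20)) {
    analytic <- prf_predict(list(x0 = gt$x0[v], y0 = gt$y0[v],
                                 sigma = gt$sigma[v]), ap)
    expect_equal(runs[[1]][v, ], zscore(analytic), tolerance = 1e-12)
  }
  expect_identical(runs[[1]], runs[[2]])  # no noise: runs coincide
  expect_error(simulate_source(mesh, gt, cfg), "aperture")
  expect_error(simulate_source(mesh, gt[1:3, ], cfg, aperture = ap),
               "cover all mesh vertices")
})

test_that("seeded simulation is reproducible and runs are independent", {
  cfg <- synthetic_config(mesh_rows = 5, mesh_cols = 5, n_runs = 2,
                          n_timepoints_per_run = 50, seed = 42L)
  mesh <- make_mesh(5, 5, cfg$vertex_spacing, "L")
  gt <- make_retinotopic_map(mesh)
  a <- simulate_source(mesh, gt, cfg, resting = TRUE)
  b <- simulate_source(mesh, gt, cfg, resting = TRUE)
  expect_identical(a, b)
  expect_false(identical(a[[1]], a[[2]]))
  d1 <- simulate_dataset(cfg, conditions = "rest")
  d2 <- simulate_dataset(cfg, conditions = "rest")
  expect_identical(d1$targets$rest, d2$targets$rest)
})

test_that("resting-state spatial correlation decays on the planted scale", {
  cfg <- synthetic_config(mesh_rows = 16, mesh_cols = 16, noise_sd = 0,
                          source_global = 0, n_runs = 1,
                          n_timepoints_per_run = 800,
                          spatial_corr_length = 4)
  mesh <- make_mesh(16, 16, cfg$vertex_spacing, "L")
  gt <- make_retinotopic_map(mesh)
  s <- simulate_source(mesh, gt, cfg, resting = TRUE)[[1]]
  eu <- as.matrix(dist(mesh$vertices))
  cc <- stats::cor(t(s))
  ut <- upper.tri(eu)
  bins <- cut(eu[ut], breaks = c(0, 3, 6, 9, 12, 20))
  prof <- tapply(cc[ut], bins, mean)
  # empirical correlogram: monotone decay over the first bins
  expect_true(all(diff(prof[1:4]) < 0))
  # Gaussian-kernel smoothing of white noise gives corr exp(-d^2/(4 l^2));
  # compare at d ~ 2 l (allowing for demeaning and edge effects)
  expect_gt(prof[[1]], 0.6)
  expect_lt(prof[[3]], 0.35)
})

test_that("targets are exact CF-weighted sums in the zero-noise limit", {
  cfg <- synthetic_config(mesh_rows = 8, mesh_cols = 8, noise_sd = 0,
                          global_coupling = 0, n_targets = 8, n_runs = 2,
                          n_timepoints_per_run = 120)
  d <- simulate_dataset(cfg, conditions = "rest")
  gt <- d$cf_gt
  for (i in c(1, 5)) {
    h <- gt$hemisphere[i]
    m <- d$meshes[[h]]
    w <- exp(-as.matrix(dist(m$vertices))[, gt$v0[i]]^2 /
               (2 * gt$sigma_cf[i]^2))
    pred <- cf_predict(w, d$source$rest[[h]][[1]])
    expect_equal(stats::cor(pred, d$targets$rest[[1]][i, ]), 1,
                 tolerance = 1e-9)
  }
})

test_that("pure-null targets follow the mean source signal", {
  cfg <- synthetic_config(mesh_rows = 8, mesh_cols = 8, noise_sd = 0,
                          n_targets = 6, n_null_targets = 6, n_runs = 1,
                          n_timepoints_per_run = 120)
  d <- simulate_dataset(cfg, conditions = "rest")
  expect_true(all(d$cf_gt$is_null))
  mean_src <- zscore(colMeans(rbind(d$source$rest$L[[1]],
                                    d$source$rest$R[[1]])))
  for (i in seq_len(3)) {
    expect_equal(stats::cor(d$targets$rest[[1]][i, ], mean_src), 1,
                 tolerance = 1e-9)
  }
})

test_that("out-of-range planted centers are rejected", {
  cfg <- synthetic_config(mesh_rows = 4, mesh_cols = 4, n_targets = 2,
                          n_runs = 1, n_timepoints_per_run = 30)
  meshes <- list(L = make_mesh(4, 4, 2, "L"), R = make_mesh(4, 4, 2, "R"))
  gt <- make_cf_ground_truth(meshes, cfg)
  gt$v0[1] <- 99L
  src <- list(L = list(matrix(rnorm(16 * 30), 16)),
              R = list(matrix(rnorm(16 * 30), 16)))
  expect_error(simulate_targets(src, gt, meshes, cfg), "out of range")
})
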