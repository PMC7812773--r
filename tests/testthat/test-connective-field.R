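test_that("CF profiles follow the surface Gaussian exactly", {
  D <- chain_distmat(9, s = 1)
  w <- cf_profile(v0 = 3, sigma = 2, D)
  expect_equal(w[3], 1)                      # exp(0) at the center
  expect_equal(w[5], exp(-1 / 2))            # one sigma away
  expect_equal(w[7], exp(-2))                # two sigma away
  expect_true(all(diff(w[3:9]) < 0))         # monotone decay
  expect_error(cf_profile(99, 2, D), "not in the source vertex set")
})

test_that("CF predictions are z-scored weighted sums of source signals", {
  set.seed(3)
  s <- matrix(rnorm(5 * 80), 5, 80)
  ind <- c(0, 0, 1, 0, 0)
  expect_equal(cf_predict(ind, s), as.vector(zscore(s[3, ])))
  w <- runif(5)
  p <- cf_predict(w, s)
  expect_equal(mean(p), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(p^2)), 1, tolerance = 1e-12)
  expect_error(cf_predict(w[1:3], s), "does not match")
})

test_that("candidate sets enumerate centers x sigma grid in tie-break order", {
  cand <- cf_candidates(list(L = c(4L, 9L), R = c(2L, 5L, 7L)))
  expect_equal(nrow(cand), 5L * 13L)
  expect_true(!is.unsorted(cand$sigma))            # sigma ascending outermost
  first <- cand[cand$sigma == 0.5, ]
  expect_equal(first$hemisphere, c("L", "L", "R", "R", "R"))
  expect_equal(first$v0, c(4L, 9L, 2L, 5L, 7L))
  expect_error(cf_candidates(list(L = 1L), sigma_grid = c(2, 1)),
               "increasing")
  expect_error(cf_candidates(list(L = 1L), sigma_grid = c(-1, 2)),
               "positive")
})

test_that("noise-free planted CFs are recovered exactly by the grid fit", {
  cfg <- synthetic_config(mesh_rows = 9, mesh_cols = 9, noise_sd = 0,
                          global_coupling = 0, source_global = 0,
                          n_targets = 12, n_runs = 2,
                          n_timepoints_per_run = 150)
  d <- simulate_dataset(cfg, conditions = "rest")
  dists <- lapply(d$meshes, planar_distmat)  # exact geodesics on a flat sheet
  cand <- cf_candidates(list(L = 1:81, R = 1:81))
  # one run: targets are z-scored per run at generation, so the single-run
  # fit reproduces the generating construction exactly
  src <- list(L = d$source$rest$L[[1]], R = d$source$rest$R[[1]])
  fit <- cf_grid_fit(d$targets$rest[[1]], cand, src, dists)
  expect_equal(fit$v0, d$cf_gt$v0)
  expect_equal(fit$hemisphere, d$cf_gt$hemisphere)
  expect_equal(fit$sigma_cf, d$cf_gt$sigma_cf)
  expect_equal(fit$r2, rep(1, 12), tolerance = 1e-9)
})

test_that("exact correlation ties resolve to smallest sigma, lowest center", {
  # two source vertices with identical time courses: every candidate predicts
  # the same series, so all squared correlations tie
  set.seed(5)
  s <- rnorm(100)
  src <- list(L = rbind(s, s))
  D <- chain_distmat(2, s = 1)
  cand <- cf_candidates(list(L = 1:2))
  fit <- cf_grid_fit(matrix(s, 1), cand, src, list(L = D))
  expect_equal(fit$sigma_cf, 0.5)   # smallest sigma in the grid
  expect_equal(fit$v0, 1L)          # lowest center index
  # zero-variance targets are flagged, not fitted
  flat <- cf_grid_fit(matrix(1, 1, 100), cand, src, list(L = D))
  expect_true(flat$flagged)
  expect_true(is.na(flat$v0))
})

test_that("leave-one-run-out CV uses each run once and is leak-free", {
  cfg <- synthetic_config(mesh_rows = 8, mesh_cols = 8, n_targets = 10,
                          n_runs = 4, n_timepoints_per_run = 100)
  d <- simulate_dataset(cfg, conditions = "rest")
  dists <- lapply(d$meshes, geodesic_distances)
  cand <- cf_candidates(list(L = seq(1, 64, by = 2), R = seq(1, 64, by = 2)))
  fit <- cf_crossvalidate(d$targets$rest, d$source$rest, cand, dists)
  expect_equal(sort(unique(fit$folds$fold)), 1:4)
  expect_equal(unname(table(fit$folds$fold)), rep(10L, 4), ignore_attr = TRUE)
  expect_error(cf_crossvalidate(d$targets$rest[1], lapply(d$source$rest, `[`, 1),
                                cand, dists), "within-set")
  # leakage: replacing the held-out run's targets with noise must not change
  # what the training folds select
  noisy <- d$targets$rest
  set.seed(99)
  noisy[[2]] <- matrix(rnorm(length(noisy[[2]])), nrow(noisy[[2]]))
  fit2 <- cf_crossvalidate(noisy, d$source$rest, cand, dists)
  f1 <- fit$folds[fit$folds$fold == 2, ]
  f2 <- fit2$folds[fit2$folds$fold == 2, ]
  expect_equal(f1$v0, f2$v0)
  expect_equal(f1$sigma_cf, f2$sigma_cf)
  expect_equal(f1$hemisphere, f2$hemisphere)
})

test_that("noise-free CV reaches perfect out-of-set prediction", {
  cfg <- synthetic_config(mesh_rows = 8, mesh_cols = 8, noise_sd = 0,
                          global_coupling = 0, source_global = 0,
                          n_targets = 6, n_runs = 3,
                          n_timepoints_per_run = 120)
  d <- simulate_dataset(cfg, conditions = "rest")
  dists <- lapply(d$meshes, planar_distmat)
  cand <- cf_candidates(list(L = 1:64, R = 1:64))
  fit <- cf_crossvalidate(d$targets$rest, d$source$rest, cand, dists)
  expect_equal(fit$summary$cv_r, rep(1, 6), tolerance = 1e-9)
  # identical selection in every fold
  for (i in seq_len(6)) {
    fi <- fit$folds[fit$folds$target == i, ]
    expect_equal(length(unique(fi$v0)), 1L)
    expect_equal(length(unique(fi$sigma_cf)), 1L)
  }
})

test_that("the null-model correction is a plain referenced difference", {
  expect_equal(null_model_correction(0.5, 0.5), 0)
  expect_equal(null_model_correction(c(0.4, 0.1), c(0.1, 0.3)),
               c(0.3, -0.2))
})

test_that("one-sample significance handles degenerate and planted cases", {
  z <- cf_significance(rep(0, 10))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  sym <- cf_significance(c(-0.4, 0.4, -0.1, 0.1))
  expect_equal(sym$t, 0, tolerance = 1e-12)
  set.seed(21)
  pos <- cf_significance(rnorm(20, mean = 0.3, sd = 0.1))
  expect_lt(pos$p, 1e-6)
  expect_equal(pos$df, 19)
  expect_error(cf_significance(0.3), "at least 2")
  # matches the standard t-test when variance is present
  set.seed(22)
  v <- rnorm(15, 0.1)
  ref <- t.test(v)
  got <- cf_significance(v)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
})

test_that("recovery degrades monotonically along a noise ladder", {
  err_at <- function(noise) {
    cfg <- synthetic_config(mesh_rows = 12, mesh_cols = 12,
                            noise_sd = noise, n_targets = 60,
                            n_timepoints_per_run = 250)
    d <- simulate_dataset(cfg, conditions = "rest")
    dists <- lapply(d$meshes, geodesic_distances)
    cand <- cf_candidates(list(L = 1:144, R = 1:144))
    fit <- cf_crossvalidate(d$targets$rest, d$source$rest, cand, dists)
    e <- v0_distance(d$meshes, fit$summary$v0, fit$summary$hemisphere,
                     d$cf_gt$v0, d$cf_gt$hemisphere)
    mean(pmin(e, 10 * cfg$vertex_spacing))  # capped mean center error, mm
  }
  ladder <- vapply(c(0.75, 1.5, 3), err_at, numeric(1))
  expect_true(ladder[1] <= ladder[2] && ladder[2] <= ladder[3])
  expect_lt(ladder[1], ladder[3])
})
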