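test_that("single-state simulation reproduces the emission distribution", {
  cfg <- sim_config(1, mu = 120, sigma = 90, zmass = 0, kappa = 1,
                    Gamma = matrix(1), n_steps = 10000, seed = 7)
  tr <- simulate_hmm_track(cfg)
  expect_true(all(tr$states == 1))
  se <- 90 / sqrt(10000)
  expect_lt(abs(mean(tr$step_lengths) - 120), 3 * se)
})

test_that("identity transitions with a fixed start give a constant chain", {
  cfg <- sim_config(2, mu = c(10, 200), sigma = c(10, 150),
                    Gamma = diag(2), n_steps = 500, seed = 3)
  tr <- simulate_hmm_track(cfg, start_state = 1)
  expect_true(all(tr$states == 1))
  expect_error(simulate_hmm_track(cfg), "stationary")
})

test_that("state frequencies converge to the stationary distribution", {
  cfg <- sim_config(2, mu = c(10, 200), sigma = c(10, 150),
                    Gamma = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
                    n_steps = 20000, seed = 5)
  tr <- simulate_hmm_track(cfg)
  expect_lt(abs(mean(tr$states == 1) - 0.5), 0.02)

  G <- matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)
  delta <- stationary_distribution(G)
  expect_equal(delta, c(0.6, 0.4), tolerance = 1e-12)
  cfg2 <- sim_config(2, mu = c(10, 200), sigma = c(10, 150), Gamma = G,
                     n_steps = 20000, seed = 6)
  tr2 <- simulate_hmm_track(cfg2)
  se <- sqrt(0.6 * 0.4 / 20000)
  # Markov dependence inflates the binomial SE; allow a small multiple
  expect_lt(abs(mean(tr2$states == 1) - 0.6), 8 * se)
})

test_that("per-state emissions match the configured parameters", {
  cfg <- sim_config(2, mu = c(8, 320), sigma = c(8, 250),
                    zmass = c(0.15, 0.02), angle_mean = c(pi, 0),
                    kappa = c(1, 2),
                    Gamma = persistent_gamma(c(.6, .4), .8),
                    n_steps = 30000, seed = 11)
  tr <- simulate_hmm_track(cfg)
  for (k in 1:2) {
    Lk <- tr$step_lengths[tr$states == k]
    pos <- Lk[Lk > 0]
    expect_lt(abs(mean(pos) - cfg$mu[k]) / cfg$mu[k], 0.05)
    expect_lt(abs(sd(pos) - cfg$sigma[k]) / cfg$sigma[k], 0.1)
    expect_lt(abs(mean(Lk == 0) - cfg$zmass[k]), 0.01)
    ang <- tr$turning_draws[tr$states == k]
    circ_mean <- atan2(mean(sin(ang)), mean(cos(ang)))
    diff <- abs(urbanmove::wrap_angle(circ_mean - cfg$angle_mean[k]))
    expect_lt(diff, 0.1)
  }
})

test_that("identical seed and config give bit-identical tracks", {
  cfg <- sim_config(2, mu = c(10, 300), sigma = c(10, 200),
                    Gamma = persistent_gamma(c(.5, .5), .7),
                    n_steps = 500, seed = 99)
  expect_identical(simulate_hmm_track(cfg), simulate_hmm_track(cfg))
})

test_that("territorial attraction bounds excursions from the anchor", {
  base <- sim_config(2, mu = c(10, 300), sigma = c(10, 200),
                     kappa = c(1, 2),
                     Gamma = persistent_gamma(c(.5, .5), .8),
                     n_steps = 10000, seed = 21, anchor = c(0, 0),
                     attraction = 0)
  free <- simulate_territorial_track(base)
  expect_identical(free, simulate_hmm_track(base))
  pulled_cfg <- sim_config(2, mu = c(10, 300), sigma = c(10, 200),
                           kappa = c(1, 2),
                           Gamma = persistent_gamma(c(.5, .5), .8),
                           n_steps = 10000, seed = 21, anchor = c(0, 0),
                           attraction = 0.8)
  pulled <- simulate_territorial_track(pulled_cfg)
  expect_true(all(is.finite(pulled$fixes$x)), all(is.finite(pulled$fixes$y)))
  d_free <- sqrt(free$fixes$x^2 + free$fixes$y^2)
  d_pulled <- sqrt(pulled$fixes$x^2 + pulled$fixes$y^2)
  expect_lt(quantile(d_pulled, 0.99), quantile(d_free, 0.99))
  expect_error(sim_config(1, mu = 10, sigma = 10, Gamma = matrix(1),
                          attraction = 1.2), "attraction")
})

test_that("fix schedules have the expected grid and dropout behavior", {
  sched <- make_fix_schedule(24 * 3600, 15 * 60, dropout_prob = 0)
  expect_length(sched, 97)
  expect_error(make_fix_schedule(24 * 3600, 900, dropout_prob = 1),
               "dropout_prob")
  s1 <- make_fix_schedule(24 * 3600, 900, dropout_prob = 0.5, seed = 4)
  s2 <- make_fix_schedule(24 * 3600, 900, dropout_prob = 0.5, seed = 4)
  expect_identical(s1, s2)
  expect_lt(length(s1), 97)
})

test_that("position-error injection displaces only interior fixes", {
  tr <- track_from_xy(seq(0, 1000, by = 100), rep(0, 11))
  same <- inject_position_errors(tr, 0, 15000, seed = 1)
  expect_equal(same$x, tr$x)
  expect_length(attr(same, "spike_indices"), 0)

  spiked <- inject_position_errors(tr, 1, 15000, seed = 2)
  idx <- attr(spiked, "spike_indices")
  expect_false(any(idx %in% c(1, nrow(tr))))
  v <- compute_speeds(spiked)
  # 15 km displacement over a 15-min gap: both adjacent segments > 50 km/h
  expect_gt(v[idx - 1], 50)
  expect_gt(v[idx], 50)
  expect_error(inject_position_errors(tr, 1, -5), "spike_distance")
})

test_that("imperviousness rasters honor their pattern contracts", {
  ext <- c(0, 3000, 0, 3000)
  u <- make_imperviousness_raster(ext, 30, "uniform", level = 35)
  expect_true(all(u$values == 35))
  g <- make_imperviousness_raster(ext, 30, "gradient", level = 100)
  cm <- colMeans(g$values)
  expect_true(all(diff(cm) >= 0))
  expect_true(all(g$values >= 0 & g$values <= 100))
  p1 <- make_imperviousness_raster(ext, 30, "patches", level = 80, seed = 9)
  p2 <- make_imperviousness_raster(ext, 30, "patches", level = 80, seed = 9)
  expect_identical(p1, p2)
  expect_error(make_imperviousness_raster(ext, 30, "uniform", level = 120),
               "level")
})

test_that("rasters and tracks survive a text round trip", {
  ext <- c(0, 600, 0, 300)
  r <- make_imperviousness_raster(ext, 30, "patches", level = 75, seed = 2)
  path <- tempfile(fileext = ".txt")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$cell_size, r$cell_size)

  cfg <- sim_config(2, mu = c(10, 300), sigma = c(10, 200),
                    zmass = c(0.1, 0), Gamma = persistent_gamma(c(.5, .5), .8),
                    n_steps = 50, seed = 8)
  tr <- simulate_hmm_track(cfg)
  tpath <- tempfile(fileext = ".csv")
  write_track(tr, tpath)
  back <- read_track(tpath)
  expect_equal(back$x, tr$fixes$x, tolerance = 1e-12)
  expect_equal(back$timestamp, tr$fixes$timestamp)
  expect_equal(back$true_state, tr$fixes$true_state)
})
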