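test_that("step emission mixes a zero point mass with a gamma density", {
  expect_equal(step_emission(0, mu = 10, sigma = 5, z = 0.1), 0.1)
  L <- c(1, 5, 20)
  expect_equal(step_emission(L, 10, 5, z = 0),
               dgamma(L, shape = 4, scale = 2.5))
  # mean/SD parameterization against a numerically differentiated CDF
  mu <- 7.6; s <- 7.2
  shape <- mu^2 / s^2; scale <- s^2 / mu
  expect_equal(shape, 1.114, tolerance = 1e-3)
  expect_equal(scale, 6.821, tolerance = 1e-3)
  h <- 1e-5
  num <- (pgamma(mu + h, shape, scale = scale) -
            pgamma(mu - h, shape, scale = scale)) / (2 * h)
  expect_equal(step_emission(mu, mu, s, z = 0.2), 0.8 * num, tolerance = 1e-6)
  expect_error(step_emission(-1, 10, 5), "nonnegative")
})

test_that("angle emission is a normalized von Mises with uniform limit", {
  phi <- seq(-3, 3, by = 0.5)
  expect_equal(angle_emission(phi, m = 1, kappa = 0), rep(1 / (2 * pi), 13))
  # I0(2) by power series
  i0 <- sum(vapply(0:40, function(j) (2 / 2)^(2 * j) / factorial(j)^2, 1))
  expect_equal(angle_emission(1.3, m = 1.3, kappa = 2),
               exp(2) / (2 * pi * i0), tolerance = 1e-10)
  expect_equal(exp(2) / (2 * pi * i0), 0.5159, tolerance = 1e-4)
  for (k in c(0, 1, 5)) {
    int <- integrate(function(p) angle_emission(p, m = 0.7, kappa = k),
                     -pi, pi, rel.tol = 1e-10)$value
    expect_equal(int, 1, tolerance = 1e-8)
  }
  expect_equal(angle_emission(NA, m = 0, kappa = 3), 1)
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    params <- random_params(K)
    s <- random_series(6)
    oracle <- oracle_enumerate(s$L, s$phi, params)
    expect_equal(forward_loglik(s, params), oracle$loglik, tolerance = 1e-8)
  }
})

test_that("degenerate chains reduce the likelihood to a single state", {
  set.seed(1)
  s <- random_series(20)
  p1 <- random_params(1)
  manual <- sum(log(oracle_emission(s$L, s$phi, p1)))
  expect_equal(forward_loglik(s, p1), manual, tolerance = 1e-10)
  # identity transitions pinned to state 1 equal the 1-state likelihood
  p2 <- random_params(2)
  pinned <- structure(list(K = 2L, mu = p2$mu, sigma = p2$sigma,
                           zmass = p2$zmass, angle_mean = p2$angle_mean,
                           kappa = p2$kappa, Gamma = diag(2),
                           delta = c(1, 0)), class = "hmm_params")
  single <- structure(list(K = 1L, mu = p2$mu[1], sigma = p2$sigma[1],
                           zmass = p2$zmass[1], angle_mean = p2$angle_mean[1],
                           kappa = p2$kappa[1], Gamma = matrix(1),
                           delta = 1), class = "hmm_params")
  expect_equal(forward_loglik(s, pinned), forward_loglik(s, single),
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant under burst permutation", {
  set.seed(7)
  params <- random_params(2)
  bursts <- lapply(1:4, function(i) random_series(30))
  ll1 <- forward_loglik(bursts, params)
  ll2 <- forward_loglik(bursts[c(3, 1, 4, 2)], params)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("Viterbi matches brute-force argmax over all paths", {
  set.seed(23)
  for (rep in 1:5) {
    K <- 3
    params <- random_params(K)
    s <- random_series(8)
    oracle <- oracle_enumerate(s$L, s$phi, params)
    expect_equal(viterbi(s, params), oracle$viterbi)
  }
  p1 <- random_params(1)
  s <- random_series(15)
  expect_equal(viterbi(s, p1), rep(1L, 15))
})

test_that("posteriors match enumeration and agree with Viterbi when sharp", {
  set.seed(31)
  for (rep in 1:5) {
    params <- random_params(2)
    s <- random_series(6)
    oracle <- oracle_enumerate(s$L, s$phi, params)
    post <- state_posteriors(s, params)
    expect_equal(post, oracle$posterior, tolerance = 1e-8)
    expect_equal(rowSums(post), rep(1, 6), tolerance = 1e-10)
  }
  p1 <- random_params(1)
  s1 <- random_series(10)
  expect_true(all(state_posteriors(s1, p1) == 1))
  # on well-separated states, confident posterior argmax matches Viterbi
  params <- hmm_params(c(8, 400), c(8, 300), c(.05, .05), c(pi, 0),
                       c(.5, 2), persistent_gamma(c(.5, .5), .8))
  cfg <- sim_config(2, c(8, 400), c(8, 300), c(.05, .05), c(pi, 0), c(.5, 2),
                    persistent_gamma(c(.5, .5), .8), n_steps = 300, seed = 4)
  tr <- simulate_hmm_track(cfg)
  ser <- steps_and_angles(tr$fixes)
  post <- state_posteriors(ser, params)
  vit <- viterbi(ser, params)
  sharp <- apply(post, 1, max) > 0.75
  expect_gt(mean(sharp), 0.8)
  expect_true(all((apply(post, 1, which.max) == vit)[sharp]))
})

test_that("decoding recovers well-separated simulated states", {
  cfg <- sim_config(2, mu = c(8, 350), sigma = c(8, 250), zmass = c(.05, .01),
                    angle_mean = c(pi, 0), kappa = c(.5, 2),
                    Gamma = persistent_gamma(c(.6, .4), .85),
                    n_steps = 2000, seed = 17)
  tr <- simulate_hmm_track(cfg)
  ser <- steps_and_angles(tr$fixes)
  params <- hmm_params(cfg$mu, cfg$sigma, cfg$zmass, cfg$angle_mean,
                       cfg$kappa, cfg$Gamma)
  vit <- viterbi(ser, params)
  expect_gt(mean(vit == tr$states), 0.95)
})

test_that("predictive power averages the maximum posterior, boundary at 0.90", {
  certain <- matrix(c(1, 0), 10, 2, byrow = TRUE)
  expect_equal(predictive_power(certain)$index, 1)
  expect_true(predictive_power(certain)$strong)
  even <- matrix(0.5, 10, 2)
  pp <- predictive_power(even)
  expect_equal(pp$index, 0.5)
  expect_false(pp$strong)
  boundary <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                    matrix(c(0.8, 0.2), 5, 2, byrow = TRUE))
  ppb <- predictive_power(boundary)
  expect_equal(ppb$index, 0.9)
  expect_true(ppb$strong)
  # invariance under state relabeling
  expect_equal(predictive_power(boundary[, 2:1])$index, ppb$index)
})

test_that("free-parameter counts and AIC follow the stated formula", {
  expect_equal(count_free_params(2, zeros_present = TRUE), 12)
  expect_equal(count_free_params(3, zeros_present = TRUE), 21)
  expect_equal(count_free_params(2, zeros_present = FALSE), 10)
  fake <- structure(list(loglik = -1000, p = 12), class = "hmm_fit")
  expect_equal(AIC(fake), 2024)
})

test_that("plausibility labels ordered states and rejects indistinct ones", {
  good3 <- hmm_params(c(122, 7.5, 625), c(114, 7.2, 385), rep(.01, 3),
                      rep(0, 3), c(0.7, 0.5, 2),
                      persistent_gamma(rep(1 / 3, 3), .8))
  pc <- plausibility_check(good3)
  expect_true(pc$plausible)
  expect_equal(pc$labels, c("foraging", "encamped", "traveling"))
  bad <- hmm_params(c(100, 102, 625), c(80, 80, 300), rep(.01, 3),
                    rep(0, 3), c(.5, .7, 2),
                    persistent_gamma(rep(1 / 3, 3), .8))
  pcb <- plausibility_check(bad)
  expect_false(pcb$plausible)
  expect_match(pcb$reasons, "indistinct")
  two <- hmm_params(c(7.6, 319), c(7.2, 256), c(.01, .01), c(pi, 0),
                    c(.5, 1.5), persistent_gamma(c(.58, .42), .8))
  pct <- plausibility_check(two)
  expect_true(pct$plausible)
  expect_equal(pct$labels, c("encamped", "moving"))
  # traveling must be the most directed moving state
  swapped <- hmm_params(c(7.5, 122, 625), c(7.2, 114, 385), rep(.01, 3),
                        rep(0, 3), c(.5, 2, .7),
                        persistent_gamma(rep(1 / 3, 3), .8))
  expect_false(plausibility_check(swapped)$plausible)
})

test_that("stationary distributions solve delta Gamma = delta", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2)),
               c(.5, .5))
  expect_equal(stationary_distribution(matrix(c(.8, .2, .3, .7), 2,
                                              byrow = TRUE)), c(.6, .4))
  expect_error(stationary_distribution(diag(2)), "stationary")
  set.seed(2)
  G <- matrix(rgamma(9, 2), 3)
  G <- G / rowSums(G)
  d <- stationary_distribution(G)
  expect_equal(as.numeric(d %*% G), d, tolerance = 1e-12)
})
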