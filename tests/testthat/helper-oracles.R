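# Independent plain-R oracles for the movement-model algorithms: emission
# densities from stats::dgamma/base::besselI and exhaustive enumeration over
# all K^T state paths. These never touch the package's compiled recursions.

oracle_emission <- function(L, phi, params) {
  K <- params$K
  E <- matrix(0, length(L), K)
  for (k in seq_len(K)) {
    shape <- params$mu[k]^2 / params$sigma[k]^2
    scale <- params$sigma[k]^2 / params$mu[k]
    step <- ifelse(L == 0, params$zmass[k],
                   (1 - params$zmass[k]) *
                     dgamma(L, shape = shape, scale = scale))
    ang <- exp(params$kappa[k] * cos(phi - params$angle_mean[k])) /
      (2 * pi * besselI(params$kappa[k], 0))
    ang[is.na(phi)] <- 1
    E[, k] <- step * ang
  }
  E
}

# Exhaustive path enumeration: joint probability of every state path, giving
# the log-likelihood, the argmax path, and marginal state posteriors.
oracle_enumerate <- function(L, phi, params) {
  K <- params$K
  Tn <- length(L)
  E <- oracle_emission(L, phi, params)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  probs <- apply(paths, 1, function(s) {
    p <- params$delta[s[1]] * E[1, s[1]]
    if (Tn > 1) {
      for (t in 2:Tn) p <- p * params$Gamma[s[t - 1], s[t]] * E[t, s[t]]
    }
    p
  })
  total <- sum(probs)
  post <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) {
    for (k in seq_len(K)) post[t, k] <- sum(probs[paths[, t] == k]) / total
  }
  list(loglik = log(total),
       viterbi = as.integer(paths[which.max(probs), ]),
       posterior = post)
}

# Random valid model parameters for property-style checks.
random_params <- function(K, zeros = TRUE) {
  mu <- sort(exp(runif(K, log(5), log(800))))
  sigma <- mu * runif(K, 0.5, 1.5)
  zmass <- if (zeros) runif(K, 0.05, 0.2) else rep(0, K)
  angle_mean <- runif(K, -pi, pi)
  kappa <- runif(K, 0, 3)
  G <- matrix(rgamma(K * K, shape = 2) + 0.05, K, K)
  G <- G / rowSums(G)
  hmm_params(mu, sigma, zmass, angle_mean, kappa, G)
}

# Random observation series with zeros and the missing-angle convention.
random_series <- function(Tn, zero_prob = 0.15) {
  L <- rgamma(Tn, shape = 1.2, scale = 150)
  L[runif(Tn) < zero_prob] <- 0
  phi <- runif(Tn, -pi, pi)
  phi[1] <- NA
  for (t in 2:Tn) if (L[t] == 0 || L[t - 1] == 0) phi[t] <- NA
  structure(list(L = L, phi = phi, burst_id = "oracle"),
            class = "step_series")
}

# Regular 15-min track through given waypoints (for cleaning/burst tests).
track_from_xy <- function(x, y, interval = 900, id = "test",
                          t0 = as.POSIXct("2016-01-01", tz = "UTC")) {
  data.frame(animal_id = id,
             timestamp = t0 + interval * (seq_along(x) - 1),
             x = x, y = y, stringsAsFactors = FALSE)
}
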