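#' K-state movement-model parameters
#'
#' Parameters of a hidden Markov movement model with zero-inflated gamma step
#' lengths and von Mises turning angles. The gamma is parameterized by mean
#' and SD (meters), the scale on which field studies report state step
#' lengths; internally shape = mu^2/sigma^2 and scale = sigma^2/mu. The
#' initial distribution is tied to the stationary distribution of the
#' transition matrix.
#'
#' @param mu,sigma per-state mean and SD of positive step lengths (m, > 0).
#' @param zmass per-state zero-step probability in `[0, 1)`.
#' @param angle_mean per-state von Mises mean turning angle (rad).
#' @param kappa per-state von Mises concentration (>= 0).
#' @param Gamma K x K transition matrix (rows sum to 1); for K = 1 the 1x1
#'   matrix `[1]`.
#' @return an object of class `hmm_params` with the stationary initial
#'   distribution in `$delta`.
#' @export
hmm_params <- function(mu, sigma, zmass = rep(0, length(mu)),
                       angle_mean = rep(0, length(mu)),
                       kappa = rep(0, length(mu)),
                       Gamma = diag(length(mu))) {
  K <- length(mu)
  stopifnot(length(sigma) == K, length(zmass) == K,
            length(angle_mean) == K, length(kappa) == K)
  if (any(mu <= 0) || any(sigma <= 0)) stop("mu and sigma must be positive")
  if (any(zmass < 0 | zmass >= 1)) stop("zmass must lie in [0, 1)")
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  Gamma <- as.matrix(Gamma)
  if (!all(dim(Gamma) == c(K, K)) || any(Gamma < 0) ||
      any(abs(rowSums(Gamma) - 1) > 1e-10))
    stop("Gamma must be a row-stochastic ", K, " x ", K, " matrix")
  delta <- if (K == 1) 1 else stationary_distribution(Gamma)
  structure(list(K = K, mu = mu, sigma = sigma, zmass = zmass,
                 angle_mean = wrap_angle(angle_mean), kappa = kappa,
                 Gamma = Gamma, delta = delta),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(x$K, "-state movement model\n", sep = "")
  tab <- data.frame(mu_m = x$mu, sigma_m = x$sigma, zero_mass = x$zmass,
                    angle_mean = x$angle_mean, kappa = x$kappa)
  print(tab, digits = 4)
  cat("transition matrix:\n")
  print(round(x$Gamma, 4))
  cat("stationary distribution:", round(x$delta, 4), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `delta %*% Gamma = delta`, `sum(delta) = 1` by a linear system.
#' Errors when the chain has no unique stationary distribution (e.g. the
#' identity matrix).
#'
#' @param Gamma row-stochastic square matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  K <- nrow(Gamma)
  if (any(abs(rowSums(Gamma) - 1) > 1e-8) || any(Gamma < 0))
    stop("Gamma must be row-stochastic")
  if (K == 1) return(1)
  A <- t(diag(K) - Gamma)
  A[K, ] <- 1
  b <- c(rep(0, K - 1), 1)
  delta <- tryCatch(solve(A, b), error = function(e)
    stop("no unique stationary distribution (reducible or degenerate chain)"))
  if (any(delta < -1e-10) || abs(sum(delta) - 1) > 1e-8 ||
      max(abs(delta %*% Gamma - delta)) > 1e-8)
    stop("no unique stationary distribution (reducible or degenerate chain)")
  as.numeric(pmax(delta, 0) / sum(pmax(delta, 0)))
}

#' Zero-inflated gamma step-length density
#'
#' Returns the zero-mass `z` at `L = 0` and `(1 - z)` times the gamma
#' density (mean `mu`, SD `sigma`) for positive lengths.
#'
#' @param L step length in meters (>= 0); vectorized.
#' @param mu,sigma gamma mean and SD (m).
#' @param z zero-step probability.
#' @return density values.
#' @export
step_emission <- function(L, mu, sigma, z = 0) {
  stopifnot(mu > 0, sigma > 0, z >= 0, z < 1)
  if (any(L < 0)) stop("step lengths must be nonnegative")
  shape <- mu^2 / sigma^2
  scale <- sigma^2 / mu
  ifelse(L == 0, z, (1 - z) * dgamma(L, shape = shape, scale = scale))
}

#' von Mises turning-angle density
#'
#' `exp(kappa * cos(phi - m)) / (2 * pi * I0(kappa))`; a missing angle
#' contributes likelihood factor 1 (the observation is marginalized out).
#' `kappa = 0` gives the circular uniform `1/(2*pi)`.
#'
#' @param phi turning angle in radians, possibly `NA`; vectorized.
#' @param m mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return density values (1 where `phi` is `NA`).
#' @export
angle_emission <- function(phi, m = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  out <- exp(kappa * (cos(phi - m) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  out[is.na(phi)] <- 1
  out
}

## Internal: pool a step_series or list of them into vectors + burst starts.
pool_series <- function(series_list) {
  if (inherits(series_list, "step_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, TRUE, "step_series")))
  L <- unlist(lapply(series_list, `[[`, "L"), use.names = FALSE)
  phi <- unlist(lapply(series_list, `[[`, "phi"), use.names = FALSE)
  lens <- vapply(series_list, function(s) length(s$L), integer(1))
  starts <- cumsum(c(0L, head(lens, -1)))
  ids <- vapply(series_list, `[[`, character(1), "burst_id")
  list(L = L, phi = phi, starts = starts, lens = lens, ids = ids)
}

## Internal: emission matrix for pooled observations.
emission_matrix <- function(L, phi, params) {
  emission_matrix_cpp(L, phi, params$mu, params$sigma, params$zmass,
                      params$angle_mean, params$kappa)
}

#' Forward log-likelihood of pooled bursts
#'
#' Scaled forward algorithm summed over bursts; every burst restarts from the
#' stationary initial distribution. Per-step emission is the product of the
#' step-length and turning-angle densities.
#'
#' @param series_list a `step_series` or list of them.
#' @param params an `hmm_params`.
#' @return log-likelihood (may be `-Inf` when an observation is impossible
#'   under the parameters).
#' @export
forward_loglik <- function(series_list, params) {
  stopifnot(inherits(params, "hmm_params"))
  pooled <- pool_series(series_list)
  E <- emission_matrix(pooled$L, pooled$phi, params)
  bad <- which(!is.finite(E), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite emission density at step ", bad[1, 1],
         " (state ", bad[1, 2], ")")
  forward_loglik_cpp(E, params$Gamma, params$delta, as.integer(pooled$starts))
}

#' Viterbi decoding of a burst
#'
#' Most likely state path under the model, computed in log space; ties are
#' broken toward the lower state index.
#'
#' @param series a `step_series`.
#' @param params an `hmm_params`.
#' @return integer state sequence in `1..K`.
#' @export
viterbi <- function(series, params) {
  stopifnot(inherits(series, "step_series"), inherits(params, "hmm_params"))
  E <- emission_matrix(series$L, series$phi, params)
  as.integer(viterbi_cpp(E, params$Gamma, params$delta))
}

#' Forward-backward state posteriors of a burst
#'
#' Smoothed probability of each state at each step given the whole burst.
#'
#' @param series a `step_series`.
#' @param params an `hmm_params`.
#' @return T x K matrix with rows summing to 1.
#' @export
state_posteriors <- function(series, params) {
  stopifnot(inherits(series, "step_series"), inherits(params, "hmm_params"))
  E <- emission_matrix(series$L, series$phi, params)
  fb <- forward_backward_cpp(E, params$Gamma, params$delta)
  post <- fb$alpha * fb$beta
  post / rowSums(post)
}

#' Decode one or more bursts
#'
#' Runs Viterbi and forward-backward decoding on each burst.
#'
#' @param series_list a `step_series` or list of them.
#' @param params an `hmm_params`.
#' @return list of `decoded_burst` objects: burst id, `states` (Viterbi),
#'   `posterior` (T x K), `max_posterior` (probability of the most likely
#'   state at each step).
#' @export
decode <- function(series_list, params) {
  if (inherits(series_list, "step_series")) series_list <- list(series_list)
  lapply(series_list, function(s) {
    post <- state_posteriors(s, params)
    structure(list(burst_id = s$burst_id,
                   states = viterbi(s, params),
                   posterior = post,
                   max_posterior = apply(post, 1, max)),
              class = "decoded_burst")
  })
}

#' Predictive-power index of a decoded model
#'
#' Mean over all steps of the probability of the most likely state (the
#' maximum posterior). A model is considered strongly predictive when the
#' index is at least 0.90 (boundary inclusive). The index is invariant under
#' relabeling of states.
#'
#' @param decoded a `decoded_burst`, a list of them, or a (list of)
#'   posterior matrix/matrices.
#' @return list with `index` in `(0, 1]` and logical `strong`.
#' @export
predictive_power <- function(decoded) {
  if (inherits(decoded, "decoded_burst") || is.matrix(decoded))
    decoded <- list(decoded)
  maxima <- unlist(lapply(decoded, function(d) {
    if (inherits(d, "decoded_burst")) return(d$max_posterior)
    if (is.matrix(d)) return(apply(d, 1, max))
    stop("decoded must be decoded bursts or posterior matrices")
  }))
  idx <- mean(maxima)
  list(index = idx, strong = idx >= 0.90)
}

#' Number of free parameters of a movement model
#'
#' Each state contributes a gamma mean and SD and a von Mises mean and
#' concentration (4 parameters), plus one zero-mass parameter per state when
#' the data contain zero-length steps; the transition matrix contributes
#' `K * (K - 1)`. The initial distribution is tied to the stationary
#' distribution and adds none.
#'
#' @param params an `hmm_params` (or integer K).
#' @param zeros_present logical: do the data contain zero-length steps?
#' @return integer parameter count.
#' @export
count_free_params <- function(params, zeros_present = TRUE) {
  K <- if (inherits(params, "hmm_params")) params$K else as.integer(params)
  K * 4L + K * as.integer(zeros_present) + K * (K - 1L)
}

#' @export
AIC.hmm_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$p
}

#' Biological plausibility of fitted movement states
#'
#' Orders states by mean step length and assigns field labels: 2 states are
#' encamped/moving; 3 are encamped/foraging/traveling; 4 are
#' encamped/foraging/searching/traveling. The check fails when consecutive
#' mean step lengths are not separated by at least `separation_ratio`
#' (indistinct states), or when the traveling state does not have the
#' highest angular concentration among the moving states (traveling should
#' be the most directed behavior).
#'
#' @param params an `hmm_params`.
#' @param separation_ratio minimum ratio of consecutive ordered means
#'   (default 2).
#' @return list with `plausible` (logical), `labels` (in original state
#'   order; `NA` on failure), `order` (permutation sorting states by mean),
#'   and `reasons` (character, empty when plausible).
#' @export
plausibility_check <- function(params, separation_ratio = 2) {
  stopifnot(inherits(params, "hmm_params"))
  K <- params$K
  ord <- order(params$mu)
  mu_sorted <- params$mu[ord]
  label_sets <- list(
    "1" = "single",
    "2" = c("encamped", "moving"),
    "3" = c("encamped", "foraging", "traveling"),
    "4" = c("encamped", "foraging", "searching", "traveling"))
  if (K > 4) stop("plausibility labels defined for K <= 4")
  labels_sorted <- label_sets[[as.character(K)]]
  reasons <- character(0)
  if (K >= 2) {
    ratios <- mu_sorted[-1] / mu_sorted[-K]
    if (any(ratios < separation_ratio))
      reasons <- c(reasons, paste0(
        "indistinct states: consecutive mean step-length ratio ",
        paste(round(ratios, 2), collapse = ", "), " below ", separation_ratio))
  }
  if (K >= 3) {
    kappa_moving <- params$kappa[ord][-1]
    if (which.max(kappa_moving) != length(kappa_moving))
      reasons <- c(reasons, paste0(
        "traveling state does not have the highest angular concentration ",
        "among moving states"))
  }
  plausible <- length(reasons) == 0
  labels <- rep(NA_character_, K)
  if (plausible) labels[ord] <- labels_sorted
  list(plausible = plausible, labels = labels, order = ord, reasons = reasons)
}

#' State labels of a fitted model
#'
#' Convenience accessor: labels in state order from [plausibility_check()],
#' falling back to `state1..stateK` when the fit is implausible.
#'
#' @param params an `hmm_params`.
#' @return character vector of length K.
#' @export
state_labels <- function(params) {
  pc <- plausibility_check(params)
  if (pc$plausible) pc$labels else paste0("state", seq_len(params$K))
}
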