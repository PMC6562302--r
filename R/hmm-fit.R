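## Working-scale transform for likelihood maximization:
## log mu, log sigma, logit z (only when the data contain zeros), raw angle
## mean (periodic through cos), log kappa, and row-wise multinomial logits of
## Gamma with the diagonal as reference category. The initial distribution is
## tied to the stationary distribution of Gamma throughout.

pack_params <- function(params, zeros_present) {
  K <- params$K
  theta <- c(log(params$mu), log(params$sigma))
  if (zeros_present) {
    z <- pmin(pmax(params$zmass, 1e-6), 1 - 1e-6)
    theta <- c(theta, log(z / (1 - z)))
  }
  theta <- c(theta, params$angle_mean, log(pmax(params$kappa, 1e-4)))
  if (K > 1) {
    eta <- log(pmax(params$Gamma, 1e-12) / pmax(diag(params$Gamma), 1e-12))
    theta <- c(theta, as.vector(t(eta))[as.vector(t(diag(K) == 0))])
  }
  theta
}

unpack_params <- function(theta, K, zeros_present) {
  i <- 0
  take <- function(n) {
    out <- theta[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  mu <- exp(take(K))
  sigma <- exp(take(K))
  zmass <- if (zeros_present) plogis(take(K)) else rep(0, K)
  angle_mean <- wrap_angle(take(K))
  kappa <- exp(take(K))
  if (K > 1) {
    eta <- take(K * (K - 1))
    Gamma <- matrix(0, K, K)
    pos <- 1
    for (r in seq_len(K)) {
      row <- numeric(K)
      for (cc in seq_len(K)) {
        if (cc != r) {
          row[cc] <- eta[pos]
          pos <- pos + 1
        }
      }
      erow <- exp(row - max(row))
      Gamma[r, ] <- erow / sum(erow)
    }
  } else {
    Gamma <- matrix(1, 1, 1)
  }
  list(mu = mu, sigma = sigma, zmass = zmass, angle_mean = angle_mean,
       kappa = kappa, Gamma = Gamma)
}

neg_loglik_working <- function(theta, K, zeros_present, L, phi, starts) {
  if (any(!is.finite(theta))) return(1e10)
  p <- unpack_params(theta, K, zeros_present)
  if (any(!is.finite(p$mu)) || any(!is.finite(p$sigma)) ||
      any(p$mu <= 0) || any(p$sigma <= 0) || any(!is.finite(p$kappa)))
    return(1e10)
  delta <- tryCatch(
    if (K == 1) 1 else stationary_distribution(p$Gamma),
    error = function(e) NULL)
  if (is.null(delta)) return(1e10)
  E <- emission_matrix_cpp(L, phi, p$mu, p$sigma, p$zmass, p$angle_mean,
                           p$kappa)
  if (any(!is.finite(E))) return(1e10)
  ll <- forward_loglik_cpp(E, p$Gamma, delta, starts)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Build a multi-start grid for movement-model fitting
#'
#' Starting values are the Cartesian product of candidate per-state step
#' means (quantiles of the positive step lengths, assigned to states in
#' ascending order), shared candidate turning-angle means, and shared
#' candidate concentrations; step SDs start equal to the means and the
#' transition matrix starts with 0.9 on the diagonal. Running the
#' optimization from every combination guards against local maxima of the
#' likelihood.
#'
#' @param series_list a `step_series` or list of them.
#' @param K number of states.
#' @param step_quantile_levels list of length-K quantile-level vectors, one
#'   candidate mean set each; defaults to a midpoint set, a spread set, and
#'   an upper-tail set (the last keeps starts out of the short-step mass
#'   when one state dominates the time budget).
#' @param angle_mean_candidates candidate von Mises means applied to all
#'   states (default 0 and pi).
#' @param kappa_candidates candidate concentrations applied to all states
#'   (default 0.5 and 2).
#' @param diag_prob starting self-transition probability.
#' @return list of `hmm_params` starting points (length = product of the
#'   numbers of options).
#' @export
build_start_grid <- function(series_list, K, step_quantile_levels = NULL,
                             angle_mean_candidates = c(0, pi),
                             kappa_candidates = c(0.5, 2),
                             diag_prob = 0.9) {
  pooled <- pool_series(series_list)
  pos <- pooled$L[pooled$L > 0]
  if (!length(pos)) stop("no positive step lengths in the data")
  if (is.null(step_quantile_levels)) {
    mid <- (2 * seq_len(K) - 1) / (2 * K)
    spread <- if (K == 1) 0.5 else 0.05 + 0.9 * (seq_len(K) - 1) / (K - 1)
    upper <- if (K == 1) 0.5 else 0.45 + 0.5 * (seq_len(K) - 1) / (K - 1)
    step_quantile_levels <- unique(list(mid, spread, upper))
  }
  zfrac <- mean(pooled$L == 0)
  zstart <- if (zfrac > 0) min(max(zfrac, 1e-3), 0.5) else 0
  Gamma0 <- matrix((1 - diag_prob) / max(K - 1, 1), K, K)
  diag(Gamma0) <- if (K == 1) 1 else diag_prob
  starts <- list()
  for (ql in step_quantile_levels) {
    stopifnot(length(ql) == K)
    mu0 <- sort(as.numeric(quantile(pos, ql)))
    mu0 <- pmax(mu0, 1e-6)
    for (am in angle_mean_candidates) {
      for (kp in kappa_candidates) {
        starts[[length(starts) + 1]] <- hmm_params(
          mu = mu0, sigma = mu0, zmass = rep(zstart, K),
          angle_mean = rep(am, K), kappa = rep(kp, K), Gamma = Gamma0)
      }
    }
  }
  starts
}

#' Fit a K-state hidden Markov movement model
#'
#' Maximizes the pooled forward log-likelihood over working-scale parameters
#' by quasi-Newton (BFGS) optimization from every point of a starting grid,
#' and returns the best converged fit with states relabeled in ascending
#' order of mean step length. Zero-mass parameters are included only when
#' the data contain zero-length steps. The fit is assessed by the three
#' criteria used for movement models: biological plausibility of the state
#' parameters, the predictive-power index (mean maximum posterior, strong at
#' >= 0.90), and AIC.
#'
#' @param series_list a `step_series` or list of them (pooled; each burst
#'   restarts from the stationary distribution).
#' @param K number of states (1 to 4).
#' @param start_grid list of `hmm_params` starts; default
#'   [build_start_grid()].
#' @param maxit,reltol optimizer control (BFGS iterations and relative
#'   log-likelihood tolerance).
#' @param screen_maxit iteration budget of the screening stage run from
#'   every start; the `n_polish` most promising starts are then continued
#'   to full convergence (set `screen_maxit = NULL` to converge every
#'   start fully).
#' @param n_polish number of screened starts continued to convergence.
#' @param separation_ratio passed to [plausibility_check()].
#' @return an `hmm_fit`: fitted `params`, `loglik`, `aic`, `p` (free
#'   parameters), `n_obs`, per-start log-likelihoods, convergence codes,
#'   `predictive_power`, `plausibility`.
#' @export
fit_hmm <- function(series_list, K, start_grid = NULL, maxit = 500,
                    reltol = 1e-8, screen_maxit = 60, n_polish = 3,
                    separation_ratio = 2) {
  stopifnot(K >= 1, K <= 4)
  if (inherits(series_list, "step_series")) series_list <- list(series_list)
  pooled <- pool_series(series_list)
  zeros_present <- any(pooled$L == 0)
  p_free <- count_free_params(K, zeros_present)
  if (length(pooled$L) < 50 * p_free)
    warning("only ", length(pooled$L), " pooled steps for ", p_free,
            " free parameters; estimates may be unstable")
  if (is.null(start_grid)) start_grid <- build_start_grid(series_list, K)
  starts <- as.integer(pooled$starts)
  results <- vector("list", length(start_grid))
  logls <- rep(NA_real_, length(start_grid))
  codes <- rep(NA_integer_, length(start_grid))
  failures <- character(0)
  run_opt <- function(theta0, iters) {
    tryCatch(
      optim(theta0, neg_loglik_working, method = "BFGS",
            control = list(maxit = iters, reltol = reltol),
            K = K, zeros_present = zeros_present,
            L = pooled$L, phi = pooled$phi, starts = starts),
      error = function(e) e)
  }
  ## screening stage: a limited iteration budget from every grid point
  screen_iters <- if (is.null(screen_maxit)) maxit else min(screen_maxit, maxit)
  for (s in seq_along(start_grid)) {
    theta0 <- pack_params(start_grid[[s]], zeros_present)
    opt <- run_opt(theta0, screen_iters)
    if (inherits(opt, "error")) {
      failures <- c(failures, paste0("start ", s, ": ", conditionMessage(opt)))
      next
    }
    if (opt$value >= 1e10) {
      failures <- c(failures, paste0("start ", s, ": degenerate likelihood"))
      next
    }
    results[[s]] <- opt
    logls[s] <- -opt$value
    codes[s] <- opt$convergence
  }
  if (all(is.na(logls)))
    stop("all starts failed:\n", paste(failures, collapse = "\n"))
  ## polishing stage: continue the most promising starts to convergence
  if (!is.null(screen_maxit) && screen_iters < maxit) {
    top <- order(-logls)[seq_len(min(n_polish, sum(!is.na(logls))))]
    for (s in top) {
      opt <- run_opt(results[[s]]$par, maxit)
      if (inherits(opt, "error") || opt$value >= 1e10) next
      results[[s]] <- opt
      logls[s] <- -opt$value
      codes[s] <- opt$convergence
    }
  }
  best <- which.max(logls)
  raw <- unpack_params(results[[best]]$par, K, zeros_present)
  ord <- order(raw$mu)
  params <- hmm_params(mu = raw$mu[ord], sigma = raw$sigma[ord],
                       zmass = raw$zmass[ord],
                       angle_mean = raw$angle_mean[ord],
                       kappa = raw$kappa[ord],
                       Gamma = raw$Gamma[ord, ord, drop = FALSE])
  loglik <- logls[best]
  decoded <- decode(series_list, params)
  pp <- predictive_power(decoded)
  pc <- plausibility_check(params, separation_ratio = separation_ratio)
  structure(list(params = params, loglik = loglik,
                 p = p_free, aic = -2 * loglik + 2 * p_free,
                 K = K, n_obs = length(pooled$L),
                 zeros_present = zeros_present,
                 start_logliks = logls, convergence = codes,
                 failures = failures, best_start = best,
                 predictive_power = pp, plausibility = pc),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(x$K, "-state movement model fit: logL = ", format(x$loglik),
      ", AIC = ", format(x$aic), ", p = ", x$p, "\n", sep = "")
  cat("predictive power ", round(x$predictive_power$index, 3),
      if (x$predictive_power$strong) " (strong)" else " (not strong)",
      "; plausible: ", x$plausibility$plausible, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Serialize a fit to a JSON document
#'
#' @param fit an `hmm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hmm_fit"))
  doc <- list(K = fit$K, mu = fit$params$mu, sigma = fit$params$sigma,
              zmass = fit$params$zmass, angle_mean = fit$params$angle_mean,
              kappa = fit$params$kappa, Gamma = fit$params$Gamma,
              delta = fit$params$delta, loglik = fit$loglik, aic = fit$aic,
              p = fit$p, n_obs = fit$n_obs,
              predictive_power = fit$predictive_power$index,
              strongly_predictive = fit$predictive_power$strong,
              plausible = fit$plausibility$plausible,
              state_labels = state_labels(fit$params),
              start_logliks = fit$start_logliks)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
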