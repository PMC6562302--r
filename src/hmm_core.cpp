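#include <Rcpp.h>
using namespace Rcpp;

// Per-step emission densities for a K-state movement model.
// Step lengths follow a zero-inflated gamma (mean/SD parameterization):
// a point mass zmass[k] at L == 0, otherwise (1 - zmass[k]) * dgamma.
// Turning angles follow a von Mises; a missing (NA) angle contributes
// factor 1 (marginalized out).
// [[Rcpp::export]]
NumericMatrix emission_matrix_cpp(NumericVector L, NumericVector phi,
                                  NumericVector mu, NumericVector sigma,
                                  NumericVector zmass, NumericVector angle_mean,
                                  NumericVector kappa) {
  int n = L.size(), K = mu.size();
  NumericMatrix E(n, K);
  for (int k = 0; k < K; ++k) {
    double shape = (mu[k] * mu[k]) / (sigma[k] * sigma[k]);
    double scale = (sigma[k] * sigma[k]) / mu[k];
    // gamma log-density constant and von Mises normalizer hoisted per state
    double lconst = -R::lgammafn(shape) - shape * std::log(scale);
    double log1mz = std::log1p(-zmass[k]);
    double vm_lognorm = std::log(2.0 * M_PI * R::bessel_i(kappa[k], 0.0, 2.0));
    double m = angle_mean[k], kap = kappa[k];
    for (int t = 0; t < n; ++t) {
      double le;
      if (L[t] == 0.0) {
        le = std::log(zmass[k]);
      } else {
        le = log1mz + lconst + (shape - 1.0) * std::log(L[t]) - L[t] / scale;
      }
      if (!NumericVector::is_na(phi[t])) {
        le += kap * (std::cos(phi[t] - m) - 1.0) - vm_lognorm;
      }
      E(t, k) = std::exp(le);
    }
  }
  return E;
}

// Scaled forward recursion over one or more bursts laid out contiguously in E.
// burst_start holds the 0-based row index of the first observation of each
// burst; every burst restarts from delta. Returns the summed log-likelihood,
// or -Inf when a step has zero total forward mass (impossible data under the
// parameters).
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix E, NumericMatrix Gamma,
                          NumericVector delta, IntegerVector burst_start) {
  int n = E.nrow(), K = E.ncol(), B = burst_start.size();
  double ll = 0.0;
  std::vector<double> alpha(K), tmp(K);
  for (int b = 0; b < B; ++b) {
    int s = burst_start[b];
    int e = (b + 1 < B) ? burst_start[b + 1] : n;
    double sum = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = delta[k] * E(s, k);
      sum += alpha[k];
    }
    if (!(sum > 0.0) || !R_finite(sum)) return R_NegInf;
    ll += std::log(sum);
    for (int k = 0; k < K; ++k) alpha[k] /= sum;
    for (int t = s + 1; t < e; ++t) {
      sum = 0.0;
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += alpha[i] * Gamma(i, j);
        tmp[j] = a * E(t, j);
        sum += tmp[j];
      }
      if (!(sum > 0.0) || !R_finite(sum)) return R_NegInf;
      ll += std::log(sum);
      for (int k = 0; k < K; ++k) alpha[k] = tmp[k] / sum;
    }
  }
  return ll;
}

// Scaled forward and backward variables for one burst; used by the
// forward-backward smoother. Returns list(log_alpha_scaled = alpha rows
// normalized, log_c = per-step log normalizers, beta = scaled backward rows).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix E, NumericMatrix Gamma,
                          NumericVector delta) {
  int n = E.nrow(), K = E.ncol();
  NumericMatrix alpha(n, K), beta(n, K);
  NumericVector logc(n);
  double sum;
  for (int k = 0; k < K; ++k) alpha(0, k) = delta[k] * E(0, k);
  sum = 0.0;
  for (int k = 0; k < K; ++k) sum += alpha(0, k);
  if (!(sum > 0.0)) stop("zero forward mass at step 1");
  logc[0] = std::log(sum);
  for (int k = 0; k < K; ++k) alpha(0, k) /= sum;
  for (int t = 1; t < n; ++t) {
    sum = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * Gamma(i, j);
      alpha(t, j) = a * E(t, j);
      sum += alpha(t, j);
    }
    if (!(sum > 0.0)) stop("zero forward mass at step %d", t + 1);
    logc[t] = std::log(sum);
    for (int k = 0; k < K; ++k) alpha(t, k) /= sum;
  }
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += Gamma(i, j) * E(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / std::exp(logc[t + 1]);
    }
  }
  return List::create(_["alpha"] = alpha, _["beta"] = beta, _["log_c"] = logc);
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix E, NumericMatrix Gamma,
                          NumericVector delta) {
  int n = E.nrow(), K = E.ncol();
  NumericMatrix v(n, K);
  IntegerMatrix back(n, K);
  for (int k = 0; k < K; ++k) v(0, k) = std::log(delta[k]) + std::log(E(0, k));
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double cand = v(t - 1, i) + std::log(Gamma(i, j));
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + std::log(E(t, j));
      back(t, j) = arg;
    }
  }
  IntegerVector path(n);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    if (v(n - 1, k) > best) { best = v(n - 1, k); arg = k; }
  }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t) {
    arg = back(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
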