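#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Sample a discrete-time Markov chain of length n from per-frame transition
// matrix P (rows sum to 1) and initial distribution pi0. Uses R's RNG so
// set.seed() controls reproducibility. States returned 1-based.
// [[Rcpp::export]]
IntegerVector cpp_sim_markov(int n, NumericMatrix P, NumericVector pi0) {
  int K = P.nrow();
  IntegerVector s(n);
  // cumulative rows
  NumericMatrix cumP(K, K);
  for (int i = 0; i < K; ++i) {
    double c = 0.0;
    for (int j = 0; j < K; ++j) { c += P(i, j); cumP(i, j) = c; }
  }
  double u = unif_rand(), c = 0.0;
  int cur = K - 1;
  for (int j = 0; j < K; ++j) { c += pi0[j]; if (u <= c) { cur = j; break; } }
  s[0] = cur + 1;
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    int nx = K - 1;
    for (int j = 0; j < K; ++j) { if (u <= cumP(cur, j)) { nx = j; break; } }
    cur = nx;
    s[t] = cur + 1;
  }
  return s;
}

static inline double reflect_into(double x, double lo, double hi) {
  // fold x into [lo, hi] by mirror reflection
  if (hi <= lo) return lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    else x = 2.0 * hi - x;
  }
  return x;
}

// Simulate centroid positions given a 1-based state sequence (1=Q, 2=D, 3=R).
// Displacement into frame t is governed by states[t]; frame 0 sits at (x0,y0).
// Q: isotropic Gaussian jitter (sd jitter). D: log-normal speed, heading
// reversed with probability 1/2 each frame. R: log-normal speed, persistent
// heading with Gaussian angular diffusion (sd turn_sd). Positions reflect at
// [0, width-1] x [0, height-1]. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_sim_track(IntegerVector states, NumericVector mu,
                            NumericVector sigma, double jitter, double turn_sd,
                            double frame_rate, double width, double height,
                            double x0, double y0) {
  int n = states.size();
  NumericMatrix pos(n, 2);
  double x = x0, y = y0;
  double theta = unif_rand() * 2.0 * M_PI;
  pos(0, 0) = x; pos(0, 1) = y;
  for (int t = 1; t < n; ++t) {
    int s = states[t] - 1;
    double dx, dy;
    if (s == 0) {
      dx = norm_rand() * jitter;
      dy = norm_rand() * jitter;
    } else {
      if (s == 1) {
        if (unif_rand() < 0.5) theta += M_PI;
      } else {
        theta += norm_rand() * turn_sd;
      }
      double speed = std::exp(mu[s] + sigma[s] * norm_rand());
      double step = speed / frame_rate;
      dx = step * std::cos(theta);
      dy = step * std::sin(theta);
    }
    x = reflect_into(x + dx, 0.0, width - 1.0);
    y = reflect_into(y + dy, 0.0, height - 1.0);
    pos(t, 0) = x; pos(t, 1) = y;
  }
  return pos;
}

// Scaled forward pass. B: n x K emission densities, pi0 initial, A transition.
// Returns log P(observations | params).
// [[Rcpp::export]]
double cpp_forward_loglik(NumericMatrix B, NumericVector pi0, NumericMatrix A) {
  int n = B.nrow(), K = B.ncol();
  std::vector<double> alpha(K), anew(K);
  double ll = 0.0, c = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi0[k] * B(0, k); c += alpha[k]; }
  if (c <= 0) c = DBL_MIN;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  ll += std::log(c);
  for (int t = 1; t < n; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha[j] * A(j, k);
      anew[k] = s * B(t, k);
      c += anew[k];
    }
    if (c <= 0) c = DBL_MIN;
    for (int k = 0; k < K; ++k) alpha[k] = anew[k] / c;
    ll += std::log(c);
  }
  return ll;
}

// Scaled forward-backward. Returns log-likelihood, per-frame posteriors gamma
// (n x K), and summed transition responsibilities xi (K x K).
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix B, NumericVector pi0, NumericMatrix A) {
  int n = B.nrow(), K = B.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K), xi(K, K);
  NumericVector cvec(n);
  double ll = 0.0, c = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); c += alpha(0, k); }
  if (c <= 0) c = DBL_MIN;
  cvec[0] = c;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;
  ll += std::log(c);
  for (int t = 1; t < n; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = s * B(t, k);
      c += alpha(t, k);
    }
    if (c <= 0) c = DBL_MIN;
    cvec[t] = c;
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    ll += std::log(c);
  }
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / cvec[t + 1];
    }
  }
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g <= 0) g = DBL_MIN;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t + 1 < n; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / cvec[t + 1];
      }
    }
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Max-product Viterbi in log space. logB: n x K emission log-densities.
// Ties broken toward the lowest state index (strict > to replace).
// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix logB, NumericVector logpi, NumericMatrix logA) {
  int n = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  int last = 0;
  double best = delta(n - 1, 0);
  for (int k = 1; k < K; ++k) {
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); last = k; }
  }
  IntegerVector path(n);
  path[n - 1] = last + 1;
  for (int t = n - 1; t > 0; --t) {
    last = psi(t, last);
    path[t - 1] = last + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}
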