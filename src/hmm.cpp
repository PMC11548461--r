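#include <Rcpp.h>
using namespace Rcpp;

// Numerical core of the hidden Markov behaviour model.
// Observation t carries a step length (m / fix interval), a turning angle
// (rad, NA when undefined) and optionally covariate values driving the
// transition matrix. Segments are independent; each restarts at pi0.

static const double LOG_2PI = 1.837877066409345483560659;
static const double ZERO_STEP = 1e-6; // metres; "step exactly zero"

// log I0(kappa), stable for large kappa via the exponentially scaled Bessel
static inline double log_bessel_i0(double kappa) {
  return std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
}

// Zero-inflated positive step law.
// family 1: normal truncated to (0, Inf), renormalised, with (mu, sigma)
//           the parameters of the untruncated law.
// family 2: gamma with mean mu and standard deviation sigma.
static inline double step_logdens(double x, double mu, double sigma,
                                  double zeta, int family) {
  if (x < ZERO_STEP) {
    return (zeta > 0.0) ? std::log(zeta) : R_NegInf;
  }
  double lp;
  if (family == 1) {
    // log phi((x-mu)/sigma)/sigma - log P(X > 0)
    lp = R::dnorm(x, mu, sigma, 1) - R::pnorm(0.0, mu, sigma, 0, 1);
  } else {
    double shape = (mu / sigma) * (mu / sigma);
    double scale = sigma * sigma / mu;
    lp = R::dgamma(x, shape, scale, 1);
  }
  return std::log1p(-zeta) + lp;
}

static inline double angle_logdens(double theta, double mu_angle,
                                   double kappa) {
  return kappa * std::cos(theta - mu_angle) - LOG_2PI - log_bessel_i0(kappa);
}

// Row-wise multinomial logit transition matrix at covariate row z (length p).
// beta has 1+p rows and N*(N-1) columns ordered (i,j) row-major over the
// off-diagonal entries: (1,2),(1,3),...,(2,1),(2,3),...
static void gamma_at(const NumericMatrix& beta, const double* z, int p,
                     int N, std::vector<double>& G) {
  int col = 0;
  for (int i = 0; i < N; ++i) {
    double denom = 1.0;
    std::vector<double> e(N, 0.0);
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double eta = beta(0, col);
      for (int k = 0; k < p; ++k) eta += beta(1 + k, col) * z[k];
      e[j] = std::exp(eta);
      denom += e[j];
      ++col;
    }
    for (int j = 0; j < N; ++j)
      G[i * N + j] = (j == i) ? 1.0 / denom : e[j] / denom;
  }
}

// Per-observation log emission densities, T x N. Missing angles contribute 0.
// Per-state constants (zero-inflation masses, truncation normaliser, gamma
// shape/scale, Bessel normaliser) are hoisted out of the observation loop.
// [[Rcpp::export(name = ".cpp_emission_logdens")]]
NumericMatrix cpp_emission_logdens(NumericVector step, NumericVector angle,
                                   NumericVector mu, NumericVector sigma,
                                   NumericVector zeta, NumericVector mu_angle,
                                   NumericVector kappa, int family) {
  int T = step.size(), N = mu.size();
  NumericMatrix la(T, N);
  std::vector<double> lzero(N), lpos(N), lang(N), c1(N), c2(N), c3(N);
  for (int i = 0; i < N; ++i) {
    lzero[i] = (zeta[i] > 0.0) ? std::log(zeta[i]) : R_NegInf;
    lpos[i] = std::log1p(-zeta[i]);
    lang[i] = LOG_2PI + log_bessel_i0(kappa[i]);
    if (family == 1) {
      // log N(x; mu, sigma) truncated to (0, Inf):
      //   -log sigma - log(2pi)/2 - ((x-mu)/sigma)^2/2 - log P(X > 0)
      c1[i] = -std::log(sigma[i]) - 0.5 * LOG_2PI -
        R::pnorm(0.0, mu[i], sigma[i], 0, 1);
      c2[i] = 0.0; // unused
    } else {
      double shape = (mu[i] / sigma[i]) * (mu[i] / sigma[i]);
      double scale = sigma[i] * sigma[i] / mu[i];
      c1[i] = -R::lgammafn(shape) - shape * std::log(scale);
      c2[i] = shape;
      c3[i] = scale;
    }
  }
  for (int t = 0; t < T; ++t) {
    double x = step[t];
    bool hasang = !NumericVector::is_na(angle[t]);
    for (int i = 0; i < N; ++i) {
      double l;
      if (x < ZERO_STEP) {
        l = lzero[i];
      } else if (family == 1) {
        double z = (x - mu[i]) / sigma[i];
        l = lpos[i] + c1[i] - 0.5 * z * z;
      } else {
        l = lpos[i] + c1[i] + (c2[i] - 1.0) * std::log(x) - x / c3[i];
      }
      if (hasang)
        l += kappa[i] * std::cos(angle[t] - mu_angle[i]) - lang[i];
      la(t, i) = l;
    }
  }
  return la;
}

// Forward-algorithm negative log-likelihood, scaled to avoid underflow.
// seg: integer segment id per observation; a change of value starts a new
// segment (initial distribution pi0). covar: T x p matrix (p may be 0).
// [[Rcpp::export(name = ".cpp_forward_nll")]]
double cpp_forward_nll(NumericVector step, NumericVector angle,
                       IntegerVector seg, NumericMatrix covar,
                       NumericVector mu, NumericVector sigma,
                       NumericVector zeta, NumericVector mu_angle,
                       NumericVector kappa, NumericMatrix beta,
                       NumericVector pi0, int family) {
  int T = step.size(), N = mu.size(), p = covar.ncol();
  NumericMatrix la = cpp_emission_logdens(step, angle, mu, sigma, zeta,
                                          mu_angle, kappa, family);
  std::vector<double> alpha(N), tmp(N), G(N * N), z(p > 0 ? p : 1);
  bool const_gamma = true;
  for (int k = 1; k < beta.nrow(); ++k)
    for (int c = 0; c < beta.ncol(); ++c)
      if (beta(k, c) != 0.0) const_gamma = false;
  if (const_gamma) {
    for (int k = 0; k < p; ++k) z[k] = 0.0;
    gamma_at(beta, z.data(), p, N, G);
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    // shift emission row to linear space
    double mx = R_NegInf;
    for (int i = 0; i < N; ++i) if (la(t, i) > mx) mx = la(t, i);
    if (!R_finite(mx)) return R_PosInf; // impossible observation
    bool newseg = (t == 0) || (seg[t] != seg[t - 1]);
    if (!const_gamma && !newseg) {
      for (int k = 0; k < p; ++k) z[k] = covar(t, k);
      gamma_at(beta, z.data(), p, N, G);
    }
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      double pred;
      if (newseg) {
        pred = pi0[i];
      } else {
        pred = 0.0;
        for (int j = 0; j < N; ++j) pred += alpha[j] * G[j * N + i];
      }
      tmp[i] = pred * std::exp(la(t, i) - mx);
      s += tmp[i];
    }
    if (!(s > 0.0) || !R_finite(s)) return R_PosInf;
    for (int i = 0; i < N; ++i) alpha[i] = tmp[i] / s;
    ll += std::log(s) + mx;
  }
  return -ll;
}

// Viterbi decoding in log space; ties resolved toward the lower state index.
// [[Rcpp::export(name = ".cpp_viterbi")]]
IntegerVector cpp_viterbi(NumericVector step, NumericVector angle,
                          IntegerVector seg, NumericMatrix covar,
                          NumericVector mu, NumericVector sigma,
                          NumericVector zeta, NumericVector mu_angle,
                          NumericVector kappa, NumericMatrix beta,
                          NumericVector pi0, int family) {
  int T = step.size(), N = mu.size(), p = covar.ncol();
  NumericMatrix la = cpp_emission_logdens(step, angle, mu, sigma, zeta,
                                          mu_angle, kappa, family);
  std::vector<double> lpi(N), G(N * N), z(p > 0 ? p : 1), lG(N * N);
  for (int i = 0; i < N; ++i)
    lpi[i] = (pi0[i] > 0) ? std::log(pi0[i]) : R_NegInf;
  bool const_gamma = true;
  for (int k = 1; k < beta.nrow(); ++k)
    for (int c = 0; c < beta.ncol(); ++c)
      if (beta(k, c) != 0.0) const_gamma = false;
  if (const_gamma) {
    for (int k = 0; k < p; ++k) z[k] = 0.0;
    gamma_at(beta, z.data(), p, N, G);
    for (int i = 0; i < N * N; ++i)
      lG[i] = (G[i] > 0) ? std::log(G[i]) : R_NegInf;
  }
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);
  IntegerVector path(T);
  int seg_start = 0;
  auto backtrack = [&](int s0, int s1) {
    // argmax at the last obs of the segment, first (lowest) index on ties
    int best = 0;
    for (int i = 1; i < N; ++i)
      if (delta(s1, i) > delta(s1, best)) best = i;
    path[s1] = best + 1;
    for (int t = s1; t > s0; --t) {
      best = psi(t, best);
      path[t - 1] = best + 1;
    }
  };
  for (int t = 0; t < T; ++t) {
    bool newseg = (t == 0) || (seg[t] != seg[t - 1]);
    if (newseg && t > 0) {
      backtrack(seg_start, t - 1);
      seg_start = t;
    }
    if (newseg) {
      for (int i = 0; i < N; ++i) delta(t, i) = lpi[i] + la(t, i);
    } else {
      if (!const_gamma) {
        for (int k = 0; k < p; ++k) z[k] = covar(t, k);
        gamma_at(beta, z.data(), p, N, G);
        for (int i = 0; i < N * N; ++i)
          lG[i] = (G[i] > 0) ? std::log(G[i]) : R_NegInf;
      }
      for (int i = 0; i < N; ++i) {
        int argb = 0;
        double b = delta(t - 1, 0) + lG[0 * N + i];
        for (int j = 1; j < N; ++j) {
          double v = delta(t - 1, j) + lG[j * N + i];
          if (v > b) { b = v; argb = j; }
        }
        delta(t, i) = b + la(t, i);
        psi(t, i) = argb;
      }
    }
  }
  if (T > 0) backtrack(seg_start, T - 1);
  return path;
}

// Transition matrix at one covariate row (exported for the R surface).
// [[Rcpp::export(name = ".cpp_gamma_at")]]
NumericMatrix cpp_gamma_at(NumericMatrix beta, NumericVector z, int n_states) {
  int p = z.size();
  std::vector<double> G(n_states * n_states);
  gamma_at(beta, REAL(z), p, n_states, G);
  NumericMatrix out(n_states, n_states);
  for (int i = 0; i < n_states; ++i)
    for (int j = 0; j < n_states; ++j) out(i, j) = G[i * n_states + j];
  return out;
}
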