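// Core numerics: Genz-type randomized-QMC multivariate normal CDF and the
// exact (closed-form) joint-model log-likelihood accumulated over subjects.
//
// Each subject's marginal likelihood is
//   L_i = N(Y_i; x_i alpha + B_i beta, sigma_eps^2 I + B_i Sigma B_i^T)
//         * Phi_K(D mu_post + c; 0, I_K + D Sigma_post D^T),
// where (mu_post, Sigma_post) are the Gaussian-conjugacy posterior moments of
// the random spline coefficients given Y_i alone, and row k of D / entry c_k
// encode the signed probit linear predictor of interval k (sign -1 only for
// the event interval of a subject with delta = 1).

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// standard normal CDF via erfc: accurate over the whole real line
static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// Wichura's AS241 (PPND16) inverse normal CDF, ~1e-16 relative accuracy.
static double phi_inv(double p) {
  if (p <= 0.0) return -1e30;
  if (p >= 1.0) return 1e30;
  double q = p - 0.5, r, val;
  if (std::fabs(q) <= 0.425) {
    r = 0.180625 - q * q;
    return q *
      (((((((2509.0809287301226727 * r + 33430.575583588128105) * r +
        67265.770927008700853) * r + 45921.953931549871457) * r +
        13731.693765509461125) * r + 1971.5909503065514427) * r +
        133.14166789178437745) * r + 3.387132872796366608) /
      (((((((5226.495278852545703 * r + 28729.085735721942674) * r +
        39307.89580009271061) * r + 21213.794301586595867) * r +
        5394.1960214247511077) * r + 687.1870074920579083) * r +
        42.313330701600911252) * r + 1.0);
  }
  r = (q < 0.0) ? p : 1.0 - p;
  r = std::sqrt(-std::log(r));
  if (r <= 5.0) {
    r -= 1.6;
    val = (((((((7.7454501427834140764e-4 * r + 0.0227238449892691845833) * r +
      0.24178072517745061177) * r + 1.27045825245236838258) * r +
      3.64784832476320460504) * r + 5.7694972214606914055) * r +
      4.6303378461565452959) * r + 1.42343711074968357734) /
      (((((((1.05075007164441684324e-9 * r + 5.475938084995344946e-4) * r +
      0.0151986665636164571966) * r + 0.14810397642748007459) * r +
      0.68976733498510000455) * r + 1.6763848301838038494) * r +
      2.05319162663775882187) * r + 1.0);
  } else {
    r -= 5.0;
    val = (((((((2.01033439929228813265e-7 * r + 2.71155556874348757815e-5) * r +
      0.0012426609473880784386) * r + 0.026532189526576123093) * r +
      0.29656057182850489123) * r + 1.7848265399172913358) * r +
      5.4637849111641143699) * r + 6.6579046435011037772) /
      (((((((2.04426310338993978564e-15 * r + 1.4215117583164458887e-7) * r +
      1.8463183175100546818e-5) * r + 7.868691311456132591e-4) * r +
      0.0148753612908506148525) * r + 0.13692988092273580531) * r +
      0.59983220655588793769) * r + 1.0);
  }
  return (q < 0.0) ? -val : val;
}

// 10-point Gauss-Legendre rule on [-1, 1] (half nodes; symmetric)
static const double GL10_X[5] = {0.1488743389816312, 0.4333953941292472,
                                 0.6794095682990244, 0.8650633666889845,
                                 0.9739065285171717};
static const double GL10_W[5] = {0.2955242247147529, 0.2692667193099963,
                                 0.2190863625159820, 0.1494513491505806,
                                 0.0666713443086881};

// P(Z1 <= a, Z2 <= b), corr rho: Phi(a)Phi(b) plus the Sheppard/Drezner
// integral over [0, asin(rho)], composite Gauss-Legendre (~1e-14 accurate)
static double bvn_cdf(double a, double b, double rho) {
  if (rho > 1.0 - 1e-12) return phi_cdf(std::min(a, b));
  if (rho < -1.0 + 1e-12)
    return std::max(phi_cdf(a) + phi_cdf(b) - 1.0, 0.0);
  double alpha = std::asin(rho);
  double sum = 0.0;
  const int nseg = 6;
  for (int s = 0; s < nseg; ++s) {
    double lo = alpha * s / nseg, hi = alpha * (s + 1) / nseg;
    double c = 0.5 * (hi + lo), h = 0.5 * (hi - lo);
    for (int i = 0; i < 5; ++i) {
      for (int pm = 0; pm < 2; ++pm) {
        double th = c + (pm ? h : -h) * GL10_X[i];
        double sth = std::sin(th), cth2 = 1.0 - sth * sth;
        sum += GL10_W[i] * h *
          std::exp(-(a * a + b * b - 2.0 * a * b * sth) / (2.0 * cth2));
      }
    }
  }
  return std::min(std::max(phi_cdf(a) * phi_cdf(b) + sum / (2.0 * M_PI), 0.0),
                  1.0);
}

static const double RPRIMES[19] = {2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37,
                                   41, 43, 47, 53, 59, 61, 67};

// splitmix64-style deterministic uniform stream for the Cranley-Patterson
// shifts; keeps the CDF reproducible for a given seed.
struct ShiftRng {
  uint64_t s;
  explicit ShiftRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
};

// P(Z <= upper), Z ~ N(0, Sigma). Richtmyer lattice with nshift random
// shifts and antithetic pairing; err gets ~3 standard errors.
static double genz_cdf(const vec& upper, const mat& Sigma,
                       int npts, int nshift, uint64_t seed, double* err,
                       bool* fail = nullptr) {
  const int K = upper.n_elem;
  if (err) *err = 0.0;
  if (fail) *fail = false;
  if (K == 0) return 1.0;
  if (Sigma.diag().min() <= 0.0 || !upper.is_finite()) {
    if (fail) { *fail = true; return 0.0; }
    Rcpp::stop("mvn_cdf: covariance matrix is not positive semidefinite");
  }
  if (K == 1) return phi_cdf(upper(0) / std::sqrt(Sigma(0, 0)));
  if (K == 2) {
    double s0 = std::sqrt(Sigma(0, 0)), s1 = std::sqrt(Sigma(1, 1));
    double r01 = Sigma(0, 1) / (s0 * s1);
    r01 = std::min(std::max(r01, -1.0), 1.0);
    return bvn_cdf(upper(0) / s0, upper(1) / s1, r01);
  }

  // integrate the most restrictive variable first
  uvec ord = sort_index(upper / sqrt(Sigma.diag()));
  vec b = upper(ord);
  mat S = Sigma(ord, ord);
  S = 0.5 * (S + S.t()); // exact symmetry for arma's strict chol
  mat L;
  if (!chol(L, S, "lower")) {
    mat S2 = S + (1e-10 * trace(S) / K) * eye(K, K);
    if (!chol(L, S2, "lower")) {
      if (fail) { *fail = true; return 0.0; }
      Rcpp::stop("mvn_cdf: covariance matrix is not positive semidefinite");
    }
  }

  const double e1 = phi_cdf(b(0) / L(0, 0));
  if (e1 <= 0.0) return 0.0;

  std::vector<double> q(K - 1);
  for (int i = 0; i < K - 1; ++i) q[i] = std::sqrt(RPRIMES[i % 19] + i / 19);

  ShiftRng rng(seed);
  std::vector<double> shift(K - 1), y(K - 1), w(K - 1);
  double tot = 0.0, totsq = 0.0;

  for (int sh = 0; sh < nshift; ++sh) {
    for (int i = 0; i < K - 1; ++i) shift[i] = rng.unif();
    double acc = 0.0;
    for (int j = 1; j <= npts; ++j) {
      for (int i = 0; i < K - 1; ++i) {
        // fractional part; avoids fmod (glibc >= 2.38 symbol on some hosts)
        double t = j * q[i] + shift[i];
        w[i] = t - std::floor(t);
      }
      for (int anti = 0; anti < 2; ++anti) {
        double f = e1, eprev = e1;
        for (int i = 1; i < K; ++i) {
          double wi = anti ? (1.0 - w[i - 1]) : w[i - 1];
          double u = eprev * wi;
          if (u < 1e-300) { f = 0.0; break; }
          y[i - 1] = phi_inv(u);
          double m = 0.0;
          for (int l = 0; l < i; ++l) m += L(i, l) * y[l];
          eprev = phi_cdf((b(i) - m) / L(i, i));
          f *= eprev;
          if (f <= 0.0) break;
        }
        acc += f;
      }
    }
    acc /= (2.0 * npts);
    tot += acc;
    totsq += acc * acc;
  }
  double mean = tot / nshift;
  if (err && nshift > 1) {
    double var = (totsq - nshift * mean * mean) / (nshift - 1.0);
    *err = 3.0 * std::sqrt(std::max(var, 0.0) / nshift);
  }
  return std::min(std::max(mean, 0.0), 1.0);
}

// [[Rcpp::export]]
Rcpp::List cpp_mvn_cdf(const arma::vec& upper, const arma::mat& Sigma,
                       int npts, int nshift, double seed) {
  double err = 0.0;
  double val = genz_cdf(upper, Sigma, npts, nshift, (uint64_t)seed, &err);
  return Rcpp::List::create(Rcpp::Named("value") = val,
                            Rcpp::Named("error") = err);
}

// ---------------------------------------------------------------------------
// Batch log-likelihood

struct Layout {
  int p, Mb, qt, q, gv, M, kind; // kind: 0 = pspline, 1 = random int+slope
};

struct Params {
  vec alpha, beta, at, gamma;
  double se, s0, s1, s2, rho;
};

static Params unpack(const vec& theta, const Layout& L) {
  Params P;
  int i = 0;
  P.alpha = (L.p > 0) ? theta.subvec(i, i + L.p - 1) : vec();
  i += L.p;
  P.beta = theta.subvec(i, i + L.Mb - 1); i += L.Mb;
  P.at = (L.qt > 0) ? theta.subvec(i, i + L.qt - 1) : vec();
  i += L.qt;
  int ng = L.gv ? L.M * L.q : L.q;
  P.gamma = (ng > 0) ? theta.subvec(i, i + ng - 1) : vec();
  i += ng;
  P.se = std::exp(theta(i++));
  P.s0 = std::exp(theta(i++));
  P.s1 = std::exp(theta(i++));
  P.s2 = (L.kind == 0) ? std::exp(theta(i++)) : 0.0;
  P.rho = std::tanh(theta(i++));
  return P;
}

static mat build_sigma_cpp(const Params& P, int Mb) {
  mat S(Mb, Mb, fill::zeros);
  S(0, 0) = P.s0 * P.s0;
  S(1, 1) = P.s1 * P.s1;
  S(0, 1) = S(1, 0) = P.rho * P.s0 * P.s1;
  for (int l = 2; l < Mb; ++l) S(l, l) = P.s2 * P.s2;
  return S;
}

// Per-subject (longitudinal, survival) log-likelihood contributions.
// prep is a flat preprocessed representation of the dataset (see prep_data()).
// [[Rcpp::export]]
arma::mat cpp_subject_logliks(const arma::vec& theta, const Rcpp::List& prep,
                              int npts, int nshift, double seed,
                              bool with_surv = true) {
  Layout L;
  L.p = prep["p"]; L.Mb = prep["Mb"]; L.qt = prep["qt"]; L.q = prep["q"];
  L.gv = prep["gv"]; L.M = prep["M"]; L.kind = prep["kind"];
  const int nsub = prep["nsub"];
  ivec ni = prep["ni"], ni_off = prep["ni_off"];
  ivec sstar = prep["sstar"], delta = prep["delta"], xs_off = prep["xs_off"];
  vec y_all = prep["y_all"];
  mat B_all = prep["B_all"], Xs_all = prep["Xs_all"];
  mat X_all;
  if (L.p > 0) X_all = Rcpp::as<mat>(prep["X_all"]);
  cube A = prep["A"]; // q x Mb x M association maps

  Params P = unpack(theta, L);
  mat Sigma = build_sigma_cpp(P, L.Mb);

  mat out(nsub, 2, fill::zeros);
  for (int i = 0; i < nsub; ++i) {
    const int n = ni(i);
    vec mu_post(L.Mb, fill::zeros);
    mat Sig_post = Sigma;
    double lml = 0.0;
    if (n > 0) {
      mat B = B_all.rows(ni_off(i), ni_off(i) + n - 1);
      vec r = y_all.subvec(ni_off(i), ni_off(i) + n - 1) - B * P.beta;
      if (L.p > 0) r -= X_all.rows(ni_off(i), ni_off(i) + n - 1) * P.alpha;
      mat BS = B * Sigma;
      mat G = BS * B.t();
      G.diag() += P.se * P.se + 1e-12;
      mat Lg;
      if (!chol(Lg, G, "lower")) {
        out(i, 0) = out(i, 1) = -1e8; // degenerate region: flag, keep going
        continue;
      }
      vec z = solve(trimatl(Lg), r);
      lml = -0.5 * n * LOG2PI - accu(log(Lg.diag())) - 0.5 * dot(z, z);
      mat W = solve(trimatl(Lg), BS); // n x Mb
      mu_post = W.t() * z;
      Sig_post = Sigma - W.t() * W;
    }
    out(i, 0) = lml;
    if (!with_surv) continue;

    const int K = sstar(i);
    mat D(K, L.Mb);
    vec cc(K);
    for (int k = 0; k < K; ++k) {
      const mat& Ak = A.slice(k);
      vec gk = L.gv ? P.gamma.subvec((size_t)k * L.q, (size_t)k * L.q + L.q - 1)
                    : P.gamma;
      rowvec drow = (L.q > 0) ? rowvec(gk.t() * Ak) : rowvec(L.Mb, fill::zeros);
      double ck = dot(drow, P.beta);
      if (L.qt > 0) ck += dot(Xs_all.row(xs_off(i) + k), P.at);
      double sgn = (k == K - 1 && delta(i) == 1) ? -1.0 : 1.0;
      D.row(k) = sgn * drow;
      cc(k) = sgn * ck;
    }
    vec upper = D * mu_post + cc;
    mat C = D * Sig_post * D.t();
    C = 0.5 * (C + C.t());
    C.diag() += 1.0;
    if (upper.has_nonfinite() || C.has_nonfinite()) {
      out(i, 1) = -1e8;
      continue;
    }
    bool fail = false;
    double pval = genz_cdf(upper, C, npts, nshift, (uint64_t)seed, nullptr,
                           &fail);
    out(i, 1) = fail ? -1e8 : std::log(std::max(pval, 1e-300));
  }
  return out;
}

// Penalized negative log-likelihood: -sum(parts) + lambda * sum(beta[3:]^2).
// include_long / include_surv allow the longitudinal-only (stage-1) fit.
// [[Rcpp::export]]
double cpp_pen_negloglik(const arma::vec& theta, const Rcpp::List& prep,
                         double lambda, int npts, int nshift, double seed,
                         bool include_long, bool include_surv) {
  // smooth soft box on the unconstrained scale: the likelihood is evaluated
  // at theta clamped to [-30, 30] (keeps exp() transforms finite) plus a
  // quadratic barrier, so line searches stay on a smooth decreasing surface
  vec th = theta;
  double barrier = 0.0;
  for (uword i = 0; i < th.n_elem; ++i) {
    if (!std::isfinite(th(i))) return 1e10;
    if (th(i) > 30.0) { barrier += (th(i) - 30.0) * (th(i) - 30.0); th(i) = 30.0; }
    else if (th(i) < -30.0) { barrier += (th(i) + 30.0) * (th(i) + 30.0); th(i) = -30.0; }
  }
  barrier *= 1e3;
  mat parts = cpp_subject_logliks(th, prep, npts, nshift, seed,
                                  include_surv);
  double ll = 0.0;
  if (include_long) ll += accu(parts.col(0));
  if (include_surv) ll += accu(parts.col(1));
  Layout L;
  L.p = prep["p"]; L.Mb = prep["Mb"]; L.qt = prep["qt"]; L.q = prep["q"];
  L.gv = prep["gv"]; L.M = prep["M"]; L.kind = prep["kind"];
  double pen = 0.0;
  if (L.kind == 0 && lambda > 0.0) {
    Params P = unpack(th, L);
    for (int l = 2; l < L.Mb; ++l) pen += P.beta(l) * P.beta(l);
    pen *= lambda;
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll + pen + barrier;
}
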