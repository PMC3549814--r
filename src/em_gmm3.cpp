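#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact constrained M-step for the mixing weights: maximize sum_k Nk log wk
// over {wk >= w_floor, sum wk = 1}. KKT: components whose proportional share
// falls below the floor sit at the floor; the rest share the remainder
// proportionally to Nk.
static void floor_weights(double *w, const double *nk, double n,
                          double w_floor) {
  bool at_floor[3] = {false, false, false};
  for (int pass = 0; pass < 3; ++pass) {
    double free_mass = 1.0, free_nk = 0.0;
    for (int k = 0; k < 3; ++k) {
      if (at_floor[k]) free_mass -= w_floor;
      else free_nk += nk[k];
    }
    bool changed = false;
    for (int k = 0; k < 3; ++k) {
      if (at_floor[k]) { w[k] = w_floor; continue; }
      w[k] = free_nk > 0.0 ? free_mass * nk[k] / free_nk
                           : free_mass / 3.0;
      if (w[k] < w_floor) { at_floor[k] = true; changed = true; }
    }
    if (!changed) break;
  }
}

// Warm-started EM for a univariate 3-component Gaussian mixture.
// Components are fate-indexed (SF, CF, NF); warm starts keep that
// association across belief-propagation iterations. Standard deviations are
// floored at sigma_floor and mixing weights at w_floor (keeping all three
// fate hypotheses alive across belief-propagation iterations); both floors
// make the M-step a constrained maximizer, so the log-likelihood trace is
// non-decreasing as long as the initial parameters also respect the floors
// (enforced here).
// [[Rcpp::export]]
List em_gmm3_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                 NumericVector sigma0, int max_iter, double tol,
                 double sigma_floor, double w_floor = 0.0,
                 bool fix_weights = false) {
  const int n = x.size();
  const int K = 3;
  if (w0.size() != K || mu0.size() != K || sigma0.size() != K)
    stop("initial parameters must have length 3");
  if (n < 3) stop("need at least 3 particles");
  if (sigma_floor <= 0.0) stop("sigma_floor must be positive");
  if (w_floor < 0.0 || w_floor >= 1.0 / 3.0)
    stop("w_floor must be in [0, 1/3)");

  std::vector<double> w(K), mu(K), sg(K);
  double wsum = 0.0;
  for (int k = 0; k < K; ++k) {
    w[k] = w0[k] > 0.0 ? w0[k] : 0.0;
    wsum += w[k];
    mu[k] = mu0[k];
    sg[k] = sigma0[k] > sigma_floor ? sigma0[k] : sigma_floor;
  }
  if (wsum <= 0.0) stop("mixing weights must not all be zero");
  for (int k = 0; k < K; ++k) w[k] /= wsum;
  if (w_floor > 0.0) {
    double share[3] = {w[0], w[1], w[2]};
    floor_weights(w.data(), share, 1.0, w_floor);
  }

  const double LOG2PI = std::log(2.0 * M_PI);
  std::vector<double> r(static_cast<size_t>(n) * K);
  std::vector<double> ll_trace;
  ll_trace.reserve(max_iter);
  double ll_prev = R_NegInf;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    // E step with the log-likelihood of the current parameters
    double cons[3], inv[3];
    for (int k = 0; k < K; ++k) {
      if (w[k] <= 0.0) { cons[k] = R_NegInf; inv[k] = 0.0; continue; }
      cons[k] = std::log(w[k]) - std::log(sg[k]) - 0.5 * LOG2PI;
      inv[k] = 1.0 / sg[k];
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double lk[3];
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        if (w[k] <= 0.0) { lk[k] = R_NegInf; continue; }
        double z = (x[i] - mu[k]) * inv[k];
        lk[k] = cons[k] - 0.5 * z * z;
        if (lk[k] > m) m = lk[k];
      }
      // terms more than ~34 log-units below the max are < 2e-15 of it and
      // cannot affect the sum at double precision
      double t[3], s = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = lk[k] - m;
        t[k] = (d < -34.0) ? 0.0 : (d == 0.0 ? 1.0 : std::exp(d));
        s += t[k];
      }
      ll += m + std::log(s);
      for (int k = 0; k < K; ++k)
        r[static_cast<size_t>(i) * K + k] = t[k] / s;
    }
    ll_trace.push_back(ll);
    if (it > 0 && std::fabs(ll - ll_prev) < tol) break;
    ll_prev = ll;

    // M step (sigma constrained below by sigma_floor, weights by w_floor)
    double nk[3];
    for (int k = 0; k < K; ++k) {
      double s0 = 0.0, s1 = 0.0;
      for (int i = 0; i < n; ++i) {
        double rik = r[static_cast<size_t>(i) * K + k];
        s0 += rik;
        s1 += rik * x[i];
      }
      nk[k] = s0;
      if (s0 < 1e-12) continue; // dead component: keep location and spread
      double mk = s1 / s0;
      double s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mk;
        s2 += r[static_cast<size_t>(i) * K + k] * d * d;
      }
      double sk = std::sqrt(s2 / s0);
      mu[k] = mk >= 0.0 ? mk : 0.0; // expression levels are nonnegative
      sg[k] = sk > sigma_floor ? sk : sigma_floor;
    }
    if (!fix_weights) floor_weights(w.data(), nk, n, w_floor);
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sigma"] = NumericVector(sg.begin(), sg.end()),
                      _["loglik"] = NumericVector(ll_trace.begin(),
                                                  ll_trace.end()),
                      _["iterations"] = static_cast<int>(ll_trace.size()));
}
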