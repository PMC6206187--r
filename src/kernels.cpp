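// Hot numerical kernels for the Metropolis-within-Gibbs sampler. Both are
// plain single-pass loops over the observation vector; everything else in
// the sampler stays in R.
#include <Rcpp.h>
using namespace Rcpp;

static inline double softplus(double x) {
  // log(1 + exp(x)) without overflow
  return x > 0 ? x + log1p(exp(-x)) : log1p(exp(x));
}

// Sum of Bernoulli log likelihoods: sum_i y_i * eta_i - log(1 + e^{eta_i}).
// [[Rcpp::export]]
double cpp_bern_ll(NumericVector y, NumericVector eta) {
  const int n = y.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += y[i] * eta[i] - softplus(eta[i]);
  return s;
}

// Bernoulli log likelihoods aggregated by site-season cell (1-based cell
// index); returns a vector of length ncell with zeros for empty cells.
// [[Rcpp::export]]
NumericVector cpp_cell_ll(NumericVector y, NumericVector eta,
                          IntegerVector cell, int ncell) {
  const int n = y.size();
  NumericVector out(ncell);
  for (int i = 0; i < n; ++i)
    out[cell[i] - 1] += y[i] * eta[i] - softplus(eta[i]);
  return out;
}

static inline double lse2(double a, double b) {
  // log(e^a + e^b), exact at -Inf
  double m = a > b ? a : b;
  if (m == R_NegInf) return R_NegInf;
  return m + log(exp(a - m) + exp(b - m));
}

// Forward-filter backward-sample the two-state occupancy chain of every
// site. ll1/ll0 are per-cell observation log likelihoods given z = 1 / 0
// (ll0 is -Inf where a detection occurred, so sampled z never contradicts
// a detection). Uses R's RNG, so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_ffbs(NumericMatrix ll1, NumericMatrix ll0,
                       NumericVector psi, NumericVector phi,
                       NumericVector gamma) {
  const int S = ll1.nrow(), T = ll1.ncol();
  NumericMatrix LA0(S, T), LA1(S, T);
  IntegerMatrix z(S, T);
  for (int i = 0; i < S; ++i) {
    LA0(i, 0) = log1p(-psi[i]) + ll0(i, 0);
    LA1(i, 0) = log(psi[i]) + ll1(i, 0);
  }
  for (int t = 0; t < T - 1; ++t) {
    const double lf = log(phi[t]), lnf = log1p(-phi[t]);
    const double lg = log(gamma[t]), lng = log1p(-gamma[t]);
    for (int i = 0; i < S; ++i) {
      LA0(i, t + 1) = ll0(i, t + 1) + lse2(LA0(i, t) + lng, LA1(i, t) + lnf);
      LA1(i, t + 1) = ll1(i, t + 1) + lse2(LA0(i, t) + lg, LA1(i, t) + lf);
    }
  }
  for (int i = 0; i < S; ++i) {
    double d = LA1(i, T - 1) - LA0(i, T - 1);
    double p1 = ISNAN(d) ? 0.5 : 1.0 / (1.0 + exp(-d));
    z(i, T - 1) = unif_rand() < p1 ? 1 : 0;
  }
  for (int t = T - 2; t >= 0; --t) {
    const double lf = log(phi[t]), lnf = log1p(-phi[t]);
    const double lg = log(gamma[t]), lng = log1p(-gamma[t]);
    for (int i = 0; i < S; ++i) {
      const bool on = z(i, t + 1) == 1;
      double d = (LA1(i, t) + (on ? lf : lnf)) - (LA0(i, t) + (on ? lg : lng));
      double p1 = ISNAN(d) ? 0.5 : 1.0 / (1.0 + exp(-d));
      z(i, t) = unif_rand() < p1 ? 1 : 0;
    }
  }
  return z;
}
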