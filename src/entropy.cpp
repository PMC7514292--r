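#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in transfer entropy TE_{Y->X} in bits from aligned symbol series,
// single-lag embedding: TE = sum p(x1,x0,y0) log2[ p(x1|x0,y0) / p(x1|x0) ],
// counts over t = 1..T-1. Symbols must be in [0, n_bins).
// [[Rcpp::export(name = ".te_symbols_cpp")]]
double te_symbols_cpp(IntegerVector x, IntegerVector y, int n_bins) {
  const int T = x.size();
  if (y.size() != T) stop("length mismatch");
  const int nb = n_bins, nb2 = nb * nb;
  const int n = T - 1;
  std::vector<double> c3(static_cast<size_t>(nb2) * nb, 0.0);
  std::vector<double> c_x1x0(nb2, 0.0), c_x0y0(nb2, 0.0), c_x0(nb, 0.0);
  for (int t = 0; t < n; ++t) {
    const int x1 = x[t + 1], x0 = x[t], y0 = y[t];
    if (x1 < 0 || x1 >= nb || x0 < 0 || x0 >= nb || y0 < 0 || y0 >= nb)
      stop("symbol out of range");
    c3[x1 + nb * x0 + nb2 * y0] += 1.0;
    c_x1x0[x1 + nb * x0] += 1.0;
    c_x0y0[x0 + nb * y0] += 1.0;
    c_x0[x0] += 1.0;
  }
  double te = 0.0;
  for (int y0 = 0; y0 < nb; ++y0)
    for (int x0 = 0; x0 < nb; ++x0)
      for (int x1 = 0; x1 < nb; ++x1) {
        const double n3 = c3[x1 + nb * x0 + nb2 * y0];
        if (n3 > 0.0) {
          const double p3 = n3 / n;
          const double p_cond_joint = n3 / c_x0y0[x0 + nb * y0];
          const double p_cond_own = c_x1x0[x1 + nb * x0] / c_x0[x0];
          te += p3 * std::log2(p_cond_joint / p_cond_own);
        }
      }
  // plug-in TE is a conditional mutual information, >= 0 up to rounding
  if (te < 0.0) te = 0.0;
  return te;
}

// Conditional entropy H(x_{t+1} | x_t) in bits:
// H = -sum p(x1,x0) log2[ p(x1,x0) / p(x0) ], counts over t = 1..T-1.
// [[Rcpp::export(name = ".ce_symbols_cpp")]]
double ce_symbols_cpp(IntegerVector x, int n_bins) {
  const int T = x.size();
  const int nb = n_bins;
  const int n = T - 1;
  std::vector<double> c2(static_cast<size_t>(nb) * nb, 0.0), c0(nb, 0.0);
  for (int t = 0; t < n; ++t) {
    const int x1 = x[t + 1], x0 = x[t];
    if (x1 < 0 || x1 >= nb || x0 < 0 || x0 >= nb) stop("symbol out of range");
    c2[x1 + nb * x0] += 1.0;
    c0[x0] += 1.0;
  }
  double h = 0.0;
  for (int x0 = 0; x0 < nb; ++x0)
    for (int x1 = 0; x1 < nb; ++x1) {
      const double n2 = c2[x1 + nb * x0];
      if (n2 > 0.0) h -= (n2 / n) * std::log2(n2 / c0[x0]);
    }
  if (h < 0.0) h = 0.0;
  return h;
}

// Mean transfer entropy over surrogate permutations of the source:
// column s of `perms` holds a 1-based permutation of 1..T applied to y.
// [[Rcpp::export(name = ".te_surrogate_mean_cpp")]]
double te_surrogate_mean_cpp(IntegerVector x, IntegerVector y,
                             IntegerMatrix perms, int n_bins) {
  const int T = x.size();
  IntegerVector yp(T);
  double acc = 0.0;
  for (int s = 0; s < perms.ncol(); ++s) {
    for (int t = 0; t < T; ++t) yp[t] = y[perms(t, s) - 1];
    acc += te_symbols_cpp(x, yp, n_bins);
  }
  return acc / perms.ncol();
}

// Lempel-Ziv (1976) exhaustive-history production count c(n).
// Each phrase is the longest substring reproducible from the extended
// history (copy source may overlap the phrase) plus one innovation symbol;
// a terminal phrase needs no innovation.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1;
  int l = 1;
  while (l < n) {
    int kmax = 0;
    for (int i = 0; i < l; ++i) {
      int k = 0;
      while (l + k < n && s[i + k] == s[l + k]) ++k;
      if (k > kmax) kmax = k;
    }
    ++c;
    l += kmax + 1;
  }
  return c;
}
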