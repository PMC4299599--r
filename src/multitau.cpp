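#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Multi-tau correlation estimator.
//
// Implements G_ij(tau) = <dF_i(t) dF_j(t+tau)> / (<F_i><F_j>) on a
// quasi-logarithmic lag grid: `m` linear lags per octave doubling of the
// sampling interval. The first 2m lags are evaluated at the native bin
// width; each subsequent octave halves the series by pairwise averaging and
// evaluates lags m+1..2m at the coarsened resolution. The zero-lag bin is
// excluded. Normalization is the symmetric (lag-dependent mean) estimator,
// which removes the finite-length bias of the naive global-mean form.

static double corr_at_lag(const std::vector<double>& x,
                          const std::vector<double>& y, size_t k) {
  const size_t n = x.size();
  if (k >= n) return NA_REAL;
  const size_t m = n - k;
  double sxy = 0.0, sx = 0.0, sy = 0.0;
  for (size_t i = 0; i < m; ++i) {
    sxy += x[i] * y[i + k];
    sx += x[i];
    sy += y[i + k];
  }
  const double mx = sx / m, my = sy / m;
  if (mx == 0.0 || my == 0.0) return 0.0;  // no signal, no fluctuation
  return (sxy / m) / (mx * my) - 1.0;
}

// [[Rcpp::export]]
List cpp_multitau(NumericVector x, NumericVector y, double dt, int m,
                  double max_lag) {
  const size_t n = (size_t)x.size();
  if ((size_t)y.size() != n) stop("channel vectors differ in length");
  std::vector<double> cx(x.begin(), x.end()), cy(y.begin(), y.end());
  std::vector<double> lags, G;

  // level 0: lags 1..2m at native resolution
  for (int k = 1; k <= 2 * m; ++k) {
    const double lag = k * dt;
    if (lag > max_lag || (size_t)k >= cx.size()) break;
    lags.push_back(lag);
    G.push_back(corr_at_lag(cx, cy, (size_t)k));
  }

  double res = dt;
  for (;;) {
    // coarsen by pairwise averaging
    const size_t nn = cx.size() / 2;
    if (nn < (size_t)(2 * m + 2)) break;
    for (size_t i = 0; i < nn; ++i) {
      cx[i] = 0.5 * (cx[2 * i] + cx[2 * i + 1]);
      cy[i] = 0.5 * (cy[2 * i] + cy[2 * i + 1]);
    }
    cx.resize(nn);
    cy.resize(nn);
    res *= 2.0;
    bool done = false;
    for (int k = m + 1; k <= 2 * m; ++k) {
      const double lag = k * res;
      if (lag > max_lag || (size_t)k >= nn) {
        done = true;
        break;
      }
      lags.push_back(lag);
      G.push_back(corr_at_lag(cx, cy, (size_t)k));
    }
    if (done) break;
  }

  return List::create(_["lags"] = wrap(lags), _["G"] = wrap(G));
}
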