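#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Partial Correlation with Information Theory: for every trio (x, y, z) the
// three first-order partial correlations are computed; the trio tolerance is
// the mean of the ratios partial/direct (terms whose direct correlation is
// numerically zero are skipped); the x-y association is eliminated if for
// some z both |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz|.
//
// Numerical guards: correlations are clamped to |r| <= 1 - 1e-12 before the
// partials so the denominators stay positive.

static inline double partial(double rxy, double rxz, double ryz) {
  return (rxy - rxz * ryz) /
         std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
}

// [[Rcpp::export(name = ".pcit_cpp")]]
LogicalMatrix pcit_cpp(NumericMatrix r) {
  const int n = r.nrow();
  if (r.ncol() != n) stop("correlation matrix must be square");
  NumericMatrix rc(n, n);
  const double lim = 1.0 - 1e-12;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = r(i, j);
      if (v > lim) v = lim;
      if (v < -lim) v = -lim;
      rc(i, j) = v;
    }
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) keep(i, j) = (i != j);

  const double tiny = 1e-12;
  for (int x = 0; x < n - 1; ++x) {
    for (int y = x + 1; y < n; ++y) {
      const double rxy = rc(x, y);
      bool elim = false;
      for (int z = 0; z < n && !elim; ++z) {
        if (z == x || z == y) continue;
        const double rxz = rc(x, z), ryz = rc(y, z);
        const double pxy = partial(rxy, rxz, ryz);
        const double pxz = partial(rxz, rxy, ryz);
        const double pyz = partial(ryz, rxy, rxz);
        double s = 0.0; int m = 0;
        if (std::fabs(rxy) >= tiny) { s += pxy / rxy; ++m; }
        if (std::fabs(rxz) >= tiny) { s += pxz / rxz; ++m; }
        if (std::fabs(ryz) >= tiny) { s += pyz / ryz; ++m; }
        if (m == 0) continue;
        const double eps = s / m;
        if (std::fabs(rxy) <= std::fabs(eps * rxz) &&
            std::fabs(rxy) <= std::fabs(eps * ryz))
          elim = true;
      }
      if (elim) { keep(x, y) = false; keep(y, x) = false; }
    }
  }
  return keep;
}
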