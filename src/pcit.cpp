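#include <Rcpp.h>
using namespace Rcpp;

// PCIT trio elimination on a correlation matrix.
//
// For every trio (x,y,z) the three first-order partial correlations are
// computed; the trio's tolerance eps is the mean of the |partial/direct|
// ratios (pairs with |direct| < 1e-12 skipped; trio skipped if all three
// are). The edge x-y is flagged non-significant by the trio when
// |rxy| <= |eps*rxz| and |rxy| <= |eps*ryz|; an edge survives iff no trio
// flags it. Returns a logical keep-matrix with a FALSE diagonal.
// [[Rcpp::export]]
LogicalMatrix pcit_keep_cpp(NumericMatrix C) {
  const int n = C.nrow();
  if (n != C.ncol()) stop("correlation matrix must be square");
  if (n < 3) stop("PCIT needs at least 3 nodes");
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) keep(i, j) = (i != j);

  const double tiny = 1e-12;
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = C(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = C(x, z), ryz = C(y, z);
        const double dxy = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
        const double dxz = (1.0 - rxy * rxy) * (1.0 - ryz * ryz);
        const double dyz = (1.0 - rxy * rxy) * (1.0 - rxz * rxz);
        if (dxy <= 0.0 || dxz <= 0.0 || dyz <= 0.0) continue; // degenerate
        const double pxy = (rxy - rxz * ryz) / std::sqrt(dxy);
        const double pxz = (rxz - rxy * ryz) / std::sqrt(dxz);
        const double pyz = (ryz - rxy * rxz) / std::sqrt(dyz);
        double eps = 0.0;
        int cnt = 0;
        if (std::fabs(rxy) >= tiny) { eps += std::fabs(pxy / rxy); ++cnt; }
        if (std::fabs(rxz) >= tiny) { eps += std::fabs(pxz / rxz); ++cnt; }
        if (std::fabs(ryz) >= tiny) { eps += std::fabs(pyz / ryz); ++cnt; }
        if (cnt == 0) continue;
        eps /= cnt;
        if (std::fabs(rxy) <= std::fabs(eps * rxz) &&
            std::fabs(rxy) <= std::fabs(eps * ryz)) {
          keep(x, y) = keep(y, x) = false;
        }
        if (std::fabs(rxz) <= std::fabs(eps * rxy) &&
            std::fabs(rxz) <= std::fabs(eps * ryz)) {
          keep(x, z) = keep(z, x) = false;
        }
        if (std::fabs(ryz) <= std::fabs(eps * rxy) &&
            std::fabs(ryz) <= std::fabs(eps * rxz)) {
          keep(y, z) = keep(z, y) = false;
        }
      }
    }
  }
  return keep;
}
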