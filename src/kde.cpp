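#include <Rcpp.h>
using namespace Rcpp;

// Evaluate a 2-D Gaussian-product KDE with diagonal bandwidth (hx, hy) at
// query points q (m x 2), sample points pts (n x 2). Returns densities that
// integrate to 1 over the plane.
// [[Rcpp::export]]
NumericVector kde_gauss_eval(NumericMatrix q, NumericMatrix pts,
                             double hx, double hy) {
  const int m = q.nrow(), n = pts.nrow();
  NumericVector out(m);
  const double norm = 1.0 / (2.0 * M_PI * hx * hy * (double)n);
  for (int i = 0; i < m; ++i) {
    const double qx = q(i, 0), qy = q(i, 1);
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dx = (qx - pts(j, 0)) / hx;
      const double dy = (qy - pts(j, 1)) / hy;
      const double e = dx * dx + dy * dy;
      if (e < 80.0) s += std::exp(-0.5 * e);
    }
    out[i] = s * norm;
  }
  return out;
}
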