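// Parallel-beam single-axis-tilt projector (Joseph's method).
//
// Geometry convention (fixed package-wide):
//   * volumes are (m, n, z) arrays: u[r, c, k], r fastest in memory;
//   * the tilt axis is the image row axis (r); a voxel moves in the
//     (column, slice) plane when the specimen is tilted;
//   * tilt series are (m, n_det, n_alpha) arrays, one image per angle;
//   * angle 0 integrates along the slice axis k; positive angles rotate
//     right-handedly about the row axis.
//
// Rays are parameterised by slice index k (valid for |alpha| < 90 deg):
// a detector column at centred coordinate s meets slice k (centred
// coordinate t) at centred column coordinate x = (s + t*sin a)/cos a,
// sampled by linear interpolation between adjacent columns with path
// weight 1/cos a per unit slice step.  The adjoint transposes the exact
// interpolation weights, so <Au, b> == <u, A*b> up to rounding.
//
// Both kernels take `wexp`: entries |A_ij| are raised to this power
// before use.  wexp = 1 is the plain operator; other exponents serve the
// diagonal-preconditioner row/column sums (apply to a ones volume or to
// the mask stack).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector fp_parallel(NumericVector u, int m, int n, int z,
                          NumericVector angles_rad, int det_n,
                          double wexp = 1.0) {
  const int na = angles_rad.size();
  NumericVector out(static_cast<R_xlen_t>(m) * det_n * na);
  const double cx = 0.5 * (n - 1);     // volume column centre
  const double cz = 0.5 * (z - 1);     // slice centre
  const double cs = 0.5 * (det_n - 1); // detector column centre
  const bool pw = (wexp != 1.0);
  const double *pu = u.begin();
  double *po = out.begin();
  for (int i = 0; i < na; ++i) {
    const double ca = std::cos(angles_rad[i]);
    const double sa = std::sin(angles_rad[i]);
    double w = 1.0 / ca;
    if (pw) w = std::pow(w, wexp);
    for (int c = 0; c < det_n; ++c) {
      const double s = c - cs;
      double *orow = po + static_cast<R_xlen_t>(m) * (c + static_cast<R_xlen_t>(det_n) * i);
      for (int k = 0; k < z; ++k) {
        const double x = (s + (k - cz) * sa) / ca + cx;
        if (x < 0.0 || x > n - 1) continue;
        int x0 = static_cast<int>(std::floor(x));
        if (x0 == n - 1) x0 = n - 2; // x == n-1 exactly: use left cell
        double fx = x - x0;
        double w1 = w * (1.0 - fx), w2 = w * fx;
        if (pw) { w1 = w * std::pow(1.0 - fx, wexp); w2 = w * std::pow(fx, wexp); }
        const double *u0 = pu + static_cast<R_xlen_t>(m) * (x0 + static_cast<R_xlen_t>(n) * k);
        const double *u1 = u0 + m;
        for (int r = 0; r < m; ++r)
          orow[r] += w1 * u0[r] + w2 * u1[r];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector bp_parallel(NumericVector b, int m, int n, int z,
                          NumericVector angles_rad, int det_n,
                          double wexp = 1.0) {
  const int na = angles_rad.size();
  NumericVector out(static_cast<R_xlen_t>(m) * n * z);
  const double cx = 0.5 * (n - 1);
  const double cz = 0.5 * (z - 1);
  const double cs = 0.5 * (det_n - 1);
  const bool pw = (wexp != 1.0);
  const double *pb = b.begin();
  double *po = out.begin();
  for (int i = 0; i < na; ++i) {
    const double ca = std::cos(angles_rad[i]);
    const double sa = std::sin(angles_rad[i]);
    double w = 1.0 / ca;
    if (pw) w = std::pow(w, wexp);
    for (int c = 0; c < det_n; ++c) {
      const double s = c - cs;
      const double *brow = pb + static_cast<R_xlen_t>(m) * (c + static_cast<R_xlen_t>(det_n) * i);
      for (int k = 0; k < z; ++k) {
        const double x = (s + (k - cz) * sa) / ca + cx;
        if (x < 0.0 || x > n - 1) continue;
        int x0 = static_cast<int>(std::floor(x));
        if (x0 == n - 1) x0 = n - 2;
        double fx = x - x0;
        double w1 = w * (1.0 - fx), w2 = w * fx;
        if (pw) { w1 = w * std::pow(1.0 - fx, wexp); w2 = w * std::pow(fx, wexp); }
        double *u0 = po + static_cast<R_xlen_t>(m) * (x0 + static_cast<R_xlen_t>(n) * k);
        double *u1 = u0 + m;
        for (int r = 0; r < m; ++r) {
          u0[r] += w1 * brow[r];
          u1[r] += w2 * brow[r];
        }
      }
    }
  }
  return out;
}
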