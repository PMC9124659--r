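// Image-stack warping and finite-difference kernels.
//
// Shift sign convention: warping a stack by f MOVES IMAGE CONTENT by +f
// (f0 along columns, f1 along rows), i.e. out[r, c] = in[r - f1, c - f0]
// with bilinear interpolation and edge replication outside the support.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector warp_stack_cpp(NumericVector imgs, int m, int n, int na,
                             NumericVector f0, NumericVector f1) {
  NumericVector out(static_cast<R_xlen_t>(m) * n * na);
  const double *pi = imgs.begin();
  double *po = out.begin();
  for (int i = 0; i < na; ++i) {
    const double s0 = f0[i], s1 = f1[i];
    const double *img = pi + static_cast<R_xlen_t>(m) * n * i;
    double *o = po + static_cast<R_xlen_t>(m) * n * i;
    for (int c = 0; c < n; ++c) {
      const double xc = c - s0;
      int c0 = static_cast<int>(std::floor(xc));
      double fc = xc - c0;
      int c0c = clampi(c0, 0, n - 1), c1c = clampi(c0 + 1, 0, n - 1);
      const double *col0 = img + static_cast<R_xlen_t>(m) * c0c;
      const double *col1 = img + static_cast<R_xlen_t>(m) * c1c;
      double *oc = o + static_cast<R_xlen_t>(m) * c;
      for (int r = 0; r < m; ++r) {
        const double xr = r - s1;
        int r0 = static_cast<int>(std::floor(xr));
        double fr = xr - r0;
        int r0c = clampi(r0, 0, m - 1), r1c = clampi(r0 + 1, 0, m - 1);
        double v0 = (1.0 - fr) * col0[r0c] + fr * col0[r1c];
        double v1 = (1.0 - fr) * col1[r0c] + fr * col1[r1c];
        oc[r] = (1.0 - fc) * v0 + fc * v1;
      }
    }
  }
  return out;
}

// Central differences in the interior, one-sided at image borders.
// Returns (m, n, na, 2): [..,1] = d/d(column), [..,2] = d/d(row).
// [[Rcpp::export]]
NumericVector central_gradient_cpp(NumericVector imgs, int m, int n, int na) {
  const R_xlen_t npx = static_cast<R_xlen_t>(m) * n * na;
  NumericVector out(2 * npx);
  const double *pi = imgs.begin();
  double *g0 = out.begin();        // column derivative
  double *g1 = out.begin() + npx;  // row derivative
  for (int i = 0; i < na; ++i) {
    const double *img = pi + static_cast<R_xlen_t>(m) * n * i;
    double *o0 = g0 + static_cast<R_xlen_t>(m) * n * i;
    double *o1 = g1 + static_cast<R_xlen_t>(m) * n * i;
    for (int c = 0; c < n; ++c) {
      const int cl = (c == 0) ? 0 : c - 1;
      const int cr = (c == n - 1) ? n - 1 : c + 1;
      const double dc = (cr == cl) ? 1.0 : (cr - cl);
      const double *coll = img + static_cast<R_xlen_t>(m) * cl;
      const double *colr = img + static_cast<R_xlen_t>(m) * cr;
      const double *col = img + static_cast<R_xlen_t>(m) * c;
      double *t0 = o0 + static_cast<R_xlen_t>(m) * c;
      double *t1 = o1 + static_cast<R_xlen_t>(m) * c;
      for (int r = 0; r < m; ++r) {
        t0[r] = (colr[r] - coll[r]) / dc;
        const int rl = (r == 0) ? 0 : r - 1;
        const int rr = (r == m - 1) ? m - 1 : r + 1;
        t1[r] = (col[rr] - col[rl]) / (rr - rl);
      }
    }
  }
  return out;
}

// Forward differences per axis, zero (Neumann) at the far edge.
// Volume (m, n, z) -> gradient (m, n, z, 3): comps d/dr, d/dc, d/dk.
// [[Rcpp::export]]
NumericVector grad3d_cpp(NumericVector u, int m, int n, int z) {
  const R_xlen_t nv = static_cast<R_xlen_t>(m) * n * z;
  NumericVector out(3 * nv);
  const double *pu = u.begin();
  double *gr = out.begin();
  double *gc = out.begin() + nv;
  double *gk = out.begin() + 2 * nv;
  const R_xlen_t sm = 1, sn = m, sz = static_cast<R_xlen_t>(m) * n;
  for (int k = 0; k < z; ++k)
    for (int c = 0; c < n; ++c) {
      const R_xlen_t base = sn * c + sz * k;
      for (int r = 0; r < m; ++r) {
        const R_xlen_t j = base + r;
        gr[j] = (r < m - 1) ? pu[j + sm] - pu[j] : 0.0;
        gc[j] = (c < n - 1) ? pu[j + sn] - pu[j] : 0.0;
        gk[j] = (k < z - 1) ? pu[j + sz] - pu[j] : 0.0;
      }
    }
  return out;
}

// Divergence: negative adjoint of grad3d_cpp, so that
// sum(grad3d(u) * p) == -sum(u * div3d(p)) exactly.
// [[Rcpp::export]]
NumericVector div3d_cpp(NumericVector p, int m, int n, int z) {
  const R_xlen_t nv = static_cast<R_xlen_t>(m) * n * z;
  NumericVector out(nv);
  const double *pr = p.begin();
  const double *pc = p.begin() + nv;
  const double *pk = p.begin() + 2 * nv;
  double *po = out.begin();
  const R_xlen_t sm = 1, sn = m, sz = static_cast<R_xlen_t>(m) * n;
  for (int k = 0; k < z; ++k)
    for (int c = 0; c < n; ++c) {
      const R_xlen_t base = sn * c + sz * k;
      for (int r = 0; r < m; ++r) {
        const R_xlen_t j = base + r;
        double d = 0.0;
        if (r < m - 1) d += pr[j];
        if (r > 0)     d -= pr[j - sm];
        if (c < n - 1) d += pc[j];
        if (c > 0)     d -= pc[j - sn];
        if (k < z - 1) d += pk[j];
        if (k > 0)     d -= pk[j - sz];
        po[j] = d;
      }
    }
  return out;
}
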