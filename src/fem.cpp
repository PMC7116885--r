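// P1 finite element operators for the monodomain equation on triangle or
// tetrahedral meshes. Produces COO triplets for the anisotropic stiffness
// matrix and a lumped (row-sum) mass vector. Coordinates are expected in
// cm and diffusion tensors in cm^2/ms, so that M dV/dt = -K V is
// dimensionally consistent with V in mV and t in ms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(NumericMatrix verts, IntegerMatrix elems,
                  NumericMatrix dtens) {
  const int n = verts.nrow();
  const int m = elems.nrow();
  const int k = elems.ncol();           // 3 = triangles, 4 = tets
  if (k != 3 && k != 4) stop("elements must have 3 or 4 vertices");
  const int d = k - 1;
  if (dtens.nrow() != m || dtens.ncol() != d * d)
    stop("diffusion tensor matrix must be m x d^2");

  const int nt = m * k * k;
  IntegerVector ti(nt), tj(nt);
  NumericVector tx(nt);
  NumericVector mass(n);

  for (int e = 0; e < m; ++e) {
    int idx[4];
    for (int a = 0; a < k; ++a) {
      idx[a] = elems(e, a);
      if (idx[a] < 0 || idx[a] >= n) stop("element %d: vertex index out of range", e + 1);
    }
    double g[4][3];                      // gradients of hat functions
    double meas;
    if (d == 2) {
      const double x0 = verts(idx[0], 0), y0 = verts(idx[0], 1);
      const double x1 = verts(idx[1], 0), y1 = verts(idx[1], 1);
      const double x2 = verts(idx[2], 0), y2 = verts(idx[2], 1);
      const double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
      if (det <= 0.0) stop("element %d: non-positive area", e + 1);
      meas = 0.5 * det;
      // grad lambda_a = rot of opposite edge / det
      g[0][0] = (y1 - y2) / det; g[0][1] = (x2 - x1) / det; g[0][2] = 0.0;
      g[1][0] = (y2 - y0) / det; g[1][1] = (x0 - x2) / det; g[1][2] = 0.0;
      g[2][0] = (y0 - y1) / det; g[2][1] = (x1 - x0) / det; g[2][2] = 0.0;
    } else {
      double J[3][3];
      for (int c = 0; c < 3; ++c) {
        J[c][0] = verts(idx[1], c) - verts(idx[0], c);
        J[c][1] = verts(idx[2], c) - verts(idx[0], c);
        J[c][2] = verts(idx[3], c) - verts(idx[0], c);
      }
      const double det =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      if (det <= 0.0) stop("element %d: non-positive volume", e + 1);
      meas = det / 6.0;
      double inv[3][3];                  // inverse of J, times det
      inv[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]);
      inv[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
      inv[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]);
      inv[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
      inv[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]);
      inv[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
      inv[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      inv[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
      inv[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]);
      // grad lambda_{a+1} = row a of J^{-1}; grad lambda_0 = -sum
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c) g[a + 1][c] = inv[a][c] / det;
      for (int c = 0; c < 3; ++c)
        g[0][c] = -(g[1][c] + g[2][c] + g[3][c]);
    }

    // K_ab = meas * grad_a . (D grad_b)
    double Dg[4][3];
    for (int a = 0; a < k; ++a) {
      for (int r = 0; r < d; ++r) {
        double acc = 0.0;
        for (int c = 0; c < d; ++c) acc += dtens(e, r * d + c) * g[a][c];
        Dg[a][r] = acc;
      }
    }
    const int off = e * k * k;
    for (int a = 0; a < k; ++a) {
      mass[idx[a]] += meas / k;
      for (int b = 0; b < k; ++b) {
        double acc = 0.0;
        for (int r = 0; r < d; ++r) acc += g[a][r] * Dg[b][r];
        const int p = off + a * k + b;
        ti[p] = idx[a];
        tj[p] = idx[b];
        tx[p] = meas * acc;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["mass"] = mass);
}

// Signed measures (area in 2D from xy, volume in 3D) per element.
// [[Rcpp::export(name = ".element_measures")]]
NumericVector element_measures(NumericMatrix verts, IntegerMatrix elems) {
  const int m = elems.nrow();
  const int k = elems.ncol();
  NumericVector out(m);
  for (int e = 0; e < m; ++e) {
    if (k == 3) {
      const int a = elems(e, 0), b = elems(e, 1), c = elems(e, 2);
      out[e] = 0.5 * ((verts(b, 0) - verts(a, 0)) * (verts(c, 1) - verts(a, 1)) -
                      (verts(c, 0) - verts(a, 0)) * (verts(b, 1) - verts(a, 1)));
    } else {
      const int a = elems(e, 0), b = elems(e, 1), c = elems(e, 2),
                dd = elems(e, 3);
      double u[3], v[3], w[3];
      for (int c2 = 0; c2 < 3; ++c2) {
        u[c2] = verts(b, c2) - verts(a, c2);
        v[c2] = verts(c, c2) - verts(a, c2);
        w[c2] = verts(dd, c2) - verts(a, c2);
      }
      out[e] = (u[0] * (v[1] * w[2] - v[2] * w[1]) -
                u[1] * (v[0] * w[2] - v[2] * w[0]) +
                u[2] * (v[0] * w[1] - v[1] * w[0])) / 6.0;
    }
  }
  return out;
}
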