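// Tensor-product piecewise cubic spline interpolation of a 3D PSF stack.
//
// The stack is interpolated by a C2-continuous tricubic spline with
// not-a-knot end conditions in each dimension, stored as 64 polynomial
// coefficients per voxel (4 per dimension).  Evaluation and analytic
// first derivatives are exposed for rendering and Fisher-information
// computations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Linear operator mapping n knot values to n second derivatives of the
// not-a-knot interpolating cubic spline on a unit-spaced grid.
static mat notaknot_operator(const int n) {
  mat A(n, n, fill::zeros);
  mat B(n, n, fill::zeros);
  // interior rows: sigma_{i-1} + 4 sigma_i + sigma_{i+1} = 6 (y_{i-1} - 2 y_i + y_{i+1})
  for (int i = 1; i < n - 1; ++i) {
    A(i, i - 1) = 1.0; A(i, i) = 4.0; A(i, i + 1) = 1.0;
    B(i, i - 1) = 6.0; B(i, i) = -12.0; B(i, i + 1) = 6.0;
  }
  // not-a-knot: third derivative continuous at the first/last interior knot,
  // i.e. sigma is locally linear there.
  A(0, 0) = 1.0; A(0, 1) = -2.0; A(0, 2) = 1.0;
  A(n - 1, n - 3) = 1.0; A(n - 1, n - 2) = -2.0; A(n - 1, n - 1) = 1.0;
  return solve(A, B);
}

// Given knot values (columns of Y, each length n) return per-interval
// cubic coefficients: for interval i and local t in [0,1],
// S(t) = a + b t + c t^2 + d t^3.  Output: (n-1) x 4 x ncol, flattened as
// cube slices per column.
static void spline_coeffs_1d(const mat& M, const mat& Y, cube& out) {
  const int n = Y.n_rows;
  const int m = Y.n_cols;
  mat S = M * Y;  // second derivatives at knots
  out.set_size(n - 1, 4, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n - 1; ++i) {
      const double yi = Y(i, j), yi1 = Y(i + 1, j);
      const double si = S(i, j), si1 = S(i + 1, j);
      out(i, 0, j) = yi;
      out(i, 1, j) = (yi1 - yi) - (2.0 * si + si1) / 6.0;
      out(i, 2, j) = si / 2.0;
      out(i, 3, j) = (si1 - si) / 6.0;
    }
  }
}

// Build 64-coefficient-per-voxel tensor-product spline from a stack
// v[row, col, plane] (R array, column-major).  Returns numeric array with
// dim (nr-1, nc-1, np-1, 64); coefficient index = 1 + m + 4*n + 16*p for
// the monomial tr^m * tc^n * tp^p (tr: row offset, tc: col, tp: plane).
// [[Rcpp::export]]
Rcpp::NumericVector cspline_build(Rcpp::NumericVector v_) {
  Rcpp::IntegerVector dims = v_.attr("dim");
  if (dims.size() != 3) Rcpp::stop("stack must be a 3D array");
  const int nr = dims[0], nc = dims[1], np = dims[2];
  if (nr < 4 || nc < 4 || np < 4)
    Rcpp::stop("need at least 4 knots in every dimension");
  const cube v(v_.begin(), nr, nc, np);  // copy

  mat Mr = notaknot_operator(nr);
  mat Mc = notaknot_operator(nc);
  mat Mp = notaknot_operator(np);

  // Pass 1: spline along planes (p).  For each (r, c): np values ->
  // (np-1) x 4 coeffs.  Store as C1[r, c, kp, q] via a flat vector.
  const int npv = np - 1;
  std::vector<double> C1((size_t)nr * nc * npv * 4);
  {
    // columns of Y: one per (r, c)
    mat Y(np, nr * nc);
    for (int p = 0; p < np; ++p)
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          Y(p, r + nr * c) = v(r, c, p);
    cube cf;
    spline_coeffs_1d(Mp, Y, cf);  // (np-1) x 4 x (nr*nc)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        for (int kp = 0; kp < npv; ++kp)
          for (int q = 0; q < 4; ++q)
            C1[((size_t)r) + nr * (c + (size_t)nc * (kp + (size_t)npv * q))] =
              cf(kp, q, r + nr * c);
  }

  // Pass 2: spline along columns (c).  For each (r, kp, q): nc values ->
  // (nc-1) x 4.  Store C2[r, kc, kp, n, q].
  const int ncv = nc - 1;
  std::vector<double> C2((size_t)nr * ncv * npv * 16);
  {
    mat Y(nc, nr * npv * 4);
    for (int q = 0; q < 4; ++q)
      for (int kp = 0; kp < npv; ++kp)
        for (int r = 0; r < nr; ++r) {
          const int col = r + nr * (kp + npv * q);
          for (int c = 0; c < nc; ++c)
            Y(c, col) = C1[((size_t)r) + nr * (c + (size_t)nc * (kp + (size_t)npv * q))];
        }
    cube cf;
    spline_coeffs_1d(Mc, Y, cf);
    for (int q = 0; q < 4; ++q)
      for (int nn = 0; nn < 4; ++nn)
        for (int kp = 0; kp < npv; ++kp)
          for (int kc = 0; kc < ncv; ++kc)
            for (int r = 0; r < nr; ++r)
              C2[((size_t)r) + nr * (kc + (size_t)ncv * (kp + (size_t)npv * (nn + 4 * (size_t)q)))] =
                cf(kc, nn, r + nr * (kp + npv * q));
  }

  // Pass 3: spline along rows (r).  For each (kc, kp, n, q): nr values ->
  // (nr-1) x 4.  Final coeff[kr, kc, kp, m + 4n + 16q].
  const int nrv = nr - 1;
  Rcpp::NumericVector out((R_xlen_t)nrv * ncv * npv * 64);
  {
    mat Y(nr, ncv * npv * 16);
    for (int q = 0; q < 4; ++q)
      for (int nn = 0; nn < 4; ++nn)
        for (int kp = 0; kp < npv; ++kp)
          for (int kc = 0; kc < ncv; ++kc) {
            const int col = kc + ncv * (kp + npv * (nn + 4 * q));
            for (int r = 0; r < nr; ++r)
              Y(r, col) = C2[((size_t)r) + nr * (kc + (size_t)ncv * (kp + (size_t)npv * (nn + 4 * (size_t)q)))];
          }
    cube cf;
    spline_coeffs_1d(Mr, Y, cf);
    for (int q = 0; q < 4; ++q)
      for (int nn = 0; nn < 4; ++nn)
        for (int mm = 0; mm < 4; ++mm)
          for (int kp = 0; kp < npv; ++kp)
            for (int kc = 0; kc < ncv; ++kc)
              for (int kr = 0; kr < nrv; ++kr)
                out[((R_xlen_t)kr) + nrv * (kc + (R_xlen_t)ncv * (kp + (R_xlen_t)npv *
                    (mm + 4 * (R_xlen_t)nn + 16 * (R_xlen_t)q)))] =
                  cf(kr, mm, kc + ncv * (kp + npv * (nn + 4 * q)));
  }
  out.attr("dim") = Rcpp::IntegerVector::create(nrv, ncv, npv, 64);
  return out;
}

struct EvalResult { double f, dr, dc, dp; };

static inline EvalResult eval_voxel(const double* a, const R_xlen_t stride,
                                    const double tr, const double tc, const double tp) {
  // a: pointer to coeff[kr, kc, kp, 0]; stride between consecutive coeff
  // indices.  Horner in p, then c, then r, tracking derivatives.
  double pr[4], pc[4], pp[4];
  pr[0] = 1; pr[1] = tr; pr[2] = tr * tr; pr[3] = pr[2] * tr;
  pc[0] = 1; pc[1] = tc; pc[2] = tc * tc; pc[3] = pc[2] * tc;
  pp[0] = 1; pp[1] = tp; pp[2] = tp * tp; pp[3] = pp[2] * tp;
  double f = 0, dr = 0, dc = 0, dp = 0;
  for (int q = 0; q < 4; ++q)
    for (int nn = 0; nn < 4; ++nn)
      for (int mm = 0; mm < 4; ++mm) {
        const double co = a[stride * (mm + 4 * nn + 16 * q)];
        f  += co * pr[mm] * pc[nn] * pp[q];
        if (mm > 0) dr += co * mm * pr[mm - 1] * pc[nn] * pp[q];
        if (nn > 0) dc += co * nn * pr[mm] * pc[nn - 1] * pp[q];
        if (q  > 0) dp += co * q  * pr[mm] * pc[nn] * pp[q - 1];
      }
  return {f, dr, dc, dp};
}

// Evaluate the spline (and optionally its gradient) at arbitrary points
// given in continuous grid units (0 .. n-1 along each axis).  pts is an
// N x 3 matrix with columns (row, col, plane).  Points outside the grid
// are clamped to the boundary voxel (polynomial extrapolation within it).
// [[Rcpp::export]]
Rcpp::NumericMatrix cspline_eval(Rcpp::NumericVector coef_, Rcpp::NumericMatrix pts,
                                 bool deriv = false) {
  Rcpp::IntegerVector dims = coef_.attr("dim");
  const int nrv = dims[0], ncv = dims[1], npv = dims[2];
  const R_xlen_t stride = (R_xlen_t)nrv * ncv * npv;
  const double* cf = coef_.begin();
  const int N = pts.nrow();
  Rcpp::NumericMatrix out(N, deriv ? 4 : 1);
  for (int i = 0; i < N; ++i) {
    double gr = pts(i, 0), gc = pts(i, 1), gp = pts(i, 2);
    int kr = std::min(std::max((int)std::floor(gr), 0), nrv - 1);
    int kc = std::min(std::max((int)std::floor(gc), 0), ncv - 1);
    int kp = std::min(std::max((int)std::floor(gp), 0), npv - 1);
    const double tr = gr - kr, tc = gc - kc, tp = gp - kp;
    const double* a = cf + ((R_xlen_t)kr + nrv * (kc + (R_xlen_t)ncv * kp));
    EvalResult e = eval_voxel(a, stride, tr, tc, tp);
    out(i, 0) = e.f;
    if (deriv) { out(i, 1) = e.dr; out(i, 2) = e.dc; out(i, 3) = e.dp; }
  }
  return out;
}
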