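// Minimal convolutional-network primitives (forward and backward) used by
// the localizer.  Tensors are R arrays with dim (H, W, C, B), column-major.
// Convolutions are 3x3, stride 1, zero-padded ("same").

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col3(const double* x, int H, int W, int C, mat& X) {
  // X: (H*W) x (9*C); column index = dy + 3*dx + 9*ch with dy,dx in {0,1,2}
  // meaning source offset (dy-1, dx-1).  Writes are contiguous down rows.
  X.zeros(H * W, 9 * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = x + (size_t)H * W * ch;
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        double* col = X.colptr(dy + 3 * dx + 9 * ch);
        const int c0 = std::max(0, 1 - dx), c1 = std::min(W, W + 1 - dx);
        const int r0 = std::max(0, 1 - dy), r1 = std::min(H, H + 1 - dy);
        for (int c = c0; c < c1; ++c) {
          const double* src = xc + (size_t)H * (c + dx - 1) + (r0 + dy - 1);
          double* dst = col + (size_t)H * c + r0;
          std::memcpy(dst, src, (r1 - r0) * sizeof(double));
        }
      }
    }
  }
}

static void col2im3(const mat& X, int H, int W, int C, double* dx_) {
  for (int ch = 0; ch < C; ++ch) {
    double* xc = dx_ + (size_t)H * W * ch;
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        const double* col = X.colptr(dy + 3 * dx + 9 * ch);
        const int c0 = std::max(0, 1 - dx), c1 = std::min(W, W + 1 - dx);
        const int r0 = std::max(0, 1 - dy), r1 = std::min(H, H + 1 - dy);
        for (int c = c0; c < c1; ++c) {
          double* dst = xc + (size_t)H * (c + dx - 1) + (r0 + dy - 1);
          const double* src = col + (size_t)H * c + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// weight array w has dim (3, 3, Cin, Cout); its flat layout matches the
// im2col column order, so it wraps directly as a (9*Cin) x Cout matrix.

// [[Rcpp::export]]
Rcpp::NumericVector conv3_fwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                              Rcpp::NumericVector b_) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd.size() > 3 ? xd[3] : 1;
  Rcpp::IntegerVector wd = w_.attr("dim");
  const int Cout = wd[3];
  if (wd[2] != Cin) Rcpp::stop("conv3_fwd: channel mismatch");
  const mat Wm(const_cast<double*>(w_.begin()), 9 * Cin, Cout, false, true);
  const rowvec bias(const_cast<double*>(b_.begin()), Cout, false, true);
  Rcpp::NumericVector y_((R_xlen_t)H * W * Cout * B);
  mat X;
  for (int b = 0; b < B; ++b) {
    im2col3(x_.begin() + (size_t)H * W * Cin * b, H, W, Cin, X);
    mat Y(y_.begin() + (size_t)H * W * Cout * b, H * W, Cout, false, true);
    Y = X * Wm;  // writes straight into the output memory
    Y.each_row() += bias;
  }
  y_.attr("dim") = Rcpp::IntegerVector::create(H, W, Cout, B);
  return y_;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                     Rcpp::NumericVector dy_, bool need_dx = true) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd.size() > 3 ? xd[3] : 1;
  Rcpp::IntegerVector wd = w_.attr("dim");
  const int Cout = wd[3];
  const mat Wm(const_cast<double*>(w_.begin()), 9 * Cin, Cout, false, true);
  Rcpp::NumericVector dw_((R_xlen_t)9 * Cin * Cout);
  Rcpp::NumericVector db_(Cout);
  Rcpp::NumericVector dx_;
  if (need_dx) {
    dx_ = Rcpp::NumericVector((R_xlen_t)H * W * Cin * B);
    dx_.attr("dim") = xd;
  }
  mat dW(dw_.begin(), 9 * Cin, Cout, false, true);
  rowvec dB(db_.begin(), Cout, false, true);
  mat X;
  for (int b = 0; b < B; ++b) {
    const mat G(const_cast<double*>(dy_.begin()) + (size_t)H * W * Cout * b,
                H * W, Cout, false, true);
    im2col3(x_.begin() + (size_t)H * W * Cin * b, H, W, Cin, X);
    dW += X.t() * G;
    dB += sum(G, 0);
    if (need_dx) {
      mat dXcol = G * Wm.t();  // HW x 9Cin
      col2im3(dXcol, H, W, Cin, dx_.begin() + (size_t)H * W * Cin * b);
    }
  }
  dw_.attr("dim") = Rcpp::IntegerVector::create(3, 3, Cin, Cout);
  return Rcpp::List::create(Rcpp::Named("dx") = dx_, Rcpp::Named("dw") = dw_,
                            Rcpp::Named("db") = db_);
}

// [[Rcpp::export]]
Rcpp::NumericVector avgpool2_fwd(Rcpp::NumericVector x_) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd.size() > 3 ? xd[3] : 1;
  const int H2 = H / 2, W2 = W / 2;
  Rcpp::NumericVector y_((R_xlen_t)H2 * W2 * C * B);
  const double* xp = x_.begin();
  double* yp = y_.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* xs = xp + (size_t)H * W * cb;
    double* ys = yp + (size_t)H2 * W2 * cb;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        ys[r + (size_t)H2 * c] = 0.25 * (xs[2 * r + (size_t)H * (2 * c)] +
                                         xs[2 * r + 1 + (size_t)H * (2 * c)] +
                                         xs[2 * r + (size_t)H * (2 * c + 1)] +
                                         xs[2 * r + 1 + (size_t)H * (2 * c + 1)]);
  }
  y_.attr("dim") = Rcpp::IntegerVector::create(H2, W2, C, B);
  return y_;
}

// [[Rcpp::export]]
Rcpp::NumericVector avgpool2_bwd(Rcpp::NumericVector dy_, int H, int W) {
  Rcpp::IntegerVector yd = dy_.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], B = yd.size() > 3 ? yd[3] : 1;
  Rcpp::NumericVector dx_((R_xlen_t)H * W * C * B);
  const double* gp = dy_.begin();
  double* dp = dx_.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* gs = gp + (size_t)H2 * W2 * cb;
    double* ds = dp + (size_t)H * W * cb;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r) {
        const double g = 0.25 * gs[r + (size_t)H2 * c];
        ds[2 * r + (size_t)H * (2 * c)] = g;
        ds[2 * r + 1 + (size_t)H * (2 * c)] = g;
        ds[2 * r + (size_t)H * (2 * c + 1)] = g;
        ds[2 * r + 1 + (size_t)H * (2 * c + 1)] = g;
      }
  }
  dx_.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  return dx_;
}

// [[Rcpp::export]]
Rcpp::NumericVector upsample2_fwd(Rcpp::NumericVector x_) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd.size() > 3 ? xd[3] : 1;
  const int H2 = 2 * H, W2 = 2 * W;
  Rcpp::NumericVector y_((R_xlen_t)H2 * W2 * C * B);
  const double* xp = x_.begin();
  double* yp = y_.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* xs = xp + (size_t)H * W * cb;
    double* ys = yp + (size_t)H2 * W2 * cb;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        ys[r + (size_t)H2 * c] = xs[r / 2 + (size_t)H * (c / 2)];
  }
  y_.attr("dim") = Rcpp::IntegerVector::create(H2, W2, C, B);
  return y_;
}

// [[Rcpp::export]]
Rcpp::NumericVector upsample2_bwd(Rcpp::NumericVector dy_) {
  Rcpp::IntegerVector yd = dy_.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], B = yd.size() > 3 ? yd[3] : 1;
  const int H = H2 / 2, W = W2 / 2;
  Rcpp::NumericVector dx_((R_xlen_t)H * W * C * B);
  const double* gp = dy_.begin();
  double* dp = dx_.begin();
  for (size_t cb = 0; cb < (size_t)C * B; ++cb) {
    const double* gs = gp + (size_t)H2 * W2 * cb;
    double* ds = dp + (size_t)H * W * cb;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        ds[r / 2 + (size_t)H * (c / 2)] += gs[r + (size_t)H2 * c];
  }
  dx_.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  return dx_;
}
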