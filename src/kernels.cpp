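// Low-level network kernels.
//
// Activation layout: a batch of B feature maps of size H x W with C channels
// is stored as an (B*W*H) x C matrix, pixel index p = b*W*H + x*H + y
// (y fastest, column-major within each slice).  3x3 convolutions are computed
// as nine shifted GEMMs: Y = sum_o shift_o(X) %*% W[o] + bias, which keeps
// every multiply inside BLAS without materializing a 9x im2col copy.
//
// Weight layout for a 3x3 conv: (9*Cin) x Cout, row block o*Cin..(o+1)*Cin-1
// holds the kernel tap for offset o = (dx+1)*3 + (dy+1), dy/dx in {-1,0,1}.
// Offset (dy,dx) means output pixel (y,x) reads input pixel (y+dy, x+dx).
//
// pad = 0: zero padding (the default, "same" convolution);
// pad = 1: circular (torus) padding, used by the translation-equivariance
//          checks where exact wraparound shifts are required.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// C += alpha * op(A) * op(B), calling BLAS directly so strided blocks of
// larger matrices accumulate in place (no Armadillo temporaries).
static void dgemm_acc(char ta, char tb, int m, int n, int k,
                      const double* A, int lda, const double* B, int ldb,
                      double* C, int ldc, double alpha = 1.0,
                      double beta = 1.0) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha,
                  const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc FCONE FCONE);
}

static void shift_into(const arma::mat& X, arma::mat& Xs,
                       int H, int W, int B, int dy, int dx, bool wrap) {
  Xs.zeros();
  for (int b = 0; b < B; ++b) {
    const int base = b * W * H;
    for (int x = 0; x < W; ++x) {
      int xin = x + dx;
      if (wrap) {
        xin = ((xin % W) + W) % W;
      } else if (xin < 0 || xin >= W) {
        continue;
      }
      if (wrap) {
        for (int y = 0; y < H; ++y) {
          int yin = ((y + dy) % H + H) % H;
          Xs.row(base + x * H + y) = X.row(base + xin * H + yin);
        }
      } else {
        const int y0 = std::max(0, -dy);
        const int y1 = std::min(H - 1, H - 1 - dy);
        if (y0 > y1) continue;
        Xs.rows(base + x * H + y0, base + x * H + y1) =
          X.rows(base + xin * H + y0 + dy, base + xin * H + y1 + dy);
      }
    }
  }
}

// Collect the output rows whose 1-D shifted read crosses an in-slice
// column boundary (y + dy outside [0, H)); used to cancel the spurious
// contribution the big strided GEMM adds there.
static void boundary_rows(int H, int W, int B, int dy, int dx,
                          std::vector<arma::uword>& out_rows,
                          std::vector<arma::uword>& in_rows) {
  out_rows.clear(); in_rows.clear();
  if (dy == 0) return;
  const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
  const int y = (dy > 0) ? H - 1 : 0;
  // the block trim already excluded (x1, H-1) for dy > 0 and (x0, 0) for
  // dy < 0, so those rows need no cancellation
  const int xa = (dy < 0) ? x0 + 1 : x0;
  const int xb = (dy > 0) ? x1 - 1 : x1;
  for (int b = 0; b < B; ++b) {
    const int base = b * W * H;
    for (int x = xa; x <= xb; ++x) {
      const int pout = base + x * H + y;
      out_rows.push_back((arma::uword)pout);
      in_rows.push_back((arma::uword)(pout + dx * H + dy));
    }
  }
}

// dst += shift_{dy,dx}(src) * M  (zero padding), computed as one strided
// GEMM per slice over the trimmed valid block plus a boundary fix-up.
static void gemm_shift_add(arma::mat& dst, const arma::mat& src,
                           const arma::mat& M,
                           int H, int W, int B, int dy, int dx) {
  const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
  if (x0 > x1) return;
  const int trim_lo = std::max(0, -dy), trim_hi = std::max(0, dy);
  const int lds = src.n_rows, ldd = dst.n_rows;
  for (int b = 0; b < B; ++b) {
    const int base = b * W * H;
    const int a = base + x0 * H + trim_lo;
    const int z = base + x1 * H + H - 1 - trim_hi;
    if (a > z) continue;
    dgemm_acc('N', 'N', z - a + 1, M.n_cols, M.n_rows,
              src.memptr() + (a + dx * H + dy), lds,
              M.memptr(), M.n_rows,
              dst.memptr() + a, ldd);
  }
  std::vector<arma::uword> orow, irow;
  boundary_rows(H, W, B, dy, dx, orow, irow);
  if (!orow.empty()) {
    const arma::uvec ov(orow), iv(irow);
    dst.rows(ov) -= src.rows(iv) * M;
  }
}

// [[Rcpp::export(name = ".cpp_conv3x3_forward")]]
arma::mat cpp_conv3x3_forward(const arma::mat& X, const arma::mat& Wt,
                              const arma::rowvec& bias,
                              int H, int W, int B, int pad) {
  const int Cin = X.n_cols;
  const int Cout = Wt.n_cols;
  if ((int)Wt.n_rows != 9 * Cin)
    stop("weight matrix has %d rows, expected 9*Cin = %d", (int)Wt.n_rows, 9 * Cin);
  if ((int)X.n_rows != B * W * H)
    stop("activation matrix has %d rows, expected B*W*H = %d", (int)X.n_rows, B * W * H);
  arma::mat Y(X.n_rows, Cout);
  Y.each_row() = bias;
  if (pad == 1) {
    arma::mat Xs(X.n_rows, Cin);
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      shift_into(X, Xs, H, W, B, dy, dx, true);
      Y += Xs * Wt.rows(o * Cin, (o + 1) * Cin - 1);
    }
  } else {
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      gemm_shift_add(Y, X, Wt.rows(o * Cin, (o + 1) * Cin - 1),
                     H, W, B, dy, dx);
    }
  }
  return Y;
}

// dW_o += shift_{dy,dx}(X)^T * dY via the same strided-block + fix-up idea.
static void gemm_shift_weight(arma::mat& dWo, const arma::mat& X,
                              const arma::mat& dY,
                              int H, int W, int B, int dy, int dx) {
  const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
  if (x0 > x1) return;
  const int trim_lo = std::max(0, -dy), trim_hi = std::max(0, dy);
  const int ldx = X.n_rows, ldy = dY.n_rows;
  for (int b = 0; b < B; ++b) {
    const int base = b * W * H;
    const int a = base + x0 * H + trim_lo;
    const int z = base + x1 * H + H - 1 - trim_hi;
    if (a > z) continue;
    dgemm_acc('T', 'N', X.n_cols, dY.n_cols, z - a + 1,
              X.memptr() + (a + dx * H + dy), ldx,
              dY.memptr() + a, ldy,
              dWo.memptr(), dWo.n_rows);
  }
  std::vector<arma::uword> orow, irow;
  boundary_rows(H, W, B, dy, dx, orow, irow);
  if (!orow.empty()) {
    const arma::uvec ov(orow), iv(irow);
    dWo -= X.rows(iv).t() * dY.rows(ov);
  }
}

// [[Rcpp::export(name = ".cpp_conv3x3_backward")]]
List cpp_conv3x3_backward(const arma::mat& X, const arma::mat& Wt,
                          const arma::mat& dY,
                          int H, int W, int B, int pad) {
  const int Cin = X.n_cols;
  arma::mat dW(9 * Cin, Wt.n_cols, arma::fill::zeros);
  arma::mat dX(X.n_rows, Cin, arma::fill::zeros);
  if (pad == 1) {
    arma::mat Xs(X.n_rows, Cin);
    arma::mat tmp(X.n_rows, Cin);
    arma::mat tmps(X.n_rows, Cin);
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      shift_into(X, Xs, H, W, B, dy, dx, true);
      dW.rows(o * Cin, (o + 1) * Cin - 1) = Xs.t() * dY;
      tmp = dY * Wt.rows(o * Cin, (o + 1) * Cin - 1).t();
      shift_into(tmp, tmps, H, W, B, -dy, -dx, true);
      dX += tmps;
    }
  } else {
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      arma::mat dWo(Cin, Wt.n_cols, arma::fill::zeros);
      gemm_shift_weight(dWo, X, dY, H, W, B, dy, dx);
      dW.rows(o * Cin, (o + 1) * Cin - 1) = dWo;
      // dX(q) += dY(q + (-dy,-dx)) * W_o^T
      gemm_shift_add(dX, dY, Wt.rows(o * Cin, (o + 1) * Cin - 1).t(),
                     H, W, B, -dy, -dx);
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(const arma::mat& X, int H, int W, int B) {
  if (H % 2 != 0 || W % 2 != 0) stop("max-pooling needs even H and W");
  const int C = X.n_cols;
  const int H2 = H / 2, W2 = W / 2;
  arma::mat Y(B * W2 * H2, C);
  arma::umat idx(B * W2 * H2, C);
  for (int b = 0; b < B; ++b) {
    const int base_in = b * W * H, base_out = b * W2 * H2;
    for (int x = 0; x < W2; ++x) {
      for (int y = 0; y < H2; ++y) {
        const int pout = base_out + x * H2 + y;
        const int p00 = base_in + (2 * x) * H + 2 * y;
        const int p01 = base_in + (2 * x + 1) * H + 2 * y;
        const int cand[4] = {p00, p00 + 1, p01, p01 + 1};
        for (int c = 0; c < C; ++c) {
          int best = cand[0];
          double v = X(cand[0], c);
          for (int j = 1; j < 4; ++j) {
            if (X(cand[j], c) > v) { v = X(cand[j], c); best = cand[j]; }
          }
          Y(pout, c) = v;
          idx(pout, c) = best;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
arma::mat cpp_maxpool_backward(const arma::mat& dY, const arma::umat& idx,
                               int n_in) {
  const int C = dY.n_cols;
  arma::mat dX(n_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (arma::uword p = 0; p < dY.n_rows; ++p) {
      dX(idx(p, c), c) += dY(p, c);
    }
  }
  return dX;
}

// Bilinear interpolation weights for one axis, integer upsampling factor f,
// half-pixel-center convention: src = (dst + 0.5)/f - 0.5.
static void bilin_axis(int n_in, int f, bool wrap,
                       std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& w1) {
  const int n_out = n_in * f;
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int d = 0; d < n_out; ++d) {
    double s = (d + 0.5) / f - 0.5;
    double fl = std::floor(s);
    int a = (int)fl;
    double w = s - fl;
    int b = a + 1;
    if (wrap) {
      a = ((a % n_in) + n_in) % n_in;
      b = ((b % n_in) + n_in) % n_in;
    } else {
      if (a < 0) { a = 0; b = 0; w = 0.0; }
      if (b > n_in - 1) { b = n_in - 1; a = n_in - 1; w = 0.0; }
    }
    i0[d] = a; i1[d] = b; w1[d] = w;
  }
}

// [[Rcpp::export(name = ".cpp_upsample_forward")]]
arma::mat cpp_upsample_forward(const arma::mat& X, int H, int W, int B,
                               int f, int pad) {
  const int C = X.n_cols;
  const int Ho = H * f, Wo = W * f;
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  bilin_axis(H, f, pad == 1, y0, y1, wy);
  bilin_axis(W, f, pad == 1, x0, x1, wx);
  arma::mat Y(B * Wo * Ho, C);
  for (int b = 0; b < B; ++b) {
    const int base_in = b * W * H, base_out = b * Wo * Ho;
    for (int x = 0; x < Wo; ++x) {
      const int ca = base_in + x0[x] * H, cb = base_in + x1[x] * H;
      const double ux = wx[x];
      for (int y = 0; y < Ho; ++y) {
        const double uy = wy[y];
        Y.row(base_out + x * Ho + y) =
          (1 - ux) * ((1 - uy) * X.row(ca + y0[y]) + uy * X.row(ca + y1[y])) +
          ux * ((1 - uy) * X.row(cb + y0[y]) + uy * X.row(cb + y1[y]));
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".cpp_upsample_backward")]]
arma::mat cpp_upsample_backward(const arma::mat& dY, int H, int W, int B,
                                int f, int pad) {
  const int C = dY.n_cols;
  const int Ho = H * f, Wo = W * f;
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  bilin_axis(H, f, pad == 1, y0, y1, wy);
  bilin_axis(W, f, pad == 1, x0, x1, wx);
  arma::mat dX(B * W * H, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int base_in = b * W * H, base_out = b * Wo * Ho;
    for (int x = 0; x < Wo; ++x) {
      const int ca = base_in + x0[x] * H, cb = base_in + x1[x] * H;
      const double ux = wx[x];
      for (int y = 0; y < Ho; ++y) {
        const double uy = wy[y];
        const arma::rowvec g = dY.row(base_out + x * Ho + y);
        dX.row(ca + y0[y]) += (1 - ux) * (1 - uy) * g;
        dX.row(ca + y1[y]) += (1 - ux) * uy * g;
        dX.row(cb + y0[y]) += ux * (1 - uy) * g;
        dX.row(cb + y1[y]) += ux * uy * g;
      }
    }
  }
  return dX;
}

// Fused batch-norm + ReLU.  Z is the conv output; mu/invstd are the
// normalization statistics (batch or running).  Returns xhat and the
// post-activation Y; the ReLU mask is implicit in Y > 0.

// [[Rcpp::export(name = ".cpp_bn_act_forward")]]
List cpp_bn_act_forward(const arma::mat& Z, const arma::vec& mu,
                        const arma::vec& invstd, const arma::vec& gamma,
                        const arma::vec& beta) {
  const arma::uword n = Z.n_rows, C = Z.n_cols;
  arma::mat xhat(n, C), Y(n, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double m = mu(c), s = invstd(c), g = gamma(c), b = beta(c);
    const double* z = Z.colptr(c);
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    for (arma::uword i = 0; i < n; ++i) {
      const double v = (z[i] - m) * s;
      xh[i] = v;
      const double a = v * g + b;
      y[i] = a > 0 ? a : 0.0;
    }
  }
  return List::create(_["xhat"] = xhat, _["Y"] = Y);
}

// Backward of the fused block: applies the ReLU mask (Y > 0), then the
// batch-norm backward with batch statistics.  Returns dZ, dgamma, dbeta.

// [[Rcpp::export(name = ".cpp_bn_act_backward")]]
List cpp_bn_act_backward(const arma::mat& dY, const arma::mat& Y,
                         const arma::mat& xhat, const arma::vec& gamma,
                         const arma::vec& invstd) {
  const arma::uword n = dY.n_rows, C = dY.n_cols;
  arma::mat dZ(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double g = gamma(c), s = invstd(c);
    const double* dy = dY.colptr(c);
    const double* y = Y.colptr(c);
    const double* xh = xhat.colptr(c);
    double* dz = dZ.colptr(c);
    double sum_d = 0.0, sum_dx = 0.0, sum_g = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double d = (y[i] > 0) ? dy[i] : 0.0;
      dz[i] = d;                      // stash masked dY
      sum_d += d;
      sum_dx += d * xh[i];
    }
    dgamma(c) = sum_dx;
    dbeta(c) = sum_d;
    const double mh = g * sum_d / n;
    const double mxh = g * sum_dx / n;
    (void)sum_g;
    for (arma::uword i = 0; i < n; ++i) {
      dz[i] = (dz[i] * g - mh - xh[i] * mxh) * s;
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
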