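// 3x3 "same" convolution forward/backward on flattened spatial batches.
// An activation tensor (H, W, C, N) is a matrix with H*W*N rows
// (row = i + j*H + n*H*W, zero-based) and C columns, column-major.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".conv3x3_fwd")]]
NumericMatrix conv3x3_fwd_cpp(NumericMatrix X, int H, int W, int N,
                              NumericVector Wk, NumericVector b,
                              double leak = -1.0) {
  IntegerVector wd = Wk.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int R = H * W * N;
  if (X.ncol() != cin || X.nrow() != R) stop("conv3x3: shape mismatch");
  NumericMatrix Y(R, cout);
  const double *x = X.begin(), *w = Wk.begin(), *bb = b.begin();
  double *y = Y.begin();

  for (int co = 0; co < cout; ++co) {
    double *yc = y + (size_t)co * R;
    const double bv = bb[co];
    for (int r = 0; r < R; ++r) yc[r] = bv;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = x + (size_t)ci * R;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double wv = w[(di + 1) + 3 * (dj + 1) + 9 * (ci + cin * co)];
          if (wv == 0.0) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int n = 0; n < N; ++n) {
            const size_t base = (size_t)n * H * W;
            for (int j = j0; j < j1; ++j) {
              const size_t dst = base + (size_t)j * H;
              const size_t src = base + (size_t)(j + dj) * H + di;
              for (int i = i0; i < i1; ++i)
                yc[dst + i] += wv * xc[src + i];
            }
          }
        }
      }
    }
  }
  if (leak >= 0.0) {
    for (size_t k = 0; k < (size_t)R * cout; ++k)
      if (y[k] < 0) y[k] *= leak;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3x3_bwd")]]
List conv3x3_bwd_cpp(NumericMatrix dY, NumericMatrix X, int H, int W, int N,
                     NumericVector Wk) {
  IntegerVector wd = Wk.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int R = H * W * N;
  NumericMatrix dX(R, cin);
  NumericVector dW(3 * 3 * cin * cout);
  dW.attr("dim") = IntegerVector::create(3, 3, cin, cout);
  NumericVector db(cout);
  const double *dy = dY.begin(), *x = X.begin(), *w = Wk.begin();
  double *dx = dX.begin(), *dw = dW.begin();

  for (int co = 0; co < cout; ++co) {
    const double *dyc = dy + (size_t)co * R;
    double acc = 0.0;
    for (int r = 0; r < R; ++r) acc += dyc[r];
    db[co] = acc;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = x + (size_t)ci * R;
      double *dxc = dx + (size_t)ci * R;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double wv = w[(di + 1) + 3 * (dj + 1) + 9 * (ci + cin * co)];
          double gw = 0.0;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int n = 0; n < N; ++n) {
            const size_t base = (size_t)n * H * W;
            for (int j = j0; j < j1; ++j) {
              const size_t dst = base + (size_t)j * H;
              const size_t src = base + (size_t)(j + dj) * H + di;
              for (int i = i0; i < i1; ++i) {
                const double g = dyc[dst + i];
                gw += g * xc[src + i];
                dxc[src + i] += g * wv;
              }
            }
          }
          dw[(di + 1) + 3 * (dj + 1) + 9 * (ci + cin * co)] = gw;
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericMatrix relu_bwd_cpp(NumericMatrix dY, NumericMatrix A,
                           double leak = 0.0) {
  NumericMatrix out(dY.nrow(), dY.ncol());
  const double *dy = dY.begin(), *a = A.begin();
  double *o = out.begin();
  const size_t K = (size_t)dY.nrow() * dY.ncol();
  for (size_t k = 0; k < K; ++k) o[k] = a[k] > 0 ? dy[k] : leak * dy[k];
  return out;
}
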