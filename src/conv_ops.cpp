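// Hot-path tensor ops for the shallow CNN: 3x3 stride-1 pad-1 convolution
// (forward and backward) and 2x2 stride-2 max pooling. Batches are plain
// numeric matrices with ONE IMAGE PER COLUMN, so each image is contiguous
// in memory; within a column the layout matches an R array of
// dim c(H, W, C): index = y + H*x + H*W*c (0-based). Inner loops run down
// contiguous y ranges and auto-vectorize. Single-threaded, deterministic.

#include <Rcpp.h>
using namespace Rcpp;

// X: (H*W*Cin) x n; Wm: (9*Cin) x Cout with row index k = dy + 3*dx + 9*ci
// (offsets dy, dx in {0,1,2} standing for {-1,0,+1}); bias length Cout.
// Returns (H*W*Cout) x n.
// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& X, int H, int W, int Cin,
                               const NumericMatrix& Wm,
                               const NumericVector& bias) {
  const int n = X.ncol();
  const int Cout = Wm.ncol();
  const int HW = H * W;
  NumericMatrix out(HW * Cout, n);
  for (int img = 0; img < n; ++img) {
    const double* xc = &X(0, img);
    double* oc_all = &out(0, img);
    for (int oc = 0; oc < Cout; ++oc) {
      double* op = oc_all + (R_xlen_t)HW * oc;
      std::fill(op, op + HW, bias[oc]);
      for (int ci = 0; ci < Cin; ++ci) {
        const double* ip = xc + (R_xlen_t)HW * ci;
        for (int dx = 0; dx < 3; ++dx) {
          const int x_lo = std::max(0, 1 - dx);
          const int x_hi = std::min(W - 1, W - dx);
          for (int dy = 0; dy < 3; ++dy) {
            const double w = Wm(dy + 3 * dx + 9 * ci, oc);
            if (w == 0.0) continue;
            const int y_lo = std::max(0, 1 - dy);
            const int y_hi = std::min(H - 1, H - dy);
            for (int x = x_lo; x <= x_hi; ++x) {
              double* o = op + (R_xlen_t)H * x + y_lo;
              const double* in = ip + (R_xlen_t)H * (x + dx - 1) +
                (y_lo + dy - 1);
              for (int y = y_lo; y <= y_hi; ++y) *o++ += w * *in++;
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradients of the same convolution. dOut: (H*W*Cout) x n. Returns dW
// ((9*Cin) x Cout), db (Cout), and dX ((H*W*Cin) x n) when want_dx.
// [[Rcpp::export]]
List cpp_conv_backward(const NumericMatrix& X, const NumericMatrix& dOut,
                       int H, int W, int Cin, const NumericMatrix& Wm,
                       bool want_dx) {
  const int n = X.ncol();
  const int Cout = Wm.ncol();
  const int HW = H * W;
  NumericMatrix dW(9 * Cin, Cout);
  NumericVector db(Cout);
  NumericMatrix dX(want_dx ? HW * Cin : 1, want_dx ? n : 1);
  for (int img = 0; img < n; ++img) {
    const double* xc = &X(0, img);
    const double* gc = &dOut(0, img);
    double* dxc = want_dx ? &dX(0, img) : nullptr;
    for (int oc = 0; oc < Cout; ++oc) {
      const double* gp = gc + (R_xlen_t)HW * oc;
      double acc_b = 0.0;
      for (int i = 0; i < HW; ++i) acc_b += gp[i];
      db[oc] += acc_b;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* ip = xc + (R_xlen_t)HW * ci;
        double* dip = want_dx ? dxc + (R_xlen_t)HW * ci : nullptr;
        for (int dx = 0; dx < 3; ++dx) {
          const int x_lo = std::max(0, 1 - dx);
          const int x_hi = std::min(W - 1, W - dx);
          for (int dy = 0; dy < 3; ++dy) {
            const int k = dy + 3 * dx + 9 * ci;
            const double w = Wm(k, oc);
            const int y_lo = std::max(0, 1 - dy);
            const int y_hi = std::min(H - 1, H - dy);
            double acc_w = 0.0;
            for (int x = x_lo; x <= x_hi; ++x) {
              const double* g = gp + (R_xlen_t)H * x + y_lo;
              const R_xlen_t in_off = (R_xlen_t)H * (x + dx - 1) +
                (y_lo + dy - 1);
              const double* in = ip + in_off;
              const int len = y_hi - y_lo + 1;
              for (int y = 0; y < len; ++y) acc_w += in[y] * g[y];
              if (want_dx) {
                double* di = dip + in_off;
                for (int y = 0; y < len; ++y) di[y] += w * g[y];
              }
            }
            dW(k, oc) += acc_w;
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// 2x2 stride-2 max pooling on (H*W*C) x n input. Returns the pooled batch
// ((H/2*W/2*C) x n) and the 1-based flat winner index (into the input
// column) per pooled position. Ties resolve to the first element in
// (dy, dx) scan order.
// [[Rcpp::export]]
List cpp_maxpool_forward(const NumericMatrix& X, int H, int W, int C) {
  const int n = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HWo = Ho * Wo;
  NumericMatrix out(HWo * C, n);
  IntegerMatrix amax(HWo * C, n);
  for (int img = 0; img < n; ++img) {
    const double* xc = &X(0, img);
    double* op = &out(0, img);
    int* ap = &amax(0, img);
    for (int c = 0; c < C; ++c) {
      const int in_base = H * W * c;
      for (int x = 0; x < Wo; ++x) {
        for (int y = 0; y < Ho; ++y) {
          double best = R_NegInf;
          int besti = -1;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              const int i = in_base + H * (2 * x + dx) + 2 * y + dy;
              if (xc[i] > best) { best = xc[i]; besti = i; }
            }
          }
          const int o = HWo * c + Ho * x + y;
          op[o] = best;
          ap[o] = besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(const NumericMatrix& dOut,
                                   const IntegerMatrix& argmax, int in_len) {
  const int n = dOut.ncol();
  NumericMatrix dX(in_len, n);
  for (int img = 0; img < n; ++img) {
    const double* gp = &dOut(0, img);
    const int* ap = &argmax(0, img);
    double* dp = &dX(0, img);
    for (int j = 0; j < dOut.nrow(); ++j) dp[ap[j] - 1] += gp[j];
  }
  return dX;
}
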