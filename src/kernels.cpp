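// Low-level numeric kernels for the 3D regression U-Net and phantom generator.
// Tensor layout: column-major R arrays with dim c(C, D, H, W, N)
// (channel fastest, batch slowest). All convolutions are "valid" (no padding),
// stride 1, isotropic cubic kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-D tensor (C, D, H, W, N)");
  return d;
}

// Fill the transposed patch matrix PT (nout x k^3*Cin): column (cin, a, b,
// cc) holds, over output voxels, the input value at channel cin and offset
// (a,b,cc). Runs over the fastest output axis are contiguous in both source
// (stride Cin) and destination (stride 1), gathered with a strided copy.
static void im2colT(const double* xn, arma::mat& PT, int Cin, int D, int H,
                    int W, int OD, int OH, int OW, int k) {
  const int nout = OD * OH * OW;
  for (int cc = 0; cc < k; ++cc)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a)
        for (int ci = 0; ci < Cin; ++ci) {
          double* col = PT.colptr(ci + Cin * (a + k * (b + k * cc)));
          for (int ow = 0; ow < OW; ++ow)
            for (int oh = 0; oh < OH; ++oh) {
              const double* src = xn + ci + static_cast<R_xlen_t>(Cin) *
                (a + static_cast<R_xlen_t>(D) * ((oh + b) + static_cast<R_xlen_t>(H) * (ow + cc)));
              double* dst = col + OD * (oh + static_cast<R_xlen_t>(OH) * ow);
              for (int od = 0; od < OD; ++od) dst[od] = src[static_cast<R_xlen_t>(Cin) * od];
            }
          (void)nout;
        }
}

// Valid 3D convolution via im2col + one GEMM per sample.
// x: (Cin, D, H, W, N); w: (Cout, Cin, k, k, k); bias: Cout.
// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = tensor_dim(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weight must be 5-D (Cout, Cin, k, k, k)");
  const int Cin = xd[0], D = xd[1], H = xd[2], W = xd[3], N = xd[4];
  const int Cout = wd[0], k = wd[2];
  if (wd[1] != Cin || wd[3] != k || wd[4] != k)
    stop("weight dims inconsistent with input channels/kernel");
  const int OD = D - k + 1, OH = H - k + 1, OW = W - k + 1;
  if (OD < 1 || OH < 1 || OW < 1) stop("input smaller than kernel");
  const int nout = OD * OH * OW;
  const int kc = k * k * k * Cin;

  NumericVector y(static_cast<R_xlen_t>(Cout) * nout * N);
  y.attr("dim") = IntegerVector::create(Cout, OD, OH, OW, N);

  // weight array viewed as (Cout x k^3*Cin) without copy (column-major)
  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, kc, false, true);
  arma::mat PT(nout, kc);
  arma::mat YT(nout, Cout);
  const double* xp = x.begin();
  double* yp = y.begin();

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + static_cast<R_xlen_t>(n) * Cin * D * H * W;
    im2colT(xn, PT, Cin, D, H, W, OD, OH, OW, k);
    YT = PT * Wm.t();
    double* yn = yp + static_cast<R_xlen_t>(n) * Cout * nout;
    for (int c = 0; c < Cout; ++c) {
      const double* src = YT.colptr(c);
      const double bc = bias[c];
      for (int j = 0; j < nout; ++j) yn[c + static_cast<R_xlen_t>(Cout) * j] = src[j] + bc;
    }
  }
  return y;
}

// Backward pass of the valid 3D convolution (re-gathers patches).
// Returns list(dx, dw, db). dy: (Cout, OD, OH, OW, N).
// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = tensor_dim(x);
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = tensor_dim(dy);
  const int Cin = xd[0], D = xd[1], H = xd[2], W = xd[3], N = xd[4];
  const int Cout = wd[0], k = wd[2];
  const int OD = yd[1], OH = yd[2], OW = yd[3];
  if (yd[0] != Cout || yd[4] != N || OD != D - k + 1 || OH != H - k + 1 || OW != W - k + 1)
    stop("dy dims inconsistent");
  const int nout = OD * OH * OW;
  const int kc = k * k * k * Cin;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, kc, false, true);
  arma::mat dWm(dw.begin(), Cout, kc, false, true);
  arma::mat PT(nout, kc), DYT(nout, Cout), DPT(nout, kc);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + static_cast<R_xlen_t>(n) * Cin * D * H * W;
    double* dxn = dxp + static_cast<R_xlen_t>(n) * Cin * D * H * W;
    const double* dyn = dyp + static_cast<R_xlen_t>(n) * Cout * nout;
    for (int c = 0; c < Cout; ++c) {
      double* dst = DYT.colptr(c);
      double acc = 0.0;
      for (int j = 0; j < nout; ++j) {
        const double v = dyn[c + static_cast<R_xlen_t>(Cout) * j];
        dst[j] = v;
        acc += v;
      }
      db[c] += acc;
    }
    im2colT(xn, PT, Cin, D, H, W, OD, OH, OW, k);
    dWm += (PT.t() * DYT).t();
    DPT = DYT * Wm;
    // col2im scatter-add
    for (int cc = 0; cc < k; ++cc)
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a)
          for (int ci = 0; ci < Cin; ++ci) {
            const double* col = DPT.colptr(ci + Cin * (a + k * (b + k * cc)));
            for (int ow = 0; ow < OW; ++ow)
              for (int oh = 0; oh < OH; ++oh) {
                double* dst = dxn + ci + static_cast<R_xlen_t>(Cin) *
                  (a + static_cast<R_xlen_t>(D) * ((oh + b) + static_cast<R_xlen_t>(H) * (ow + cc)));
                const double* src = col + OD * (oh + static_cast<R_xlen_t>(OH) * ow);
                for (int od = 0; od < OD; ++od) dst[static_cast<R_xlen_t>(Cin) * od] += src[od];
              }
          }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 average pooling, stride 2 (spatial dims must be even).
// [[Rcpp::export(name = ".avgPool2Forward")]]
NumericVector avgpool2_forward(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3], N = xd[4];
  if (D % 2 || H % 2 || W % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const int OD = D / 2, OH = H / 2, OW = W / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * OD * OH * OW * N);
  y.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          double* dst = yp + static_cast<R_xlen_t>(C) *
            (od + static_cast<R_xlen_t>(OD) * (oh + static_cast<R_xlen_t>(OH) * (ow + static_cast<R_xlen_t>(OW) * n)));
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                const double* src = xp + static_cast<R_xlen_t>(C) *
                  ((2 * od + dd) + static_cast<R_xlen_t>(D) * ((2 * oh + dh) + static_cast<R_xlen_t>(H) * ((2 * ow + dw2) + static_cast<R_xlen_t>(W) * n)));
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
          for (int c = 0; c < C; ++c) dst[c] *= 0.125;
        }
  }
  return y;
}

// [[Rcpp::export(name = ".avgPool2Backward")]]
NumericVector avgpool2_backward(NumericVector dy) {
  IntegerVector yd = tensor_dim(dy);
  const int C = yd[0], OD = yd[1], OH = yd[2], OW = yd[3], N = yd[4];
  const int D = OD * 2, H = OH * 2, W = OW * 2;
  NumericVector dx(static_cast<R_xlen_t>(C) * D * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, D, H, W, N);
  const double* yp = dy.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double* src = yp + static_cast<R_xlen_t>(C) *
            (od + static_cast<R_xlen_t>(OD) * (oh + static_cast<R_xlen_t>(OH) * (ow + static_cast<R_xlen_t>(OW) * n)));
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                double* dst = xp + static_cast<R_xlen_t>(C) *
                  ((2 * od + dd) + static_cast<R_xlen_t>(D) * ((2 * oh + dh) + static_cast<R_xlen_t>(H) * ((2 * ow + dw2) + static_cast<R_xlen_t>(W) * n)));
                for (int c = 0; c < C; ++c) dst[c] += 0.125 * src[c];
              }
        }
  }
  return dx;
}

// Nearest-neighbour ("repeat") 2x upsampling.
// [[Rcpp::export(name = ".upsample2Forward")]]
NumericVector upsample2_forward(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3], N = xd[4];
  const int OD = D * 2, OH = H * 2, OW = W * 2;
  NumericVector y(static_cast<R_xlen_t>(C) * OD * OH * OW * N);
  y.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double* src = xp + static_cast<R_xlen_t>(C) *
            ((od / 2) + static_cast<R_xlen_t>(D) * ((oh / 2) + static_cast<R_xlen_t>(H) * ((ow / 2) + static_cast<R_xlen_t>(W) * n)));
          double* dst = yp + static_cast<R_xlen_t>(C) *
            (od + static_cast<R_xlen_t>(OD) * (oh + static_cast<R_xlen_t>(OH) * (ow + static_cast<R_xlen_t>(OW) * n)));
          std::memcpy(dst, src, sizeof(double) * C);
        }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2Backward")]]
NumericVector upsample2_backward(NumericVector dy) {
  IntegerVector yd = tensor_dim(dy);
  const int C = yd[0], OD = yd[1], OH = yd[2], OW = yd[3], N = yd[4];
  if (OD % 2 || OH % 2 || OW % 2) stop("dims must be even");
  const int D = OD / 2, H = OH / 2, W = OW / 2;
  NumericVector dx(static_cast<R_xlen_t>(C) * D * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, D, H, W, N);
  const double* yp = dy.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double* src = yp + static_cast<R_xlen_t>(C) *
            (od + static_cast<R_xlen_t>(OD) * (oh + static_cast<R_xlen_t>(OH) * (ow + static_cast<R_xlen_t>(OW) * n)));
          double* dst = xp + static_cast<R_xlen_t>(C) *
            ((od / 2) + static_cast<R_xlen_t>(D) * ((oh / 2) + static_cast<R_xlen_t>(H) * ((ow / 2) + static_cast<R_xlen_t>(W) * n)));
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
  }
  return dx;
}

// Separable Gaussian smoothing of a single 3-D volume, zero-padded boundary.
// sigma in voxels; kernel truncated at 3.5 sigma.
// [[Rcpp::export(name = ".gaussSmooth3d")]]
NumericVector gauss_smooth3d(NumericVector x, double sigma) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("expected a 3-D volume");
  if (sigma <= 0) return clone(x);
  const int D = xd[0], H = xd[1], W = xd[2];
  const int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += kern[i + r]; }
  for (auto& v : kern) v /= s;

  NumericVector a = clone(x), b(x.size());
  b.attr("dim") = xd;
  auto idx = [&](int d, int h, int w) {
    return static_cast<R_xlen_t>(d) + static_cast<R_xlen_t>(D) * (h + static_cast<R_xlen_t>(H) * w);
  };
  // axis 1 (d)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int dd = d + i;
          if (dd >= 0 && dd < D) acc += kern[i + r] * a[idx(dd, h, w)];
        }
        b[idx(d, h, w)] = acc;
      }
  // axis 2 (h)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int hh = h + i;
          if (hh >= 0 && hh < H) acc += kern[i + r] * b[idx(d, hh, w)];
        }
        a[idx(d, h, w)] = acc;
      }
  // axis 3 (w)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int ww = w + i;
          if (ww >= 0 && ww < W) acc += kern[i + r] * a[idx(d, h, ww)];
        }
        b[idx(d, h, w)] = acc;
      }
  return b;
}
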