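// Low-level neural-network primitives operating on 4-d arrays laid out
// (H, W, C, N) in R's column-major order.  Convolutions use TensorFlow-style
// "same" zero padding: out = ceil(in/stride), total pad = (out-1)*stride+k-in,
// split floor/ceil with the extra row/column at the bottom/right.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x, const char* what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("%s must be a 4-d array", what);
  IntegerVector dd(d);
  if (dd.size() != 4) stop("%s must be a 4-d array (H, W, C, N)", what);
  return dd;
}

// Fill the im2col block for output columns [w0, w0+wc) of sample n.
// A has Ho*wc rows and k*k*C columns; column index is kh + k*(kw + k*ci),
// matching the column-major layout of a (k, k, Cin, Cout) kernel array.
static void im2col_block(const double* xp, arma::mat& A,
                         int H, int W, int C, int k, int stride,
                         int pbh, int pbw, int Ho, int w0, int wc) {
  for (int ci = 0; ci < C; ci++) {
    const double* xc = xp + (R_xlen_t)H * W * ci;
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        int col = kh + k * (kw + k * ci);
        double* Ac = A.colptr(col);
        // stride 1: the valid output rows form one contiguous block copy
        int lo = (stride == 1) ? std::max(0, pbh - kh) : -1;
        int hi = (stride == 1) ? std::min(Ho, H + pbh - kh) : -1;
        for (int j = 0; j < wc; j++) {
          int wo = w0 + j;
          int iw = wo * stride - pbw + kw;
          double* Aj = Ac + (size_t)Ho * j;
          if (iw < 0 || iw >= W) {
            std::fill(Aj, Aj + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (R_xlen_t)H * iw;
          if (stride == 1) {
            if (lo > 0) std::fill(Aj, Aj + lo, 0.0);
            if (hi > lo)
              std::copy(xcol + lo - pbh + kh, xcol + hi - pbh + kh, Aj + lo);
            if (hi < Ho) std::fill(Aj + std::max(hi, 0), Aj + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ho++) {
              int ih = ho * stride - pbh + kh;
              Aj[ho] = (ih >= 0 && ih < H) ? xcol[ih] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, int stride) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input has %d channels, kernel expects %d", C, Cin);
  int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  int pbh = std::max((Ho - 1) * stride + k - H, 0) / 2;
  int pbw = std::max((Wo - 1) * stride + k - W, 0) / 2;
  int kkC = k * k * C;

  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  int chunk = std::max(1, std::min(Wo, (int)(250000 / std::max(1, Ho * kkC))));
  arma::mat A((size_t)Ho * chunk, kkC);
  for (int n = 0; n < N; n++) {
    const double* xp = x.begin() + (R_xlen_t)H * W * C * n;
    double* op = out.begin() + (R_xlen_t)Ho * Wo * Cout * n;
    for (int w0 = 0; w0 < Wo; w0 += chunk) {
      int wc = std::min(chunk, Wo - w0);
      if ((int)A.n_rows != Ho * wc) A.set_size((size_t)Ho * wc, kkC);
      im2col_block(xp, A, H, W, C, k, stride, pbh, pbw, Ho, w0, wc);
      arma::mat Y = A * Wm;
      for (int co = 0; co < Cout; co++) {
        std::copy(Y.colptr(co), Y.colptr(co) + (size_t)Ho * wc,
                  op + (R_xlen_t)Ho * Wo * co + (R_xlen_t)Ho * w0);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w"), yd = dims4(dy, "dy");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  if (yd[0] != Ho || yd[1] != Wo || yd[2] != Cout || yd[3] != N)
    stop("dy shape does not match the forward output");
  int pbh = std::max((Ho - 1) * stride + k - H, 0) / 2;
  int pbw = std::max((Wo - 1) * stride + k - W, 0) / 2;
  int kkC = k * k * C;

  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector dx((R_xlen_t)x.size());
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kkC, Cout, false, true);

  int chunk = std::max(1, std::min(Wo, (int)(250000 / std::max(1, Ho * kkC))));
  arma::mat A((size_t)Ho * chunk, kkC);
  arma::mat dYc((size_t)Ho * chunk, Cout);
  for (int n = 0; n < N; n++) {
    const double* xp = x.begin() + (R_xlen_t)H * W * C * n;
    const double* dyp = dy.begin() + (R_xlen_t)Ho * Wo * Cout * n;
    double* dxp = dx.begin() + (R_xlen_t)H * W * C * n;
    for (int w0 = 0; w0 < Wo; w0 += chunk) {
      int wc = std::min(chunk, Wo - w0);
      if ((int)A.n_rows != Ho * wc) {
        A.set_size((size_t)Ho * wc, kkC);
        dYc.set_size((size_t)Ho * wc, Cout);
      }
      im2col_block(xp, A, H, W, C, k, stride, pbh, pbw, Ho, w0, wc);
      for (int co = 0; co < Cout; co++) {
        std::copy(dyp + (R_xlen_t)Ho * Wo * co + (R_xlen_t)Ho * w0,
                  dyp + (R_xlen_t)Ho * Wo * co + (R_xlen_t)Ho * (w0 + wc),
                  dYc.colptr(co));
      }
      dWm += A.t() * dYc;
      arma::mat dA = dYc * Wm.t();
      // col2im: scatter-add dA back onto dx
      for (int ci = 0; ci < C; ci++) {
        double* xc = dxp + (R_xlen_t)H * W * ci;
        for (int kw = 0; kw < k; kw++) {
          for (int kh = 0; kh < k; kh++) {
            int col = kh + k * (kw + k * ci);
            const double* Ac = dA.colptr(col);
            int lo = (stride == 1) ? std::max(0, pbh - kh) : -1;
            int hi = (stride == 1) ? std::min(Ho, H + pbh - kh) : -1;
            for (int j = 0; j < wc; j++) {
              int iw = (w0 + j) * stride - pbw + kw;
              if (iw < 0 || iw >= W) continue;
              const double* Aj = Ac + (size_t)Ho * j;
              double* xcol = xc + (R_xlen_t)H * iw;
              if (stride == 1) {
                const double* src = Aj + lo;
                double* dst = xcol + lo - pbh + kh;
                for (int t = 0; t < hi - lo; t++) dst[t] += src[t];
              } else {
                for (int ho = 0; ho < Ho; ho++) {
                  int ih = ho * stride - pbh + kh;
                  if (ih >= 0 && ih < H) xcol[ih] += Aj[ho];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}



// Pixel-center bilinear interpolation weights for a x2 upsampling:
// source coordinate of output index i is (i + 0.5)/2 - 0.5, clamped.
static void up2_coords(int i, int n, int& i0, int& i1, double& f) {
  double src = (i + 0.5) / 2.0 - 0.5;
  i0 = (int)std::floor(src);
  f = src - i0;
  if (i0 < 0) { i0 = 0; i1 = 0; f = 0.0; }
  else if (i0 >= n - 1) { i0 = n - 1; i1 = n - 1; f = 0.0; }
  else i1 = i0 + 1;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = dims4(x, "x");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; i++) up2_coords(i, H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < Wo; j++) up2_coords(j, W, w0[j], w1[j], fw[j]);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* p = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      double* q = y.begin() + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; j++) {
        const double* c0 = p + (R_xlen_t)H * w0[j];
        const double* c1 = p + (R_xlen_t)H * w1[j];
        double* qc = q + (R_xlen_t)Ho * j;
        double a = 1.0 - fw[j], b = fw[j];
        for (int i = 0; i < Ho; i++) {
          double v0 = c0[h0[i]] * (1.0 - fh[i]) + c0[h1[i]] * fh[i];
          double v1 = c1[h0[i]] * (1.0 - fh[i]) + c1[h1[i]] * fh[i];
          qc[i] = a * v0 + b * v1;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dims4(dy, "dy");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  if (Ho != 2 * H || Wo != 2 * W) stop("dy shape does not match 2x upsampling");
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; i++) up2_coords(i, H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < Wo; j++) up2_coords(j, W, w0[j], w1[j], fw[j]);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* q = dy.begin() + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      double* p = dx.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; j++) {
        double* c0 = p + (R_xlen_t)H * w0[j];
        double* c1 = p + (R_xlen_t)H * w1[j];
        const double* qc = q + (R_xlen_t)Ho * j;
        double a = 1.0 - fw[j], b = fw[j];
        for (int i = 0; i < Ho; i++) {
          double g = qc[i];
          c0[h0[i]] += a * (1.0 - fh[i]) * g;
          c0[h1[i]] += a * fh[i] * g;
          c1[h0[i]] += b * (1.0 - fh[i]) * g;
          c1[h1[i]] += b * fh[i] * g;
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  RawVector mask(x.size());
  const double* p = x.begin();
  double* q = y.begin();
  Rbyte* mp = mask.begin();
  for (R_xlen_t i = 0; i < x.size(); i++) {
    bool pos = p[i] > 0;
    q[i] = pos ? p[i] : 0.0;
    mp[i] = pos;
  }
  return List::create(_["y"] = y, _["mask"] = mask);
}


// dy * mask * scale, used for both ReLU and dropout backward passes
// [[Rcpp::export]]
NumericVector cpp_mask_mul(NumericVector dy, RawVector mask, double scale) {
  if (dy.size() != mask.size()) stop("mask length mismatch");
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* p = dy.begin();
  const Rbyte* mp = mask.begin();
  double* q = out.begin();
  for (R_xlen_t i = 0; i < dy.size(); i++)
    q[i] = mp[i] ? p[i] * scale : 0.0;
  return out;
}

// Fused batch-norm -> ReLU -> inverted-dropout forward. One pass computes
// the batch statistics (training mode), a second writes the normalized,
// rectified, dropped output plus compact masks. Dropout uses a xorshift64
// generator seeded from R's RNG stream (one draw), so results remain
// reproducible under set.seed while avoiding millions of unif_rand calls.
// [[Rcpp::export]]
List cpp_post_forward(NumericVector z, NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar,
                      bool training, double eps, bool relu, double keep) {
  IntegerVector zd = dims4(z, "z");
  int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector m(C), v(C);
  if (training) {
    for (int c = 0; c < C; c++) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; n++) {
        const double* p = z.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t i = 0; i < plane; i++) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double cnt = (double)plane * N;
      m[c] = s / cnt;
      v[c] = std::max(s2 / cnt - m[c] * m[c], 0.0);
    }
  } else {
    m = clone(rmean);
    v = clone(rvar);
  }
  bool drop = keep < 1.0;
  NumericVector y(z.size());
  y.attr("dim") = zd;
  RawVector relu_mask(relu ? z.size() : 0);
  RawVector drop_mask(drop ? z.size() : 0);
  uint64_t rng = 0;
  if (drop) {
    rng = (uint64_t)(unif_rand() * 9007199254740992.0) | 1ull;
    for (int i = 0; i < 8; i++) { // warm up
      rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    }
  }
  double inv = drop ? 1.0 / keep : 1.0;
  for (int c = 0; c < C; c++) {
    double scale = gamma[c] / std::sqrt(v[c] + eps);
    double shift = beta[c] - m[c] * scale;
    for (int n = 0; n < N; n++) {
      R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* p = z.begin() + off;
      double* q = y.begin() + off;
      for (R_xlen_t i = 0; i < plane; i++) {
        double val = p[i] * scale + shift;
        if (relu) {
          bool pos = val > 0;
          relu_mask[off + i] = pos;
          if (!pos) val = 0;
        }
        if (drop) {
          rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
          bool on = (rng >> 11) * (1.0 / 9007199254740992.0) < keep;
          drop_mask[off + i] = on;
          val = on ? val * inv : 0.0;
        }
        q[i] = val;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = m, _["var"] = v,
                      _["relu_mask"] = relu_mask, _["drop_mask"] = drop_mask);
}

// Fused backward through dropout -> ReLU -> batch norm.
// [[Rcpp::export]]
List cpp_post_backward(NumericVector z, NumericVector dy, NumericVector gamma,
                       NumericVector m, NumericVector v, double eps,
                       RawVector relu_mask, RawVector drop_mask, double keep) {
  IntegerVector zd = dims4(z, "z");
  int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  double cnt = (double)plane * N;
  bool relu = relu_mask.size() > 0;
  bool drop = drop_mask.size() > 0;
  double inv = drop ? 1.0 / keep : 1.0;
  NumericVector dx(z.size());
  dx.attr("dim") = zd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; c++) {
    double invsd = 1.0 / std::sqrt(v[c] + eps);
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; n++) {
      R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* pz = z.begin() + off;
      const double* pd = dy.begin() + off;
      for (R_xlen_t i = 0; i < plane; i++) {
        double g = pd[i];
        if (drop) g = drop_mask[off + i] ? g * inv : 0.0;
        if (relu && !relu_mask[off + i]) g = 0.0;
        s1 += g;
        s2 += g * (pz[i] - m[c]) * invsd;
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    double a = s1 / cnt, b = s2 / cnt, gg = gamma[c] * invsd;
    for (int n = 0; n < N; n++) {
      R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* pz = z.begin() + off;
      const double* pd = dy.begin() + off;
      double* q = dx.begin() + off;
      for (R_xlen_t i = 0; i < plane; i++) {
        double g = pd[i];
        if (drop) g = drop_mask[off + i] ? g * inv : 0.0;
        if (relu && !relu_mask[off + i]) g = 0.0;
        q[i] = gg * (g - a - (pz[i] - m[c]) * invsd * b);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
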