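// 2-d image utilities: mirror padding, mirror-boundary separable Gaussian
// blur, affine and displacement-field warps (bilinear or nearest, mirror
// fill), and 8-connected component labelling.  Matrices are row = image row.

#include <Rcpp.h>
using namespace Rcpp;

// Reflection without edge repetition (period 2n-2), valid for any integer.
static inline int mirr(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  i %= p;
  if (i < 0) i += p;
  return i < n ? i : p - i;
}

// [[Rcpp::export]]
NumericMatrix cpp_mirror_pad(NumericMatrix x, int top, int bottom,
                             int left, int right) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H + top + bottom, W + left + right);
  for (int j = 0; j < out.ncol(); j++) {
    int sj = mirr(j - left, W);
    for (int i = 0; i < out.nrow(); i++)
      out(i, j) = x(mirr(i - top, H), sj);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma) {
  if (sigma <= 0) return clone(x);
  int H = x.nrow(), W = x.ncol();
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& k : ker) k /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; j++)          // vertical pass
    for (int i = 0; i < H; i++) {
      double a = 0;
      for (int t = -r; t <= r; t++) a += ker[t + r] * x(mirr(i + t, H), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; j++)          // horizontal pass
    for (int i = 0; i < H; i++) {
      double a = 0;
      for (int t = -r; t <= r; t++) a += ker[t + r] * tmp(i, mirr(j + t, W));
      out(i, j) = a;
    }
  return out;
}

static inline double sample_mirror(const NumericMatrix& x, double ri, double ci,
                                   bool bilinear) {
  int H = x.nrow(), W = x.ncol();
  if (!bilinear) {
    return x(mirr((int)std::floor(ri + 0.5), H),
             mirr((int)std::floor(ci + 0.5), W));
  }
  int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
  double fr = ri - r0, fc = ci - c0;
  int r0m = mirr(r0, H), r1m = mirr(r0 + 1, H);
  int c0m = mirr(c0, W), c1m = mirr(c0 + 1, W);
  return (1 - fr) * ((1 - fc) * x(r0m, c0m) + fc * x(r0m, c1m)) +
         fr * ((1 - fc) * x(r1m, c0m) + fc * x(r1m, c1m));
}

// A maps output (row, col) to input coords:
// r_in = A[0]*r + A[1]*c + A[2];  c_in = A[3]*r + A[4]*c + A[5]
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix x, NumericVector A, bool bilinear) {
  if (A.size() != 6) stop("A must have 6 elements");
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double ri = A[0] * i + A[1] * j + A[2];
      double ci = A[3] * i + A[4] * j + A[5];
      out(i, j) = sample_mirror(x, ri, ci, bilinear);
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_displacement(NumericMatrix x, NumericMatrix dr,
                                    NumericMatrix dc, bool bilinear) {
  int H = x.nrow(), W = x.ncol();
  if (dr.nrow() != H || dr.ncol() != W || dc.nrow() != H || dc.ncol() != W)
    stop("displacement fields must match the image shape");
  NumericMatrix out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++)
      out(i, j) = sample_mirror(x, i + dr(i, j), j + dc(i, j), bilinear);
  return out;
}

// 8-connected labelling of the nonzero pixels of a binary matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix x) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) {
      if (x(i, j) == 0 || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      stack.push_back(i + H * j);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % H, cj = idx / H;
        for (int dj = -1; dj <= 1; dj++) {
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (x(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + H * nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
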