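#include <Rcpp.h>
using namespace Rcpp;

// Layout convention for feature maps: numeric array with dim = c(C, H, W, N)
// (channel fastest).  im2col produces a (C*kh*kw) x (oH*oW*N) matrix whose row
// index runs c fastest, then kernel-row ki, then kernel-col kj; convolution is
// then crossprod(Wmat, col) with Wmat = matrix(w, C*kh*kw, F) for weights
// stored as dim = c(C, kh, kw, F).

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector xdim,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix col(C * kh * kw, oH * oW * N);
  const double* xp = x.begin();
  double* cp = col.begin();
  const int R = C * kh * kw;
  for (int n = 0; n < N; ++n) {
    const int xoffn = C * H * W * n;
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        const int q = oi + oH * (oj + oW * n);
        double* colq = cp + (size_t)R * q;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = oj * sw - pw + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oi * sh - ph + ki;
            double* dst = colq + C * (ki + kh * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src = xp + xoffn + C * (h + H * w);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix col, IntegerVector xdim,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  NumericVector x(C * H * W * N);
  double* xp = x.begin();
  const double* cp = col.begin();
  const int R = C * kh * kw;
  for (int n = 0; n < N; ++n) {
    const int xoffn = C * H * W * n;
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        const int q = oi + oH * (oj + oW * n);
        const double* colq = cp + (size_t)R * q;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = oj * sw - pw + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oi * sh - ph + ki;
            if (h < 0 || h >= H) continue;
            const double* src = colq + C * (ki + kh * kj);
            double* dst = xp + xoffn + C * (h + H * w);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  x.attr("dim") = xdim;
  return x;
}

// Max pooling; returns pooled values and 1-based argmax linear indices into x.
// [[Rcpp::export(name = ".maxpool_cpp")]]
List maxpool_cpp(NumericVector x, IntegerVector xdim,
                 int kh, int kw, int sh, int sw, int ph, int pw) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  NumericVector y(C * oH * oW * N);
  IntegerVector amax(C * oH * oW * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const int xoffn = C * H * W * n;
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int besti = -1;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = oj * sw - pw + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = oi * sh - ph + ki;
              if (h < 0 || h >= H) continue;
              const int idx = xoffn + c + C * (h + H * w);
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const int yq = c + C * (oi + oH * (oj + oW * n));
          y[yq] = (besti >= 0) ? best : 0.0;
          amax[yq] = besti + 1;  // 1-based; 0 if window fully in padding
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, oH, oW, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (int k = 0; k < dy.size(); ++k)
    if (argmax[k] > 0) dx[argmax[k] - 1] += dy[k];
  dx.attr("dim") = xdim;
  return dx;
}

// Confocal sum: for one frequency bin, A(r) = sum_ij dX[i,j] * conj(H[i,r]) * conj(H[j,r]) * conj(S)
// is evaluated in R with complex matrix algebra; no C++ needed there.
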