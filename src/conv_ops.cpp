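// Stride-1 2-D convolution kernels (im2col + GEMM) used by the network layers.
// Compute is single-precision: activations/weights arrive as R doubles, are
// narrowed to float for the GEMM, and results are widened back. All shape
// handling assumes the package's (H, W, C, N) column-major tensor layout and
// (k, k, Cin, Cout) weight layout, so matrix(w, k*k*Cin, Cout) lines up with
// the im2col column ordering (di fastest, then dj, then channel). All batch
// samples are stacked into a single GEMM; when the stacked spatial extent is
// small relative to the channel count the transposed product is used instead
// (better BLAS shapes for the deep low-resolution stages).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill rows [rowOff, rowOff + Ho*Wo) of P with the im2col expansion of one
// sample (P has N*Ho*Wo rows).
static void im2col(const float* x, int H, int W, int C, int k, int pad,
                   arma::fmat& P, std::size_t rowOff) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        float* col = P.colptr(q) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dj - pad;
          float* dst = col + (std::size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0f);
            continue;
          }
          const float* src = xc + (std::size_t)wi * H;
          if (pad == 0) {
            std::copy(src, src + Ho, dst);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho + di - pad;
              dst[ho] = (hi < 0 || hi >= H) ? 0.0f : src[hi];
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::fmat& P, std::size_t rowOff, int H, int W,
                   int C, int k, int pad, float* x) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  std::fill(x, x + (std::size_t)H * W * C, 0.0f);
  for (int c = 0; c < C; ++c) {
    float* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        const float* col = P.colptr(q) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dj - pad;
          if (wi < 0 || wi >= W) continue;
          float* dst = xc + (std::size_t)wi * H;
          const float* src = col + (std::size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + di - pad;
            if (hi >= 0 && hi < H) dst[hi] += src[ho];
          }
        }
      }
    }
  }
}

static arma::fvec as_float(const NumericVector& v) {
  arma::fvec out(v.size());
  const double* p = v.begin();
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)p[i];
  return out;
}

// Persistent scratch pools for the large im2col workspaces. A fresh
// allocation per call would go straight to mmap/munmap and pay the
// kernel's page-zeroing cost (seconds at 480x480 feature sizes); reusing
// one buffer amortises that away.
static std::vector<float>& scratch(int which, std::size_t n) {
  static std::vector<float> bufs[2];
  // release grossly oversized buffers (e.g. after a full-resolution pass)
  // so small-scale work does not pin hundreds of megabytes
  if (bufs[which].size() > 4 * n && bufs[which].size() > (32u << 20))
    std::vector<float>().swap(bufs[which]);
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// postA/postB: optional per-output-channel affine applied after the
// convolution (used to fold inference-mode batch norm into the kernel);
// relu: clamp negatives during the output copy.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector b,
                             int k, int pad,
                             NumericVector postA, NumericVector postB,
                             bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = (int)(w.size() / ((std::size_t)k * k * C));
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const std::size_t hw = (std::size_t)Ho * Wo;
  arma::fvec xf = as_float(x), wf = as_float(w), bf = as_float(b);
  arma::fmat Wm(wf.memptr(), (std::size_t)k * k * C, Cout, false, true);
  const std::size_t pn = hw * N * (std::size_t)k * k * C;
  arma::fmat P(scratch(0, pn).data(), hw * N, (std::size_t)k * k * C,
               false, true);
  for (int n = 0; n < N; ++n)
    im2col(xf.memptr() + (std::size_t)n * H * W * C, H, W, C, k, pad, P,
           hw * n);
  arma::fmat Y;
  if (hw * N >= 128 || hw * N >= (std::size_t)Cout) {
    Y = P * Wm;
  } else {
    Y = (Wm.t() * P.t()).t();
  }
  Y.each_row() += bf.t();
  const bool affine = postA.size() == Cout;
  NumericVector y(hw * Cout * N);
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + hw * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Y.colptr(co) + hw * n;
      double* dst = yp + hw * co;
      const float a = affine ? (float)postA[co] : 1.0f;
      const float sh = affine ? (float)postB[co] : 0.0f;
      if (affine && relu) {
        for (std::size_t i = 0; i < hw; ++i) {
          const float v = a * src[i] + sh;
          dst[i] = v > 0.0f ? v : 0.0;
        }
      } else if (affine) {
        for (std::size_t i = 0; i < hw; ++i) dst[i] = a * src[i] + sh;
      } else if (relu) {
        for (std::size_t i = 0; i < hw; ++i)
          dst[i] = src[i] > 0.0f ? src[i] : 0.0;
      } else {
        for (std::size_t i = 0; i < hw; ++i) dst[i] = src[i];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, NumericVector dy,
                    int k, int pad, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = (int)(w.size() / ((std::size_t)k * k * C));
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const std::size_t hw = (std::size_t)Ho * Wo;
  arma::fvec xf = as_float(x), wf = as_float(w), dyf = as_float(dy);
  arma::fmat Wm(wf.memptr(), (std::size_t)k * k * C, Cout, false, true);
  // Stack upstream gradients: dY (N*HoWo, Cout)
  arma::fmat dY(hw * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::copy(dyf.memptr() + hw * (Cout * n + co),
                dyf.memptr() + hw * (Cout * n + co) + hw,
                dY.colptr(co) + hw * n);
  const std::size_t pn = hw * N * (std::size_t)k * k * C;
  arma::fmat P(scratch(0, pn).data(), hw * N, (std::size_t)k * k * C,
               false, true);
  for (int n = 0; n < N; ++n)
    im2col(xf.memptr() + (std::size_t)n * H * W * C, H, W, C, k, pad, P,
           hw * n);
  arma::fmat dW = P.t() * dY;
  arma::fvec db = arma::sum(dY, 0).t();
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) {
    arma::fmat dP(scratch(1, pn).data(), hw * N, (std::size_t)k * k * C,
                  false, true);
    if (hw * N >= 128 || hw * N >= (std::size_t)(k * k * C))
      dP = dY * Wm.t();
    else
      dP = (Wm * dY.t()).t();
    arma::fvec dxf((std::size_t)H * W * C);
    for (int n = 0; n < N; ++n) {
      col2im(dP, hw * n, H, W, C, k, pad, dxf.memptr());
      double* dxp = dx.begin() + (std::size_t)n * H * W * C;
      for (std::size_t i = 0; i < (std::size_t)H * W * C; ++i)
        dxp[i] = dxf[i];
    }
    dx.attr("dim") = xdim;
  }
  NumericVector dwR(w.size()), dbR(Cout);
  const float* dwp = dW.memptr();
  for (R_xlen_t i = 0; i < dwR.size(); ++i) dwR[i] = dwp[i];
  for (int i = 0; i < Cout; ++i) dbR[i] = db[i];
  dwR.attr("dim") = IntegerVector::create(k, k, C, Cout);
  return List::create(Named("dx") = dx, Named("dw") = dwR, Named("db") = dbR);
}

// In-place Adam update for one parameter array. The caller guarantees
// exclusive ownership of p/m/v (the training loop deep-copies parameters
// once up front); updating in place avoids reallocating ~1 GB of arrays
// per optimisation step at full model size.
// [[Rcpp::export]]
void cpp_adam(NumericVector p, NumericVector m, NumericVector v,
              NumericVector g, double lr, double b1, double b2,
              double eps, double bc1, double bc2) {
  double* pp = p.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  const double* pg = g.begin();
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
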