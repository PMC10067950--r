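// 2-D convolution forward/backward for [H, W, C] feature cubes, via
// im2col + BLAS GEMM. Weights are column-major R arrays [kh, kw, Cin, Cout];
// zero padding, integer stride, cross-correlation convention.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// patch matrix: rows = output pixels (column-major over HO x WO),
// cols = kernel taps (column-major over kh x kw x Cin)
static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int HO, int WO) {
  const int H = x.n_rows, W = x.n_cols, CI = x.n_slices;
  arma::mat xc(HO * WO, kh * kw * CI, arma::fill::zeros);
  for (int ci = 0; ci < CI; ++ci) {
    const double* xs = x.slice_memptr(ci);
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        double* col = xc.colptr(u + kh * (v + kw * ci));
        for (int j = 0; j < WO; ++j) {
          const int c = j * stride + v - pad;
          if (c < 0 || c >= W) continue;
          const double* src = xs + (size_t)c * H;
          double* dst = col + (size_t)j * HO;
          for (int i = 0; i < HO; ++i) {
            const int r = i * stride + u - pad;
            if (r >= 0 && r < H) dst[i] = src[r];
          }
        }
      }
    }
  }
  return xc;
}

// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const NumericVector& w,
                         const NumericVector& b, int kh, int kw,
                         int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, CI = x.n_slices;
  const int CO = b.size();
  const int HO = (H + 2 * pad - kh) / stride + 1;
  const int WO = (W + 2 * pad - kw) / stride + 1;
  const arma::mat xc = im2col(x, kh, kw, stride, pad, HO, WO);
  const arma::mat wm(const_cast<double*>(w.begin()), kh * kw * CI, CO, false);
  arma::mat ym = xc * wm;
  for (int co = 0; co < CO; ++co) ym.col(co) += b[co];
  arma::cube y(HO, WO, CO);
  std::copy(ym.memptr(), ym.memptr() + ym.n_elem, y.memptr());
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(const arma::cube& x, const NumericVector& w,
                   const arma::cube& dy, int kh, int kw,
                   int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, CI = x.n_slices;
  const int HO = dy.n_rows, WO = dy.n_cols, CO = dy.n_slices;
  const arma::mat xc = im2col(x, kh, kw, stride, pad, HO, WO);
  const arma::mat dym(const_cast<double*>(dy.memptr()), HO * WO, CO, false);
  const arma::mat wm(const_cast<double*>(w.begin()), kh * kw * CI, CO, false);

  arma::mat dwm = xc.t() * dym;
  NumericVector dw(dwm.begin(), dwm.end());
  NumericVector db(CO);
  for (int co = 0; co < CO; ++co) db[co] = arma::accu(dym.col(co));

  // col2im: scatter-add the patch-space gradient back to input pixels
  arma::mat dxc = dym * wm.t();
  arma::cube dx(H, W, CI, arma::fill::zeros);
  for (int ci = 0; ci < CI; ++ci) {
    double* dxs = dx.slice_memptr(ci);
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const double* col = dxc.colptr(u + kh * (v + kw * ci));
        for (int j = 0; j < WO; ++j) {
          const int c = j * stride + v - pad;
          if (c < 0 || c >= W) continue;
          double* dst = dxs + (size_t)c * H;
          const double* src = col + (size_t)j * HO;
          for (int i = 0; i < HO; ++i) {
            const int r = i * stride + u - pad;
            if (r >= 0 && r < H) dst[r] += src[i];
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// group normalisation: groups of channels normalised jointly over
// (H, W, C/g); returns y, xhat and per-group inverse std
// [[Rcpp::export]]
List gn_fw_cpp(const arma::cube& x, const NumericVector& gamma,
               const NumericVector& beta, int groups, double eps,
               bool relu) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int cg = C / groups;
  const size_t hw = (size_t)H * W;
  arma::cube y(H, W, C), xhat(H, W, C);
  NumericVector istd(groups);
  for (int g = 0; g < groups; ++g) {
    const size_t n = hw * cg;
    const double* xs = x.slice_memptr(g * cg);
    double mu = 0.0;
    for (size_t k = 0; k < n; ++k) mu += xs[k];
    mu /= n;
    double v = 0.0;
    for (size_t k = 0; k < n; ++k) { const double d = xs[k] - mu; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[g] = is;
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double* xc = x.slice_memptr(c);
      double* xh = xhat.slice_memptr(c);
      double* yc = y.slice_memptr(c);
      const double ga = gamma[c], be = beta[c];
      for (size_t k = 0; k < hw; ++k) {
        const double z = (xc[k] - mu) * is;
        xh[k] = z;
        const double o = ga * z + be;
        yc[k] = (relu && o < 0.0) ? 0.0 : o;
      }
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("istd") = istd);
}

// [[Rcpp::export]]
List gn_bw_cpp(const arma::cube& dy, const arma::cube& xhat,
               const NumericVector& istd, const NumericVector& gamma,
               int groups) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  const int cg = C / groups;
  const size_t hw = (size_t)H * W;
  arma::cube dx(H, W, C);
  NumericVector dgamma(C), dbeta(C);
  for (int g = 0; g < groups; ++g) {
    const double n = (double)hw * cg;
    double s1 = 0.0, s2 = 0.0;
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double* dyc = dy.slice_memptr(c);
      const double* xh = xhat.slice_memptr(c);
      double dg = 0.0, db = 0.0;
      for (size_t k = 0; k < hw; ++k) {
        dg += dyc[k] * xh[k];
        db += dyc[k];
      }
      dgamma[c] = dg; dbeta[c] = db;
      s1 += db * gamma[c];
      s2 += dg * gamma[c];
    }
    const double is = istd[g];
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double* dyc = dy.slice_memptr(c);
      const double* xh = xhat.slice_memptr(c);
      double* dxc = dx.slice_memptr(c);
      const double ga = gamma[c];
      for (size_t k = 0; k < hw; ++k) {
        dxc[k] = is * (dyc[k] * ga - s1 / n - xh[k] * s2 / n);
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
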