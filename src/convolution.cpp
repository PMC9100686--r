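#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Dense 3D convolution / pooling kernels used by the structural branch.
// Feature tensors are laid out as 5-d arrays (H, W, D, batch, channel) so
// that the innermost spatial index is contiguous; kernels are
// (K, K, K, in_channel, out_channel). Convolutions are stride-1 with
// "same" zero padding p = (K-1)/2, pooling is non-overlapping with floor
// division of the spatial extent (trailing voxels that do not fill a
// window are dropped).

static void get_dims5(const NumericVector& x, int* d, const char* what) {
  SEXP dimattr = x.attr("dim");
  if (Rf_isNull(dimattr)) stop("'%s' must be a 5-d array", what);
  IntegerVector dd(dimattr);
  if (dd.size() != 5) stop("'%s' must be a 5-d array", what);
  for (int i = 0; i < 5; ++i) d[i] = dd[i];
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector bias) {
  int dx[5], dw[5];
  get_dims5(x, dx, "x");
  get_dims5(w, dw, "w");
  const int H = dx[0], W = dx[1], D = dx[2], B = dx[3], Ci = dx[4];
  const int K = dw[0], Co = dw[4];
  if (dw[1] != K || dw[2] != K) stop("kernel must be cubic");
  if (dw[3] != Ci) stop("kernel input channels do not match input");
  if (K % 2 == 0) stop("kernel size must be odd for same padding");
  if (bias.size() != Co) stop("bias length must equal output channels");
  const int p = (K - 1) / 2;
  const size_t vox = (size_t)H * W * D;

  NumericVector out(vox * B * Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* po = out.begin();

  for (int co = 0; co < Co; ++co) {
    const double bv = bias[co];
    for (int b = 0; b < B; ++b) {
      double* o = po + vox * ((size_t)b + (size_t)B * co);
      for (size_t v = 0; v < vox; ++v) o[v] = bv;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* in = px + vox * ((size_t)b + (size_t)B * ci);
        for (int kk = 0; kk < K; ++kk) {
          const int dk = kk - p;
          const int k0 = std::max(0, -dk), k1 = std::min(D, D - dk);
          for (int kj = 0; kj < K; ++kj) {
            const int dj = kj - p;
            const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            for (int ki = 0; ki < K; ++ki) {
              const int di = ki - p;
              const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
              const double wv =
                pw[ki + (size_t)K * (kj + (size_t)K * (kk + (size_t)K * (ci + (size_t)Ci * co)))];
              if (wv == 0.0) continue;
              for (int k = k0; k < k1; ++k) {
                for (int j = j0; j < j1; ++j) {
                  double* orow = o + (size_t)H * (j + (size_t)W * k);
                  const double* irow =
                    in + di + (size_t)H * ((j + dj) + (size_t)W * (k + dk));
                  for (int i = i0; i < i1; ++i) orow[i] += wv * irow[i];
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, D, B, Co);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int dx[5], dw[5], dg[5];
  get_dims5(x, dx, "x");
  get_dims5(w, dw, "w");
  get_dims5(gy, dg, "gy");
  const int H = dx[0], W = dx[1], D = dx[2], B = dx[3], Ci = dx[4];
  const int K = dw[0], Co = dw[4];
  if (dg[0] != H || dg[1] != W || dg[2] != D || dg[3] != B || dg[4] != Co)
    stop("gradient dimensions do not match forward output");
  const int p = (K - 1) / 2;
  const size_t vox = (size_t)H * W * D;

  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();

  for (int co = 0; co < Co; ++co) {
    double bacc = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* g = pg + vox * ((size_t)b + (size_t)B * co);
      for (size_t v = 0; v < vox; ++v) bacc += g[v];
      for (int ci = 0; ci < Ci; ++ci) {
        const double* in = px + vox * ((size_t)b + (size_t)B * ci);
        double* gin = pgx + vox * ((size_t)b + (size_t)B * ci);
        for (int kk = 0; kk < K; ++kk) {
          const int dk = kk - p;
          const int k0 = std::max(0, -dk), k1 = std::min(D, D - dk);
          for (int kj = 0; kj < K; ++kj) {
            const int dj = kj - p;
            const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            for (int ki = 0; ki < K; ++ki) {
              const int di = ki - p;
              const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
              const size_t widx =
                ki + (size_t)K * (kj + (size_t)K * (kk + (size_t)K * (ci + (size_t)Ci * co)));
              const double wv = pw[widx];
              double wacc = 0.0;
              for (int k = k0; k < k1; ++k) {
                for (int j = j0; j < j1; ++j) {
                  const double* grow = g + (size_t)H * (j + (size_t)W * k);
                  const size_t off = di + (size_t)H * ((j + dj) + (size_t)W * (k + dk));
                  const double* irow = in + off;
                  double* gxrow = gin + off;
                  for (int i = i0; i < i1; ++i) {
                    wacc += irow[i] * grow[i];
                    gxrow[i] += wv * grow[i];
                  }
                }
              }
              pgw[widx] += wacc;
            }
          }
        }
      }
    }
    gb[co] = bacc;
  }
  gx.attr("dim") = IntegerVector::create(H, W, D, B, Ci);
  gw.attr("dim") = IntegerVector::create(K, K, K, Ci, Co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, int pool) {
  int dx[5];
  get_dims5(x, dx, "x");
  const int H = dx[0], W = dx[1], D = dx[2], B = dx[3], C = dx[4];
  if (pool < 1) stop("pool size must be positive");
  const int Ho = H / pool, Wo = W / pool, Do = D / pool;
  if (Ho < 1 || Wo < 1 || Do < 1)
    stop("spatial extent (%d x %d x %d) smaller than pool size %d", H, W, D, pool);
  const size_t vox = (size_t)H * W * D;
  const size_t ovox = (size_t)Ho * Wo * Do;

  NumericVector out(ovox * B * C);
  IntegerVector idx(ovox * B * C);  // 1-based linear index into x
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();

  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const size_t ibase = vox * ((size_t)b + (size_t)B * c);
      const double* in = px + ibase;
      double* o = po + ovox * ((size_t)b + (size_t)B * c);
      int* oi = pi + ovox * ((size_t)b + (size_t)B * c);
      for (int ko = 0; ko < Do; ++ko) {
        for (int jo = 0; jo < Wo; ++jo) {
          for (int io = 0; io < Ho; ++io) {
            double best = R_NegInf;
            size_t bestidx = 0;
            for (int dk = 0; dk < pool; ++dk) {
              const int k = ko * pool + dk;
              for (int dj = 0; dj < pool; ++dj) {
                const int j = jo * pool + dj;
                for (int di = 0; di < pool; ++di) {
                  const int i = io * pool + di;
                  const size_t lin = i + (size_t)H * (j + (size_t)W * k);
                  const double v = in[lin];
                  if (v > best) { best = v; bestidx = lin; }
                }
              }
            }
            const size_t olin = io + (size_t)Ho * (jo + (size_t)Wo * ko);
            o[olin] = best;
            oi[olin] = (int)(ibase + bestidx) + 1;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Do, B, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, Do, B, C);
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  if (xdim.size() != 5) stop("xdim must have length 5");
  size_t n = 1;
  for (int i = 0; i < 5; ++i) n *= (size_t)xdim[i];
  if (gy.size() != idx.size()) stop("gradient and index sizes differ");
  NumericVector gx(n);
  double* p = gx.begin();
  const double* g = gy.begin();
  const int* id = idx.begin();
  const R_xlen_t m = gy.size();
  for (R_xlen_t t = 0; t < m; ++t) p[id[t] - 1] += g[t];
  gx.attr("dim") = xdim;
  return gx;
}

// ---- batch normalization helpers (channel-last 5-d tensors) -----------

// [[Rcpp::export]]
List bn3d_stats(NumericVector x) {
  int dx[5];
  get_dims5(x, dx, "x");
  const int C = dx[4];
  const size_t n = (size_t)dx[0] * dx[1] * dx[2] * dx[3];
  NumericVector mu(C), var(C);
  const double* p = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = p + n * c;
    double s = 0.0, s2 = 0.0;
    for (size_t i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y[..., c] = x[..., c] * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector bn3d_apply(NumericVector x, NumericVector scale,
                         NumericVector shift) {
  int dx[5];
  get_dims5(x, dx, "x");
  const int C = dx[4];
  const size_t n = (size_t)dx[0] * dx[1] * dx[2] * dx[3];
  NumericVector y(x.size());
  const double* p = x.begin();
  double* q = y.begin();
  for (int c = 0; c < C; ++c) {
    const double a = scale[c], b = shift[c];
    const double* col = p + n * c;
    double* out = q + n * c;
    for (size_t i = 0; i < n; ++i) out[i] = col[i] * a + b;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Backward of y = gamma * (x - mu) * invstd + beta given the raw input x.
// [[Rcpp::export]]
List bn3d_bw(NumericVector x, NumericVector dy, NumericVector mu,
             NumericVector invstd, NumericVector gamma) {
  int dx5[5];
  get_dims5(x, dx5, "x");
  const int C = dx5[4];
  const size_t n = (size_t)dx5[0] * dx5[1] * dx5[2] * dx5[3];
  NumericVector dxv(x.size()), dgamma(C), dbeta(C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  double* pdx = dxv.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c];
    const double* xc = px + n * c;
    const double* dc = pdy + n * c;
    double sb = 0.0, sg = 0.0;
    for (size_t i = 0; i < n; ++i) {
      const double xhat = (xc[i] - m) * is;
      sb += dc[i];
      sg += dc[i] * xhat;
    }
    dbeta[c] = sb;
    dgamma[c] = sg;
    const double m1 = g * sb / n;      // mean of dxhat
    const double m2 = g * sg / n;      // mean of dxhat * xhat
    double* ox = pdx + n * c;
    for (size_t i = 0; i < n; ++i) {
      const double xhat = (xc[i] - m) * is;
      ox[i] = is * (g * dc[i] - m1 - xhat * m2);
    }
  }
  dxv.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dxv, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Fused ReLU with mask capture: y = max(x, 0), mask = x > 0.
// [[Rcpp::export]]
List relu_fw(NumericVector x) {
  NumericVector y(x.size());
  LogicalVector mask(x.size());
  const double* p = x.begin();
  double* q = y.begin();
  int* m = mask.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool pos = p[i] > 0;
    m[i] = pos;
    q[i] = pos ? p[i] : 0.0;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}
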