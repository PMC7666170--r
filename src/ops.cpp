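// Low-level kernels for the patch classifier and the segmentation module.
//
// Array layout convention (matching R): activations are numeric vectors with
// dim (H, W, C, N), column-major, H fastest.  Convolution weights are passed
// as a K x Cout matrix with K = kh*kw*Cin and flat index k = di + kh*(dj + kw*c),
// i.e. the natural flattening of an R array dim (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col in single precision: gemm-heavy layers run in float, which is ample
// for NN training; parameters and activations remain double on the R side.
static inline void im2col_one(const double* x, int H, int W, int C,
                              int kh, int kw, int pad,
                              int Ho, int Wo, arma::fmat& M) {
  // M: (Ho*Wo) x (kh*kw*C), zero-filled by caller when pad > 0
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)H * W * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + kh * (dj + kw * c);
        float* Mcol = M.colptr(k);
        for (int j = 0; j < Wo; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) {
            if (pad > 0) for (int i = 0; i < Ho; ++i) Mcol[i + (size_t)Ho * j] = 0.0f;
            continue;
          }
          const double* col = plane + (size_t)H * jj;
          float* out = Mcol + (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i + di - pad;
            out[i] = (ii < 0 || ii >= H) ? 0.0f : (float)col[ii];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward(NumericVector x, IntegerVector xdim,
                           NumericMatrix Wm, NumericVector b,
                           int kh, int kw, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C, Cout = Wm.ncol();
  if (Wm.nrow() != K) stop("weight matrix rows do not match kh*kw*Cin");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wd(const_cast<double*>(Wm.begin()), K, Cout, false, true);
  const arma::fmat Wa = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat M(Ho * (size_t)Wo, K, arma::fill::zeros);
  arma::fmat Y(Ho * (size_t)Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, Ho, Wo, M);
    Y = M * Wa;
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Y.colptr(co);
      double* out = yn + (size_t)Ho * Wo * co;
      const double bc = b[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) out[i] = src[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(NumericVector x, IntegerVector xdim,
                   NumericMatrix Wm, NumericVector dy,
                   int kh, int kw, int pad, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C, Cout = Wm.ncol();
  const arma::mat Wd(const_cast<double*>(Wm.begin()), K, Cout, false, true);
  const arma::fmat Wa = arma::conv_to<arma::fmat>::from(Wd);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : (size_t)0);
  if (need_dx) dx.attr("dim") = xdim;
  arma::fmat dW(K, Cout, arma::fill::zeros);
  arma::frowvec db(Cout, arma::fill::zeros);
  arma::fmat M(Ho * (size_t)Wo, K, arma::fill::zeros);
  arma::fmat dYf(Ho * (size_t)Wo, Cout);
  arma::fmat dM(Ho * (size_t)Wo, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2col_one(xn, H, W, C, kh, kw, pad, Ho, Wo, M);
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (size_t i = 0; i < (size_t)Ho * Wo * Cout; ++i)
      dYf[i] = (float)dyn[i];
    dW += M.t() * dYf;
    db += arma::sum(dYf, 0);
    if (!need_dx) continue;
    dM = dYf * Wa.t();
    // col2im scatter-add
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double* plane = dxn + (size_t)H * W * c;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const int k = di + kh * (dj + kw * c);
          const float* Mcol = dM.colptr(k);
          for (int j = 0; j < Wo; ++j) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            double* col = plane + (size_t)H * jj;
            const float* src = Mcol + (size_t)Ho * j;
            for (int i = 0; i < Ho; ++i) {
              const int ii = i + di - pad;
              if (ii >= 0 && ii < H) col[ii] += src[i];
            }
          }
        }
      }
    }
  }
  return List::create(
    _["dW"] = wrap(arma::conv_to<arma::mat>::from(dW)),
    _["db"] = wrap(arma::conv_to<arma::vec>::from(db.t())),
    _["dx"] = dx);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector x, IntegerVector xdim, int size, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into the (H,W) plane
  IntegerVector ydim = IntegerVector::create(Ho, Wo, C, N);
  y.attr("dim") = ydim;
  idx.attr("dim") = ydim;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int i0 = i * stride, j0 = j * stride;
          double best = plane[i0 + (size_t)H * j0];
          int bidx = i0 + H * j0;
          for (int dj = 0; dj < size; ++dj) {
            for (int di = 0; di < size; ++di) {
              const int ii = i0 + di, jj = j0 + dj;
              const double v = plane[ii + (size_t)H * jj];
              if (v > best) { best = v; bidx = ii + H * jj; }
            }
          }
          // output written in (Ho fastest) order => must index explicitly
          const size_t oo = (size_t)i + (size_t)Ho * j + (size_t)Ho * Wo * (c + (size_t)C * n);
          y[oo] = best;
          idx[oo] = bidx;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = idx.attr("dim");
  const int Ho = ydim[0], Wo = ydim[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const size_t planeY = (size_t)Ho * Wo, planeX = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t offY = planeY * (c + (size_t)C * n);
      double* plane = dx.begin() + planeX * (c + (size_t)C * n);
      for (size_t o = 0; o < planeY; ++o)
        plane[idx[offY + o]] += dy[offY + o];
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".bn_conv_stats")]]
List bn_conv_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  const double m = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_conv_apply")]]
NumericVector bn_conv_apply(NumericVector x, IntegerVector xdim,
                            NumericVector gamma, NumericVector beta,
                            NumericVector mean, NumericVector var, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] / std::sqrt(var[c] + eps);
    const double sh = beta[c] - mean[c] * sc;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (size_t i = 0; i < plane; ++i) q[i] = p[i] * sc + sh;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bn_conv_backward")]]
List bn_conv_backward(NumericVector x, IntegerVector xdim,
                      NumericVector gamma, NumericVector mean, NumericVector var,
                      NumericVector dy, double eps) {
  // gradient for training-mode BN (batch statistics)
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xdim;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mean[c]) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c] * inv;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      double* pq = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (px[i] - mean[c]) * inv;
        pq[i] = g * (pd[i] - (sdy + xh * sdyx) / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- 8-connected component labeling (union-find) ----------------------------

// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(1, 0); // parent[0] unused; labels start at 1
  IntegerMatrix lab(H, W);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // neighbors already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      const int ni[4] = { i - 1, i - 1, i,     i + 1 };
      const int nj[4] = { j,     j - 1, j - 1, j - 1 };
      for (int t = 0; t < 4; ++t) {
        if (ni[t] < 0 || ni[t] >= H || nj[t] < 0) continue;
        const int l = lab(ni[t], nj[t]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // flatten labels to 1..K
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) {
        const int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++K;
        lab(i, j) = remap[r];
      }
  return lab;
}
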