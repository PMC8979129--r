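// Dense CPU kernels for the network engine.
//
// Tensor layout everywhere: R arrays with dim = c(H, W, C, N) (column-major,
// H fastest).  Convolution weights: dim = c(kh, kw, Cin, Cout); the first
// three dims flatten to the im2col row index, so each output channel's
// filter is one contiguous column of a (kh*kw*Cin) x Cout matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample (pointer to H*W*C doubles) into K (D x L)
static void im2col_one(const double *x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, arma::mat &K) {
  const int L = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double *Krow = K.memptr() + r; // stride D between columns
        const int D = K.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w0 = wo * stride - pad + kj;
          const bool wok = (w0 >= 0 && w0 < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int h0 = ho * stride - pad + ki;
            const int l = ho + Ho * wo;
            double v = 0.0;
            if (wok && h0 >= 0 && h0 < H) v = xc[h0 + H * w0];
            Krow[(size_t)l * D] = v;
          }
        }
      }
    }
  }
}

// scatter-add columns of K (D x L) back into one sample (adjoint of im2col)
static void col2im_one(const arma::mat &K, double *x, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  const int D = K.n_rows;
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double *Krow = K.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w0 = wo * stride - pad + kj;
          if (w0 < 0 || w0 >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h0 = ho * stride - pad + ki;
            if (h0 < 0 || h0 >= H) continue;
            xc[h0 + H * w0] += Krow[(size_t)(ho + Ho * wo) * D];
          }
        }
      }
    }
  }
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// samples per GEMM chunk so the im2col buffer stays modest (~64 MB)
static inline int chunk_samples(int D, int L, int N) {
  const double maxElems = 8.0e6;
  int c = (int)(maxElems / ((double)D * L));
  if (c < 1) c = 1;
  if (c > N) c = N;
  return c;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int D = kh * kw * C, L = Ho * Wo;
  NumericVector y(Dimension(IntegerVector::create(Ho, Wo, Cout, N)));
  arma::mat Wmat(const_cast<double*>(w.begin()), D, Cout, false, true);
  const int CH = chunk_samples(D, L, N);
  arma::mat K(D, (size_t)L * CH);
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int nc = std::min(CH, N - n0);
    for (int j = 0; j < nc; ++j) {
      arma::mat Kj(K.colptr((size_t)j * L), D, L, false, true);
      im2col_one(x.begin() + (size_t)(n0 + j) * H * W * C, H, W, C,
                 kh, kw, stride, pad, Ho, Wo, Kj);
    }
    arma::mat Y = K.cols(0, (size_t)nc * L - 1).t() * Wmat;
    for (int j = 0; j < nc; ++j) {
      arma::mat Yn(y.begin() + (size_t)(n0 + j) * L * Cout, L, Cout, false, true);
      Yn = Y.rows((size_t)j * L, (size_t)(j + 1) * L - 1);
      if (b.size() == Cout)
        for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_data")]]
NumericVector conv2d_bwd_data(NumericVector dy, NumericVector w,
                              int stride, int pad, int Hin, int Win) {
  int Ho, Wo, Cout, N; dims4(dy, Ho, Wo, Cout, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("channel mismatch");
  const int D = kh * kw * Cin, L = Ho * Wo;
  NumericVector dx(Dimension(IntegerVector::create(Hin, Win, Cin, N))); // zero-initialized
  arma::mat Wmat(const_cast<double*>(w.begin()), D, Cout, false, true);
  const int CH = chunk_samples(D, L, N);
  arma::mat dYall((size_t)L * CH, Cout);
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int nc = std::min(CH, N - n0);
    for (int j = 0; j < nc; ++j)
      dYall.rows((size_t)j * L, (size_t)(j + 1) * L - 1) =
        arma::mat(const_cast<double*>(dy.begin()) + (size_t)(n0 + j) * L * Cout,
                  L, Cout, false, true);
    arma::mat K = Wmat * dYall.rows(0, (size_t)nc * L - 1).t();
    for (int j = 0; j < nc; ++j)
      col2im_one(K.cols((size_t)j * L, (size_t)(j + 1) * L - 1),
                 dx.begin() + (size_t)(n0 + j) * Hin * Win * Cin, Hin, Win,
                 Cin, kh, kw, stride, pad, Ho, Wo);
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_bwd_filter")]]
NumericVector conv2d_bwd_filter(NumericVector x, NumericVector dy,
                                int kh, int kw, int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho, Wo, Cout, N2; dims4(dy, Ho, Wo, Cout, N2);
  if (N2 != N) stop("batch mismatch");
  const int D = kh * kw * C, L = Ho * Wo;
  NumericVector dw(Dimension(IntegerVector::create(kh, kw, C, Cout)));
  arma::mat dW(dw.begin(), D, Cout, false, true);
  const int CH = chunk_samples(D, L, N);
  arma::mat K(D, (size_t)L * CH);
  arma::mat dYall((size_t)L * CH, Cout);
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int nc = std::min(CH, N - n0);
    for (int j = 0; j < nc; ++j) {
      arma::mat Kj(K.colptr((size_t)j * L), D, L, false, true);
      im2col_one(x.begin() + (size_t)(n0 + j) * H * W * C, H, W, C,
                 kh, kw, stride, pad, Ho, Wo, Kj);
      dYall.rows((size_t)j * L, (size_t)(j + 1) * L - 1) =
        arma::mat(const_cast<double*>(dy.begin()) + (size_t)(n0 + j) * L * Cout,
                  L, Cout, false, true);
    }
    dW += K.cols(0, (size_t)nc * L - 1) *
          dYall.rows(0, (size_t)nc * L - 1);
  }
  return dw;
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Dimension(IntegerVector::create(Ho, Wo, C, N)));
  IntegerVector arg(Dimension(IntegerVector::create(Ho, Wo, C, N))); // linear index into the sample plane
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)n * H * W * C;
    double *ys = y.begin() + (size_t)n * Ho * Wo * C;
    int *as = arg.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double *xc = xs + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int w0 = wo * stride - pad + kj;
            if (w0 < 0 || w0 >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h0 = ho * stride - pad + ki;
              if (h0 < 0 || h0 >= H) continue;
              const double v = xc[h0 + H * w0];
              if (v > best) { best = v; besti = h0 + H * w0 + H * W * c; }
            }
          }
          const size_t o = ho + Ho * ((size_t)wo + Wo * c);
          ys[o] = best; as[o] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg,
                          int Hin, int Win) {
  int Ho, Wo, C, N; dims4(dy, Ho, Wo, C, N);
  NumericVector dx(Dimension(IntegerVector::create(Hin, Win, C, N)));
  const size_t plane = (size_t)Hin * Win * C, oplane = (size_t)Ho * Wo * C;
  for (int n = 0; n < N; ++n) {
    double *dxs = dx.begin() + n * plane;
    const double *dys = dy.begin() + n * oplane;
    const int *as = arg.begin() + n * oplane;
    for (size_t o = 0; o < oplane; ++o)
      if (as[o] >= 0) dxs[as[o]] += dys[o];
  }
  return dx;
}

// fused optimizer updates: m and v (state) are modified in place (the
// optimizer owns them); the returned parameter is a fresh allocation
// [[Rcpp::export(name = ".adam_step")]]
NumericVector adam_step(NumericVector p, NumericVector m, NumericVector v,
                        NumericVector g, double lr, double b1, double b2,
                        double eps, double corr) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  out.attr("dim") = p.attr("dim");
  double *mp = m.begin(), *vp = v.begin(), *op = out.begin();
  const double *pp = p.begin(), *gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    op[i] = pp[i] - lr * corr * mp[i] / (std::sqrt(vp[i]) + eps);
  }
  return out;
}

// [[Rcpp::export(name = ".rmsprop_step")]]
NumericVector rmsprop_step(NumericVector p, NumericVector s, NumericVector g,
                           double lr, double alpha, double eps) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  out.attr("dim") = p.attr("dim");
  double *sp = s.begin(), *op = out.begin();
  const double *pp = p.begin(), *gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    sp[i] = alpha * sp[i] + (1 - alpha) * gp[i] * gp[i];
    op[i] = pp[i] - lr * gp[i] / (std::sqrt(sp[i]) + eps);
  }
  return out;
}

// single-pass batch-norm training forward: returns out, xhat, invstd
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W, cplane = plane * C;
  const double m = (double)plane * N;
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + n * cplane + c * plane;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] += s; var[c] += s2;
    }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = var[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + n * cplane + c * plane;
      double *oc = out.begin() + n * cplane + c * plane;
      double *hc = xhat.begin() + n * cplane + c * plane;
      const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
      for (size_t i = 0; i < plane; ++i) {
        hc[i] = (xc[i] - mc) * ic;
        oc[i] = gc * hc[i] + bc;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = var);
}

// batch-norm training backward from cached xhat/invstd
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector dout, NumericVector xhat, NumericVector invstd,
            NumericVector gamma) {
  int H, W, C, N; dims4(dout, H, W, C, N);
  const size_t plane = (size_t)H * W, cplane = plane * C;
  const double m = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dc = dout.begin() + n * cplane + c * plane;
      const double *hc = xhat.begin() + n * cplane + c * plane;
      double sg = 0, sb = 0;
      for (size_t i = 0; i < plane; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dc = dout.begin() + n * cplane + c * plane;
      const double *hc = xhat.begin() + n * cplane + c * plane;
      double *xc = dx.begin() + n * cplane + c * plane;
      const double k = gamma[c] * invstd[c] / m;
      const double dg = dgamma[c], db = dbeta[c];
      for (size_t i = 0; i < plane; ++i)
        xc[i] = k * (m * dc[i] - db - hc[i] * dg);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// forward that also returns the im2col matrix for reuse in the filter
// gradient (only called for modest tensor sizes)
// [[Rcpp::export(name = ".conv2d_fwd_k")]]
List conv2d_fwd_k(NumericVector x, NumericVector w, NumericVector b,
                  int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int D = kh * kw * C, L = Ho * Wo;
  NumericVector y(Dimension(IntegerVector::create(Ho, Wo, Cout, N)));
  NumericMatrix Kall(D, (R_xlen_t)L * N);
  arma::mat Kmat(Kall.begin(), D, (size_t)L * N, false, true);
  arma::mat Wmat(const_cast<double*>(w.begin()), D, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Kn(Kmat.colptr((size_t)n * L), D, L, false, true);
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
               pad, Ho, Wo, Kn);
  }
  arma::mat Y = Kmat.t() * Wmat;   // (L*N) x Cout
  for (int n = 0; n < N; ++n) {
    arma::mat Yn(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    Yn = Y.rows((size_t)n * L, (size_t)(n + 1) * L - 1);
    if (b.size() == Cout)
      for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
  }
  return List::create(_["out"] = y, _["K"] = Kall);
}

// filter gradient from a cached im2col matrix: one GEMM
// [[Rcpp::export(name = ".conv2d_bwd_filter_k")]]
NumericVector conv2d_bwd_filter_k(NumericMatrix Kall, NumericVector dy,
                                  int kh, int kw, int Cin) {
  int Ho, Wo, Cout, N; dims4(dy, Ho, Wo, Cout, N);
  const int D = kh * kw * Cin, L = Ho * Wo;
  if (Kall.nrow() != D || Kall.ncol() != (R_xlen_t)L * N) stop("K shape mismatch");
  arma::mat Kmat(Kall.begin(), D, (size_t)L * N, false, true);
  arma::mat dYall((size_t)L * N, Cout);
  for (int n = 0; n < N; ++n)
    dYall.rows((size_t)n * L, (size_t)(n + 1) * L - 1) =
      arma::mat(const_cast<double*>(dy.begin()) + (size_t)n * L * Cout,
                L, Cout, false, true);
  NumericVector dw(Dimension(IntegerVector::create(kh, kw, Cin, Cout)));
  arma::mat dW(dw.begin(), D, Cout, false, true);
  dW = Kmat * dYall;
  return dw;
}
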