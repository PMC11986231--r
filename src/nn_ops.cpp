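// Low-level numeric kernels for the convolutional segmenter.
// Tensors are R arrays in (H, W, C, N) layout (column-major, H fastest);
// convolution weights are (kh, kw, Cin, Cout). Stride is always 1; spatial
// downsampling is done by 2x2 max-pooling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int kh, int kw, int pad, int Ho, int Wo) {
  arma::mat K(kh * kw * C, Ho * Wo);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const int col = i + Ho * j;
      double* kc = K.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int n = 0; n < kw; ++n) {
          const int jj = j + n - pad;
          for (int m = 0; m < kh; ++m) {
            const int ii = i + m - pad;
            const int r = m + kh * (n + kw * c);
            kc[r] = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                      ? x[ii + H * (jj + W * c)] : 0.0;
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector out(Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  for (int n = 0; n < N; ++n) {
    arma::mat K = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo);
    arma::mat O = K.t() * Wm;  // (HoWo x Cout)
    double* op = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      const double* oc = O.colptr(co);
      double* dst = op + (size_t)co * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) dst[p] = oc[p] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  arma::mat gW(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  // spatially flipped, channel-swapped kernel: gx = conv(gout, Wf, kh-1-pad)
  arma::mat Wf(kh * kw * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int co = 0; co < Cout; ++co) {
      for (int n = 0; n < kw; ++n) {
        for (int m = 0; m < kh; ++m) {
          Wf(m + kh * (n + kw * co), ci) =
            w[(kh - 1 - m) + kh * ((kw - 1 - n) + kw * ci + kw * Cin * co)];
        }
      }
    }
  }
  const int pad2 = kh - 1 - pad;

  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout,
                Ho * Wo, Cout, false, true);
    arma::mat K = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo);
    gW += K * G;
    gb += arma::sum(G, 0).t();
    arma::mat K2 = im2col(gout.begin() + (size_t)n * Ho * Wo * Cout,
                          Ho, Wo, Cout, kh, kw, pad2, H, W);
    arma::mat GX(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, Cin,
                 false, true);
    GX = K2.t() * Wf;
  }

  NumericVector gwR(w.size());
  gwR.attr("dim") = wd;
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gwR.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwR,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[i] = y[i] > 0 ? g[i] : 0.0;
  return gx;
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(out.size());  // linear index into x of each max

  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xp = x.begin() + s * H * W;
    double* op = out.begin() + s * Ho * Wo;
    int* ip = idx.begin() + s * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = 2 * i + H * (2 * j);
        double bv = xp[best];
        const int cand[3] = {2 * i + 1 + H * (2 * j), 2 * i + H * (2 * j + 1),
                             2 * i + 1 + H * (2 * j + 1)};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        op[i + Ho * j] = bv;
        ip[i + Ho * j] = (int)(s * H * W) + best;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector gout,
                                    IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (int p = 0; p < gout.size(); ++p) gx[idx[p]] += gout[p];
  return gx;
}

// ---- batch normalization (training mode, per-channel over H,W,N) -----------

// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  NumericVector mean(C), invstd(C);
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + n * cs + c * hw;
      for (size_t p = 0; p < hw; ++p) { s += xp[p]; s2 += xp[p] * xp[p]; }
    }
    const double mu = s / m;
    const double var = s2 / m - mu * mu;
    const double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + n * cs + c * hw;
      double* hp = xhat.begin() + n * cs + c * hw;
      double* yp = y.begin() + n * cs + c * hw;
      for (size_t p = 0; p < hw; ++p) {
        hp[p] = (xp[p] - mu) * is;
        yp[p] = g * hp[p] + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector g, NumericVector xhat, NumericVector gamma,
                     NumericVector invstd) {
  IntegerVector xd = g.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  const double m = (double)hw * N;
  NumericVector gx(g.size()); gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgh = 0;
    for (int n = 0; n < N; ++n) {
      const double* gp = g.begin() + n * cs + c * hw;
      const double* hp = xhat.begin() + n * cs + c * hw;
      for (size_t p = 0; p < hw; ++p) { sg += gp[p]; sgh += gp[p] * hp[p]; }
    }
    gbeta[c] = sg; ggamma[c] = sgh;
    const double k = gamma[c] * invstd[c];
    const double a = sg / m, b = sgh / m;
    for (int n = 0; n < N; ++n) {
      const double* gp = g.begin() + n * cs + c * hw;
      const double* hp = xhat.begin() + n * cs + c * hw;
      double* op = gx.begin() + n * cs + c * hw;
      for (size_t p = 0; p < hw; ++p) op[p] = k * (gp[p] - a - hp[p] * b);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- attention broadcasts ---------------------------------------------------

// (H,W,1,N) -> (H,W,C,N)
// [[Rcpp::export]]
NumericVector cpp_bcast_spatial(NumericVector a, int C) {
  IntegerVector d = a.attr("dim");
  const int H = d[0], W = d[1], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector out(hw * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* ap = a.begin() + n * hw;
    for (int c = 0; c < C; ++c) {
      std::copy(ap, ap + hw, out.begin() + ((size_t)n * C + c) * hw);
    }
  }
  return out;
}

// sum over channels: (H,W,C,N) -> (H,W,1,N)
// [[Rcpp::export]]
NumericVector cpp_reduce_spatial(NumericVector g) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector out(hw * N);
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  std::fill(out.begin(), out.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    double* op = out.begin() + n * hw;
    for (int c = 0; c < C; ++c) {
      const double* gp = g.begin() + ((size_t)n * C + c) * hw;
      for (size_t p = 0; p < hw; ++p) op[p] += gp[p];
    }
  }
  return out;
}

// (N x C) -> (H,W,C,N)
// [[Rcpp::export]]
NumericVector cpp_bcast_channel(NumericMatrix a, int H, int W) {
  const int N = a.nrow(), C = a.ncol();
  const size_t hw = (size_t)H * W;
  NumericVector out(hw * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::fill_n(out.begin() + ((size_t)n * C + c) * hw, hw, a(n, c));
    }
  }
  return out;
}

// sum over H,W: (H,W,C,N) -> (N x C)
// [[Rcpp::export]]
NumericMatrix cpp_reduce_channel(NumericVector g) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericMatrix out(N, C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gp = g.begin() + ((size_t)n * C + c) * hw;
      double s = 0;
      for (size_t p = 0; p < hw; ++p) s += gp[p];
      out(n, c) = s;
    }
  }
  return out;
}
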