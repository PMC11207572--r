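// Hot layer kernels for the training engine.
//
// Activations arrive as dense R matrices whose row index enumerates
// (batch, channel) or (batch, time) and whose column index enumerates
// (time, feature) blocks; these kernels do the passes that are memory-
// bound in plain R: grouped batch normalization, the depthwise spatial
// convolution repacking, per-map temporal kernels of the separable
// stage, and the ELU. Inputs are accessed through no-copy proxies;
// Armadillo views wrap existing memory only where a GEMM is needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- grouped batch normalization -----------------------------------
// Columns grouped in blocks of `groupT` per feature.

// [[Rcpp::export]]
List bn_group_fwd_cpp(NumericMatrix M, NumericVector gamma,
                      NumericVector beta, int groupT,
                      NumericVector run_mean, NumericVector run_var,
                      bool training, double momentum, double eps) {
  const int R = M.nrow(), F = gamma.size();
  NumericVector m(F), v(F);
  if (training) {
    const double G = double(R) * groupT;
    for (int f = 0; f < F; ++f) {
      double s = 0.0, ss = 0.0;
      const double* col = &M(0, f * groupT);
      const R_xlen_t len = R_xlen_t(R) * groupT;
      for (R_xlen_t i = 0; i < len; ++i) { s += col[i]; ss += col[i] * col[i]; }
      m[f] = s / G;
      const double vv = ss / G - m[f] * m[f];
      v[f] = vv > 0 ? vv : 0.0;
    }
  } else {
    m = clone(run_mean); v = clone(run_var);
  }
  NumericVector inv_std(F);
  for (int f = 0; f < F; ++f) inv_std[f] = 1.0 / std::sqrt(v[f] + eps);
  NumericMatrix out(R, M.ncol());
  for (int f = 0; f < F; ++f) {
    const double a = gamma[f] * inv_std[f];
    const double b = beta[f] - a * m[f];
    const double* src = &M(0, f * groupT);
    double* dst = &out(0, f * groupT);
    const R_xlen_t len = R_xlen_t(R) * groupT;
    for (R_xlen_t i = 0; i < len; ++i) dst[i] = a * src[i] + b;
  }
  NumericVector nrm(F), nrv(F);
  for (int f = 0; f < F; ++f) {
    nrm[f] = training ? momentum * run_mean[f] + (1 - momentum) * m[f]
                      : run_mean[f];
    nrv[f] = training ? momentum * run_var[f] + (1 - momentum) * v[f]
                      : run_var[f];
  }
  return List::create(_["out"] = out, _["mean"] = m,
                      _["inv_std"] = inv_std,
                      _["run_mean"] = nrm, _["run_var"] = nrv);
}

// [[Rcpp::export]]
List bn_group_bwd_cpp(NumericMatrix M, NumericMatrix dY,
                      NumericVector gamma, NumericVector mean,
                      NumericVector inv_std, int groupT) {
  const int R = M.nrow(), F = gamma.size();
  const double G = double(R) * groupT;
  NumericMatrix dX(R, M.ncol());
  NumericVector dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double* x = &M(0, f * groupT);
    const double* dy = &dY(0, f * groupT);
    double* dx = &dX(0, f * groupT);
    const R_xlen_t len = R_xlen_t(R) * groupT;
    const double mu = mean[f], is = inv_std[f], ga = gamma[f];
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < len; ++i) {
      sg += dy[i] * (x[i] - mu);
      sb += dy[i];
    }
    sg *= is;
    dgamma[f] = sg; dbeta[f] = sb;
    const double s1 = ga * sb / G;         // mean of dxhat
    const double s2 = ga * sg / G;         // mean of dxhat * xhat
    // dx = (ga*dy - s1 - xhat*s2) * is, with xhat = (x - mu) * is
    const double c1 = ga * is;
    const double c2 = s2 * is * is;
    const double c0 = -s1 * is + mu * c2;
    for (R_xlen_t i = 0; i < len; ++i)
      dx[i] = c1 * dy[i] - c2 * x[i] + c0;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- depthwise spatial convolution ---------------------------------
// In: M (N*C x T*F1) with rows (n, c), columns (t, f);
// weights Wd: R array (C x F1 x D). Out: Z (N*T x F1*D), rows (n, t).

// [[Rcpp::export]]
NumericMatrix depthwise_fwd_cpp(NumericMatrix M, NumericVector Wd,
                                int N, int C, int T) {
  IntegerVector wd_dim = Wd.attr("dim");
  const int F1 = wd_dim[1], D = wd_dim[2];
  NumericMatrix Zout(N * T, F1 * D);
  arma::mat Xf(N * T, C);
  for (int f = 0; f < F1; ++f) {
    for (int c = 0; c < C; ++c) {
      double* dst = Xf.colptr(c);
      for (int t = 0; t < T; ++t) {
        const double* src = &M(0, t + T * f) + R_xlen_t(N) * c;
        std::copy(src, src + N, dst + R_xlen_t(N) * t);
      }
    }
    arma::mat Wf(C, D);
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        Wf(c, d) = Wd[c + C * f + R_xlen_t(C) * F1 * d];
    arma::mat Zview(&Zout(0, f * D), N * T, D, false, true);
    Zview = Xf * Wf;
  }
  return Zout;
}

// [[Rcpp::export]]
List depthwise_bwd_cpp(NumericMatrix M, NumericMatrix dZ,
                       NumericVector Wd, int N, int C, int T) {
  IntegerVector wd_dim = Wd.attr("dim");
  const int F1 = wd_dim[1], D = wd_dim[2];
  NumericMatrix dM(N * C, T * F1);
  NumericVector dWd(R_xlen_t(C) * F1 * D);
  dWd.attr("dim") = wd_dim;
  arma::mat Xf(N * T, C);
  for (int f = 0; f < F1; ++f) {
    for (int c = 0; c < C; ++c) {
      double* dst = Xf.colptr(c);
      for (int t = 0; t < T; ++t) {
        const double* src = &M(0, t + T * f) + R_xlen_t(N) * c;
        std::copy(src, src + N, dst + R_xlen_t(N) * t);
      }
    }
    arma::mat Wf(C, D);
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        Wf(c, d) = Wd[c + C * f + R_xlen_t(C) * F1 * d];
    const arma::mat dZf(const_cast<double*>(&dZ(0, f * D)),
                        N * T, D, false, true);
    arma::mat dWf = Xf.t() * dZf;              // C x D
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        dWd[c + C * f + R_xlen_t(C) * F1 * d] = dWf(c, d);
    arma::mat dXf = dZf * Wf.t();              // (N*T) x C
    for (int c = 0; c < C; ++c) {
      const double* src = dXf.colptr(c);
      for (int t = 0; t < T; ++t) {
        double* dst = &dM(0, t + T * f) + R_xlen_t(N) * c;
        std::copy(src + R_xlen_t(N) * t, src + R_xlen_t(N) * (t + 1), dst);
      }
    }
  }
  return List::create(_["dX"] = dM, _["dWd"] = dWd);
}

// ---- separable depthwise temporal kernels --------------------------
// X (N*T x M), rows (n, t); W (k x M), same padding, no bias.

// [[Rcpp::export]]
NumericMatrix sepdw_fwd_cpp(NumericMatrix X, NumericMatrix W, int N, int T) {
  const int M = X.ncol(), k = W.nrow(), pad = (k - 1) / 2;
  NumericMatrix Y(N * T, M);
  for (int mcol = 0; mcol < M; ++mcol) {
    const double* x = &X(0, mcol);
    double* y = &Y(0, mcol);
    for (int q = 0; q < k; ++q) {
      const double w = W(q, mcol);
      if (w == 0.0) continue;
      const int shift = q - pad;               // source t = t_out + shift
      const int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
      for (int t = t0; t < t1; ++t) {
        const double* xs = x + R_xlen_t(N) * (t + shift);
        double* ys = y + R_xlen_t(N) * t;
        for (int n = 0; n < N; ++n) ys[n] += w * xs[n];
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List sepdw_bwd_cpp(NumericMatrix X, NumericMatrix dY,
                   NumericMatrix W, int N, int T) {
  const int M = X.ncol(), k = W.nrow(), pad = (k - 1) / 2;
  NumericMatrix dX(N * T, M);
  NumericMatrix dW(k, M);
  for (int mcol = 0; mcol < M; ++mcol) {
    const double* x = &X(0, mcol);
    const double* dy = &dY(0, mcol);
    double* dx = &dX(0, mcol);
    for (int q = 0; q < k; ++q) {
      const double w = W(q, mcol);
      const int shift = q - pad;
      const int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
      double acc = 0.0;
      for (int t = t0; t < t1; ++t) {
        const double* xs = x + R_xlen_t(N) * (t + shift);
        const double* dys = dy + R_xlen_t(N) * t;
        double* dxs = dx + R_xlen_t(N) * (t + shift);
        for (int n = 0; n < N; ++n) {
          acc += xs[n] * dys[n];
          dxs[n] += w * dys[n];
        }
      }
      dW(q, mcol) = acc;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// ---- ELU ------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix elu_fwd_cpp(NumericMatrix X, double alpha) {
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  const R_xlen_t n = X.size();
  for (R_xlen_t i = 0; i < n; ++i)
    o[i] = x[i] >= 0 ? x[i] : alpha * (std::exp(x[i]) - 1.0);
  return out;
}

// [[Rcpp::export]]
NumericMatrix elu_bwd_cpp(NumericMatrix dY, NumericMatrix out,
                          double alpha) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* dy = dY.begin();
  const double* o = out.begin();
  double* dx = dX.begin();
  const R_xlen_t n = dY.size();
  for (R_xlen_t i = 0; i < n; ++i)
    dx[i] = o[i] >= 0 ? dy[i] : dy[i] * (o[i] + alpha);
  return dX;
}

// ---- fused temporal-conv + batch-norm + depthwise block -------------
// X (N*C x T) rows (n, c); Wt (k x F1) temporal kernels (same padding,
// no bias); BN per temporal filter; Wd (C x F1 x D) depthwise spatial
// weights. Output Z (N*T x F1*D) rows (n, t). The backward pass
// recomputes the conv activations per filter instead of caching the
// full (N*C x T*F1) intermediate, keeping the working set small.

static arma::mat band_from_kernel(const double* w, int T, int k) {
  const int pad = (k - 1) / 2;
  arma::mat B(T, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int q = 0; q < k; ++q) {
      const int s = t + q - pad;
      if (s >= 0 && s < T) B(s, t) = w[q];
    }
  return B;
}

// [[Rcpp::export]]
List eegnet_block1_fwd(NumericMatrix X, NumericMatrix Wt,
                       NumericVector gamma, NumericVector beta,
                       NumericVector run_mean, NumericVector run_var,
                       NumericVector Wd, int N, int C, int T,
                       bool training, double momentum, double eps) {
  const int F1 = Wt.ncol(), k = Wt.nrow();
  IntegerVector wd_dim = Wd.attr("dim");
  const int D = wd_dim[2];
  const arma::mat Xv(const_cast<double*>(X.begin()), N * C, T, false, true);
  NumericMatrix Zout(N * T, F1 * D);
  NumericVector m(F1), v(F1), inv_std(F1), nrm(F1), nrv(F1);
  arma::mat Xf(N * T, C);
  const double G = double(N) * C * T;
  for (int f = 0; f < F1; ++f) {
    const arma::mat Bf = band_from_kernel(&Wt(0, f), T, k);
    arma::mat Yf = Xv * Bf;                      // (N*C) x T
    double mu, var;
    if (training) {
      mu = arma::accu(Yf) / G;
      double ss = 0.0;
      const double* y = Yf.memptr();
      for (R_xlen_t i = 0; i < R_xlen_t(N) * C * T; ++i) ss += y[i] * y[i];
      var = ss / G - mu * mu;
      if (var < 0) var = 0;
      nrm[f] = momentum * run_mean[f] + (1 - momentum) * mu;
      nrv[f] = momentum * run_var[f] + (1 - momentum) * var;
    } else {
      mu = run_mean[f]; var = run_var[f];
      nrm[f] = run_mean[f]; nrv[f] = run_var[f];
    }
    m[f] = mu; v[f] = var;
    const double is = 1.0 / std::sqrt(var + eps);
    inv_std[f] = is;
    const double a = gamma[f] * is;
    const double b = beta[f] - a * mu;
    // normalize + repack: Xf(n + N*t, c) = a * Yf(n + N*c, t) + b
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        const double* src = Yf.colptr(t) + R_xlen_t(N) * c;
        double* dst = Xf.colptr(c) + R_xlen_t(N) * t;
        for (int n = 0; n < N; ++n) dst[n] = a * src[n] + b;
      }
    arma::mat Wf(C, D);
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        Wf(c, d) = Wd[c + C * f + R_xlen_t(C) * F1 * d];
    arma::mat Zview(&Zout(0, f * D), N * T, D, false, true);
    Zview = Xf * Wf;
  }
  return List::create(_["out"] = Zout, _["mean"] = m, _["inv_std"] = inv_std,
                      _["run_mean"] = nrm, _["run_var"] = nrv);
}

// [[Rcpp::export]]
List eegnet_block1_bwd(NumericMatrix X, NumericMatrix Wt,
                       NumericVector gamma, NumericVector beta,
                       NumericVector mean, NumericVector inv_std,
                       NumericVector Wd, NumericMatrix dZ,
                       int N, int C, int T, bool need_dx) {
  const int F1 = Wt.ncol(), k = Wt.nrow();
  const int pad = (k - 1) / 2;
  IntegerVector wd_dim = Wd.attr("dim");
  const int D = wd_dim[2];
  const arma::mat Xv(const_cast<double*>(X.begin()), N * C, T, false, true);
  NumericMatrix dX(N * C, T);
  arma::mat dXv(dX.begin(), N * C, T, false, true);
  NumericMatrix dWt(k, F1);
  NumericVector dWd(R_xlen_t(C) * F1 * D);
  dWd.attr("dim") = wd_dim;
  NumericVector dgamma(F1), dbeta(F1);
  arma::mat Xf(N * T, C), dXf(N * T, C), dYf(N * C, T);
  const double G = double(N) * C * T;
  for (int f = 0; f < F1; ++f) {
    const arma::mat Bf = band_from_kernel(&Wt(0, f), T, k);
    arma::mat Yf = Xv * Bf;                      // recomputed conv
    const double mu = mean[f], is = inv_std[f], ga = gamma[f];
    const double be = beta[f];
    // repack normalized activations (xhat); the BN output entering the
    // depthwise stage is ga*xhat + be
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        const double* src = Yf.colptr(t) + R_xlen_t(N) * c;
        double* dst = Xf.colptr(c) + R_xlen_t(N) * t;
        for (int n = 0; n < N; ++n) dst[n] = (src[n] - mu) * is;
      }
    // Xf currently holds xhat in (n, t) x c layout
    arma::mat Wf(C, D);
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        Wf(c, d) = Wd[c + C * f + R_xlen_t(C) * F1 * d];
    const arma::mat dZf(const_cast<double*>(&dZ(0, f * D)),
                        N * T, D, false, true);
    dXf = dZf * Wf.t();                          // d(out) in (n,t) x c
    // out = ga*xhat + be, so dWd = out' dZf = ga*(xhat' dZf) + be*colsum
    arma::mat dWf = Xf.t() * dZf;                // xhat' dZf  (C x D)
    arma::rowvec csum = arma::sum(dZf, 0);       // 1 x D
    for (int d = 0; d < D; ++d)
      for (int c = 0; c < C; ++c)
        dWd[c + C * f + R_xlen_t(C) * F1 * d] = ga * dWf(c, d) + be * csum[d];
    // BN backward: reduce d(out) over everything
    double sb = 0.0, sg = 0.0;
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        const double* dsrc = dXf.colptr(c) + R_xlen_t(N) * t;
        const double* xh = Xf.colptr(c) + R_xlen_t(N) * t;
        for (int n = 0; n < N; ++n) {
          sb += dsrc[n];
          sg += dsrc[n] * xh[n];
        }
      }
    dgamma[f] = sg;                              // sum d(out)*xhat
    dbeta[f] = sb;                               // sum d(out)
    const double s1 = ga * sb / G;
    const double s2 = ga * sg / G;
    // dY = (ga*dout - s1 - xhat*s2) * is ; repack back to (n,c) x t
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        const double* dsrc = dXf.colptr(c) + R_xlen_t(N) * t;
        const double* xh = Xf.colptr(c) + R_xlen_t(N) * t;
        double* dst = dYf.colptr(t) + R_xlen_t(N) * c;
        for (int n = 0; n < N; ++n)
          dst[n] = (ga * dsrc[n] - s1 - xh[n] * s2) * is;
      }
    // conv backward (input gradient only when a layer sits upstream)
    if (need_dx) dXv += dYf * Bf.t();
    arma::mat dG = Xv.t() * dYf;                 // T x T
    for (int q = 0; q < k; ++q) {
      double acc = 0.0;
      for (int t = 0; t < T; ++t) {
        const int s = t + q - pad;
        if (s >= 0 && s < T) acc += dG(s, t);
      }
      dWt(q, f) = acc;
    }
  }
  return List::create(_["dX"] = dX, _["dWt"] = dWt, _["dWd"] = dWd,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- average pooling over the time axis ----------------------------
// X (N*T x M) rows (n, t) -> (N*T1 x M), T1 = T / p (floor).

// [[Rcpp::export]]
NumericMatrix pool_avg_fwd_cpp(NumericMatrix X, int N, int T, int p) {
  const int M = X.ncol(), T1 = T / p;
  NumericMatrix Y(N * T1, M);
  const double invp = 1.0 / p;
  for (int mcol = 0; mcol < M; ++mcol) {
    const double* x = &X(0, mcol);
    double* y = &Y(0, mcol);
    for (int t1 = 0; t1 < T1; ++t1) {
      double* dst = y + R_xlen_t(N) * t1;
      const double* s0 = x + R_xlen_t(N) * (t1 * p);
      for (int n = 0; n < N; ++n) dst[n] = s0[n];
      for (int q = 1; q < p; ++q) {
        const double* sq = x + R_xlen_t(N) * (t1 * p + q);
        for (int n = 0; n < N; ++n) dst[n] += sq[n];
      }
      for (int n = 0; n < N; ++n) dst[n] *= invp;
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix pool_avg_bwd_cpp(NumericMatrix dY, int N, int T, int p) {
  const int M = dY.ncol(), T1 = T / p;
  NumericMatrix dX(N * T, M);
  const double invp = 1.0 / p;
  for (int mcol = 0; mcol < M; ++mcol) {
    const double* dy = &dY(0, mcol);
    double* dx = &dX(0, mcol);
    for (int t1 = 0; t1 < T1; ++t1) {
      const double* src = dy + R_xlen_t(N) * t1;
      for (int q = 0; q < p; ++q) {
        double* dst = dx + R_xlen_t(N) * (t1 * p + q);
        for (int n = 0; n < N; ++n) dst[n] = src[n] * invp;
      }
    }
  }
  return dX;
}

// ---- fused per-column batch-norm + ELU + average-pool --------------
// Z (N*T x M) rows (n, t), one BN feature per column; ELU alpha = 1;
// pooled output (N*T1 x M), T1 = T / p. Backward recomputes the
// normalized activations instead of caching them.

// [[Rcpp::export]]
List bnelu_pool_fwd_cpp(NumericMatrix Z, NumericVector gamma,
                        NumericVector beta, NumericVector run_mean,
                        NumericVector run_var, bool training,
                        double momentum, double eps, int N, int T, int p) {
  const int M = Z.ncol(), T1 = T / p;
  const R_xlen_t len = R_xlen_t(N) * T;
  NumericMatrix out(N * T1, M);
  NumericVector m(M), v(M), inv_std(M), nrm(M), nrv(M);
  for (int mc = 0; mc < M; ++mc) {
    const double* z = &Z(0, mc);
    double mu, var;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (R_xlen_t i = 0; i < len; ++i) { s += z[i]; ss += z[i] * z[i]; }
      mu = s / len;
      var = ss / len - mu * mu;
      if (var < 0) var = 0;
      nrm[mc] = momentum * run_mean[mc] + (1 - momentum) * mu;
      nrv[mc] = momentum * run_var[mc] + (1 - momentum) * var;
    } else {
      mu = run_mean[mc]; var = run_var[mc];
      nrm[mc] = run_mean[mc]; nrv[mc] = run_var[mc];
    }
    m[mc] = mu; v[mc] = var;
    const double is = 1.0 / std::sqrt(var + eps);
    inv_std[mc] = is;
    const double a = gamma[mc] * is;
    const double b = beta[mc] - a * mu;
    double* o = &out(0, mc);
    const double invp = 1.0 / p;
    for (int t1 = 0; t1 < T1; ++t1) {
      double* dst = o + R_xlen_t(N) * t1;
      for (int n = 0; n < N; ++n) dst[n] = 0.0;
      for (int q = 0; q < p; ++q) {
        const double* src = z + R_xlen_t(N) * (t1 * p + q);
        for (int n = 0; n < N; ++n) {
          const double y = a * src[n] + b;
          dst[n] += y >= 0 ? y : std::exp(y) - 1.0;
        }
      }
      for (int n = 0; n < N; ++n) dst[n] *= invp;
    }
  }
  return List::create(_["out"] = out, _["mean"] = m, _["inv_std"] = inv_std,
                      _["run_mean"] = nrm, _["run_var"] = nrv);
}

// [[Rcpp::export]]
List bnelu_pool_bwd_cpp(NumericMatrix Z, NumericMatrix dP,
                        NumericVector gamma, NumericVector beta,
                        NumericVector mean, NumericVector inv_std,
                        int N, int T, int p) {
  const int M = Z.ncol(), T1 = T / p;
  const double G = double(N) * T;
  NumericMatrix dZ(N * T, M);
  NumericVector dgamma(M), dbeta(M);
  const double invp = 1.0 / p;
  for (int mc = 0; mc < M; ++mc) {
    const double* z = &Z(0, mc);
    const double* dp = &dP(0, mc);
    double* dz = &dZ(0, mc);
    const double mu = mean[mc], is = inv_std[mc], ga = gamma[mc];
    const double a = ga * is;
    const double b = beta[mc] - a * mu;
    double sb = 0.0, sg = 0.0;
    // pass 1: d(out of BN) for every sample; reductions for BN backward
    for (int t1 = 0; t1 < T1; ++t1) {
      const double* dsrc = dp + R_xlen_t(N) * t1;
      for (int q = 0; q < p; ++q) {
        const double* src = z + R_xlen_t(N) * (t1 * p + q);
        double* dst = dz + R_xlen_t(N) * (t1 * p + q);
        for (int n = 0; n < N; ++n) {
          const double y = a * src[n] + b;           // BN output
          const double de = dsrc[n] * invp;          // through the pool
          const double dy = y >= 0 ? de : de * std::exp(y);
          dst[n] = dy;                               // stash d(BN out)
          const double xh = (src[n] - mu) * is;
          sb += dy;
          sg += dy * xh;
        }
      }
    }
    dgamma[mc] = sg; dbeta[mc] = sb;
    const double s1 = ga * sb / G;
    const double s2 = ga * sg / G;
    const double c1 = ga * is;
    const double c2 = s2 * is * is;
    const double c0 = -s1 * is + mu * c2;
    // pass 2: dZ = (ga*dy - s1 - xhat*s2) * is. The pooling-trimmed
    // tail has dy = 0 but still feeds the batch statistics, so the
    // statistic terms apply to every sample.
    const R_xlen_t full = R_xlen_t(N) * T;
    for (R_xlen_t i = 0; i < full; ++i)
      dz[i] = c1 * dz[i] - c2 * z[i] + c0;
  }
  return List::create(_["dX"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
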