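// Low-level 1D CNN kernels: im2col-based convolution, max-pooling and
// batch normalisation, each with forward and backward passes.  Tensors are
// passed as arma::cube with dimensions (length, channels, batch).
//
// The im2col buffer is laid out (l_out*b, c*k) so that, for the stride-1
// convolutions used throughout the network, every copy between the input
// cube and the buffer is a contiguous strip along the time axis and the
// heavy lifting stays inside BLAS gemm calls.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// cols(row = s*l_out + t, col = ch*k + kk) = X(t*stride - pad + kk, ch, s)
static mat im2col1d(const cube& X, const int k, const int pad,
                    const int stride) {
  const int l = X.n_rows, c = X.n_cols, b = X.n_slices;
  const int l_out = (l + 2 * pad - k) / stride + 1;
  mat cols((uword)l_out * b, (uword)c * k, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int kk = 0; kk < k; ++kk) {
      double* dst = cols.colptr((uword)ch * k + kk);
      for (int s = 0; s < b; ++s) {
        const double* src = X.slice(s).colptr(ch);
        double* d = dst + (uword)s * l_out;
        if (stride == 1) {
          // valid t range: 0 <= t - pad + kk < l
          const int t0 = std::max(0, pad - kk);
          const int t1 = std::min(l_out - 1, l - 1 + pad - kk);
          if (t1 >= t0)
            std::memcpy(d + t0, src + t0 - pad + kk,
                        (size_t)(t1 - t0 + 1) * sizeof(double));
        } else {
          for (int t = 0; t < l_out; ++t) {
            const int idx = t * stride - pad + kk;
            if (idx >= 0 && idx < l) d[t] = src[idx];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im1d(const mat& dcols, cube& dX, const int k, const int pad,
                     const int stride) {
  const int l = dX.n_rows, c = dX.n_cols, b = dX.n_slices;
  const int l_out = (l + 2 * pad - k) / stride + 1;
  for (int ch = 0; ch < c; ++ch) {
    for (int kk = 0; kk < k; ++kk) {
      const double* src = dcols.colptr((uword)ch * k + kk);
      for (int s = 0; s < b; ++s) {
        double* dst = dX.slice(s).colptr(ch);
        const double* sp = src + (uword)s * l_out;
        if (stride == 1) {
          const int t0 = std::max(0, pad - kk);
          const int t1 = std::min(l_out - 1, l - 1 + pad - kk);
          double* dd = dst - pad + kk;
          for (int t = t0; t <= t1; ++t) dd[t] += sp[t];
        } else {
          for (int t = 0; t < l_out; ++t) {
            const int idx = t * stride - pad + kk;
            if (idx >= 0 && idx < l) dst[idx] += sp[t];
          }
        }
      }
    }
  }
}

// Zero-copy view of an R array with dim (l, c, b).
static cube as_cube(Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_fwd(Rcpp::NumericVector Xr, const arma::mat& W,
                          const arma::vec& bias, const int k, const int pad,
                          const int stride) {
  const cube X = as_cube(Xr);
  const int b = X.n_slices;
  const int l_out = ((int)X.n_rows + 2 * pad - k) / stride + 1;
  const int c_out = W.n_rows;
  mat cols = im2col1d(X, k, pad, stride);
  mat Y = cols * W.t();         // (l_out*b, c_out)
  Y.each_row() += bias.t();
  Rcpp::NumericVector outr(Rcpp::Dimension(l_out, c_out, b));
  cube out(outr.begin(), l_out, c_out, b, false, true);
  for (int s = 0; s < b; ++s)
    out.slice(s) = Y.rows((uword)s * l_out, (uword)(s + 1) * l_out - 1);
  return Rcpp::List::create(Rcpp::Named("out") = outr);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(Rcpp::NumericVector Xr, const arma::mat& W,
                          Rcpp::NumericVector dYr, const int k,
                          const int pad, const int stride) {
  const cube X = as_cube(Xr);
  const cube dY = as_cube(dYr);
  const int b = X.n_slices;
  const int l_out = dY.n_rows, c_out = dY.n_cols;
  mat dYm((uword)l_out * b, c_out);
  for (int s = 0; s < b; ++s)
    dYm.rows((uword)s * l_out, (uword)(s + 1) * l_out - 1) = dY.slice(s);
  mat cols = im2col1d(X, k, pad, stride);
  mat dW = dYm.t() * cols;      // (c_out, c*k)
  vec db = sum(dYm, 0).t();
  mat dcols = dYm * W;          // (l_out*b, c*k)
  Rcpp::NumericVector dXr(Rcpp::Dimension(X.n_rows, X.n_cols, b));
  cube dX(dXr.begin(), X.n_rows, X.n_cols, b, false, true);
  col2im1d(dcols, dX, k, pad, stride);
  return Rcpp::List::create(Rcpp::Named("dX") = dXr,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool1d_fwd(const arma::cube& X, const int size,
                             const int stride, const int pad) {
  const int l = X.n_rows, c = X.n_cols, b = X.n_slices;
  const int l_out = (l + 2 * pad - size) / stride + 1;
  cube out(l_out, c, b);
  icube amax(l_out, c, b);      // index into the input length axis, 0-based
  for (int s = 0; s < b; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double* xp = X.slice(s).colptr(ch);
      double* op = out.slice(s).colptr(ch);
      sword* ap = amax.slice(s).colptr(ch);
      for (int t = 0; t < l_out; ++t) {
        const int start = t * stride - pad;
        const int i0 = std::max(0, start);
        const int i1 = std::min(l - 1, start + size - 1);
        double best = xp[i0];
        int bi = i0;
        for (int i = i0 + 1; i <= i1; ++i)
          if (xp[i] > best) { best = xp[i]; bi = i; }
        op[t] = best;
        ap[t] = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool1d_bwd(const arma::icube& amax, const arma::cube& dY,
                             const int l_in) {
  const int l_out = dY.n_rows, c = dY.n_cols, b = dY.n_slices;
  cube dX(l_in, c, b, fill::zeros);
  for (int s = 0; s < b; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double* dp = dY.slice(s).colptr(ch);
      const sword* ap = amax.slice(s).colptr(ch);
      double* op = dX.slice(s).colptr(ch);
      for (int t = 0; t < l_out; ++t) op[ap[t]] += dp[t];
    }
  return dX;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_fwd(const arma::cube& X, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& rmean,
                      const arma::vec& rvar, const double eps,
                      const double momentum, const bool training) {
  const int l = X.n_rows, c = X.n_cols, b = X.n_slices;
  const double m = (double)l * b;
  vec mu(c), v(c);
  if (training) {
    for (int ch = 0; ch < c; ++ch) {
      double s = 0.0, s2 = 0.0;
      for (int sl = 0; sl < b; ++sl) {
        const double* xp = X.slice(sl).colptr(ch);
        for (int i = 0; i < l; ++i) {
          s += xp[i];
          s2 += xp[i] * xp[i];
        }
      }
      mu(ch) = s / m;
      v(ch) = s2 / m - mu(ch) * mu(ch);
      if (v(ch) < 0) v(ch) = 0;
    }
  } else {
    mu = rmean;
    v = rvar;
  }
  cube out(l, c, b);
  for (int ch = 0; ch < c; ++ch) {
    const double invstd = 1.0 / std::sqrt(v(ch) + eps);
    const double g = gamma(ch), bt = beta(ch), mm = mu(ch);
    for (int sl = 0; sl < b; ++sl) {
      const double* xp = X.slice(sl).colptr(ch);
      double* op = out.slice(sl).colptr(ch);
      for (int i = 0; i < l; ++i) op[i] = g * (xp[i] - mm) * invstd + bt;
    }
  }
  vec nrm = rmean, nrv = rvar;
  if (training) {
    nrm = (1.0 - momentum) * rmean + momentum * mu;
    nrv = (1.0 - momentum) * rvar + momentum * v;
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = v,
                            Rcpp::Named("rmean") = nrm,
                            Rcpp::Named("rvar") = nrv);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bwd(const arma::cube& X, const arma::cube& dY,
                      const arma::vec& gamma, const arma::vec& mu,
                      const arma::vec& v, const double eps) {
  const int l = X.n_rows, c = X.n_cols, b = X.n_slices;
  const double m = (double)l * b;
  cube dX(l, c, b);
  vec dgamma(c), dbeta(c);
  for (int ch = 0; ch < c; ++ch) {
    const double invstd = 1.0 / std::sqrt(v(ch) + eps);
    const double mm = mu(ch), g = gamma(ch);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int sl = 0; sl < b; ++sl) {
      const double* xp = X.slice(sl).colptr(ch);
      const double* dp = dY.slice(sl).colptr(ch);
      for (int i = 0; i < l; ++i) {
        sum_dy += dp[i];
        sum_dy_xhat += dp[i] * (xp[i] - mm) * invstd;
      }
    }
    dgamma(ch) = sum_dy_xhat;
    dbeta(ch) = sum_dy;
    for (int sl = 0; sl < b; ++sl) {
      const double* xp = X.slice(sl).colptr(ch);
      const double* dp = dY.slice(sl).colptr(ch);
      double* op = dX.slice(sl).colptr(ch);
      for (int i = 0; i < l; ++i) {
        const double xhat = (xp[i] - mm) * invstd;
        op[i] = g * invstd *
                (dp[i] - sum_dy / m - xhat * sum_dy_xhat / m);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
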