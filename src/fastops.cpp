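#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam parameter update. p, m and v are package-internal arrays
// that are deep-copied at the start of training, so direct mutation is
// safe and avoids reallocating ~1.5M doubles per optimizer step.
// [[Rcpp::export]]
void adam_update_(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double b1, double b2, double step,
                  double vs, double eps, double wd) {
  R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_: length mismatch");
  double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i] + wd * pp[i];
    pm[i] = b1 * pm[i] + (1.0 - b1) * gi;
    pv[i] = b2 * pv[i] + (1.0 - b2) * gi * gi;
    pp[i] -= step * pm[i] / (std::sqrt(pv[i]) * vs + eps);
  }
}

// Add per-feature bias to a freshly allocated activation matrix, in place.
// [[Rcpp::export]]
void addbias_(NumericMatrix H, NumericVector b) {
  int B = H.nrow(), F = H.ncol();
  if (b.size() != F) stop("addbias_: length mismatch");
  for (int j = 0; j < F; ++j) {
    double bj = b[j];
    for (int i = 0; i < B; ++i) H(i, j) += bj;
  }
}

// BatchNorm forward: returns normalized activations, the cache needed for
// backprop, and (in training mode) the batch moments.
// [[Rcpp::export]]
List bn_forward_(NumericMatrix H, NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar, double eps,
                 bool train) {
  int B = H.nrow(), F = H.ncol();
  NumericMatrix xhat(B, F), out(B, F);
  NumericVector invstd(F), mu(F), var(F);
  for (int j = 0; j < F; ++j) {
    double m, v;
    if (train) {
      m = 0.0; for (int i = 0; i < B; ++i) m += H(i, j); m /= B;
      v = 0.0; for (int i = 0; i < B; ++i) { double d = H(i, j) - m; v += d * d; }
      v /= B;
      mu[j] = m; var[j] = v;
    } else { m = rmean[j]; v = rvar[j]; }
    double is = 1.0 / std::sqrt(v + eps);
    invstd[j] = is;
    double g = gamma[j], be = beta[j];
    for (int i = 0; i < B; ++i) {
      double xh = (H(i, j) - m) * is;
      xhat(i, j) = xh;
      out(i, j) = xh * g + be;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = var);
}

// BatchNorm backward over batch statistics.
// [[Rcpp::export]]
List bn_backward_(NumericMatrix dH, NumericMatrix xhat, NumericVector invstd,
                  NumericVector gamma) {
  int B = dH.nrow(), F = dH.ncol();
  NumericMatrix dX(B, F);
  NumericVector dgamma(F), dbeta(F);
  for (int j = 0; j < F; ++j) {
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < B; ++i) { sg += dH(i, j) * xhat(i, j); sb += dH(i, j); }
    dgamma[j] = sg; dbeta[j] = sb;
    double g = gamma[j], is = invstd[j];
    double c1 = g * sb / B, c2 = g * sg / B;
    for (int i = 0; i < B; ++i)
      dX(i, j) = (dH(i, j) * g - c1 - xhat(i, j) * c2) * is;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// LeakyReLU forward: out = H * fac with fac = slope + (1-slope)*(H > 0).
// [[Rcpp::export]]
List lrelu_forward_(NumericMatrix H, double slope) {
  int B = H.nrow(), F = H.ncol();
  NumericMatrix out(B, F), fac(B, F);
  for (int j = 0; j < F; ++j)
    for (int i = 0; i < B; ++i) {
      double f = H(i, j) > 0 ? 1.0 : slope;
      fac(i, j) = f;
      out(i, j) = H(i, j) * f;
    }
  return List::create(_["out"] = out, _["fac"] = fac);
}
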