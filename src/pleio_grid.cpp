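#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Profile log10-likelihood surface of the bivariate two-locus model.
//
// Trait 1 is regressed on [C, D_lambda1], trait 2 on [C, D_lambda2], with an
// unstructured 2x2 residual covariance (seemingly-unrelated regressions).
// Everything is computed from cross-products, so the per-cell cost does not
// depend on the sample size: CtC (p0 x p0), CtD (p0 x pd*k), DtD (pd*k x
// pd*k), CtY (p0 x 2), DtY (pd*k x 2), YtY (2 x 2).  The estimator iterates
// feasible GLS from Sigma = I (first pass = per-equation OLS); with the
// Kronecker covariance the cross-products never change across iterations.
// Cell value: -(n/2) * log10 det(Sigma_hat), the profile likelihood with the
// residual covariance at its MLE, up to a constant shared by all cells.
// [[Rcpp::export]]
arma::mat pleio_grid_cpp(const arma::mat& CtC, const arma::mat& CtD,
                         const arma::mat& DtD, const arma::mat& CtY,
                         const arma::mat& DtY, const arma::mat& YtY,
                         int n, int k, int pd, int niter) {
  const int p0 = CtC.n_rows;
  const int p = p0 + pd;
  mat out(k, k);
  out.fill(datum::nan);

  for (int i = 0; i < k; ++i) {
    const uvec di = regspace<uvec>(i * pd, (i + 1) * pd - 1);
    for (int j = 0; j < k; ++j) {
      const uvec dj = regspace<uvec>(j * pd, (j + 1) * pd - 1);

      mat X1tX1(p, p), X2tX2(p, p), X1tX2(p, p);
      X1tX1.submat(0, 0, p0 - 1, p0 - 1) = CtC;
      X1tX1.submat(0, p0, p0 - 1, p - 1) = CtD.cols(di);
      X1tX1.submat(p0, 0, p - 1, p0 - 1) = CtD.cols(di).t();
      X1tX1.submat(p0, p0, p - 1, p - 1) = DtD.submat(di, di);

      X2tX2.submat(0, 0, p0 - 1, p0 - 1) = CtC;
      X2tX2.submat(0, p0, p0 - 1, p - 1) = CtD.cols(dj);
      X2tX2.submat(p0, 0, p - 1, p0 - 1) = CtD.cols(dj).t();
      X2tX2.submat(p0, p0, p - 1, p - 1) = DtD.submat(dj, dj);

      X1tX2.submat(0, 0, p0 - 1, p0 - 1) = CtC;
      X1tX2.submat(0, p0, p0 - 1, p - 1) = CtD.cols(dj);
      X1tX2.submat(p0, 0, p - 1, p0 - 1) = CtD.cols(di).t();
      X1tX2.submat(p0, p0, p - 1, p - 1) = DtD.submat(di, dj);

      vec x1ty1 = join_vert(CtY.col(0), DtY.submat(di, uvec{0}));
      vec x1ty2 = join_vert(CtY.col(1), DtY.submat(di, uvec{1}));
      vec x2ty1 = join_vert(CtY.col(0), DtY.submat(dj, uvec{0}));
      vec x2ty2 = join_vert(CtY.col(1), DtY.submat(dj, uvec{1}));

      double S11 = datum::nan, S12 = datum::nan, S22 = datum::nan;
      double a = 1.0, b = 1.0, c = 0.0;  // Sigma^{-1}, start at identity
      bool ok = true;
      for (int it = 0; it < niter; ++it) {
        mat A(2 * p, 2 * p);
        A.submat(0, 0, p - 1, p - 1) = a * X1tX1;
        A.submat(0, p, p - 1, 2 * p - 1) = c * X1tX2;
        A.submat(p, 0, 2 * p - 1, p - 1) = c * X1tX2.t();
        A.submat(p, p, 2 * p - 1, 2 * p - 1) = b * X2tX2;
        vec r = join_vert(a * x1ty1 + c * x1ty2, c * x2ty1 + b * x2ty2);
        vec beta;
        if (!solve(beta, A, r, solve_opts::likely_sympd + solve_opts::no_approx)) {
          ok = false;
          break;
        }
        vec b1 = beta.head(p), b2 = beta.tail(p);
        S11 = YtY(0, 0) - 2.0 * dot(b1, x1ty1) +
              as_scalar(b1.t() * X1tX1 * b1);
        S22 = YtY(1, 1) - 2.0 * dot(b2, x2ty2) +
              as_scalar(b2.t() * X2tX2 * b2);
        S12 = YtY(0, 1) - dot(b1, x1ty2) - dot(b2, x2ty1) +
              as_scalar(b1.t() * X1tX2 * b2);
        double det = S11 * S22 - S12 * S12;
        double scale = std::max(S11 * S22, 1e-300);
        if (det < 1e-10 * scale) {
          // near-singular residual covariance (e.g. duplicated traits):
          // stop iterating; the floored determinant below caps the surface
          break;
        }
        double s11 = S11 / n, s22 = S22 / n, s12 = S12 / n;
        double dd = s11 * s22 - s12 * s12;
        a = s22 / dd;
        b = s11 / dd;
        c = -s12 / dd;
      }
      if (!ok || !std::isfinite(S11)) continue;
      double det = (S11 / n) * (S22 / n) - (S12 / n) * (S12 / n);
      double floor_ = 1e-12 * std::max((S11 / n) * (S22 / n), 1e-300);
      if (det < floor_) det = floor_;
      out(i, j) = -(n / 2.0) * std::log10(det);
    }
  }
  return out;
}
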