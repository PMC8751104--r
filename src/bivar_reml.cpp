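// Computational kernels for the pairwise bivariate AI-REML fit.
// The covariance model is linear in the parameters
// (su11, su22, su12, se1, se2[, se12]); step control lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// REML log-likelihood, projection matrix P and Py for one parameter vector.
// conn/partner are 0-based record indices of residual-connected pairs.
// [[Rcpp::export(name = ".bivar_relik_cpp")]]
Rcpp::List bivar_relik_cpp(const arma::vec& th,
                           const arma::mat& G11, const arma::mat& G22,
                           const arma::mat& G12,
                           const arma::vec& y, const arma::mat& X,
                           const arma::uvec& conn,
                           const arma::uvec& partner,
                           bool est_se12) {
  const uword n1 = G11.n_rows, n2 = G22.n_rows, n = n1 + n2;
  mat V(n, n);
  V.submat(0, 0, n1 - 1, n1 - 1) = th(0) * G11;
  V.submat(n1, n1, n - 1, n - 1) = th(1) * G22;
  V.submat(0, n1, n1 - 1, n - 1) = th(2) * G12;
  V.submat(n1, 0, n - 1, n1 - 1) = th(2) * G12.t();
  for (uword i = 0; i < n1; ++i) V(i, i) += th(3);
  for (uword i = n1; i < n; ++i) V(i, i) += th(4);
  if (est_se12)
    for (uword k = 0; k < conn.n_elem; ++k)
      V(conn(k), partner(k)) += th(5);

  mat L;
  if (!chol(L, V, "lower"))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  mat Linv;
  if (!inv(Linv, trimatl(L)))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  mat Vinv = Linv.t() * Linv;
  mat VX = Vinv * X;
  mat XtVX = X.t() * VX;
  XtVX = 0.5 * (XtVX + XtVX.t());
  mat P = Vinv - VX * solve(XtVX, VX.t());
  vec Py = P * y;
  double ll = -0.5 * (2.0 * accu(log(L.diag())) +
                      log_det_sympd(XtVX) + dot(y, Py));
  return Rcpp::List::create(
    Rcpp::Named("ok") = true, Rcpp::Named("ll") = ll,
    Rcpp::Named("P") = P, Rcpp::Named("Py") = Py);
}

// REML score vector and average-information matrix at the current point.
// [[Rcpp::export(name = ".bivar_derivs_cpp")]]
Rcpp::List bivar_derivs_cpp(const arma::mat& P, const arma::vec& Py,
                            const arma::mat& G11, const arma::mat& G22,
                            const arma::mat& G12,
                            const arma::uvec& conn,
                            const arma::uvec& partner,
                            bool est_se12) {
  const uword n1 = G11.n_rows, n2 = G22.n_rows, n = n1 + n2;
  const uword k = est_se12 ? 6 : 5;
  vec Py1 = Py.subvec(0, n1 - 1), Py2 = Py.subvec(n1, n - 1);

  mat Qm(n, k, fill::zeros);
  Qm.submat(0, 0, n1 - 1, 0) = G11 * Py1;
  Qm.submat(n1, 1, n - 1, 1) = G22 * Py2;
  Qm.submat(0, 2, n1 - 1, 2) = G12 * Py2;
  Qm.submat(n1, 2, n - 1, 2) = G12.t() * Py1;
  Qm.submat(0, 3, n1 - 1, 3) = Py1;
  Qm.submat(n1, 4, n - 1, 4) = Py2;
  if (est_se12)
    for (uword j = 0; j < conn.n_elem; ++j)
      Qm(conn(j), 5) = Py(partner(j));

  vec tr(k);
  tr(0) = accu(P.submat(0, 0, n1 - 1, n1 - 1) % G11);
  tr(1) = accu(P.submat(n1, n1, n - 1, n - 1) % G22);
  tr(2) = 2.0 * accu(P.submat(0, n1, n1 - 1, n - 1) % G12);
  vec dP = P.diag();
  tr(3) = accu(dP.subvec(0, n1 - 1));
  tr(4) = accu(dP.subvec(n1, n - 1));
  if (est_se12) {
    double s = 0;
    for (uword j = 0; j < conn.n_elem; ++j) s += P(conn(j), partner(j));
    tr(5) = s;
  }
  vec score = -0.5 * (tr - Qm.t() * Py);
  mat AI = 0.5 * (Qm.t() * (P * Qm));
  return Rcpp::List::create(Rcpp::Named("score") = score,
                            Rcpp::Named("AI") = AI);
}
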