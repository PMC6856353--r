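// Full-information maximum-likelihood kernel for twin Cholesky models.
//
// The expected covariance of a twin pair under an ACE Cholesky model is
//   within-twin block   W = AA' + CC' + EE'
//   cross-twin block    X = f.AA' + CC'      (f = 1 for MZ, 0.5 for DZ)
// assembled as the 2p x 2p matrix [[W, X], [X, W]].  The likelihood is
// accumulated over groups of pairs sharing a zygosity and missingness
// pattern, using the sufficient statistics (n, mean, scatter) of each
// group restricted to its observed entries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Rebuild path matrices from the parameter vector and return the total
// log-likelihood.  theta layout: free A entries, free C entries, free E
// entries (column-major order of the free mask), then the p free means.
// idx* are 1-based (row, col) index matrices into the p x p path matrices.
// [[Rcpp::export(name = ".fiml_eval_cpp")]]
double fiml_eval_cpp(const arma::vec& theta, const List& spec,
                     const List& groups) {
  const int p = as<int>(spec["p"]);
  arma::mat A = as<arma::mat>(spec["A"]);
  arma::mat E = as<arma::mat>(spec["E"]);
  const bool hasC = as<bool>(spec["hasC"]);
  arma::mat C;
  if (hasC) C = as<arma::mat>(spec["C"]);
  arma::vec means = as<arma::vec>(spec["means"]);

  const arma::umat idxA = as<arma::umat>(spec["idxA"]);
  const arma::umat idxC = as<arma::umat>(spec["idxC"]);
  const arma::umat idxE = as<arma::umat>(spec["idxE"]);

  arma::uword k = 0;
  for (arma::uword i = 0; i < idxA.n_rows; ++i)
    A(idxA(i, 0) - 1, idxA(i, 1) - 1) = theta(k++);
  for (arma::uword i = 0; i < idxC.n_rows; ++i)
    C(idxC(i, 0) - 1, idxC(i, 1) - 1) = theta(k++);
  for (arma::uword i = 0; i < idxE.n_rows; ++i)
    E(idxE(i, 0) - 1, idxE(i, 1) - 1) = theta(k++);
  for (int j = 0; j < p; ++j) means(j) = theta(k++);

  if (!A.is_finite() || !E.is_finite() || (hasC && !C.is_finite()) ||
      !means.is_finite())
    return R_NegInf;

  arma::mat AAt = A * A.t();
  arma::mat EEt = E * E.t();
  arma::mat CCt(p, p, arma::fill::zeros);
  if (hasC) CCt = C * C.t();

  arma::mat W = AAt + CCt + EEt;

  arma::vec mu(2 * p);
  mu.subvec(0, p - 1) = means;
  mu.subvec(p, 2 * p - 1) = means;

  double ll = 0.0;
  const int ng = groups.size();
  for (int g = 0; g < ng; ++g) {
    List grp = groups[g];
    const arma::uvec idx = as<arma::uvec>(grp["idx"]) - 1;  // 0-based
    const double n = as<double>(grp["n"]);
    const arma::vec xbar = as<arma::vec>(grp["xbar"]);
    const arma::mat S = as<arma::mat>(grp["S"]);
    const double f = as<double>(grp["factor"]);

    arma::mat X = f * AAt + CCt;
    arma::mat Sigma(2 * p, 2 * p);
    Sigma.submat(0, 0, p - 1, p - 1) = W;
    Sigma.submat(p, p, 2 * p - 1, 2 * p - 1) = W;
    Sigma.submat(0, p, p - 1, 2 * p - 1) = X;
    Sigma.submat(p, 0, 2 * p - 1, p - 1) = X;

    arma::mat Ssub = Sigma.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, Ssub, "lower")) return R_NegInf;

    double logdet = 0.0;
    for (arma::uword j = 0; j < L.n_rows; ++j) {
      if (L(j, j) <= 0.0) return R_NegInf;
      logdet += std::log(L(j, j));
    }
    logdet *= 2.0;

    const arma::uword kk = idx.n_elem;
    arma::vec d = xbar - mu.elem(idx);
    // tr(Sigma^-1 S) and d' Sigma^-1 d via triangular solves
    arma::mat Linv_S = arma::solve(arma::trimatl(L), S);
    arma::mat SinvS = arma::solve(arma::trimatu(L.t()), Linv_S);
    double tr = arma::trace(SinvS);
    arma::vec v = arma::solve(arma::trimatl(L), d);
    double quad = arma::dot(v, v);

    ll += -0.5 * n * (kk * LOG2PI + logdet + tr + quad);
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

// Log-likelihood of an unstructured multivariate normal (one group of the
// saturated model): theta = [means (k), lower-triangular Cholesky factor of
// Sigma (column-major, k(k+1)/2)].  Sufficient statistics as above.
// [[Rcpp::export(name = ".mvn_sat_eval_cpp")]]
double mvn_sat_eval_cpp(const arma::vec& theta, int k, const List& groups) {
  arma::vec mu = theta.subvec(0, k - 1);
  arma::mat L(k, k, arma::fill::zeros);
  arma::uword pos = k;
  for (int j = 0; j < k; ++j)
    for (int i = j; i < k; ++i) L(i, j) = theta(pos++);
  if (!L.is_finite() || !mu.is_finite()) return R_NegInf;

  arma::mat Sigma = L * L.t();
  arma::mat Lc;
  if (!arma::chol(Lc, Sigma, "lower")) return R_NegInf;

  double ll = 0.0;
  const int ng = groups.size();
  for (int g = 0; g < ng; ++g) {
    List grp = groups[g];
    const arma::uvec idx = as<arma::uvec>(grp["idx"]) - 1;
    const double n = as<double>(grp["n"]);
    const arma::vec xbar = as<arma::vec>(grp["xbar"]);
    const arma::mat S = as<arma::mat>(grp["S"]);

    arma::mat Ssub = Sigma.submat(idx, idx);
    arma::mat Ls;
    if (!arma::chol(Ls, Ssub, "lower")) return R_NegInf;
    double logdet = 0.0;
    for (arma::uword j = 0; j < Ls.n_rows; ++j) {
      if (Ls(j, j) <= 0.0) return R_NegInf;
      logdet += std::log(Ls(j, j));
    }
    logdet *= 2.0;

    arma::vec d = xbar - mu.elem(idx);
    arma::mat Linv_S = arma::solve(arma::trimatl(Ls), S);
    arma::mat SinvS = arma::solve(arma::trimatu(Ls.t()), Linv_S);
    double tr = arma::trace(SinvS);
    arma::vec v = arma::solve(arma::trimatl(Ls), d);
    double quad = arma::dot(v, v);

    ll += -0.5 * n * (idx.n_elem * LOG2PI + logdet + tr + quad);
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}
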