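#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

// Fast likelihood path: build the 4-state BV system (delta_bv, int_e,
// r_u, r_v) from a raw parameter vector and return delta_bv at the
// requested segment boundaries.  theta = (alpha_u, alpha_v, Kp, Ki[,
// A_u, A_v]); callers guarantee the invariants via box bounds.
// [[Rcpp::export]]
arma::vec bv_dbv_at(const arma::vec& theta, bool refined,
                    const arma::mat& U, const arma::vec& h,
                    const arma::uvec& idx) {
  const double fu = 1.0 / (1.0 + theta(0));
  const double fv = 1.0 / (1.0 + theta(1));
  const double Kp = theta(2), Ki = theta(3);
  const double Au = refined ? theta(4) : 0.0;
  const double Av = refined ? theta(5) : 0.0;

  arma::mat M(6, 6, arma::fill::zeros);
  M(0, 0) = -Kp; M(0, 1) = Ki; M(0, 2) = Kp; M(0, 3) = Kp;
  M(1, 0) = -1;  M(1, 2) = 1;  M(1, 3) = 1;
  M(2, 2) = Au;  M(3, 3) = Av;
  M(0, 4) = 1;   M(0, 5) = -1;
  M(2, 4) = fu;  M(3, 5) = -fv;

  const arma::uword m = h.n_elem;
  arma::vec dbv(m + 1);
  arma::vec x(4, arma::fill::zeros);
  dbv(0) = 0.0;
  std::map<long long, std::pair<arma::mat, arma::mat> > cache;
  for (arma::uword k = 0; k < m; ++k) {
    const long long key = llround(h(k) * 1e9);
    std::map<long long, std::pair<arma::mat, arma::mat> >::iterator it =
        cache.find(key);
    if (it == cache.end()) {
      arma::mat E = arma::expmat(M * h(k));
      it = cache.insert(std::make_pair(key, std::make_pair(
               arma::mat(E.submat(0, 0, 3, 3)),
               arma::mat(E.submat(0, 4, 3, 5))))).first;
    }
    x = it->second.first * x + it->second.second * U.row(k).t();
    dbv(k + 1) = x(0);
  }
  arma::vec out(idx.n_elem);
  for (arma::uword j = 0; j < idx.n_elem; ++j) out(j) = dbv(idx(j) - 1);
  return out;
}

// Zero-order-hold propagation of dx/dt = A x + B u(t), u piecewise constant.
//
// Segment k lasts h(k) minutes with input row U(k, ).  The discrete maps
// (Phi, Gamma) come from the matrix exponential of the augmented system
// [A B; 0 0], which is exact for piecewise-constant inputs.  Exponentials
// are cached per distinct segment length (protocols have few of them).
//
// Returns the state at every segment boundary: n x (m + 1).
// [[Rcpp::export]]
arma::mat sim_lti_zoh(const arma::mat& A, const arma::mat& B,
                      const arma::mat& U, const arma::vec& h,
                      const arma::vec& x0) {
  const arma::uword n = A.n_rows;
  const arma::uword p = B.n_cols;
  const arma::uword m = h.n_elem;
  if (U.n_rows != m || U.n_cols != p)
    Rcpp::stop("input matrix U must be length(h) x ncol(B)");

  arma::mat M(n + p, n + p, arma::fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = A;
  M.submat(0, n, n - 1, n + p - 1) = B;

  arma::mat out(n, m + 1);
  arma::vec x = x0;
  out.col(0) = x;

  std::map<long long, std::pair<arma::mat, arma::mat> > cache;
  for (arma::uword k = 0; k < m; ++k) {
    const long long key = llround(h(k) * 1e9);
    std::map<long long, std::pair<arma::mat, arma::mat> >::iterator it =
        cache.find(key);
    if (it == cache.end()) {
      arma::mat E = arma::expmat(M * h(k));
      it = cache.insert(std::make_pair(key, std::make_pair(
               arma::mat(E.submat(0, 0, n - 1, n - 1)),
               arma::mat(E.submat(0, n, n - 1, n + p - 1))))).first;
    }
    x = it->second.first * x + it->second.second * U.row(k).t();
    out.col(k + 1) = x;
  }
  return out;
}
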