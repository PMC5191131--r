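#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Revised primal simplex for  min c'x  s.t.  A x = b, x >= 0,
// started from a feasible basis. Dantzig pricing, switching permanently to
// Bland's rule after a degeneracy stall (termination guarantee).
// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(arma::vec c, arma::mat A, arma::vec b,
                  arma::uvec basis0, int max_iter, double tol) {
  const arma::uword m = A.n_rows, ncol = A.n_cols;
  arma::uvec basis = basis0 - 1;  // to 0-based
  bool bland = false;
  int stall = 0;
  double last_obj = std::numeric_limits<double>::infinity();

  for (int iter = 1; iter <= max_iter; ++iter) {
    arma::mat B = A.cols(basis);
    arma::vec xB = arma::solve(B, b, arma::solve_opts::fast);
    arma::vec cB = c.elem(basis);
    double obj = arma::dot(cB, xB);
    if (obj >= last_obj - 1e-12) { if (++stall > 50) bland = true; }
    else stall = 0;
    last_obj = obj;

    arma::vec y = arma::solve(B.t(), cB, arma::solve_opts::fast);
    arma::vec r = c - A.t() * y;
    for (arma::uword k = 0; k < m; ++k) r(basis(k)) = 0.0;

    arma::sword enter = -1;
    if (bland) {
      for (arma::uword j = 0; j < ncol; ++j) {
        if (r(j) < -tol) { enter = j; break; }
      }
    } else {
      double best = -tol;
      for (arma::uword j = 0; j < ncol; ++j) {
        if (r(j) < best) { best = r(j); enter = j; }
      }
    }
    if (enter < 0) {
      arma::vec x(ncol, arma::fill::zeros);
      for (arma::uword k = 0; k < m; ++k) x(basis(k)) = xB(k);
      return List::create(_["x"] = x, _["objective"] = obj,
                          _["basis"] = basis + 1, _["status"] = "optimal",
                          _["iterations"] = iter);
    }
    arma::vec d = arma::solve(B, A.col(enter), arma::solve_opts::fast);
    double rmin = std::numeric_limits<double>::infinity();
    for (arma::uword k = 0; k < m; ++k) {
      if (d(k) > tol) rmin = std::min(rmin, xB(k) / d(k));
    }
    if (!std::isfinite(rmin)) {
      return List::create(_["x"] = R_NilValue, _["objective"] = R_NegInf,
                          _["basis"] = basis + 1, _["status"] = "unbounded",
                          _["iterations"] = iter);
    }
    // leave: among ties, the smallest basis-variable index (Bland tie-break)
    arma::sword leave = -1;
    arma::uword best_var = ncol + 1;
    for (arma::uword k = 0; k < m; ++k) {
      if (d(k) > tol && xB(k) / d(k) <= rmin + tol && basis(k) < best_var) {
        best_var = basis(k);
        leave = k;
      }
    }
    basis(leave) = (arma::uword)enter;
  }
  return List::create(_["x"] = R_NilValue, _["objective"] = NA_REAL,
                      _["basis"] = basis + 1,
                      _["status"] = "iteration limit",
                      _["iterations"] = max_iter);
}
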