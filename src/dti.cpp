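// Per-voxel log-linear diffusion tensor estimation.
// Design row for volume i: [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy,
//                           -2b gx gz, -2b gy gz]
// parameters beta = [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".dti_fit")]]
List dti_fit(const arma::mat& design, const arma::mat& logS, bool wls) {
  // logS: nvol x nvox
  const arma::uword nvox = logS.n_cols, nvol = design.n_rows;
  arma::mat beta = arma::solve(design, logS);  // OLS start, 7 x nvox
  if (wls) {
    arma::mat pred = design * beta;  // predicted log-signals
    arma::mat betaw(7, nvox);
    arma::mat XtWX(7, 7);
    arma::vec XtWy(7);
    for (arma::uword v = 0; v < nvox; ++v) {
      XtWX.zeros();
      XtWy.zeros();
      for (arma::uword i = 0; i < nvol; ++i) {
        double w = std::exp(2.0 * pred(i, v));  // squared predicted signal
        const arma::rowvec xi = design.row(i);
        XtWX += w * (xi.t() * xi);
        XtWy += w * logS(i, v) * xi.t();
      }
      arma::vec sol;
      bool ok = arma::solve(sol, XtWX, XtWy,
                            arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
      if (ok) betaw.col(v) = sol;
      else betaw.col(v) = beta.col(v);  // fall back to OLS at degenerate voxels
    }
    beta = std::move(betaw);
  }
  // eigenvalues (descending) of each fitted tensor
  arma::mat evals(3, nvox);
  arma::mat33 D;
  arma::vec3 ev;
  for (arma::uword v = 0; v < nvox; ++v) {
    D(0, 0) = beta(1, v); D(1, 1) = beta(2, v); D(2, 2) = beta(3, v);
    D(0, 1) = D(1, 0) = beta(4, v);
    D(0, 2) = D(2, 0) = beta(5, v);
    D(1, 2) = D(2, 1) = beta(6, v);
    arma::eig_sym(ev, D);  // ascending
    evals(0, v) = ev[2]; evals(1, v) = ev[1]; evals(2, v) = ev[0];
  }
  return List::create(_["beta"] = beta, _["evals"] = evals);
}
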