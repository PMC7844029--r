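// Damped Newton solver for the L2-penalized Poisson log-likelihood of
// the LN encoding model. The design is passed in compressed-sparse-row
// form (row_ptr / 0-based col_idx / values) with an implicit unpenalized
// intercept as parameter 0; a logical row mask selects the training rows
// so cross-validation folds reuse one design without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// hot loops use raw pointers: element access must not depend on
// bounds-checking compile flags

static double objective_eta(const int *rp, const int *ci, const double *vx,
                            const double *y, const int *use, int n,
                            double pen, const arma::vec &w, double *eta) {
  const double *wp = w.memptr();
  const int Q = w.n_elem;
  double f = 0.0;
  for (int r = 0; r < n; ++r) {
    if (!use[r]) continue;
    double e = wp[0];
    for (int k = rp[r]; k < rp[r + 1]; ++k) e += vx[k] * wp[ci[k] + 1];
    if (e > 30.0) e = 30.0;
    eta[r] = e;
    f += y[r] * e - std::exp(e);
  }
  double penal = 0.0;
  for (int j = 1; j < Q; ++j) penal += wp[j] * wp[j];
  return f - 0.5 * pen * penal;
}

// [[Rcpp::export]]
List ln_newton_csr(IntegerVector rp, IntegerVector ci, NumericVector vx,
                   NumericVector y, LogicalVector use, double pen,
                   arma::vec w0, double tol, int maxit) {
  const int n = rp.size() - 1;
  const int Q = w0.n_elem;           // intercept + P weights
  const int *rp_p = rp.begin();
  const int *ci_p = ci.begin();
  const double *vx_p = vx.begin();
  const double *y_p = y.begin();
  const int *use_p = use.begin();
  arma::vec w = w0;
  arma::vec eta(n, arma::fill::zeros);
  double f = objective_eta(rp_p, ci_p, vx_p, y_p, use_p, n, pen, w,
                           eta.memptr());
  arma::vec g(Q, arma::fill::zeros);
  double gmax = R_PosInf;
  bool conv = false;
  int it = 0;
  while (it < maxit) {
    ++it;
    arma::mat H(Q, Q, arma::fill::zeros);
    double *Hp = H.memptr();
    g.zeros();
    double *gp = g.memptr();
    const double *ep = eta.memptr();
    for (int r = 0; r < n; ++r) {
      if (!use_p[r]) continue;
      const double lam = std::exp(ep[r]);
      const double res = y_p[r] - lam;
      gp[0] += res;
      Hp[0] += lam;
      for (int k = rp_p[r]; k < rp_p[r + 1]; ++k) {
        const int a = ci_p[k] + 1;
        const double va = vx_p[k];
        gp[a] += res * va;
        Hp[a * Q] += lam * va;         // H(0, a), column-major
        const double lva = lam * va;
        double *Hcol;
        for (int l = k; l < rp_p[r + 1]; ++l) {
          Hcol = Hp + (ci_p[l] + 1) * Q;
          Hcol[a] += lva * vx_p[l];    // upper triangle (sorted idx)
        }
      }
    }
    const double *wp = w.memptr();
    for (int j = 1; j < Q; ++j) { gp[j] -= pen * wp[j]; Hp[j * Q + j] += pen; }
    gmax = arma::abs(g).max();
    if (gmax < tol) { conv = true; break; }
    H = arma::symmatu(H);
    arma::vec delta;
    bool ok = arma::solve(delta, H, g, arma::solve_opts::likely_sympd +
                                         arma::solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-8;
      arma::solve(delta, H, g);
    }
    double step = 1.0;
    arma::vec w_new;
    arma::vec eta_new(n, arma::fill::zeros);
    double f_new = R_NegInf;
    while (true) {
      w_new = w + step * delta;
      f_new = objective_eta(rp_p, ci_p, vx_p, y_p, use_p, n, pen, w_new,
                            eta_new.memptr());
      if (std::isfinite(f_new) && (f_new >= f || step < 1e-6)) break;
      step *= 0.5;
    }
    const double improved = f_new - f;
    w = w_new; eta = eta_new; f = f_new;
    if (improved < 1e-10 * std::max(1.0, std::fabs(f))) {
      // re-check optimality at the (essentially converged) point
      arma::vec g2(Q, arma::fill::zeros);
      double *g2p = g2.memptr();
      const double *ep2 = eta.memptr();
      const double *wp2 = w.memptr();
      for (int r = 0; r < n; ++r) {
        if (!use_p[r]) continue;
        const double res = y_p[r] - std::exp(ep2[r]);
        g2p[0] += res;
        for (int k = rp_p[r]; k < rp_p[r + 1]; ++k)
          g2p[ci_p[k] + 1] += res * vx_p[k];
      }
      for (int j = 1; j < Q; ++j) g2p[j] -= pen * wp2[j];
      gmax = arma::abs(g2).max();
      conv = gmax < 1e-4;
      break;
    }
  }
  double kernel = f;
  double penal = 0.0;
  for (unsigned j = 1; j < w.n_elem; ++j) penal += w[j] * w[j];
  kernel += 0.5 * pen * penal;
  return List::create(_["coef"] = w, _["kernel"] = kernel,
                      _["converged"] = conv, _["iter"] = it,
                      _["grad_max"] = gmax);
}
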