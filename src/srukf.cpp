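// Square-root unscented Kalman filter core.
//
// Maintains the upper-triangular Cholesky factor S (S'S = P) of the state
// covariance through QR decompositions and rank-1 updates/downdates; the
// full covariance is never formed except in the re-factorization fallback.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// rank-1 Cholesky update (sgn = +1) / downdate (sgn = -1) of an upper factor
static bool chol_rank1(mat &R, vec x, double sgn) {
  const uword n = R.n_rows;
  for (uword k = 0; k < n; ++k) {
    double rkk = R(k, k);
    double d = rkk * rkk + sgn * x(k) * x(k);
    if (d <= 0.0 || !std::isfinite(d)) return false;
    double r = std::sqrt(d);
    double c = r / rkk;
    double s = x(k) / rkk;
    R(k, k) = r;
    for (uword j = k + 1; j < n; ++j) {
      R(k, j) = (R(k, j) + sgn * s * x(j)) / c;
      x(j) = c * x(j) - s * R(k, j);
    }
  }
  return true;
}

// recompute an upper Cholesky factor from S'S + sgn * w * x x', flooring
// eigenvalues (fallback when a downdate loses positive definiteness)
static mat refactor(const mat &S, const vec &x, double w, double sgn) {
  mat P = S.t() * S + sgn * w * (x * x.t());
  P = 0.5 * (P + P.t());
  vec ev;
  mat V;
  eig_sym(ev, V, P);
  double fl = 1e-12 * std::max(ev.max(), 1e-300);
  ev = clamp(ev, fl, datum::inf);
  mat Pf = V * diagmat(ev) * V.t();
  return chol(0.5 * (Pf + Pf.t()), "upper");
}

static mat qr_upper(const mat &M) {
  mat Qm, Rm;
  qr_econ(Qm, Rm, M);
  // fix signs so the factor has a positive diagonal
  for (uword i = 0; i < Rm.n_rows; ++i) {
    if (Rm(i, i) < 0) Rm.row(i) *= -1.0;
  }
  return Rm;
}

// [[Rcpp::export]]
Rcpp::List srukf_run_cpp(const arma::mat &F, const arma::mat &Qchol,
                         const arma::mat &H, const arma::mat &Rchol,
                         const arma::mat &S0, const arma::vec &x0,
                         const arma::mat &E, double alpha, double beta,
                         double kappa) {
  const uword n = F.n_rows;
  const uword m = H.n_rows;
  const uword T = E.n_cols;
  const double lam = alpha * alpha * (n + kappa) - n;
  const double gam = std::sqrt(n + lam);
  const double wm0 = lam / (n + lam);
  const double wc0 = wm0 + 1.0 - alpha * alpha + beta;
  const double wi = 0.5 / (n + lam);
  const double swi = std::sqrt(wi);

  vec x = x0;
  mat S = S0;
  mat out(n, T);
  int n_refactor = 0;

  mat sig(n, 2 * n + 1), sigp(n, 2 * n + 1);
  for (uword t = 0; t < T; ++t) {
    // --- sigma points from (x, S), S upper: sqrt factor is S' (columns) ---
    sig.col(0) = x;
    for (uword i = 0; i < n; ++i) {
      vec si = S.row(i).t();
      sig.col(1 + i) = x + gam * si;
      sig.col(1 + n + i) = x - gam * si;
    }
    // --- time update ---
    sigp = F * sig;
    vec xbar = wm0 * sigp.col(0);
    for (uword i = 1; i < 2 * n + 1; ++i) xbar += wi * sigp.col(i);
    mat dev(2 * n + n, n);
    for (uword i = 1; i < 2 * n + 1; ++i) {
      dev.row(i - 1) = swi * (sigp.col(i) - xbar).t();
    }
    dev.rows(2 * n, 3 * n - 1) = Qchol;
    mat Sp = qr_upper(dev);
    vec d0 = sigp.col(0) - xbar;
    double sgn0 = (wc0 >= 0) ? 1.0 : -1.0;
    if (!chol_rank1(Sp, std::sqrt(std::abs(wc0)) * d0, sgn0)) {
      Sp = refactor(Sp, d0, std::abs(wc0), sgn0);
      ++n_refactor;
    }
    // --- redraw sigma points from the predicted density ---
    sig.col(0) = xbar;
    for (uword i = 0; i < n; ++i) {
      vec si = Sp.row(i).t();
      sig.col(1 + i) = xbar + gam * si;
      sig.col(1 + n + i) = xbar - gam * si;
    }
    // --- measurement update ---
    mat zsig = H * sig;
    vec zbar = wm0 * zsig.col(0);
    for (uword i = 1; i < 2 * n + 1; ++i) zbar += wi * zsig.col(i);
    mat devz(2 * n + m, m);
    for (uword i = 1; i < 2 * n + 1; ++i) {
      devz.row(i - 1) = swi * (zsig.col(i) - zbar).t();
    }
    devz.rows(2 * n, 2 * n + m - 1) = Rchol;
    mat Sz = qr_upper(devz);
    vec dz0 = zsig.col(0) - zbar;
    if (!chol_rank1(Sz, std::sqrt(std::abs(wc0)) * dz0, sgn0)) {
      Sz = refactor(Sz, dz0, std::abs(wc0), sgn0);
      ++n_refactor;
    }
    mat Pxz = wc0 * (sig.col(0) - xbar) * (zsig.col(0) - zbar).t();
    for (uword i = 1; i < 2 * n + 1; ++i) {
      Pxz += wi * (sig.col(i) - xbar) * (zsig.col(i) - zbar).t();
    }
    mat Kt = solve(trimatu(Sz), solve(trimatl(Sz.t()), Pxz.t()));
    mat K = Kt.t();
    x = xbar + K * (E.col(t) - zbar);
    mat U = K * Sz.t(); // n x m; P = P_pred - U U'
    S = Sp;
    for (uword j = 0; j < m; ++j) {
      vec u = U.col(j);
      if (!chol_rank1(S, u, -1.0)) {
        S = refactor(S, u, 1.0, -1.0);
        ++n_refactor;
      }
    }
    out.col(t) = x;
  }
  return Rcpp::List::create(
    Rcpp::Named("states") = out,
    Rcpp::Named("n_refactor") = n_refactor
  );
}
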