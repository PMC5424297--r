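// Numerical core: compressed-encoding ODE evaluation, the embedded
// Runge-Kutta-Fehlberg 4(5) step, BDF steps solved by modified
// Newton-Raphson with reused LU factors, and the full sampling loop.
// All indices arriving from R are 0-based (the encoding's convention).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Plain view of the compressed encoding (no copies of the R vectors).
struct Encoding {
  const int *vh_species, *vh_row, *vh_kidx;
  const double *vh_coef;
  const int *oh_first, *oh_last;      // per species, inclusive span; first>last => empty
  const int *va_species, *va_exp;
  const int *oa_first, *oa_last;      // per monomial row (reaction), inclusive span
  const double *K;
  int n_species, n_reactions;
};

Encoding make_encoding(const List &enc) {
  Encoding e;
  e.vh_species = INTEGER(enc["vh_species"]);
  e.vh_row     = INTEGER(enc["vh_row"]);
  e.vh_coef    = REAL(enc["vh_coef"]);
  e.vh_kidx    = INTEGER(enc["vh_kidx"]);
  e.oh_first   = INTEGER(enc["oh_first"]);
  e.oh_last    = INTEGER(enc["oh_last"]);
  e.va_species = INTEGER(enc["va_species"]);
  e.va_exp     = INTEGER(enc["va_exp"]);
  e.oa_first   = INTEGER(enc["oa_first"]);
  e.oa_last    = INTEGER(enc["oa_last"]);
  e.K          = REAL(enc["constants"]);
  e.n_species  = as<int>(enc["n_species"]);
  e.n_reactions = as<int>(enc["n_reactions"]);
  return e;
}

// Product of reactant factors of one monomial row: prod_r X_r^{a_ir}.
inline double monomial_factor(const Encoding &e, int row, const double *X) {
  double prod = 1.0;
  for (int t = e.oa_first[row]; t <= e.oa_last[row]; ++t) {
    const double x = X[e.va_species[t]];
    prod *= (e.va_exp[t] == 2) ? x * x : x;
  }
  return prod;
}

// f_j = sum over species-j entries of h_ji * k_i * prod X^a.
void eval_deriv(const Encoding &e, const double *X, double *f) {
  for (int j = 0; j < e.n_species; ++j) {
    double acc = 0.0;
    for (int t = e.oh_first[j]; t <= e.oh_last[j]; ++t)
      acc += e.vh_coef[t] * e.K[e.vh_kidx[t]] * monomial_factor(e, e.vh_row[t], X);
    f[j] = acc;
  }
}

// Exact Jacobian of the polynomial right-hand side.
void eval_jac(const Encoding &e, const double *X, arma::mat &J) {
  J.zeros();
  for (int j = 0; j < e.n_species; ++j) {
    for (int t = e.oh_first[j]; t <= e.oh_last[j]; ++t) {
      const int row = e.vh_row[t];
      const double hk = e.vh_coef[t] * e.K[e.vh_kidx[t]];
      for (int d = e.oa_first[row]; d <= e.oa_last[row]; ++d) {
        // differentiate w.r.t. the species of entry d, keep the others
        double term = hk;
        for (int o = e.oa_first[row]; o <= e.oa_last[row]; ++o) {
          const double x = X[e.va_species[o]];
          if (o == d)
            term *= (e.va_exp[o] == 2) ? 2.0 * x : 1.0;
          else
            term *= (e.va_exp[o] == 2) ? x * x : x;
        }
        J(j, e.va_species[d]) += term;
      }
    }
  }
}

// Classical Fehlberg 4(5) tableau.
const double C2 = 1.0 / 4.0, C3 = 3.0 / 8.0, C4 = 12.0 / 13.0, C5 = 1.0, C6 = 1.0 / 2.0;
const double A21 = 1.0 / 4.0;
const double A31 = 3.0 / 32.0, A32 = 9.0 / 32.0;
const double A41 = 1932.0 / 2197.0, A42 = -7200.0 / 2197.0, A43 = 7296.0 / 2197.0;
const double A51 = 439.0 / 216.0, A52 = -8.0, A53 = 3680.0 / 513.0, A54 = -845.0 / 4104.0;
const double A61 = -8.0 / 27.0, A62 = 2.0, A63 = -3544.0 / 2565.0, A64 = 1859.0 / 4104.0,
             A65 = -11.0 / 40.0;
// fourth-order (w) and fifth-order (u) weights
const double B41 = 25.0 / 216.0, B43 = 1408.0 / 2565.0, B44 = 2197.0 / 4104.0, B45 = -1.0 / 5.0;
const double B51 = 16.0 / 135.0, B53 = 6656.0 / 12825.0, B54 = 28561.0 / 56430.0,
             B55 = -9.0 / 50.0, B56 = 2.0 / 55.0;
// ER = |w - u| / dt evaluated directly as |sum (b4 - b5)_i l_i|, which is
// algebraically identical but avoids the cancellation of forming u and w first.
const double E1 = B41 - B51, E3 = B43 - B53, E4 = B44 - B54, E5 = B45 - B55, E6 = -B56;

// One RKF step: fills stages (N x 6), u, w, ER.
void rkf_core(const Encoding &e, const arma::vec &X, double dt,
              arma::mat &l, arma::vec &u, arma::vec &w, arma::vec &er) {
  const int N = e.n_species;
  arma::vec tmp(N);
  eval_deriv(e, X.memptr(), l.colptr(0));
  tmp = X + dt * (A21 * l.col(0));
  eval_deriv(e, tmp.memptr(), l.colptr(1));
  tmp = X + dt * (A31 * l.col(0) + A32 * l.col(1));
  eval_deriv(e, tmp.memptr(), l.colptr(2));
  tmp = X + dt * (A41 * l.col(0) + A42 * l.col(1) + A43 * l.col(2));
  eval_deriv(e, tmp.memptr(), l.colptr(3));
  tmp = X + dt * (A51 * l.col(0) + A52 * l.col(1) + A53 * l.col(2) + A54 * l.col(3));
  eval_deriv(e, tmp.memptr(), l.colptr(4));
  tmp = X + dt * (A61 * l.col(0) + A62 * l.col(1) + A63 * l.col(2) + A64 * l.col(3) +
                  A65 * l.col(4));
  eval_deriv(e, tmp.memptr(), l.colptr(5));
  w = X + dt * (B41 * l.col(0) + B43 * l.col(2) + B44 * l.col(3) + B45 * l.col(4));
  u = X + dt * (B51 * l.col(0) + B53 * l.col(2) + B54 * l.col(3) + B55 * l.col(4) +
                B56 * l.col(5));
  er = arma::abs(E1 * l.col(0) + E3 * l.col(2) + E4 * l.col(3) + E5 * l.col(4) +
                 E6 * l.col(5));
}

// Modified Newton-Raphson for the BDF residual
//   G(z) = z + hist_comb - dt*beta0*f(z),  iteration matrix I - dt*beta0*J,
// factorized once (LU, partial pivoting) and reused; one refactorization is
// allowed when the update norm stagnates. Returns true on convergence.
bool bdf_newton(const Encoding &e, const arma::vec &hist_comb, double dt, double beta0,
                arma::vec &z, double eps_nr, int max_it, int &iters) {
  const int N = e.n_species;
  arma::vec f(N), G(N), step(N);
  arma::mat J(N, N), L, U;
  arma::uvec P;
  bool refactorized = false;

  eval_jac(e, z.memptr(), J);
  arma::mat M = arma::eye(N, N) - dt * beta0 * J;
  arma::mat Pm;
  if (!arma::lu(L, U, Pm, M)) return false;
  if (arma::any(arma::abs(U.diag()) < 1e-300)) return false;

  double prev_norm = -1.0;
  int stagnant = 0;
  for (iters = 0; iters < max_it; ++iters) {
    eval_deriv(e, z.memptr(), f.memptr());
    G = z + hist_comb - dt * beta0 * f;
    if (!G.is_finite()) return false;
    step = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(L), Pm * G));
    z -= step;
    const double nrm = arma::norm(step, "inf");
    if (nrm < eps_nr) { ++iters; return true; }
    if (prev_norm > 0 && nrm > 0.9 * prev_norm) {
      if (++stagnant >= 3) {
        if (refactorized) return false;  // already retried with a fresh Jacobian
        eval_jac(e, z.memptr(), J);
        M = arma::eye(N, N) - dt * beta0 * J;
        if (!arma::lu(L, U, Pm, M)) return false;
        refactorized = true;
        stagnant = 0;
        prev_norm = -1.0;
        continue;
      }
    } else {
      stagnant = 0;
    }
    prev_norm = nrm;
  }
  return false;
}

void bdf_table(int q, arma::vec &alpha, double &beta0) {
  switch (q) {
  case 1: alpha = {1.0, -1.0}; beta0 = 1.0; break;
  case 2: alpha = {1.0, -4.0 / 3.0, 1.0 / 3.0}; beta0 = 2.0 / 3.0; break;
  case 3: alpha = {1.0, -18.0 / 11.0, 9.0 / 11.0, -2.0 / 11.0}; beta0 = 6.0 / 11.0; break;
  case 4:
    alpha = {1.0, -48.0 / 25.0, 36.0 / 25.0, -16.0 / 25.0, 3.0 / 25.0};
    beta0 = 12.0 / 25.0;
    break;
  case 5:
    alpha = {1.0, -300.0 / 137.0, 300.0 / 137.0, -200.0 / 137.0, 75.0 / 137.0,
             -12.0 / 137.0};
    beta0 = 60.0 / 137.0;
    break;
  case 6:
    alpha = {1.0, -360.0 / 147.0, 450.0 / 147.0, -400.0 / 147.0, 225.0 / 147.0,
             -72.0 / 147.0, 10.0 / 147.0};
    beta0 = 60.0 / 147.0;
    break;
  default: stop("BDF order must be between 1 and 6");
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_eval_deriv(List enc, NumericVector X) {
  Encoding e = make_encoding(enc);
  NumericVector f(e.n_species);
  eval_deriv(e, X.begin(), f.begin());
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_jacobian(List enc, NumericVector X) {
  Encoding e = make_encoding(enc);
  arma::mat J(e.n_species, e.n_species);
  eval_jac(e, X.begin(), J);
  return wrap(J);
}

// [[Rcpp::export]]
List cpp_rkf_step(List enc, NumericVector X, double dt) {
  Encoding e = make_encoding(enc);
  const int N = e.n_species;
  arma::vec x(X.begin(), N), u(N), w(N), er(N);
  arma::mat l(N, 6);
  rkf_core(e, x, dt, l, u, w, er);
  return List::create(_["stages"] = wrap(l), _["u"] = wrap(u), _["w"] = wrap(w),
                      _["ER"] = wrap(er));
}

// [[Rcpp::export]]
List cpp_bdf_step(List enc, NumericMatrix history, double dt, int q, double eps_nr,
                  int max_it) {
  Encoding e = make_encoding(enc);
  const int N = e.n_species;
  if (history.nrow() < q) stop("history must hold at least q states");
  arma::vec alpha;
  double beta0;
  bdf_table(q, alpha, beta0);
  // history row 0 = most recent state X(t); combination sum_{i=1..q} alpha_i X(t-(i-1)dt)
  arma::vec hist_comb(N, arma::fill::zeros);
  for (int i = 1; i <= q; ++i)
    for (int j = 0; j < N; ++j) hist_comb(j) += alpha(i) * history(i - 1, j);
  arma::vec z(N);
  for (int j = 0; j < N; ++j) z(j) = history(0, j);  // initial guess: latest state
  int iters = 0;
  bool ok = bdf_newton(e, hist_comb, dt, beta0, z, eps_nr, max_it, iters);
  return List::create(_["state"] = wrap(z), _["converged"] = ok, _["iterations"] = iters);
}

// Full sampling loop: explicit RKF steps with the per-species error controller,
// switch to BDF macro-steps when the step-size collapses below eps_s.
// [[Rcpp::export]]
List cpp_simulate(List enc, NumericVector X0, NumericVector times, NumericVector eps,
                  double dt0, double eps_s, double delta_max, double dt_max_opt,
                  int q, double dt_bdf, double eps_nr, int max_it, int bdf_run_steps) {
  Encoding e = make_encoding(enc);
  const int N = e.n_species;
  const int S = times.size();
  arma::vec X(X0.begin(), N), u(N), w(N), er(N), epsv(eps.begin(), N);
  arma::mat l(N, 6);
  arma::mat out(S, N);
  long accepted = 0, rejected = 0, bdf_steps = 0, switches = 0;
  std::string error_msg = "";

  for (int j = 0; j < N; ++j) out(0, j) = X(j);
  double t = times[0];
  double dt = dt0;
  // BDF history: row 0 most recent; valid rows tracked by hist_len, spacing hist_dt
  arma::mat hist(q, N, arma::fill::zeros);
  int hist_len = 0;
  double hist_dt = -1.0;

  for (int s = 1; s < S && error_msg.empty(); ++s) {
    const double target = times[s];
    while (t < target) {
      const double remaining = target - t;
      if (remaining <= 1e-14 * std::max(1.0, std::abs(target))) { t = target; break; }
      const double dt_eff = std::min(dt, remaining);
      rkf_core(e, X, dt_eff, l, u, w, er);
      const bool finite = u.is_finite() && er.is_finite();
      bool ok = finite;
      if (finite)
        for (int j = 0; j < N; ++j)
          if (er(j) > epsv(j)) { ok = false; break; }
      if (ok) {
        ++accepted;
        X = u;
        t += dt_eff;
        double mind = delta_max;
        for (int j = 0; j < N; ++j) {
          const double d = (er(j) == 0.0)
                               ? delta_max
                               : 0.84 * std::pow(epsv(j) / er(j), 0.25);
          mind = std::min(mind, d);
        }
        const double dt_cap = (dt_max_opt > 0) ? dt_max_opt : remaining;
        dt = std::min(std::max(dt_eff * mind, 1e-300), std::max(dt_cap, dt0));
        hist_len = 0;  // explicit progress invalidates the BDF history
        continue;
      }
      ++rejected;
      double mind = delta_max;
      bool any = false;
      if (finite)
        for (int j = 0; j < N; ++j)
          if (er(j) > 0 && std::isfinite(er(j))) {
            mind = std::min(mind, 0.84 * std::pow(epsv(j) / er(j), 0.25));
            any = true;
          }
      if (!any) mind = 0.1;  // non-finite stages: shrink hard
      const double dt_new = dt_eff * mind;
      if (dt_new >= eps_s) { dt = dt_new; continue; }
      // stiffness detected: run BDF macro-steps
      ++switches;
      if (hist_len == 0) {
        hist.row(0) = X.t();
        hist_len = 1;
        hist_dt = -1.0;
      }
      for (int ms = 0; ms < bdf_run_steps && t < target; ++ms) {
        const double h = std::min(dt_bdf, target - t);
        if (h <= 0) break;
        if (hist_dt > 0 && std::abs(h - hist_dt) > 1e-12 * dt_bdf) {
          // spacing about to break: keep only the current state
          hist.row(0) = X.t();
          hist_len = 1;
        }
        const int q_eff = std::min(q, hist_len);  // order ramp-up
        arma::vec alpha;
        double beta0;
        bdf_table(q_eff, alpha, beta0);
        arma::vec hist_comb(N, arma::fill::zeros);
        for (int i = 1; i <= q_eff; ++i) hist_comb += alpha(i) * hist.row(i - 1).t();
        arma::vec z = X;
        int iters = 0;
        if (!bdf_newton(e, hist_comb, h, beta0, z, eps_nr, max_it, iters)) {
          error_msg = "Newton-Raphson failed to converge in BDF step at t=" +
                      std::to_string(t);
          break;
        }
        if (!z.is_finite()) { error_msg = "non-finite state in BDF step"; break; }
        // shift history down, push new state on top
        for (int i = std::min(hist_len, q - 1); i >= 1; --i) hist.row(i) = hist.row(i - 1);
        hist.row(0) = z.t();
        hist_len = std::min(hist_len + 1, q);
        hist_dt = h;
        X = z;
        t += h;
        ++bdf_steps;
      }
      dt = dt0;  // hand control back to the explicit method
    }
    if (!error_msg.empty()) break;
    if (!X.is_finite()) { error_msg = "non-finite state during integration"; break; }
    for (int j = 0; j < N; ++j) out(s, j) = X(j);
  }

  return List::create(_["states"] = wrap(out), _["accepted"] = (double)accepted,
                      _["rejected"] = (double)rejected, _["bdf_steps"] = (double)bdf_steps,
                      _["switches"] = (double)switches, _["error"] = error_msg);
}
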