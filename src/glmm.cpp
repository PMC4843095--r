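// Marginal likelihood of a per-gene Poisson log-linear mixed model:
//   y_i ~ Poisson(exp(x_i' beta + offset_i + u_rep[rep_i] + u_plate[plate_i]))
//   u_rep ~ N(0, s_rep^2 I), u_plate ~ N(0, s_plate^2 I), independent.
// Evaluated by Laplace approximation over the joint random-effect vector,
// or by per-group adaptive Gauss-Hermite quadrature when a single grouping
// factor is active (the two-factor likelihood does not factor by group).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BIG = 1e10;
static const double SD_ACTIVE = 1e-8;

// penalized joint log density g(u) up to the prior normalizer, plus helpers
struct GlmmData {
  arma::vec y, eta0, lgy;   // lgy = lgamma(y+1)
  arma::ivec rep, plate;    // 0-based column index into u, or -1 if inactive
  int q_rep, q_plate;
  double s_rep, s_plate;
};

static bool eta_ok(const arma::vec& eta) {
  return eta.max() < 40.0 && eta.is_finite();
}

static arma::vec make_eta(const GlmmData& d, const arma::vec& u) {
  arma::vec eta = d.eta0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    if (d.q_rep > 0)   eta[i] += u[d.rep[i]];
    if (d.q_plate > 0) eta[i] += u[d.q_rep + d.plate[i]];
  }
  return eta;
}

// log joint density: Poisson loglik + N(0, D) prior (with normalizer)
static double g_joint(const GlmmData& d, const arma::vec& u,
                      const arma::vec& eta) {
  double ll = arma::sum(d.y % eta - arma::exp(eta) - d.lgy);
  for (int j = 0; j < d.q_rep; ++j)
    ll += -0.5 * u[j] * u[j] / (d.s_rep * d.s_rep)
          - 0.5 * std::log(2.0 * M_PI * d.s_rep * d.s_rep);
  for (int j = 0; j < d.q_plate; ++j) {
    double uj = u[d.q_rep + j];
    ll += -0.5 * uj * uj / (d.s_plate * d.s_plate)
          - 0.5 * std::log(2.0 * M_PI * d.s_plate * d.s_plate);
  }
  return ll;
}

// Laplace log marginal likelihood; returns -BIG on numeric failure
static double loglik_laplace(const GlmmData& d) {
  int q = d.q_rep + d.q_plate;
  if (q == 0) {
    if (!eta_ok(d.eta0)) return -BIG;
    return arma::sum(d.y % d.eta0 - arma::exp(d.eta0) - d.lgy);
  }
  arma::vec u(q, arma::fill::zeros);
  arma::vec eta = make_eta(d, u);
  if (!eta_ok(eta)) return -BIG;
  double g = g_joint(d, u, eta);
  arma::vec dinv(q);
  for (int j = 0; j < d.q_rep; ++j)   dinv[j] = 1.0 / (d.s_rep * d.s_rep);
  for (int j = 0; j < d.q_plate; ++j) dinv[d.q_rep + j] =
      1.0 / (d.s_plate * d.s_plate);

  arma::mat H(q, q);
  for (int it = 0; it < 100; ++it) {
    arma::vec mu = arma::exp(eta);
    arma::vec grad(q, arma::fill::zeros);
    H.zeros();
    for (arma::uword i = 0; i < d.y.n_elem; ++i) {
      int jr = d.q_rep > 0 ? d.rep[i] : -1;
      int jp = d.q_plate > 0 ? d.q_rep + d.plate[i] : -1;
      double r = d.y[i] - mu[i];
      if (jr >= 0) { grad[jr] += r; H(jr, jr) += mu[i]; }
      if (jp >= 0) { grad[jp] += r; H(jp, jp) += mu[i]; }
      if (jr >= 0 && jp >= 0) { H(jr, jp) += mu[i]; H(jp, jr) += mu[i]; }
    }
    grad -= dinv % u;
    H.diag() += dinv;
    arma::vec step;
    if (!arma::solve(step, H, grad, arma::solve_opts::likely_sympd))
      return -BIG;
    // step halving to keep g increasing
    double t = 1.0;
    for (int h = 0; h < 30; ++h) {
      arma::vec u_new = u + t * step;
      arma::vec eta_new = make_eta(d, u_new);
      if (eta_ok(eta_new)) {
        double g_new = g_joint(d, u_new, eta_new);
        if (g_new >= g - 1e-12) { u = u_new; eta = eta_new; g = g_new; break; }
      }
      t *= 0.5;
      if (h == 29) return g;  // stuck; return current value
    }
    if (arma::abs(t * step).max() < 1e-11) break;
  }
  // recompute Hessian at the mode
  arma::vec mu = arma::exp(eta);
  H.zeros();
  for (arma::uword i = 0; i < d.y.n_elem; ++i) {
    int jr = d.q_rep > 0 ? d.rep[i] : -1;
    int jp = d.q_plate > 0 ? d.q_rep + d.plate[i] : -1;
    if (jr >= 0) H(jr, jr) += mu[i];
    if (jp >= 0) H(jp, jp) += mu[i];
    if (jr >= 0 && jp >= 0) { H(jr, jp) += mu[i]; H(jp, jr) += mu[i]; }
  }
  H.diag() += dinv;
  double ldet, sign;
  if (!arma::log_det(ldet, sign, H) || sign <= 0) return -BIG;
  return g + 0.5 * q * std::log(2.0 * M_PI) - 0.5 * ldet;
}

// adaptive Gauss-Hermite over a single grouping factor (likelihood factors
// across groups); gidx 0-based, ngrp levels, random-effect sd s
static double loglik_agq(const arma::vec& y, const arma::vec& eta0,
                         const arma::vec& lgy, const arma::ivec& gidx,
                         int ngrp, double s,
                         const arma::vec& ghx, const arma::vec& ghw) {
  if (!eta_ok(eta0)) return -BIG;
  double total = 0.0;
  double s2 = s * s;
  int K = ghx.n_elem;
  for (int gg = 0; gg < ngrp; ++gg) {
    std::vector<int> idx;
    for (arma::uword i = 0; i < y.n_elem; ++i)
      if (gidx[i] == gg) idx.push_back(i);
    if (idx.empty()) continue;
    // 1-D Newton for the mode of h(u)
    double u = 0.0;
    double h_cur = -std::numeric_limits<double>::infinity();
    auto h_of = [&](double uu) {
      double v = -0.5 * uu * uu / s2 - 0.5 * std::log(2.0 * M_PI * s2);
      for (int i : idx) {
        double e = eta0[i] + uu;
        if (e > 40.0) return -BIG;
        v += y[i] * e - std::exp(e) - lgy[i];
      }
      return v;
    };
    h_cur = h_of(u);
    double curv = 1.0 / s2;
    for (int it = 0; it < 100; ++it) {
      double grad = -u / s2, hess = 1.0 / s2;
      for (int i : idx) {
        double mu = std::exp(eta0[i] + u);
        grad += y[i] - mu;
        hess += mu;
      }
      curv = hess;
      double step = grad / hess, t = 1.0;
      for (int hh = 0; hh < 30; ++hh) {
        double h_new = h_of(u + t * step);
        if (h_new >= h_cur - 1e-12) { u += t * step; h_cur = h_new; break; }
        t *= 0.5;
      }
      if (std::abs(t * step) < 1e-12) break;
    }
    double tau = 1.0 / std::sqrt(curv);
    // log sum_k w_k exp(h(u + sqrt2 tau x_k) + x_k^2) + log(sqrt2 tau)
    arma::vec terms(K);
    for (int k = 0; k < K; ++k)
      terms[k] = std::log(ghw[k]) + h_of(u + M_SQRT2 * tau * ghx[k])
                 + ghx[k] * ghx[k];
    double m = terms.max();
    if (!std::isfinite(m)) return -BIG;
    total += m + std::log(arma::sum(arma::exp(terms - m)))
             + std::log(M_SQRT2 * tau);
  }
  return total;
}

// [[Rcpp::export]]
double cpp_glmm_loglik(const arma::vec& par, const arma::vec& y,
                       const arma::mat& X, const arma::vec& offset,
                       const arma::ivec& rep_idx, const arma::ivec& plate_idx,
                       int method, const arma::vec& ghx,
                       const arma::vec& ghw) {
  int p = X.n_cols;
  arma::vec beta = par.subvec(0, p - 1);
  double s_rep = std::max(par[p], 0.0);
  double s_plate = std::max(par[p + 1], 0.0);

  GlmmData d;
  d.y = y;
  d.eta0 = X * beta + offset;
  d.lgy = arma::vec(y.n_elem);
  for (arma::uword i = 0; i < y.n_elem; ++i) d.lgy[i] = std::lgamma(y[i] + 1.0);
  bool a_rep = s_rep > SD_ACTIVE, a_plate = s_plate > SD_ACTIVE;
  d.q_rep = a_rep ? (rep_idx.max() + 1) : 0;
  d.q_plate = a_plate ? (plate_idx.max() + 1) : 0;
  d.rep = rep_idx;
  d.plate = plate_idx;
  d.s_rep = s_rep;
  d.s_plate = s_plate;

  if (method == 1 && (int)a_rep + (int)a_plate == 1) {
    if (a_rep)
      return loglik_agq(y, d.eta0, d.lgy, rep_idx, d.q_rep, s_rep, ghx, ghw);
    return loglik_agq(y, d.eta0, d.lgy, plate_idx, d.q_plate, s_plate,
                      ghx, ghw);
  }
  return loglik_laplace(d);
}
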