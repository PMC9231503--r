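// Laplace-approximate maximum likelihood for GLMMs with crossed random
// intercepts. Outer BFGS over psi = (beta, log sigma[, log sigma_e]) with
// analytic gradients (including the third-derivative correction from the
// log-determinant term); inner Newton for the random-effect modes.
// Families: binomial-logit (with trial sizes), Poisson-log, Gaussian.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

const double LOGSIG_LO = -10.0; // sigma ~ 5e-5: variance component at zero
// latent (logit/log) scales cannot support huge random-effect SDs and the
// Laplace objective degenerates there; the gaussian response scale can
inline double hi_logsig(int family) { return family == 2 ? 15.0 : 4.0; }

struct Problem {
  mat X;        // n x p fixed design
  vec y;        // successes / counts / response
  vec m;        // binomial trial sizes (1 elsewhere)
  umat fidx;    // n x nf zero-based level codes
  uvec q;       // levels per factor
  uvec off;     // offset of each factor's block in u
  int family;   // 0 binomial, 1 poisson, 2 gaussian
  double const_ll; // y-only constants so loglik matches glm()/lm()
  uword Q() const { return q.n_elem ? off(q.n_elem - 1) + q(q.n_elem - 1) : 0; }
};

// state shared between objective and gradient at a given psi
struct Eval {
  vec u;          // random-effect modes
  mat H;          // Z'WZ + D^-1 at the mode
  mat R;          // chol(H), upper
  vec eta, r, w, wp; // linear predictor, raw residual, weights, dW/deta
  vec sig2;       // per-factor variances (clamped scale)
  double sige2;   // gaussian residual variance
  double gobj;    // penalized objective at the mode
  double logdetH;
  double nll;     // negative Laplace log-likelihood
  bool ok;
};

inline double log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

void linpred(const Problem& pb, const vec& beta, const vec& u, vec& eta) {
  eta = pb.X * beta;
  for (uword f = 0; f < pb.fidx.n_cols; ++f) {
    const uword o = pb.off(f);
    for (uword i = 0; i < eta.n_elem; ++i) eta(i) += u(o + pb.fidx(i, f));
  }
}

// loglik sum, residual y-mu, weight W, and dW/deta
double family_terms(const Problem& pb, const vec& eta, double sige2,
                    vec& r, vec& w, vec& wp) {
  const uword n = eta.n_elem;
  double ll = 0.0;
  r.set_size(n); w.set_size(n); wp.set_size(n);
  switch (pb.family) {
  case 0:
    for (uword i = 0; i < n; ++i) {
      const double e = eta(i);
      const double p = 1.0 / (1.0 + std::exp(-e));
      ll += pb.y(i) * e - pb.m(i) * log1pexp(e);
      r(i) = pb.y(i) - pb.m(i) * p;
      const double wi = pb.m(i) * p * (1.0 - p);
      w(i) = std::max(wi, 1e-12);
      wp(i) = wi * (1.0 - 2.0 * p);
    }
    break;
  case 1:
    for (uword i = 0; i < n; ++i) {
      const double mu = std::exp(std::min(eta(i), 30.0));
      ll += pb.y(i) * eta(i) - mu;
      r(i) = pb.y(i) - mu;
      w(i) = std::max(mu, 1e-12);
      wp(i) = mu;
    }
    break;
  default:
    {
      const double inv = 1.0 / sige2;
      for (uword i = 0; i < n; ++i) {
        const double d = pb.y(i) - eta(i);
        ll += -0.5 * d * d * inv - 0.5 * std::log(2.0 * M_PI * sige2);
        r(i) = d * inv;
        w(i) = inv;
        wp(i) = 0.0;
      }
    }
  }
  return ll;
}

double penalty(const Problem& pb, const vec& u, const vec& sig2) {
  double pen = 0.0;
  for (uword f = 0; f < pb.q.n_elem; ++f) {
    const uword o = pb.off(f);
    for (uword j = 0; j < pb.q(f); ++j) pen += u(o + j) * u(o + j) / sig2(f);
  }
  return 0.5 * pen;
}

void build_H(const Problem& pb, const vec& w, const vec& sig2, mat& H) {
  const uword Q = pb.Q();
  H.zeros(Q, Q);
  for (uword i = 0; i < w.n_elem; ++i) {
    for (uword f1 = 0; f1 < pb.fidx.n_cols; ++f1) {
      const uword j1 = pb.off(f1) + pb.fidx(i, f1);
      H(j1, j1) += w(i);
      for (uword f2 = f1 + 1; f2 < pb.fidx.n_cols; ++f2) {
        const uword j2 = pb.off(f2) + pb.fidx(i, f2);
        H(j1, j2) += w(i);
        H(j2, j1) += w(i);
      }
    }
  }
  for (uword f = 0; f < pb.q.n_elem; ++f) {
    const uword o = pb.off(f);
    for (uword j = 0; j < pb.q(f); ++j) H(o + j, o + j) += 1.0 / sig2(f);
  }
}

// evaluate negative Laplace loglik at psi, warm-starting u from ev.u
void evaluate(const Problem& pb, const vec& psi, Eval& ev) {
  const uword p = pb.X.n_cols, nf = pb.q.n_elem, Q = pb.Q();
  ev.ok = false;
  ev.nll = std::numeric_limits<double>::infinity();
  vec beta = psi.subvec(0, p - 1);
  ev.sig2.set_size(nf);
  double logdetD = 0.0;
  for (uword f = 0; f < nf; ++f) {
    const double ls = std::min(std::max(psi(p + f), LOGSIG_LO),
                               hi_logsig(pb.family));
    ev.sig2(f) = std::exp(2.0 * ls);
    logdetD += pb.q(f) * 2.0 * ls;
  }
  ev.sige2 = 1.0;
  if (pb.family == 2) {
    const double lse = std::min(std::max(psi(p + nf), LOGSIG_LO), 15.0);
    ev.sige2 = std::exp(2.0 * lse);
  }
  if (ev.u.n_elem != Q) ev.u = zeros<vec>(Q);
  double cur = family_terms(pb, (linpred(pb, beta, ev.u, ev.eta), ev.eta),
                            ev.sige2, ev.r, ev.w, ev.wp) -
               penalty(pb, ev.u, ev.sig2);
  if (!std::isfinite(cur)) {
    ev.u.zeros();
    linpred(pb, beta, ev.u, ev.eta);
    cur = family_terms(pb, ev.eta, ev.sige2, ev.r, ev.w, ev.wp) -
          penalty(pb, ev.u, ev.sig2);
    if (!std::isfinite(cur)) return;
  }
  vec g(Q), du, u_try, eta_t, r_t, w_t, wp_t;
  for (int it = 0; it < 100; ++it) {
    g.zeros();
    for (uword f = 0; f < pb.fidx.n_cols; ++f) {
      const uword o = pb.off(f);
      for (uword i = 0; i < ev.r.n_elem; ++i) g(o + pb.fidx(i, f)) += ev.r(i);
    }
    for (uword f = 0; f < nf; ++f) {
      const uword o = pb.off(f);
      for (uword j = 0; j < pb.q(f); ++j) g(o + j) -= ev.u(o + j) / ev.sig2(f);
    }
    build_H(pb, ev.w, ev.sig2, ev.H);
    const double gmax = Q ? norm(g, "inf") : 0.0;
    if (gmax < 1e-10 * std::max(1.0, std::abs(cur))) break;
    if (!chol(ev.R, ev.H)) return;
    du = solve(trimatu(ev.R), solve(trimatl(ev.R.t()), g));
    double step = 1.0;
    bool ok = false;
    for (int h = 0; h < 30; ++h) {
      u_try = ev.u + step * du;
      linpred(pb, beta, u_try, eta_t);
      const double f_try = family_terms(pb, eta_t, ev.sige2, r_t, w_t, wp_t) -
                           penalty(pb, u_try, ev.sig2);
      if (std::isfinite(f_try) && f_try >= cur - 1e-12) {
        cur = f_try;
        ev.u = u_try; ev.eta = eta_t; ev.r = r_t; ev.w = w_t; ev.wp = wp_t;
        ok = true;
        break;
      }
      step *= 0.5;
    }
    if (!ok) break;
  }
  build_H(pb, ev.w, ev.sig2, ev.H);
  if (!chol(ev.R, ev.H)) return;
  ev.logdetH = 2.0 * sum(log(ev.R.diag()));
  ev.gobj = cur;
  const double ll = cur - 0.5 * logdetD - 0.5 * ev.logdetH + pb.const_ll;
  if (!std::isfinite(ll)) return;
  ev.nll = -ll;
  ev.ok = true;
}

// analytic gradient of the negative Laplace loglik at a converged Eval
void gradient(const Problem& pb, const vec& psi, const Eval& ev, vec& grad) {
  const uword p = pb.X.n_cols, nf = pb.q.n_elem, Q = pb.Q(),
              n = pb.y.n_elem;
  const uword d = psi.n_elem;
  grad.zeros(d);
  mat S;
  if (Q) {
    mat Rinv = inv(trimatu(ev.R));
    S = Rinv * Rinv.t();       // H^{-1}
  }
  // h_i = z_i' S z_i
  vec h(n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double acc = 0.0;
    for (uword f1 = 0; f1 < nf; ++f1) {
      const uword j1 = pb.off(f1) + pb.fidx(i, f1);
      acc += S(j1, j1);
      for (uword f2 = f1 + 1; f2 < nf; ++f2)
        acc += 2.0 * S(j1, pb.off(f2) + pb.fidx(i, f2));
    }
    h(i) = acc;
  }
  // beta block
  if (pb.family == 2) {
    for (uword j = 0; j < p; ++j) grad(j) = -dot(ev.r, pb.X.col(j));
  } else {
    // M = Z'W X;  V = -S M gives du*/dbeta
    mat M(Q, p, fill::zeros);
    for (uword i = 0; i < n; ++i)
      for (uword f = 0; f < nf; ++f)
        M.row(pb.off(f) + pb.fidx(i, f)) += ev.w(i) * pb.X.row(i);
    mat V = -(S * M);
    for (uword j = 0; j < p; ++j) {
      double g1 = dot(ev.r, pb.X.col(j));
      double g2 = 0.0; // -0.5 sum_i W'_i * (deta_i/dbeta_j) * h_i
      for (uword i = 0; i < n; ++i) {
        double zv = 0.0;
        for (uword f = 0; f < nf; ++f) zv += V(pb.off(f) + pb.fidx(i, f), j);
        g2 += ev.wp(i) * (pb.X(i, j) + zv) * h(i);
      }
      grad(j) = -(g1 - 0.5 * g2);
    }
  }
  // log sigma blocks
  for (uword f = 0; f < nf; ++f) {
    const uword o = pb.off(f);
    double uu = 0.0, trS = 0.0;
    for (uword j = 0; j < pb.q(f); ++j) {
      uu += ev.u(o + j) * ev.u(o + j);
      trS += S(o + j, o + j);
    }
    double gl = uu / ev.sig2(f) - double(pb.q(f)) + trS / ev.sig2(f);
    if (pb.family != 2) {
      // du*/dlogsig_f = S * (2/sig2_f) u_f  (padded); correction term
      vec a = zeros<vec>(Q);
      for (uword j = 0; j < pb.q(f); ++j) a(o + j) = 2.0 * ev.u(o + j) / ev.sig2(f);
      vec da = S * a;
      double corr = 0.0;
      for (uword i = 0; i < n; ++i) {
        double zv = 0.0;
        for (uword ff = 0; ff < nf; ++ff) zv += da(pb.off(ff) + pb.fidx(i, ff));
        corr += ev.wp(i) * zv * h(i);
      }
      gl -= 0.5 * corr;
    }
    grad(p + f) = -gl;
  }
  // gaussian residual log sigma
  if (pb.family == 2) {
    double gl = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double dres = pb.y(i) - ev.eta(i);
      gl += dres * dres / ev.sige2 - 1.0;
    }
    // d(-0.5 logdetH)/dlogsige = Q - tr(S D^{-1})
    double trSD = 0.0;
    for (uword f = 0; f < nf; ++f) {
      const uword o = pb.off(f);
      for (uword j = 0; j < pb.q(f); ++j) trSD += S(o + j, o + j) / ev.sig2(f);
    }
    gl += double(Q) - trSD;
    grad(p + nf) = -gl;
  }
}

// project psi's variance coordinates into the box
void project(const Problem& pb, vec& psi) {
  const uword p = pb.X.n_cols, nf = pb.q.n_elem;
  for (uword f = 0; f < nf; ++f)
    psi(p + f) = std::min(std::max(psi(p + f), LOGSIG_LO),
                          hi_logsig(pb.family));
  if (pb.family == 2)
    psi(p + nf) = std::min(std::max(psi(p + nf), LOGSIG_LO), 15.0);
}

// zero gradient components that point out of the box or are user-fixed
void mask_gradient(const Problem& pb, const vec& psi, const uvec& fixed,
                   vec& g) {
  const uword p = pb.X.n_cols, nf = pb.q.n_elem;
  for (uword j = 0; j < g.n_elem; ++j)
    if (j < fixed.n_elem && fixed(j)) g(j) = 0.0;
  for (uword f = 0; f < nf; ++f) {
    const uword j = p + f;
    if (psi(j) <= LOGSIG_LO + 1e-12 && g(j) > 0) g(j) = 0.0; // descent wants smaller
    if (psi(j) >= hi_logsig(pb.family) - 1e-12 && g(j) < 0) g(j) = 0.0;
  }
  if (pb.family == 2) {
    const uword j = p + nf;
    if (psi(j) <= LOGSIG_LO + 1e-12 && g(j) > 0) g(j) = 0.0;
    if (psi(j) >= 15.0 - 1e-12 && g(j) < 0) g(j) = 0.0;
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List glmm_laplace_cpp(const arma::mat& X, const arma::vec& y,
                            const arma::vec& m, const arma::umat& fidx,
                            const arma::uvec& q, int family,
                            const arma::vec& psi0, const arma::vec& u0,
                            const arma::uvec& fixed,
                            const arma::mat& B0 = arma::mat(),
                            bool light = false,
                            int maxit = 500, double gtol = 1e-5,
                            double steptol = 1e-8) {
  Problem pb;
  pb.X = X; pb.y = y; pb.m = m; pb.fidx = fidx; pb.q = q; pb.family = family;
  pb.off.set_size(q.n_elem);
  uword acc = 0;
  for (uword f = 0; f < q.n_elem; ++f) { pb.off(f) = acc; acc += q(f); }
  pb.const_ll = 0.0;
  if (family == 0)
    for (uword i = 0; i < y.n_elem; ++i)
      pb.const_ll += std::lgamma(m(i) + 1.0) - std::lgamma(y(i) + 1.0) -
                     std::lgamma(m(i) - y(i) + 1.0);
  else if (family == 1)
    for (uword i = 0; i < y.n_elem; ++i) pb.const_ll -= std::lgamma(y(i) + 1.0);

  const uword d = psi0.n_elem;
  vec psi = psi0;
  project(pb, psi);
  Eval ev;
  ev.u = u0.n_elem == pb.Q() ? u0 : zeros<vec>(pb.Q());
  evaluate(pb, psi, ev);
  if (!ev.ok) { ev.u.zeros(); evaluate(pb, psi, ev); }
  vec g(d, fill::zeros);
  if (ev.ok) gradient(pb, psi, ev, g);
  mask_gradient(pb, psi, fixed, g);
  mat B = (B0.n_rows == d && B0.n_cols == d) ? B0 : eye<mat>(d, d);
  double gnorm = norm(g, "inf");
  int it = 0;
  int resets = 0;
  // gradient tolerance relative to the objective's magnitude: an absolute
  // 1e-5 is meaningless for response-scale (e.g. gram) likelihoods
  auto gtol_eff = [&](double nll) {
    return std::max(gtol, 1e-7 * std::abs(nll));
  };
  bool converged = ev.ok && gnorm < gtol_eff(ev.nll);
  for (; it < maxit && !converged && ev.ok; ++it) {
    vec dir = -(B * g);
    if (dot(dir, g) > -1e-14) { B = eye<mat>(d, d); dir = -g; }
    for (uword j = 0; j < d; ++j)
      if (j < fixed.n_elem && fixed(j)) dir(j) = 0.0;
    const double slope = dot(g, dir);
    if (slope > -1e-16) break;
    double t = 1.0;
    Eval ev_new;
    vec psi_new;
    bool ok = false;
    for (int hh = 0; hh < 40; ++hh) {
      psi_new = psi + t * dir;
      project(pb, psi_new);
      ev_new = ev; // warm-start u
      evaluate(pb, psi_new, ev_new);
      if (ev_new.ok && ev_new.nll <= ev.nll + 1e-4 * t * slope) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) {
      // stalled line search: restart with a fresh curvature estimate
      if (resets < 3) { B = eye<mat>(d, d); ++resets; continue; }
      converged = gnorm < 10 * gtol_eff(ev.nll);
      break;
    }
    vec g_new;
    gradient(pb, psi_new, ev_new, g_new);
    mask_gradient(pb, psi_new, fixed, g_new);
    const vec s = psi_new - psi;
    const vec yv = g_new - g;
    const double sy = dot(s, yv);
    if (sy > 1e-12) {
      const vec By = B * yv;
      const double yBy = dot(yv, By);
      B += ((sy + yBy) / (sy * sy)) * (s * s.t()) -
           (By * s.t() + s * By.t()) / sy;
    }
    const double stepsize = norm(s, "inf");
    psi = psi_new; ev = ev_new; g = g_new;
    gnorm = norm(g, "inf");
    if (gnorm < gtol) { converged = true; break; }
    if (stepsize < steptol) {
      if (resets < 3) { B = eye<mat>(d, d); ++resets; continue; }
      converged = gnorm < 10 * gtol_eff(ev.nll);
      break;
    }
  }

  const uword p = X.n_cols, nf = q.n_elem, Q = pb.Q();
  vec beta = psi.subvec(0, p - 1);
  vec sig(nf);
  for (uword f = 0; f < nf; ++f)
    sig(f) = std::exp(std::min(std::max(psi(p + f), LOGSIG_LO),
                                 hi_logsig(family)));
  double sige = 1.0;
  if (family == 2)
    sige = std::exp(std::min(std::max(psi(p + nf), LOGSIG_LO), 15.0));

  // Wald covariance of beta: inv(X'WX - X'WZ H^{-1} Z'WX) at the mode
  mat V;
  vec se;
  if (light) {
    V = mat(0, 0);
    se = vec(p, fill::value(NA_REAL));
  } else {
    mat Xw = X.each_col() % ev.w;
    mat A = X.t() * Xw;
    mat Vinv = A;
    if (Q > 0 && ev.ok) {
      mat Bzx(Q, p, fill::zeros);
      for (uword i = 0; i < y.n_elem; ++i)
        for (uword f = 0; f < nf; ++f)
          Bzx.row(pb.off(f) + fidx(i, f)) += ev.w(i) * X.row(i);
      mat HiB = solve(trimatu(ev.R), solve(trimatl(ev.R.t()), Bzx));
      Vinv = A - Bzx.t() * HiB;
    }
    if (!inv_sympd(V, Vinv)) V = pinv(Vinv);
    se = sqrt(clamp(V.diag(), 0.0, datum::inf));
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("vcov") = V,
      Rcpp::Named("sigma") = sig,
      Rcpp::Named("sigma_resid") = sige,
      Rcpp::Named("loglik") = ev.ok ? -ev.nll : NA_REAL,
      Rcpp::Named("u") = ev.u,
      Rcpp::Named("psi") = psi,
      Rcpp::Named("grad_norm") = gnorm,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("B") = B);
}
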