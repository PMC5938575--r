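// Fast inner loop of the generalized-filtering birdsong agent.
//
// Mirrors the R reference implementation (prediction_errors(),
// laplace_free_energy()) exactly: same error blocks, same linearization
// convention (order 0 nonlinear, higher orders linearized at order 0), same
// diagonal precisions. Gradients of F in mu are assembled from a central
// finite-difference Jacobian of the errors (g = J' Pi eps); the
// local-linearization integrator uses the Gauss-Newton curvature J' Pi J.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct Pars {
  double sigma1, beta1, tau1, rho1_base;
  double sigma2, beta2, tau2, rho2;
  vec P;              // output map (3)
  double amp_a0, amp_a1, f_ref;
  double rho_mod_cap;   // rho1 = rho1_base + cap * tanh(v / cap)
  double max_step;      // trust-region cap per LL substep (L2 norm)
  double gz, gw, gv;  // log-precisions (gz = effective, attention-weighted)
  double gz_decay;    // sensory log-precision decrement per derivative order
  double rate1, rate2;  // temporal roughness rates (per-order precision decay)
  double theta_prior_mean, theta_prior_log_prec;
  double k_mu, dt;
  int n_hidden, n_cause, n_substeps;
};

Pars parse_pars(const Rcpp::List& pl) {
  Pars p;
  p.sigma1 = pl["sigma1"]; p.beta1 = pl["beta1"]; p.tau1 = pl["tau1"];
  p.rho1_base = pl["rho1_base"];
  p.sigma2 = pl["sigma2"]; p.beta2 = pl["beta2"]; p.tau2 = pl["tau2"];
  p.rho2 = pl.containsElementNamed("rho2") ? (double)pl["rho2"] : 28.0;
  p.P = Rcpp::as<vec>(pl["output_map"]);
  p.amp_a0 = pl["amp_a0"]; p.amp_a1 = pl["amp_a1"]; p.f_ref = pl["f_ref"];
  p.rho_mod_cap = pl.containsElementNamed("rho_mod_cap")
                      ? (double)pl["rho_mod_cap"] : 8.0;
  p.max_step = pl.containsElementNamed("max_step")
                   ? (double)pl["max_step"] : 10.0;
  p.gz = pl["gamma_z_eff"]; p.gw = pl["gamma_w"]; p.gv = pl["gamma_v"];
  p.gz_decay = pl.containsElementNamed("gamma_z_decay")
                   ? (double)pl["gamma_z_decay"] : 2.0;
  p.rate1 = pl["rate1"]; p.rate2 = pl["rate2"];
  p.theta_prior_mean = pl["theta_prior_mean"];
  p.theta_prior_log_prec = pl["theta_prior_log_precision"];
  p.k_mu = pl["k_mu"]; p.dt = pl["dt"];
  p.n_hidden = pl["n_hidden"]; p.n_cause = pl["n_cause"];
  p.n_substeps = pl.containsElementNamed("n_substeps")
                     ? (int)pl["n_substeps"] : 4;
  return p;
}

inline double softplus(double x) { return x > 30 ? x : std::log1p(std::exp(x)); }
inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

vec lorenz(const vec& x, double sigma, double rho, double beta, double tau) {
  vec f(3);
  f(0) = sigma * (x(1) - x(0));
  f(1) = x(0) * (rho - x(2)) - x(1);
  f(2) = x(0) * x(1) - beta * x(2);
  return f / tau;
}

mat lorenz_jac(const vec& x, double sigma, double rho, double beta, double tau) {
  mat J(3, 3);
  J(0, 0) = -sigma;      J(0, 1) = sigma; J(0, 2) = 0;
  J(1, 0) = rho - x(2);  J(1, 1) = -1;    J(1, 2) = -x(0);
  J(2, 0) = x(1);        J(2, 1) = x(0);  J(2, 2) = -beta;
  return J / tau;
}

// mu layout: [vec(x1: 3 x (nh+1)) | vec(v: 1 x (nc+1)) | vec(x2: 3 x (nh+1))]
// errors:    [vec(eps_z: 2 x (nh+1)) | vec(eps_w1: 3 x nh) | vec(eps_v) |
//             vec(eps_w2: 3 x nh)]
//
// Blocks are carried in scaled generalized coordinates: order k stores
// T^k d^k x/dt^k with T the level's characteristic time (T1 = tau1/sigma1
// for x1 and the sensory channels, T2 = tau2/sigma2 for x2 and v). All
// orders are then O(x), errors eta^(k) = T^k eps^(k) take uniform per-block
// precisions, and the shift operator becomes D/T per block.
//
// State errors run over orders 0..nh-1 only (eta_w^(k) ~ x^(k+1) - f^(k)):
// every flow-consistent trajectory is then an exact solution, so autonomous
// expectations follow the chaotic attractor instead of its fixed points.
struct Dims {
  int nh1, nc1, n_mu, n_eps;
  int o_x1, o_v, o_x2;          // offsets into mu
  int e_z, e_w1, e_v, e_w2;     // offsets into eps
};

Dims make_dims(const Pars& p) {
  Dims d;
  d.nh1 = p.n_hidden + 1; d.nc1 = p.n_cause + 1;
  d.o_x1 = 0; d.o_v = 3 * d.nh1; d.o_x2 = d.o_v + d.nc1;
  d.n_mu = d.o_x2 + 3 * d.nh1;
  d.e_z = 0; d.e_w1 = 2 * d.nh1; d.e_v = d.e_w1 + 3 * (d.nh1 - 1);
  d.e_w2 = d.e_v + d.nc1;
  d.n_eps = d.e_w2 + 3 * (d.nh1 - 1);
  return d;
}

// prediction errors at (mu, theta) given sensory y (2 x nh1, vectorised)
vec errors(const vec& mu, const vec& y, double theta,
           const Pars& p, const Dims& d) {
  const int nh1 = d.nh1, nc1 = d.nc1;
  mat X1(const_cast<double*>(mu.memptr()) + d.o_x1, 3, nh1, false, true);
  mat X2(const_cast<double*>(mu.memptr()) + d.o_x2, 3, nh1, false, true);
  vec V = mu.subvec(d.o_v, d.o_v + nc1 - 1);
  vec eps(d.n_eps);

  // sensory: linear observation channels (y, z - f_ref), all orders
  for (int k = 0; k < nh1; ++k) {
    eps(d.e_z + 2 * k)     = y(2 * k)     - X1(1, k);
    eps(d.e_z + 2 * k + 1) = y(2 * k + 1) -
                             (X1(2, k) - (k == 0 ? p.f_ref : 0.0));
  }

  // fast level: eta^(k) = x1^(k+1)/T1 - f1^(k). The learnable order
  // parameter theta is the fast level's base rho; the cause modulates it
  // within the bounded band rho = theta + cap * tanh(v / cap). The cause's
  // scaled orders convert by (T1/T2)^k where they enter.
  double T1 = 1.0 / p.rate1, T2 = 1.0 / p.rate2;
  double rconv = T1 / T2;
  double v0 = V(0);
  double th = std::tanh(v0 / p.rho_mod_cap);
  double rho_eff = theta + p.rho_mod_cap * th;
  double dsat = 1.0 - th * th;
  vec x10 = X1.col(0);
  vec f0 = lorenz(x10, p.sigma1, rho_eff, p.beta1, p.tau1);
  mat J1 = lorenz_jac(x10, p.sigma1, rho_eff, p.beta1, p.tau1);
  vec dfdv = {0, dsat * x10(0) / p.tau1, 0};
  double rk = 1.0;
  for (int k = 0; k < nh1 - 1; ++k) {
    vec fk = (k == 0) ? f0
                      : vec(J1 * X1.col(k) +
                            dfdv * (k < nc1 ? V(k) * rk : 0.0));
    for (int i = 0; i < 3; ++i)
      eps(d.e_w1 + 3 * k + i) = X1(i, k + 1) / T1 - fk(i);
    rk *= rconv;
  }

  // cause: v - P' x2 at each cause order (both T2-scaled)
  for (int k = 0; k < nc1; ++k)
    eps(d.e_v + k) = V(k) - dot(p.P, X2.col(k));

  // slow level: eta^(k) = x2^(k+1)/T2 - f2^(k), fixed rho2
  vec x20 = X2.col(0);
  vec f20 = lorenz(x20, p.sigma2, p.rho2, p.beta2, p.tau2);
  mat J2 = lorenz_jac(x20, p.sigma2, p.rho2, p.beta2, p.tau2);
  for (int k = 0; k < nh1 - 1; ++k) {
    vec fk = (k == 0) ? f20 : vec(J2 * X2.col(k));
    for (int i = 0; i < 3; ++i)
      eps(d.e_w2 + 3 * k + i) = X2(i, k + 1) / T2 - fk(i);
  }
  return eps;
}

// per-element log-precisions: uniform per block in the scaled-error
// parametrization (equivalent to precisions decaying with derivative order
// at the level's characteristic rate in natural units)
vec log_weights(const Pars& p, const Dims& d) {
  vec lw(d.n_eps);
  // hearing conveys the value and low derivatives reliably, not high ones:
  // sensory log-precision falls by gz_decay per derivative order
  for (int k = 0; k < d.nh1; ++k)
    for (int i = 0; i < 2; ++i)
      lw(d.e_z + 2 * k + i) = p.gz - k * p.gz_decay;
  lw.subvec(d.e_w1, d.e_v - 1).fill(p.gw);
  lw.subvec(d.e_v,  d.e_w2 - 1).fill(p.gv);
  lw.subvec(d.e_w2, d.n_eps - 1).fill(p.gw);
  return lw;
}

struct FE { double F, accuracy, complexity; };

FE free_energy(const vec& eps, const vec& w, const vec& lw, double theta,
               const Pars& p, const Dims& d) {
  const double l2p = std::log(2.0 * M_PI);
  vec q = w % square(eps);
  int nz = d.e_w1 - d.e_z;
  double q_z = accu(q.subvec(d.e_z, d.e_w1 - 1));
  double lw_z = accu(lw.subvec(d.e_z, d.e_w1 - 1));
  double q_rest = accu(q) - q_z;
  double lw_rest = accu(lw) - lw_z;
  double dev = theta - p.theta_prior_mean;
  double pt = std::exp(p.theta_prior_log_prec);
  double theta_term = 0.5 * (pt * dev * dev - p.theta_prior_log_prec + l2p);
  double acc = -0.5 * (q_z - lw_z + nz * l2p);
  double comp = 0.5 * (q_rest - lw_rest + (d.n_eps - nz) * l2p) + theta_term;
  FE fe;
  fe.accuracy = acc;
  fe.complexity = comp;
  fe.F = comp - acc;
  return fe;
}

// central FD Jacobian of the errors in mu
mat error_jacobian(const vec& mu, const vec& y, double theta,
                   const Pars& p, const Dims& d) {
  mat J(d.n_eps, d.n_mu);
  vec mup = mu, mum = mu;
  for (int i = 0; i < d.n_mu; ++i) {
    double h = 1e-6 * std::max(1.0, std::abs(mu(i)));
    mup(i) = mu(i) + h; mum(i) = mu(i) - h;
    J.col(i) = (errors(mup, y, theta, p, d) -
                errors(mum, y, theta, p, d)) / (2 * h);
    mup(i) = mu(i); mum(i) = mu(i);
  }
  return J;
}

// generalized shift operator on the mu layout; in scaled coordinates
// d/dt Z_k = Z_{k+1}/T for each block
mat shift_op(const Pars& p, const Dims& d) {
  mat D = zeros<mat>(d.n_mu, d.n_mu);
  for (int k = 0; k < d.nh1 - 1; ++k)
    for (int i = 0; i < 3; ++i) {
      D(d.o_x1 + 3 * k + i, d.o_x1 + 3 * (k + 1) + i) = p.rate1;
      D(d.o_x2 + 3 * k + i, d.o_x2 + 3 * (k + 1) + i) = p.rate2;
    }
  for (int k = 0; k < d.nc1 - 1; ++k)
    D(d.o_v + k, d.o_v + k + 1) = p.rate2;
  return D;
}

// voiced prediction: the linear observation channels (y, z - f_ref) of the
// fast block at every order, in the scaled convention
vec emission_from_mu(const vec& mu, const Pars& p, const Dims& d) {
  mat X1(const_cast<double*>(mu.memptr()) + d.o_x1, 3, d.nh1, false, true);
  vec e(2 * d.nh1);
  for (int k = 0; k < d.nh1; ++k) {
    e(2 * k) = X1(1, k);
    e(2 * k + 1) = X1(2, k) - (k == 0 ? p.f_ref : 0.0);
  }
  return e;
}

// rebuild the full scaled-coordinate mu flow-consistently from order-0
// states: Z_{k+1} = T * f^(k)(Z), so all state and cause errors vanish
vec consistent_mu(const vec& x1_0, const vec& x2_0, double theta,
                  const Pars& p, const Dims& d) {
  const int nh1 = d.nh1, nc1 = d.nc1;
  double T1 = 1.0 / p.rate1, T2 = 1.0 / p.rate2;
  double rconv = T1 / T2;
  mat X2(3, nh1);
  X2.col(0) = x2_0;
  mat J2 = lorenz_jac(x2_0, p.sigma2, p.rho2, p.beta2, p.tau2);
  X2.col(1) = T2 * lorenz(x2_0, p.sigma2, p.rho2, p.beta2, p.tau2);
  for (int k = 2; k < nh1; ++k) X2.col(k) = T2 * (J2 * X2.col(k - 1));
  vec V(nc1);
  for (int k = 0; k < nc1; ++k) V(k) = dot(p.P, X2.col(k));

  double th = std::tanh(V(0) / p.rho_mod_cap);
  double rho_eff = theta + p.rho_mod_cap * th;
  double dsat = 1.0 - th * th;
  mat X1(3, nh1);
  X1.col(0) = x1_0;
  mat J1 = lorenz_jac(x1_0, p.sigma1, rho_eff, p.beta1, p.tau1);
  vec dfdv = {0, dsat * x1_0(0) / p.tau1, 0};
  X1.col(1) = T1 * lorenz(x1_0, p.sigma1, rho_eff, p.beta1, p.tau1);
  double rk = rconv;
  for (int k = 2; k < nh1; ++k) {
    vec vterm = dfdv * ((k - 1) < nc1 ? V(k - 1) * rk : 0.0);
    X1.col(k) = T1 * (J1 * X1.col(k - 1) + vterm);
    rk *= rconv;
  }
  vec mu(d.n_mu);
  mu.subvec(d.o_x1, d.o_x1 + 3 * nh1 - 1) = vectorise(X1);
  mu.subvec(d.o_v, d.o_v + nc1 - 1) = V;
  mu.subvec(d.o_x2, d.o_x2 + 3 * nh1 - 1) = vectorise(X2);
  return mu;
}

// order-0 generative dynamics (6-dim): x1 under rho(v(x2)), x2 under theta
vec gen_flow6(const vec& s, double theta, const Pars& p) {
  vec x1 = s.subvec(0, 2), x2 = s.subvec(3, 5);
  double v = dot(p.P, x2);
  double rho_eff = theta + p.rho_mod_cap * std::tanh(v / p.rho_mod_cap);
  vec f(6);
  f.subvec(0, 2) = lorenz(x1, p.sigma1, rho_eff, p.beta1, p.tau1);
  f.subvec(3, 5) = lorenz(x2, p.sigma2, p.rho2, p.beta2, p.tau2);
  return f;
}

mat gen_jac6(const vec& s, double theta, const Pars& p) {
  vec x1 = s.subvec(0, 2), x2 = s.subvec(3, 5);
  double v = dot(p.P, x2);
  double th = std::tanh(v / p.rho_mod_cap);
  double rho_eff = theta + p.rho_mod_cap * th;
  mat J = zeros<mat>(6, 6);
  J.submat(0, 0, 2, 2) = lorenz_jac(x1, p.sigma1, rho_eff, p.beta1, p.tau1);
  J.submat(3, 3, 5, 5) = lorenz_jac(x2, p.sigma2, p.rho2, p.beta2, p.tau2);
  vec dfdv = {0, (1.0 - th * th) * x1(0) / p.tau1, 0};
  J.submat(0, 3, 2, 5) = dfdv * p.P.t();
  return J;
}

struct TickOut {
  vec mu;
  FE fe;
  double gtheta, htheta;  // data-part gradient and curvature of F in theta
};

TickOut tick(const vec& mu0, const vec& y, double theta,
             const Pars& p, const Dims& d, const mat& D) {
  vec lw = log_weights(p, d);
  vec w = exp(lw);
  TickOut out;
  vec mu = mu0;
  double sub_dt = p.dt / p.n_substeps;
  vec eps;
  for (int s = 0; s < p.n_substeps; ++s) {
    eps = errors(mu, y, theta, p, d);
    if (!eps.is_finite()) Rcpp::stop("non-finite prediction errors");
    if (s == 0) out.fe = free_energy(eps, w, lw, theta, p, d);

    mat J = error_jacobian(mu, y, theta, p, d);
    // the cause-prior link is top-down only at the fast timescale: the
    // slow states are a contextual prior for the cause and are not revised
    // through it tick by tick (their own flow governs them), so the cause's
    // persistent displacement retains the order-parameter evidence
    J.submat(d.e_v, d.o_x2, d.e_w2 - 1, d.n_mu - 1).zeros();
    vec g = J.t() * (w % eps);
    mat H = J.t() * (J.each_col() % w);

    vec flow = D * mu - p.k_mu * g;
    mat JF = D - p.k_mu * H;

    // local linearization: dmu = (expm(JF dt) - I) JF^{-1} flow
    vec dmu;
    vec sol;
    bool ok = solve(sol, JF, flow, solve_opts::no_approx);
    if (ok) {
      mat E = expmat(JF * sub_dt);
      E.diag() -= 1.0;
      dmu = E * sol;
      ok = dmu.is_finite();
    }
    if (!ok) dmu = sub_dt * flow;  // Euler fallback
    double nrm = norm(dmu);
    if (nrm > p.max_step) dmu *= p.max_step / nrm;  // trust region
    mu += dmu;
    if (!mu.is_finite()) Rcpp::stop("non-finite expectations after step");
  }

  // theta gradient/curvature by central FD of the errors in theta
  double ht = 1e-5 * std::max(1.0, std::abs(theta));
  vec ep = errors(mu, y, theta + ht, p, d);
  vec em = errors(mu, y, theta - ht, p, d);
  vec de = (ep - em) / (2 * ht);
  eps = errors(mu, y, theta, p, d);
  out.gtheta = dot(de, w % eps);
  out.htheta = dot(de, w % de);
  out.mu = mu;
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".tick_core")]]
Rcpp::List tick_core(const arma::vec& mu, const arma::vec& y, double theta,
                     const Rcpp::List& pars) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  if ((int)mu.n_elem != d.n_mu) Rcpp::stop("mu has wrong length");
  if ((int)y.n_elem != 2 * d.nh1) Rcpp::stop("sensory vector has wrong length");
  mat D = shift_op(p, d);
  TickOut t = tick(mu, y, theta, p, d, D);
  return Rcpp::List::create(
      Rcpp::Named("mu") = t.mu,
      Rcpp::Named("F") = t.fe.F,
      Rcpp::Named("accuracy") = t.fe.accuracy,
      Rcpp::Named("complexity") = t.fe.complexity,
      Rcpp::Named("gtheta") = t.gtheta,
      Rcpp::Named("htheta") = t.htheta);
}

// evaluate F (and the theta trace) along a stored expectation trajectory
// against given sensory columns, without updating anything
//' @noRd
// [[Rcpp::export(name = ".fe_trace_core")]]
Rcpp::List fe_trace_core(const arma::mat& MU, const arma::mat& Y,
                         double theta, const Rcpp::List& pars) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  int T = MU.n_cols;
  vec lw = log_weights(p, d);
  vec w = exp(lw);
  vec F(T), ACC(T), COMP(T), GT(T), HT(T);
  for (int t = 0; t < T; ++t) {
    vec mu = MU.col(t);
    vec y = Y.col(t);
    vec eps = errors(mu, y, theta, p, d);
    FE fe = free_energy(eps, w, lw, theta, p, d);
    F(t) = fe.F; ACC(t) = fe.accuracy; COMP(t) = fe.complexity;
    double ht = 1e-5 * std::max(1.0, std::abs(theta));
    vec de = (errors(mu, y, theta + ht, p, d) -
              errors(mu, y, theta - ht, p, d)) / (2 * ht);
    GT(t) = dot(de, w % eps);
    HT(t) = dot(de, w % de);
  }
  return Rcpp::List::create(
      Rcpp::Named("F") = F, Rcpp::Named("accuracy") = ACC,
      Rcpp::Named("complexity") = COMP,
      Rcpp::Named("gtheta") = GT, Rcpp::Named("htheta") = HT);
}

//' @noRd
// [[Rcpp::export(name = ".errors_core")]]
arma::vec errors_core(const arma::vec& mu, const arma::vec& y, double theta,
                      const Rcpp::List& pars) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  return errors(mu, y, theta, p, d);
}

//' @noRd
// [[Rcpp::export(name = ".emission_core")]]
arma::vec emission_core(const arma::vec& mu, const Rcpp::List& pars) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  return emission_from_mu(mu, p, d);
}

// Run one singing epoch: the agent's expectations evolve by integrating its
// own generative model (order-0 states by local linearization, derivative
// orders rebuilt flow-consistently each tick) and the song is the voiced
// prediction. F and the theta trace are evaluated at the self-consistent
// state (eps = 0 by construction, so gtheta = 0 and htheta > 0).
//' @noRd
// [[Rcpp::export(name = ".sing_epoch_core")]]
Rcpp::List sing_epoch_core(const arma::vec& mu0, double theta,
                           const Rcpp::List& pars, int T) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  if ((int)mu0.n_elem != d.n_mu) Rcpp::stop("mu0 has wrong length");
  vec lw = log_weights(p, d);
  vec w = exp(lw);
  mat MU(d.n_mu, T);
  mat EMIT(2 * d.nh1, T);
  vec F(T), ACC(T), COMP(T), GT(T), HT(T);
  vec s(6);
  s.subvec(0, 2) = mu0.subvec(d.o_x1, d.o_x1 + 2);
  s.subvec(3, 5) = mu0.subvec(d.o_x2, d.o_x2 + 2);
  double sub_dt = p.dt / p.n_substeps;
  for (int t = 0; t < T; ++t) {
    for (int ss = 0; ss < p.n_substeps; ++ss) {
      vec f = gen_flow6(s, theta, p);
      mat J = gen_jac6(s, theta, p);
      vec ds;
      vec sol;
      bool ok = solve(sol, J, f, solve_opts::no_approx);
      if (ok) {
        mat E = expmat(J * sub_dt);
        E.diag() -= 1.0;
        ds = E * sol;
        ok = ds.is_finite();
      }
      if (!ok) ds = sub_dt * f;
      s += ds;
    }
    if (!s.is_finite())
      Rcpp::stop("non-finite generative state at epoch tick " +
                 std::to_string(t + 1));
    vec mu = consistent_mu(s.subvec(0, 2), s.subvec(3, 5), theta, p, d);
    MU.col(t) = mu;
    vec e = emission_from_mu(mu, p, d);
    EMIT.col(t) = e;
    vec eps = errors(mu, e, theta, p, d);
    FE fe = free_energy(eps, w, lw, theta, p, d);
    F(t) = fe.F; ACC(t) = fe.accuracy; COMP(t) = fe.complexity;
    double ht = 1e-5 * std::max(1.0, std::abs(theta));
    vec de = (errors(mu, e, theta + ht, p, d) -
              errors(mu, e, theta - ht, p, d)) / (2 * ht);
    GT(t) = dot(de, w % eps);
    HT(t) = dot(de, w % de);
  }
  return Rcpp::List::create(
      Rcpp::Named("mu") = MU, Rcpp::Named("emission") = EMIT,
      Rcpp::Named("F") = F, Rcpp::Named("accuracy") = ACC,
      Rcpp::Named("complexity") = COMP,
      Rcpp::Named("gtheta") = GT, Rcpp::Named("htheta") = HT,
      Rcpp::Named("mu_final") = MU.col(T - 1));
}

// Run one agent for an epoch. If self_audition, the sensory input at each
// tick is the agent's own emission (so eps_z = 0 exactly) and Y is ignored;
// otherwise column t of Y (2*(nh+1) x T) is the heard, already-noised input.
//' @noRd
// [[Rcpp::export(name = ".epoch_core")]]
Rcpp::List epoch_core(const arma::vec& mu0, const arma::mat& Y, double theta,
                      const Rcpp::List& pars, bool self_audition) {
  Pars p = parse_pars(pars);
  Dims d = make_dims(p);
  if ((int)mu0.n_elem != d.n_mu) Rcpp::stop("mu0 has wrong length");
  int T = Y.n_cols;
  mat D = shift_op(p, d);
  mat MU(d.n_mu, T);
  mat EMIT(2 * d.nh1, T);
  vec F(T), ACC(T), COMP(T), GT(T), HT(T);
  vec mu = mu0;
  for (int t = 0; t < T; ++t) {
    vec e = emission_from_mu(mu, p, d);
    EMIT.col(t) = e;
    vec y = self_audition ? e : vec(Y.col(t));
    TickOut o;
    try {
      o = tick(mu, y, theta, p, d, D);
    } catch (std::exception& ex) {
      Rcpp::stop(std::string(ex.what()) + " at epoch tick " +
                 std::to_string(t + 1));
    }
    mu = o.mu;
    MU.col(t) = mu;
    F(t) = o.fe.F; ACC(t) = o.fe.accuracy; COMP(t) = o.fe.complexity;
    GT(t) = o.gtheta; HT(t) = o.htheta;
  }
  return Rcpp::List::create(
      Rcpp::Named("mu") = MU, Rcpp::Named("emission") = EMIT,
      Rcpp::Named("F") = F, Rcpp::Named("accuracy") = ACC,
      Rcpp::Named("complexity") = COMP,
      Rcpp::Named("gtheta") = GT, Rcpp::Named("htheta") = HT,
      Rcpp::Named("mu_final") = mu);
}
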