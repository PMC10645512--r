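// Steady-state search for shifted-Hill ODE models of small gene circuits.
//
// Per random kinetic model: Euler integration from many initial conditions,
// with periodic Newton polishing of near-converged points and a Jacobian
// eigenvalue test so that only linearly stable fixed points are kept.
// Distinct states are merged with an inf-norm tolerance on log2 values.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double ipow(double b, int e) {
  double r = 1.0;
  while (e) { if (e & 1) r *= b; b *= b; e >>= 1; }
  return r;
}

// shifted Hill factor: lam + (1 - lam) / (1 + (x/x0)^n)
static inline double hshift(double x, double x0, int n, double lam) {
  return lam + (1.0 - lam) / (1.0 + ipow(x / x0, n));
}

struct Circuit {
  int ng;
  const double *g, *k;
  const int *eoff;   // ng+1 offsets; edges grouped by target gene
  const int *esrc;   // 0-based regulator index per edge
  const int *en;
  const double *ex0, *elam;
};

static void rhs(const Circuit& c, const double* x, double* f) {
  for (int i = 0; i < c.ng; ++i) {
    double prod = c.g[i];
    for (int e = c.eoff[i]; e < c.eoff[i + 1]; ++e)
      prod *= hshift(x[c.esrc[e]], c.ex0[e], c.en[e], c.elam[e]);
    f[i] = prod - c.k[i] * x[i];
  }
}

static void jacobian(const Circuit& c, const double* x, mat& J) {
  J.zeros();
  for (int i = 0; i < c.ng; ++i) {
    double P = c.g[i];
    for (int e = c.eoff[i]; e < c.eoff[i + 1]; ++e)
      P *= hshift(x[c.esrc[e]], c.ex0[e], c.en[e], c.elam[e]);
    for (int e = c.eoff[i]; e < c.eoff[i + 1]; ++e) {
      int j = c.esrc[e];
      double xj = x[j], x0 = c.ex0[e], lam = c.elam[e];
      int n = c.en[e];
      double h = hshift(xj, x0, n, lam);
      double dh;
      if (xj <= 0.0) {
        dh = (n == 1) ? -(1.0 - lam) / x0 : 0.0;
      } else {
        double u = ipow(xj / x0, n);
        dh = -(1.0 - lam) * n * u / (xj * (1.0 + u) * (1.0 + u));
      }
      J(i, j) += P / h * dh;
    }
    J(i, i) -= c.k[i];
  }
}

static double max_abs(const double* v, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) { double a = std::fabs(v[i]); if (a > m) m = a; }
  return m;
}

// Newton iteration from x; returns true if a fixed point with relative
// residual below newton_tol was reached. On success x holds the root.
static bool newton_polish(const Circuit& c, vec& x, double newton_tol) {
  int ng = c.ng;
  vec f(ng);
  mat J(ng, ng);
  vec y = x;
  for (int it = 0; it < 30; ++it) {
    rhs(c, y.memptr(), f.memptr());
    double scale = std::max(1.0, max_abs(y.memptr(), ng));
    if (max_abs(f.memptr(), ng) <= newton_tol * scale) { x = y; return true; }
    jacobian(c, y.memptr(), J);
    vec dy;
    bool ok = solve(dy, J, -f, solve_opts::no_approx);
    if (!ok || !dy.is_finite()) return false;
    y += dy;
    for (int i = 0; i < ng; ++i) if (y[i] < 1e-12) y[i] = 1e-12;
    if (!y.is_finite()) return false;
  }
  return false;
}

static bool is_stable(const Circuit& c, const vec& x) {
  mat J(c.ng, c.ng);
  jacobian(c, x.memptr(), J);
  cx_vec ev;
  if (!eig_gen(ev, J)) return false;
  return ev.is_finite() && real(ev).max() < 1e-8;
}

// [[Rcpp::export(name = ".steady_states_cpp")]]
Rcpp::List steady_states_cpp(Rcpp::NumericVector g, Rcpp::NumericVector k,
                             Rcpp::IntegerVector eoff, Rcpp::IntegerVector esrc,
                             Rcpp::IntegerVector en, Rcpp::NumericVector ex0,
                             Rcpp::NumericVector elam, Rcpp::NumericMatrix inits,
                             double dt, double t_max, double conv_tol,
                             double merge_tol) {
  const int ng = g.size();
  const int n_inits = inits.ncol();
  Circuit c{ng, g.begin(), k.begin(), eoff.begin(), esrc.begin(),
            en.begin(), ex0.begin(), elam.begin()};

  const int steps_per_unit = std::max(1, (int)std::lround(1.0 / dt));
  const double newton_tol = 1e-12;
  std::vector<vec> reps;       // distinct stable states (raw concentrations)
  std::vector<int> hits;       // inits attracted to each
  int n_unconverged = 0;

  vec x(ng), f(ng);
  for (int tr = 0; tr < n_inits; ++tr) {
    for (int i = 0; i < ng; ++i) x[i] = inits(i, tr);
    double trigger = 1e-3;
    bool settled = false;
    double t = 0.0;
    int unit = 0;
    while (t < t_max && !settled) {
      for (int s = 0; s < steps_per_unit; ++s) {
        rhs(c, x.memptr(), f.memptr());
        for (int i = 0; i < ng; ++i) {
          x[i] += dt * f[i];
          if (x[i] < 0.0) x[i] = 0.0;
        }
      }
      t += 1.0;
      ++unit;
      rhs(c, x.memptr(), f.memptr());
      double relrate = max_abs(f.memptr(), ng) /
                       std::max(max_abs(x.memptr(), ng), 1e-12);
      if (relrate < trigger || unit % 25 == 0) {
        vec y = x;
        if (newton_polish(c, y, newton_tol) && is_stable(c, y)) {
          x = y;
          settled = true;
        } else {
          trigger *= 0.1;   // saddle or failed polish: keep integrating
        }
      }
    }
    if (!settled) {
      rhs(c, x.memptr(), f.memptr());
      double relrate = max_abs(f.memptr(), ng) /
                       std::max(max_abs(x.memptr(), ng), 1e-12);
      settled = relrate < conv_tol;
    }
    if (!settled) { ++n_unconverged; continue; }

    // merge into the set of distinct states (inf-norm on log2 scale)
    bool found = false;
    for (size_t r = 0; r < reps.size(); ++r) {
      double d = 0.0;
      for (int i = 0; i < ng; ++i) {
        double a = std::log2(std::max(x[i], 1e-12)) -
                   std::log2(std::max(reps[r][i], 1e-12));
        a = std::fabs(a);
        if (a > d) d = a;
      }
      if (d < merge_tol) { ++hits[r]; found = true; break; }
    }
    if (!found) { reps.push_back(x); hits.push_back(1); }
  }

  mat states(reps.size(), ng);
  for (size_t r = 0; r < reps.size(); ++r)
    for (int i = 0; i < ng; ++i) states(r, i) = reps[r][i];
  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("basin_counts") = hits,
                            Rcpp::Named("n_unconverged") = n_unconverged);
}

// [[Rcpp::export(name = ".ode_rhs_cpp")]]
Rcpp::NumericVector ode_rhs_cpp(Rcpp::NumericVector state,
                                Rcpp::NumericVector g, Rcpp::NumericVector k,
                                Rcpp::IntegerVector eoff, Rcpp::IntegerVector esrc,
                                Rcpp::IntegerVector en, Rcpp::NumericVector ex0,
                                Rcpp::NumericVector elam) {
  Circuit c{(int)g.size(), g.begin(), k.begin(), eoff.begin(), esrc.begin(),
            en.begin(), ex0.begin(), elam.begin()};
  Rcpp::NumericVector f(g.size());
  rhs(c, state.begin(), f.begin());
  return f;
}
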