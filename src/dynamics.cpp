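#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous threshold dynamics. A neuron e is set to 1 iff its
// feedforward input I_e = <W_e, x> strictly exceeds theta_e (ties -> 0).
// Each update sees the effect of earlier updates within the same sweep.

static inline double dense_input(const NumericMatrix& W, const IntegerVector& x,
                                 int e, int n) {
  double I = 0.0;
  for (int f = 0; f < n; ++f)
    if (x[f]) I += W(e, f);
  return I;
}

static double dense_energy(const NumericMatrix& W, const NumericVector& theta,
                           const IntegerVector& x, int n) {
  double E = 0.0;
  for (int e = 0; e < n; ++e) {
    if (!x[e]) continue;
    E += theta[e];
    double s = 0.0;
    for (int f = 0; f < n; ++f)
      if (x[f]) s += W(e, f);
    E -= 0.5 * s;
  }
  return E;
}

// [[Rcpp::export]]
IntegerVector cpp_sweep_dense(NumericMatrix W, NumericVector theta,
                              IntegerVector state, IntegerVector order) {
  const int n = theta.size();
  IntegerVector x = clone(state);
  for (int idx = 0; idx < n; ++idx) {
    const int e = order[idx];
    x[e] = (dense_input(W, x, e, n) > theta[e]) ? 1 : 0;
  }
  return x;
}

// Repeated sweeps until one full pass changes no bit. Sweep count includes
// the final idle (confirming) pass. random_order draws a fresh permutation
// per sweep from R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_converge_dense(NumericMatrix W, NumericVector theta,
                        IntegerVector state, bool random_order,
                        int max_sweeps, bool trace_energy) {
  const int n = theta.size();
  IntegerVector x = clone(state);
  IntegerVector ord0(n);
  for (int i = 0; i < n; ++i) ord0[i] = i;
  std::vector<double> trace;
  int sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    IntegerVector ord = random_order ? Rcpp::sample(ord0, n, false) : ord0;
    bool changed = false;
    for (int idx = 0; idx < n; ++idx) {
      const int e = ord[idx];
      const int nb = (dense_input(W, x, e, n) > theta[e]) ? 1 : 0;
      if (nb != x[e]) { x[e] = nb; changed = true; }
    }
    ++sweeps;
    if (trace_energy) trace.push_back(dense_energy(W, theta, x, n));
    if (!changed) { converged = true; break; }
  }
  return List::create(_["state"] = x, _["sweeps"] = sweeps,
                      _["energy_trace"] = wrap(trace),
                      _["converged"] = converged);
}

// Single-sweep fixed-point test for a batch of states (columns).
// [[Rcpp::export]]
LogicalVector cpp_fixed_point_dense(NumericMatrix W, NumericVector theta,
                                    IntegerMatrix states) {
  const int n = theta.size();
  const int m = states.ncol();
  LogicalVector out(m);
  for (int c = 0; c < m; ++c) {
    IntegerVector x(n);
    for (int e = 0; e < n; ++e) x[e] = states(e, c);
    bool fixed = true;
    for (int e = 0; e < n && fixed; ++e) {
      const int nb = (dense_input(W, x, e, n) > theta[e]) ? 1 : 0;
      if (nb != x[e]) fixed = false;
    }
    out[c] = fixed;
  }
  return out;
}

// Batch convergence against per-column target states; reports exact
// recovery and per-column bit accuracy.
// [[Rcpp::export]]
List cpp_converge_dense_batch(NumericMatrix W, NumericVector theta,
                              IntegerMatrix states, IntegerMatrix targets,
                              bool random_order, int max_sweeps) {
  const int n = theta.size();
  const int m = states.ncol();
  LogicalVector recovered(m);
  NumericVector bit_acc(m);
  IntegerVector sweeps(m);
  IntegerVector ord0(n);
  for (int i = 0; i < n; ++i) ord0[i] = i;
  for (int c = 0; c < m; ++c) {
    IntegerVector x(n);
    for (int e = 0; e < n; ++e) x[e] = states(e, c);
    int sw = 0;
    while (sw < max_sweeps) {
      IntegerVector ord = random_order ? Rcpp::sample(ord0, n, false) : ord0;
      bool changed = false;
      for (int idx = 0; idx < n; ++idx) {
        const int e = ord[idx];
        const int nb = (dense_input(W, x, e, n) > theta[e]) ? 1 : 0;
        if (nb != x[e]) { x[e] = nb; changed = true; }
      }
      ++sw;
      if (!changed) break;
    }
    int agree = 0;
    for (int e = 0; e < n; ++e)
      if (x[e] == targets(e, c)) ++agree;
    recovered[c] = (agree == n);
    bit_acc[c] = (double)agree / n;
    sweeps[c] = sw;
  }
  return List::create(_["recovered"] = recovered, _["bit_acc"] = bit_acc,
                      _["sweeps"] = sweeps);
}

// ---- Sparse path for the permutation-symmetric (x, y, z) family ----
//
// Neurons are the n = v(v-1)/2 edges of the complete graph on v vertices;
// edge e = (i, j) with i < j. With weight x between edges sharing one
// vertex and y between disjoint edges, the feedforward input of e in a
// graph with degree sequence deg and ecount active edges is
//   I_e = x * (deg_i + deg_j - 2 x_e) + y * (ecount - deg_i - deg_j + x_e),
// so a sweep is O(n) with degree bookkeeping instead of O(n^2).

struct SymState {
  std::vector<int> deg;
  int ecount;
};

static void sym_init(const IntegerVector& ei, const IntegerVector& ej,
                     const IntegerVector& x, int v, SymState& s) {
  s.deg.assign(v, 0);
  s.ecount = 0;
  const int n = x.size();
  for (int e = 0; e < n; ++e) {
    if (x[e]) {
      ++s.deg[ei[e]];
      ++s.deg[ej[e]];
      ++s.ecount;
    }
  }
}

static double sym_energy(double px, double py, double pz, const SymState& s) {
  double s1 = 0.0;
  for (size_t i = 0; i < s.deg.size(); ++i) {
    const double d = s.deg[i];
    s1 += d * (d - 1.0) / 2.0;
  }
  const double ec = s.ecount;
  const double s0 = ec * (ec - 1.0) / 2.0 - s1;
  return -px * s1 - py * s0 + pz * ec;
}

static bool sym_sweep(double px, double py, double pz,
                      const IntegerVector& ei, const IntegerVector& ej,
                      const IntegerVector& ord, IntegerVector& x, SymState& s) {
  bool changed = false;
  const int n = x.size();
  for (int idx = 0; idx < n; ++idx) {
    const int e = ord[idx];
    const int i = ei[e], j = ej[e];
    const double dd = s.deg[i] + s.deg[j];
    const double I = px * (dd - 2.0 * x[e]) + py * (s.ecount - dd + x[e]);
    const int nb = (I > pz) ? 1 : 0;
    if (nb != x[e]) {
      const int delta = nb - x[e];
      x[e] = nb;
      s.deg[i] += delta;
      s.deg[j] += delta;
      s.ecount += delta;
      changed = true;
    }
  }
  return changed;
}

// [[Rcpp::export]]
List cpp_converge_sym(int v, double px, double py, double pz,
                      IntegerVector ei, IntegerVector ej, IntegerVector state,
                      bool random_order, int max_sweeps, bool trace_energy) {
  const int n = state.size();
  IntegerVector x = clone(state);
  SymState s;
  sym_init(ei, ej, x, v, s);
  IntegerVector ord0(n);
  for (int i = 0; i < n; ++i) ord0[i] = i;
  std::vector<double> trace;
  int sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    IntegerVector ord = random_order ? Rcpp::sample(ord0, n, false) : ord0;
    const bool changed = sym_sweep(px, py, pz, ei, ej, ord, x, s);
    ++sweeps;
    if (trace_energy) trace.push_back(sym_energy(px, py, pz, s));
    if (!changed) { converged = true; break; }
  }
  return List::create(_["state"] = x, _["sweeps"] = sweeps,
                      _["energy_trace"] = wrap(trace),
                      _["converged"] = converged);
}

// Batch recovery for the symmetric family: converge every column of
// `states` and compare with the matching column of `targets`.
// [[Rcpp::export]]
List cpp_recover_sym_batch(int v, double px, double py, double pz,
                           IntegerVector ei, IntegerVector ej,
                           IntegerMatrix states, IntegerMatrix targets,
                           bool random_order, int max_sweeps) {
  const int n = states.nrow();
  const int m = states.ncol();
  LogicalVector recovered(m);
  NumericVector bit_acc(m);
  IntegerVector sweeps(m);
  IntegerVector ord0(n);
  for (int i = 0; i < n; ++i) ord0[i] = i;
  for (int c = 0; c < m; ++c) {
    IntegerVector x(n);
    for (int e = 0; e < n; ++e) x[e] = states(e, c);
    SymState s;
    sym_init(ei, ej, x, v, s);
    int sw = 0;
    while (sw < max_sweeps) {
      IntegerVector ord = random_order ? Rcpp::sample(ord0, n, false) : ord0;
      const bool changed = sym_sweep(px, py, pz, ei, ej, ord, x, s);
      ++sw;
      if (!changed) break;
    }
    int agree = 0;
    for (int e = 0; e < n; ++e)
      if (x[e] == targets(e, c)) ++agree;
    recovered[c] = (agree == n);
    bit_acc[c] = (double)agree / n;
    sweeps[c] = sw;
  }
  return List::create(_["recovered"] = recovered, _["bit_acc"] = bit_acc,
                      _["sweeps"] = sweeps);
}
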