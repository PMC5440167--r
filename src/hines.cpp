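#include <Rcpp.h>
using namespace Rcpp;

// Implicit (backward Euler) integration of the passive cable equation on a
// tree, using Hines-ordered Gaussian elimination: compartments are numbered
// so that parent(i) < i, which makes the symmetric tree-structured system
// solvable in O(n) per step (one leaf-to-root elimination sweep, one
// root-to-leaf back-substitution).
//
// Units: mV, ms, nF, microsiemens (uS), nA.  nF*mV/ms = uS*mV = nA.
//
// parent:  0-based parent index per compartment, -1 for the root
// cap:     membrane capacitance per compartment (nF)
// g_leak:  leak conductance per compartment (uS)
// g_ax:    axial conductance linking compartment i to parent(i) (uS); the
//          root entry is ignored
// syn_comp/syn_onset: one entry per synaptic event (0-based compartment,
//          onset time in ms)
// wave:    synaptic conductance waveform (uS) sampled on the dt grid,
//          wave[0] = g at the onset instant
// i_inj:   constant injected current per compartment (nA)
// record:  0-based compartment indices to record
//
// Returns a (n_steps + 1) x length(record) matrix of voltages (mV),
// row k = time k*dt, starting from V = e_rest everywhere.
// [[Rcpp::export]]
NumericMatrix hines_simulate(IntegerVector parent,
                             NumericVector cap,
                             NumericVector g_leak,
                             NumericVector g_ax,
                             double e_rest,
                             double e_syn,
                             IntegerVector syn_comp,
                             NumericVector syn_onset,
                             NumericVector wave,
                             double dt,
                             int n_steps,
                             IntegerVector record,
                             NumericVector i_inj) {
  const int n = parent.size();
  const int n_ev = syn_comp.size();
  const int n_rec = record.size();
  const int n_wave = wave.size();

  for (int i = 1; i < n; ++i) {
    if (parent[i] < 0 || parent[i] >= i)
      stop("compartments must be ordered so that parent(i) < i");
  }

  std::vector<double> v(n, e_rest), d(n), rhs(n), gsyn(n, 0.0);
  std::vector<int> onset_step(n_ev);
  for (int e = 0; e < n_ev; ++e)
    onset_step[e] = (int)std::lround(syn_onset[e] / dt);

  // static part of the diagonal: C/dt + g_leak + axial terms
  std::vector<double> d0(n);
  for (int i = 0; i < n; ++i) d0[i] = cap[i] / dt + g_leak[i];
  for (int i = 1; i < n; ++i) {
    d0[i] += g_ax[i];
    d0[parent[i]] += g_ax[i];
  }

  NumericMatrix out(n_steps + 1, n_rec);
  for (int r = 0; r < n_rec; ++r) out(0, r) = v[record[r]];

  for (int s = 0; s < n_steps; ++s) {
    // synaptic conductance at the start of the step (treated implicitly
    // in the diagonal over [s, s+1])
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    for (int e = 0; e < n_ev; ++e) {
      int k = s - onset_step[e];
      if (k >= 0 && k < n_wave) gsyn[syn_comp[e]] += wave[k];
    }

    for (int i = 0; i < n; ++i) {
      d[i] = d0[i] + gsyn[i];
      rhs[i] = cap[i] / dt * v[i] + g_leak[i] * e_rest + gsyn[i] * e_syn +
               i_inj[i];
    }

    // eliminate children (leaf to root)
    for (int i = n - 1; i >= 1; --i) {
      double f = g_ax[i] / d[i];
      d[parent[i]] -= f * g_ax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    // back-substitute (root to leaf)
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / d[i];

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i]))
        stop("non-finite voltage at step %d, compartment %d", s + 1, i + 1);

    for (int r = 0; r < n_rec; ++r) out(s + 1, r) = v[record[r]];
  }
  return out;
}

// Steady-state voltage for constant injected currents: solves G V = I with
// the same tree elimination (no capacitance, no synapses).  Voltages are
// deviations scaled about e_rest.
// [[Rcpp::export]]
NumericVector hines_steady_state(IntegerVector parent,
                                 NumericVector g_leak,
                                 NumericVector g_ax,
                                 double e_rest,
                                 NumericVector i_inj) {
  const int n = parent.size();
  std::vector<double> d(n), rhs(n);
  for (int i = 0; i < n; ++i) {
    d[i] = g_leak[i];
    rhs[i] = g_leak[i] * e_rest + i_inj[i];
  }
  for (int i = 1; i < n; ++i) {
    d[i] += g_ax[i];
    d[parent[i]] += g_ax[i];
  }
  for (int i = n - 1; i >= 1; --i) {
    double f = g_ax[i] / d[i];
    d[parent[i]] -= f * g_ax[i];
    rhs[parent[i]] += f * rhs[i];
  }
  NumericVector v(n);
  v[0] = rhs[0] / d[0];
  for (int i = 1; i < n; ++i) v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / d[i];
  return v;
}
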