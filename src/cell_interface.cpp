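#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;

static const char* STATE_NAMES[19] = {
  "Vm", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
  "xr1", "xr2", "xs", "Rbar", "Cai", "CaSS", "CaSR", "Nai", "Ki"
};

static NumericVector pack_state(double V, const double* y) {
  NumericVector out(19);
  out[0] = V;
  for (int i = 0; i < tt06::N_STATE; ++i) out[i + 1] = y[i];
  out.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + 19);
  return out;
}

static void unpack_state(const NumericVector& s, double* V, double* y) {
  if (s.size() != 19) stop("state must have 19 entries (Vm + 18 model states)");
  *V = s[0];
  for (int i = 0; i < tt06::N_STATE; ++i) y[i] = s[i + 1];
}

// [[Rcpp::export]]
NumericVector tt06_initial_state_cpp() {
  double V, y[tt06::N_STATE];
  tt06::initial_state(y, &V);
  return pack_state(V, y);
}

// [[Rcpp::export]]
NumericVector tt06_currents_cpp(NumericVector state, int cell_type) {
  double V, y[tt06::N_STATE], I[12];
  unpack_state(state, &V, y);
  for (int i = 0; i < 19; ++i) {
    if (!R_finite(state[i])) stop("non-finite state");
  }
  tt06::currents(V, y, cell_type, I);
  NumericVector out(13);
  double tot = 0.0;
  for (int i = 0; i < 12; ++i) { out[i] = I[i]; tot += I[i]; }
  out[12] = tot;
  out.attr("names") = CharacterVector::create(
    "I_Na", "I_CaL", "I_to", "I_Kr", "I_Ks", "I_K1", "I_NaCa", "I_NaK",
    "I_pCa", "I_pK", "I_bCa", "I_bNa", "I_ion_total");
  return out;
}

// One forward-Euler (or exponential-gate) step of the state, holding or
// advancing V. Shared by the single-cell front-ends below.
static void cell_step(double* V, double* y, double dt_ms, int cell_type,
                      bool exp_gates, bool update_V, double stim_papF) {
  double I[12], inf[tt06::N_VGATE], tau[tt06::N_VGATE], dy[tt06::N_STATE];
  tt06::currents(*V, y, cell_type, I);
  tt06::gate_rates(*V, cell_type, inf, tau);
  tt06::conc_derivs(*V, y, I, update_V ? stim_papF : 0.0, dy);
  // gate g -> state index (fCass at state 6 is CaSS-gated, handled below)
  static const int GI[11] = {0, 1, 2, 3, 4, 5, 7, 8, 9, 10, 11};
  for (int g = 0; g < 11; ++g) {
    double* gv = &y[GI[g]];
    if (exp_gates) {
      *gv = inf[g] + (*gv - inf[g]) * std::exp(-dt_ms / tau[g]);
    } else {
      *gv += dt_ms * (inf[g] - *gv) / tau[g];
    }
  }
  y[6] += dt_ms * dy[6];
  for (int k = 12; k < tt06::N_STATE; ++k) y[k] += dt_ms * dy[k];
  if (update_V) {
    double tot = 0.0;
    for (int i = 0; i < 12; ++i) tot += I[i];
    *V += dt_ms * (-(tot) - stim_papF);
  }
}

// [[Rcpp::export]]
NumericVector tt06_advance_cpp(NumericVector state, double dt_ms, int n_steps,
                               int cell_type, bool exp_gates, bool update_V,
                               double stim_papF) {
  double V, y[tt06::N_STATE];
  unpack_state(state, &V, y);
  for (int s = 0; s < n_steps; ++s) {
    cell_step(&V, y, dt_ms, cell_type, exp_gates, update_V, stim_papF);
    if (!R_finite(V) || !R_finite(y[13])) {
      stop("integration diverged (non-finite state) at dt = %g ms, step %d",
           dt_ms, s + 1);
    }
  }
  return pack_state(V, y);
}

// [[Rcpp::export]]
List tt06_cell_trace_cpp(NumericVector state, double duration_ms, double dt_ms,
                         int record_every, int cell_type, bool exp_gates,
                         double stim_start_ms, double stim_dur_ms,
                         double stim_papF) {
  double V, y[tt06::N_STATE];
  unpack_state(state, &V, y);
  int n_steps = (int)std::lround(duration_ms / dt_ms);
  int n_rec = n_steps / record_every + 1;
  NumericVector times(n_rec), trace(n_rec);
  times[0] = 0.0; trace[0] = V;
  double max_dvdt = R_NegInf, t_max_dvdt = NA_REAL;
  int r = 1;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt_ms;
    double stim = (t >= stim_start_ms && t < stim_start_ms + stim_dur_ms)
                      ? stim_papF : 0.0;
    double Vprev = V;
    cell_step(&V, y, dt_ms, cell_type, exp_gates, true, stim);
    if (!R_finite(V)) stop("integration diverged at t = %g ms", t);
    double dvdt = (V - Vprev) / dt_ms;  // mV/ms == V/s
    if (dvdt > max_dvdt) { max_dvdt = dvdt; t_max_dvdt = t; }
    if ((s + 1) % record_every == 0 && r < n_rec) {
      times[r] = (s + 1) * dt_ms;
      trace[r] = V;
      ++r;
    }
  }
  return List::create(
    _["times_ms"] = times, _["Vm_mV"] = trace,
    _["max_upstroke_V_per_s"] = max_dvdt,
    _["t_max_upstroke_ms"] = t_max_dvdt,
    _["state"] = pack_state(V, y));
}
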