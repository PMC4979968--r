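#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Full thalamo-cortical network integration loop.
//
// All randomness (topology, cortical heterogeneity, Poisson drive) is drawn
// in R and passed in, so this routine is purely deterministic arithmetic.
//
// Populations: SP/NSP/TRN thalamic nuclei (IFB neurons, forward Euler, 1 ms)
// and CRX (Izhikevich cells, two 0.5 ms half-steps for v). Edge-list
// projections carry per-projection synaptic state: conductance-based
// (toward V_E / V_I) for thalamic targets, current-based decaying for
// cortical targets. Cortico-cortical all-to-all coupling is implicit:
// instantaneous pulses of +0.3 per excitatory and -1 per inhibitory spike,
// self-connections excluded, applied on the following 1 ms step.
//
// Spikes travel through per-projection ring buffers with integer-ms delays
// (minimum 1 step for network edges; the exogenous Poisson drive arrives in
// the same step it is drawn).

namespace {

struct ThalPars {
  double C, g_L, V_L, g_T, V_h, E_T, V_0, V_reset, V_E, V_I,
         tau_h_minus, tau_h_plus, k_E, k_I;
};

ThalPars read_thal(const List& p) {
  ThalPars t;
  t.C = p["C"]; t.g_L = p["g_L"]; t.V_L = p["V_L"]; t.g_T = p["g_T"];
  t.V_h = p["V_h"]; t.E_T = p["E_T"]; t.V_0 = p["V_0"];
  t.V_reset = p["V_reset"]; t.V_E = p["V_E"]; t.V_I = p["V_I"];
  t.tau_h_minus = p["tau_h_minus"]; t.tau_h_plus = p["tau_h_plus"];
  t.k_E = p["k_E"]; t.k_I = p["k_I"];
  return t;
}

struct Projection {
  int src_pop, tgt_pop;          // 0 SP, 1 NSP, 2 TRN, 3 CRX, 4 IN_SP, 5 IN_NSP
  bool exc;                      // polarity
  int delay;                     // effective buffer delay (steps)
  double tau;                    // synaptic decay (ms); > 0 always here
  std::vector<int> row_ptr;      // CSR over source index
  std::vector<int> col;          // target index (0-based, population-local)
  std::vector<double> w;         // |weight| (mS)
  std::vector<char> active;      // edge enabled flag (lesion support)
  int n_tgt;
  std::vector<double> g;         // synaptic state per target
  std::vector<double> buf;       // ring buffer (delay+1) x n_tgt arrivals
  int buf_len;
};

inline int pop_code(const std::string& s) {
  if (s == "SP") return 0;
  if (s == "NSP") return 1;
  if (s == "TRN") return 2;
  if (s == "CRX" || s == "E" || s == "I") return 3;
  if (s == "INPUT_SP") return 4;
  if (s == "INPUT_NSP") return 5;
  stop("unknown population: " + s);
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(int n_steps, double dt,
                     List sp_pars, List nsp_pars, List trn_pars,
                     List crx_pars,
                     List projections,
                     IntegerMatrix drive_sp, IntegerMatrix drive_nsp,
                     int lesion_step, LogicalVector lesion_mask,
                     NumericVector gaba,
                     NumericMatrix w_cc,
                     NumericVector v0_thal, NumericVector h0_thal,
                     NumericVector i_jitter_sd) {
  const int NT = 100;            // thalamic nucleus size
  ThalPars TP[3] = {read_thal(sp_pars), read_thal(nsp_pars),
                    read_thal(trn_pars)};

  NumericVector ca = crx_pars["a"], cb = crx_pars["b"], cc = crx_pars["c"],
                cd = crx_pars["d"], cI = crx_pars["I_intrinsic"];
  int n_exc = as<int>(crx_pars["n_exc"]);
  int n_crx = ca.size();
  double cutoff = as<double>(crx_pars["spike_cutoff"]);

  // thalamic state
  std::vector<double> V[3], h[3];
  for (int k = 0; k < 3; ++k) {
    V[k].assign(NT, v0_thal[k]);
    h[k].assign(NT, h0_thal[k]);
  }
  // cortical state
  std::vector<double> v(n_crx), u(n_crx), pulse(n_crx, 0.0);
  for (int i = 0; i < n_crx; ++i) { v[i] = -65.0; u[i] = cb[i] * v[i]; }

  // projections
  int n_proj = projections.size();
  std::vector<Projection> P(n_proj);
  std::vector<int> src_off(n_proj, 0), tgt_off(n_proj, 0);
  for (int q = 0; q < n_proj; ++q) {
    List pj = projections[q];
    Projection& pr = P[q];
    pr.src_pop = pop_code(as<std::string>(pj["source"]));
    pr.tgt_pop = pop_code(as<std::string>(pj["target"]));
    pr.exc = as<std::string>(pj["polarity"]) == "exc";
    double dl = as<double>(pj["delay"]);
    int d = (R_IsNA(dl) || dl < 1) ? (pr.src_pop >= 4 ? 0 : 1) : (int)dl;
    pr.delay = d;
    pr.tau = as<double>(pj["tau_s"]);
    if (!(pr.tau > 0)) stop("projection without tau_s reached the edge engine");
    IntegerVector src = pj["src"], tgt = pj["tgt"];
    NumericVector wv = pj["weight"];
    int n_src = as<int>(pj["n_source"]);
    pr.n_tgt = as<int>(pj["n_target"]);
    // CSR by source
    std::vector<int> cnt(n_src + 1, 0);
    for (int e = 0; e < src.size(); ++e) cnt[src[e]]++; // src is 1-based
    pr.row_ptr.assign(n_src + 1, 0);
    for (int i = 0; i < n_src; ++i) pr.row_ptr[i + 1] = pr.row_ptr[i] + cnt[i + 1];
    std::vector<int> fill(pr.row_ptr.begin(), pr.row_ptr.end());
    pr.col.resize(src.size());
    pr.w.resize(src.size());
    for (int e = 0; e < src.size(); ++e) {
      int pos = fill[src[e] - 1]++;
      pr.col[pos] = tgt[e] - 1;
      pr.w[pos] = std::fabs(wv[e]);
    }
    pr.active.assign(src.size(), 1);
    pr.g.assign(pr.n_tgt, 0.0);
    pr.buf_len = pr.delay + 1;
    pr.buf.assign((size_t)pr.buf_len * pr.n_tgt, 0.0);
    // population-local E/I indices map into the 0..n_crx-1 cortical array
    src_off[q] = (as<std::string>(pj["source"]) == "I") ? n_exc : 0;
    tgt_off[q] = (as<std::string>(pj["target"]) == "I") ? n_exc : 0;
  }

  // recording
  NumericMatrix lfp(4, n_steps);
  std::vector<int> sp_pop, sp_neuron, sp_time;
  sp_pop.reserve(1 << 20); sp_neuron.reserve(1 << 20); sp_time.reserve(1 << 20);

  std::vector<char> thal_spk[3];
  for (int k = 0; k < 3; ++k) thal_spk[k].assign(NT, 0);
  std::vector<char> crx_spk(n_crx, 0);
  std::vector<char> les(n_crx, 0);
  for (int i = 0; i < n_crx; ++i) les[i] = lesion_mask[i] ? 1 : 0;
  int n_keep = 0;
  for (int i = 0; i < n_crx; ++i) if (!les[i]) ++n_keep;

  // per-target aggregate synaptic input for cortex
  std::vector<double> crx_syn(n_crx, 0.0);

  for (int t = 0; t < n_steps; ++t) {
    bool lesioned = (lesion_step >= 0 && t >= lesion_step);
    if (lesion_step >= 0 && t == lesion_step) {
      // sever every afferent and efferent edge of lesioned cortical cells
      for (int q = 0; q < n_proj; ++q) {
        Projection& pr = P[q];
        bool src_crx = pr.src_pop == 3, tgt_crx = pr.tgt_pop == 3;
        if (!src_crx && !tgt_crx) continue;
        int n_src = (int)pr.row_ptr.size() - 1;
        for (int i = 0; i < n_src; ++i) {
          bool src_les = src_crx && les[i + src_off[q]];
          for (int e = pr.row_ptr[i]; e < pr.row_ptr[i + 1]; ++e) {
            bool tgt_les = tgt_crx && les[pr.col[e] + tgt_off[q]];
            if (src_les || tgt_les) pr.active[e] = 0;
          }
        }
      }
    }

    // exogenous Poisson arrivals land in the current slot (zero delay)
    for (int q = 0; q < n_proj; ++q) {
      Projection& pr = P[q];
      if (pr.src_pop == 4 || pr.src_pop == 5) {
        IntegerMatrix& D = (pr.src_pop == 4) ? drive_sp : drive_nsp;
        int slot = t % pr.buf_len;
        double* b = &pr.buf[(size_t)slot * pr.n_tgt];
        int n_src = (int)pr.row_ptr.size() - 1;
        for (int i = 0; i < n_src; ++i) {
          if (D(i, t)) {
            for (int e = pr.row_ptr[i]; e < pr.row_ptr[i + 1]; ++e)
              if (pr.active[e]) b[pr.col[e]] += pr.w[e];
          }
        }
      }
    }

    // synaptic state update from this step's arrivals
    std::fill(crx_syn.begin(), crx_syn.end(), 0.0);
    std::vector<double> gE[3], gI[3];
    for (int k = 0; k < 3; ++k) { gE[k].assign(NT, 0.0); gI[k].assign(NT, 0.0); }
    for (int q = 0; q < n_proj; ++q) {
      Projection& pr = P[q];
      int slot = t % pr.buf_len;
      double* arr = &pr.buf[(size_t)slot * pr.n_tgt];
      double decay = 1.0 - dt / pr.tau;
      if (pr.tgt_pop <= 2) { // thalamic conductance target
        const ThalPars& tp = TP[pr.tgt_pop];
        double gain = pr.exc ? tp.k_E : tp.k_I;
        for (int j = 0; j < pr.n_tgt; ++j) {
          pr.g[j] = pr.g[j] * decay + gain * arr[j];
          if (pr.g[j] < 0) pr.g[j] = 0;
          arr[j] = 0.0;
          if (pr.exc) gE[pr.tgt_pop][j] += pr.g[j];
          else        gI[pr.tgt_pop][j] += pr.g[j];
        }
      } else {               // cortical decaying current target
        double sign = pr.exc ? 1.0 : -1.0;
        for (int j = 0; j < pr.n_tgt; ++j) {
          pr.g[j] = pr.g[j] * decay + arr[j];
          if (pr.g[j] < 0) pr.g[j] = 0;
          arr[j] = 0.0;
          crx_syn[j + tgt_off[q]] += sign * pr.g[j];
        }
      }
    }

    // thalamic membrane + h update
    for (int k = 0; k < 3; ++k) {
      const ThalPars& tp = TP[k];
      double lfp_sum = 0.0;
      for (int i = 0; i < NT; ++i) {
        double Vi = V[k][i], hi = h[k][i];
        double IT = (Vi > tp.V_h) ? tp.g_T * hi * (Vi - tp.E_T) : 0.0;
        double IL = tp.g_L * (Vi - tp.V_L);
        double Isyn = gE[k][i] * (Vi - tp.V_E) + gI[k][i] * (Vi - tp.V_I);
        double Vn = Vi + dt / tp.C * (-IL - Isyn - IT);
        char spk = 0;
        if (Vn >= tp.V_0) { spk = 1; Vn = tp.V_reset; }
        double dh = (Vi > tp.V_h) ? -hi / tp.tau_h_minus
                                  : (1.0 - hi) / tp.tau_h_plus;
        hi += dt * dh;
        if (hi < 0) hi = 0; else if (hi > 1) hi = 1;
        V[k][i] = Vn; h[k][i] = hi; thal_spk[k][i] = spk;
        if (spk) { sp_pop.push_back(k); sp_neuron.push_back(i + 1);
                   sp_time.push_back(t); }
        lfp_sum += Vn;
        if (!std::isfinite(Vn)) stop("thalamic blow-up at step %d", t);
      }
      lfp(k, t) = lfp_sum / NT;
    }

    // cortical update
    double lfp_sum = 0.0;
    bool jitter = i_jitter_sd[0] > 0 || i_jitter_sd[1] > 0;
    for (int i = 0; i < n_crx; ++i) {
      double I = cI[i] + crx_syn[i] + pulse[i];
      if (jitter)
        I += R::norm_rand() * i_jitter_sd[i < n_exc ? 0 : 1];
      if (lesioned && !les[i]) I += gaba[t];
      double vi = v[i], ui = u[i];
      // 0.04*(vi*vi): keep the association identical to the R reference
      vi += 0.5 * dt * (0.04 * (vi * vi) + 5.0 * vi + 140.0 - ui + I);
      vi += 0.5 * dt * (0.04 * (vi * vi) + 5.0 * vi + 140.0 - ui + I);
      ui += dt * ca[i] * (cb[i] * vi - ui);
      char spk = 0;
      if (vi >= cutoff) {
        spk = 1; vi = cc[i]; ui += cd[i];
        if (!(lesioned && les[i])) {
          sp_pop.push_back(3); sp_neuron.push_back(i + 1); sp_time.push_back(t);
        }
      }
      v[i] = vi; u[i] = ui; crx_spk[i] = spk;
      if (!les[i]) lfp_sum += vi;
      if (!std::isfinite(vi)) stop("cortical blow-up at step %d", t);
    }
    lfp(3, t) = lfp_sum / n_keep;

    // next-step cortico-cortical pulses (dense all-to-all weight matrix,
    // zero diagonal = no self-connections); lesioned cells neither send
    // nor receive after the lesion
    std::fill(pulse.begin(), pulse.end(), 0.0);
    for (int j = 0; j < n_crx; ++j) {
      if (!crx_spk[j] || (lesioned && les[j])) continue;
      const double* wj = &w_cc(0, j);
      for (int i = 0; i < n_crx; ++i) pulse[i] += wj[i];
    }
    if (lesioned)
      for (int i = 0; i < n_crx; ++i) if (les[i]) pulse[i] = 0.0;

    // schedule this step's network spikes into projection buffers
    for (int q = 0; q < n_proj; ++q) {
      Projection& pr = P[q];
      if (pr.src_pop >= 4) continue;
      int slot = (t + pr.delay) % pr.buf_len;
      double* b = &pr.buf[(size_t)slot * pr.n_tgt];
      int n_src = (int)pr.row_ptr.size() - 1;
      const char* spkv = (pr.src_pop <= 2) ? &thal_spk[pr.src_pop][0]
                                           : &crx_spk[src_off[q]];
      for (int i = 0; i < n_src; ++i) {
        if (spkv[i]) {
          for (int e = pr.row_ptr[i]; e < pr.row_ptr[i + 1]; ++e)
            if (pr.active[e]) b[pr.col[e]] += pr.w[e];
        }
      }
    }
  }

  return List::create(
    _["lfp"] = lfp,
    _["spike_pop"] = wrap(sp_pop),
    _["spike_neuron"] = wrap(sp_neuron),
    _["spike_time"] = wrap(sp_time));
}
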