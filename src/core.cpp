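#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multicompartment integrator for the reduced dSPN surrogate.
//
// Units: mV, ms, nA, uS, nF, mM, um.  The compartment vector holds the
// electrical tree (soma first, Hines order: parent index < child index);
// spine heads are appended as leaf compartments coupled to their shaft
// through the neck conductance (stored in g_ax).  One backward-Euler step
// of the cable system is solved per dt with channel/synapse conductances
// frozen at the previous voltage; the tree solve is O(N) and stable for
// the microsecond spine-head time constants that an explicit scheme
// cannot integrate at dt >= 0.01 ms.

static inline double mg_block(double v) {
  // Jahr-Stevens magnesium block, [Mg] = 1 mM: half-unblock near -20 mV,
  // slope 0.062/mV.
  return 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
}

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((vh - v) / k));
}

// [[Rcpp::export]]
List sim_core(List pack, NumericVector v_init, NumericMatrix events,
              NumericMatrix inj, double duration, double dt, List rec) {
  // --- unpack compartments -------------------------------------------------
  IntegerVector parent = pack["parent"];
  NumericVector cap = pack["cap"], g_leak = pack["g_leak"];
  NumericVector g_kir = pack["g_kir"], g_ax = pack["g_ax"], dist = pack["dist"];
  double e_leak = pack["e_leak"], e_k = pack["e_k"];
  double kir_vh = pack["kir_vh"], kir_k = pack["kir_k"];
  const int nc = parent.size();

  // --- synapse rows --------------------------------------------------------
  IntegerVector s_comp = pack["syn_comp"], s_mg = pack["syn_mg"];
  IntegerVector s_pool = pack["syn_pool"], s_unit = pack["syn_unit"];
  NumericVector s_g = pack["syn_g"], s_e = pack["syn_e"];
  NumericVector s_tr = pack["syn_tr"], s_td = pack["syn_td"];
  NumericVector s_ton = pack["syn_ton"], s_wsp = pack["syn_wsp"];
  const int ns = s_comp.size();

  // --- spillover units -----------------------------------------------------
  IntegerVector un_row = pack["un_row"];
  NumericVector un_thresh = pack["un_thresh"];
  const int nu = un_row.size();

  // --- voltage-gated calcium surrogates ------------------------------------
  NumericVector g_lva = pack["g_lva"], g_hva = pack["g_hva"];
  IntegerVector lpool = pack["lpool"];
  double lva_vh = pack["lva_vh"], lva_k = pack["lva_k"], lva_tau = pack["lva_tau"];
  double hva_vh = pack["hva_vh"], hva_k = pack["hva_k"], hva_tau = pack["hva_tau"];
  double e_ca = pack["e_ca"], frac_l = pack["frac_l"];

  // --- calcium pools -------------------------------------------------------
  const int npool = as<int>(pack["n_exc"]);
  double phi_n = pack["phi_n"], vmax_n = pack["vmax_n"], km_n = pack["km_n"],
         tau_n = pack["tau_n"], base_n = pack["base_n"];
  double phi_l = pack["phi_l"], vmax_l = pack["vmax_l"], km_l = pack["km_l"],
         tau_l = pack["tau_l"], base_l = pack["base_l"];
  double phi_v = pack["phi_v"], vmax_v = pack["vmax_v"], km_v = pack["km_v"],
         tau_v = pack["tau_v"], base_v = pack["base_v"];

  // --- somatic spike mechanism --------------------------------------------
  double sp_thresh = pack["spike_thresh"], v_reset = pack["v_reset"];
  double refrac = pack["refrac"], bap_amp = pack["bap_amp"],
         bap_lambda = pack["bap_lambda"];
  double ahp_inc = pack["ahp_inc"], ahp_tau = pack["ahp_tau"];

  // --- recording options ---------------------------------------------------
  bool record = as<bool>(rec["record"]);
  IntegerVector rec_comps = rec["comps"];
  IntegerVector rec_pools = rec["pools"];
  int stride = as<int>(rec["stride"]);

  const int nstep = (int)std::lround(duration / dt);
  if (v_init.size() != nc) stop("v_init length does not match compartments");

  // state
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> s(ns, 0.0), on_until(ns, -1e18);
  std::vector<double> m_l(nc), m_h(nc);
  std::vector<double> ca_n(npool, base_n), ca_l(npool, base_l), ca_v(nc, base_v);
  std::vector<double> ca_n_pk(npool, base_n), ca_l_pk(npool, base_l),
      ca_v_pk(nc, base_v), v_pk(V), s_pk(ns, 0.0);
  std::vector<double> usum(nu, 0.0), utrig(nu, NA_REAL);
  std::vector<std::vector<int>> u_active(nu);
  std::vector<double> influx_n(npool);

  for (int c = 0; c < nc; ++c) {
    m_l[c] = boltz(V[c], lva_vh, lva_k);
    m_h[c] = boltz(V[c], hva_vh, hva_k);
  }

  // precomputed per-row gate factors and per-comp helpers
  std::vector<double> rise_f(ns), dec_f(ns);
  for (int r = 0; r < ns; ++r) {
    rise_f[r] = std::exp(-dt / s_tr[r]);
    dec_f[r] = std::exp(-dt / s_td[r]);
  }
  double lva_f = 1.0 - std::exp(-dt / lva_tau);
  double hva_f = 1.0 - std::exp(-dt / hva_tau);
  std::vector<double> kick(nc, 0.0);
  for (int c = 1; c < nc; ++c) kick[c] = bap_amp * std::exp(-dist[c] / bap_lambda);

  std::vector<double> d(nc), b(nc), gsum(nc), gE(nc), Iinj(nc);
  std::vector<double> spikes;
  double last_spike = -1e18;
  double g_ahp = 0.0;                      // somatic after-spike K conductance
  double ahp_dec = std::exp(-dt / ahp_tau);

  // trace buffers
  int nrec = record ? ((nstep + stride - 1) / stride) : 0;
  NumericMatrix vtr(record ? nrec : 0, record ? rec_comps.size() : 0);
  NumericMatrix cntr(record ? nrec : 0, record ? rec_pools.size() : 0);
  NumericMatrix cltr(record ? nrec : 0, record ? rec_pools.size() : 0);
  NumericVector ttr(record ? nrec : 0);
  int irec = 0;

  int iev = 0;
  const int nev = events.nrow(), ninj = inj.nrow();

  for (int step = 0; step < nstep; ++step) {
    double t = step * dt;

    // presynaptic events scheduled in [t, t + dt)
    while (iev < nev && events(iev, 0) < t + dt) {
      int r = (int)events(iev, 1);
      if (r < 0 || r >= ns) stop("event refers to an unknown synapse row");
      on_until[r] = events(iev, 0) + s_ton[r];
      int u = s_unit[r];
      if (u >= 0 && s_wsp[r] > 0.0) {
        usum[u] += s_wsp[r];
        if (s_pool[r] >= 0) u_active[u].push_back(s_pool[r]);
        if (ISNA(utrig[u]) && usum[u] >= un_thresh[u] - 1e-12) {
          utrig[u] = events(iev, 0);
          int ur = un_row[u];
          on_until[ur] = events(iev, 0) + s_ton[ur];
        }
      }
      ++iev;
    }

    // saturating gates
    for (int r = 0; r < ns; ++r) {
      if (t < on_until[r])
        s[r] = 1.0 - (1.0 - s[r]) * rise_f[r];
      else
        s[r] *= dec_f[r];
      if (s[r] > s_pk[r]) s_pk[r] = s[r];
    }

    // per-compartment synaptic conductance; NMDA influx bookkeeping
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gE.begin(), gE.end(), 0.0);
    std::fill(influx_n.begin(), influx_n.end(), 0.0);
    for (int r = 0; r < ns; ++r) {
      if (s[r] < 1e-9) continue;
      int c = s_comp[r];
      double g = s_g[r] * s[r];
      if (s_mg[r]) g *= mg_block(V[c]);
      gsum[c] += g;
      gE[c] += g * s_e[r];
      if (s_pool[r] >= 0) {
        double I = g * (V[c] - s_e[r]);  // inward is negative
        if (I < 0) influx_n[s_pool[r]] -= I;
      }
    }

    // Spillover calcium: each synapse has extrasynaptic NMDA receptors on
    // the shaft next to its spine, activated when the pooling unit
    // triggers; their calcium feeds that synapse's NMDA pool.  The
    // electrical unit conductance stands in for each receptor's current.
    for (int u = 0; u < nu; ++u) {
      if (ISNA(utrig[u]) || u_active[u].empty()) continue;
      int ur = un_row[u];
      if (s[ur] < 1e-9) continue;
      int c = s_comp[ur];
      double I = s_g[ur] * s[ur] * mg_block(V[c]) * (V[c] - s_e[ur]);
      if (I < 0) {
        for (int p : u_active[u]) influx_n[p] -= I;
      }
    }

    // injected currents
    std::fill(Iinj.begin(), Iinj.end(), 0.0);
    for (int j = 0; j < ninj; ++j)
      if (t >= inj(j, 2) && t < inj(j, 3)) Iinj[(int)inj(j, 0)] += inj(j, 1);

    // assemble and solve the implicit tree system
    g_ahp *= ahp_dec;
    for (int c = 0; c < nc; ++c) {
      double gk = g_kir[c] * boltz(V[c], kir_vh, -kir_k);  // closes with depol.
      if (c == 0) gk += g_ahp;
      d[c] = cap[c] / dt + g_leak[c] + gk + gsum[c];
      b[c] = cap[c] / dt * V[c] + g_leak[c] * e_leak + gk * e_k + gE[c] + Iinj[c];
    }
    for (int c = 1; c < nc; ++c) {
      d[c] += g_ax[c];
      d[parent[c]] += g_ax[c];
    }
    for (int c = nc - 1; c >= 1; --c) {
      double f = g_ax[c] / d[c];
      d[parent[c]] -= f * g_ax[c];
      b[parent[c]] += f * b[c];
    }
    V[0] = b[0] / d[0];
    for (int c = 1; c < nc; ++c) V[c] = (b[c] + g_ax[c] * V[parent[c]]) / d[c];

    // somatic spike: threshold crossing, refractory guard, reset + bAP kick
    if (V[0] >= sp_thresh && t + dt - last_spike >= refrac) {
      last_spike = t + dt;
      spikes.push_back(t + dt);
      V[0] = v_reset;
      g_ahp += ahp_inc;
      for (int c = 1; c < nc; ++c) V[c] += kick[c];
      if (spikes.size() > 500) stop("runaway spiking: > 500 somatic spikes");
    }

    // VGCC activation, calcium influx and pool updates
    for (int c = 0; c < nc; ++c) {
      m_l[c] += (boltz(V[c], lva_vh, lva_k) - m_l[c]) * lva_f;
      m_h[c] += (boltz(V[c], hva_vh, hva_k) - m_h[c]) * hva_f;
      double drive = V[c] - e_ca;
      double in_l = 0.0, in_h = 0.0;
      if (drive < 0) {
        in_l = -g_lva[c] * m_l[c] * drive;
        in_h = -g_hva[c] * m_h[c] * drive;
      }
      // pump extrusion acts on the evoked calcium above baseline, so the
      // baseline is an exact fixed point of the pool dynamics
      double ca = ca_v[c];
      double ev = ca > base_v ? ca - base_v : 0.0;
      ca += dt * (phi_v * (in_l + in_h) - vmax_v * ev / (ev + km_v) -
                  (ca - base_v) / tau_v);
      ca_v[c] = ca > 0 ? ca : 0.0;
      if (ca_v[c] > ca_v_pk[c]) ca_v_pk[c] = ca_v[c];
      if (lpool[c] >= 0) {
        int p = lpool[c];
        double cl = ca_l[p];
        double el = cl > base_l ? cl - base_l : 0.0;
        cl += dt * (phi_l * frac_l * in_h - vmax_l * el / (el + km_l) -
                    (cl - base_l) / tau_l);
        ca_l[p] = cl > 0 ? cl : 0.0;
        if (ca_l[p] > ca_l_pk[p]) ca_l_pk[p] = ca_l[p];
      }
      if (V[c] > v_pk[c]) v_pk[c] = V[c];
    }
    for (int p = 0; p < npool; ++p) {
      double cn = ca_n[p];
      double en = cn > base_n ? cn - base_n : 0.0;
      cn += dt * (phi_n * influx_n[p] - vmax_n * en / (en + km_n) -
                  (cn - base_n) / tau_n);
      ca_n[p] = cn > 0 ? cn : 0.0;
      if (ca_n[p] > ca_n_pk[p]) ca_n_pk[p] = ca_n[p];
    }

    if (record && step % stride == 0 && irec < nrec) {
      for (int j = 0; j < rec_comps.size(); ++j) vtr(irec, j) = V[rec_comps[j]];
      for (int j = 0; j < rec_pools.size(); ++j) {
        cntr(irec, j) = ca_n[rec_pools[j]];
        cltr(irec, j) = ca_l[rec_pools[j]];
      }
      ttr[irec] = t + dt;
      ++irec;
    }

    if (step % 25 == 0) {
      for (int c = 0; c < nc; ++c)
        if (!std::isfinite(V[c]))
          stop("integration failure: non-finite voltage in compartment %d at t = %f ms",
               c + 1, t);
    }
  }
  for (int c = 0; c < nc; ++c)
    if (!std::isfinite(V[c]))
      stop("integration failure: non-finite voltage in compartment %d at end", c + 1);

  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["trigger_time"] = NumericVector(utrig.begin(), utrig.end()),
      _["ca_nmda_peak"] = NumericVector(ca_n_pk.begin(), ca_n_pk.end()),
      _["ca_ltype_peak"] = NumericVector(ca_l_pk.begin(), ca_l_pk.end()),
      _["ca_v_peak"] = NumericVector(ca_v_pk.begin(), ca_v_pk.end()),
      _["v_peak"] = NumericVector(v_pk.begin(), v_pk.end()),
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["gate_peak"] = NumericVector(s_pk.begin(), s_pk.end()),
      _["unit_wsum"] = NumericVector(usum.begin(), usum.end()));
  if (record) {
    out["t"] = ttr;
    out["v_trace"] = vtr;
    out["ca_nmda_trace"] = cntr;
    out["ca_ltype_trace"] = cltr;
  }
  return out;
}
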