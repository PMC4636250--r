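// Closed-loop compartmental engine: implicit (backward-Euler) cable solver
// on the granule cell tree with Hodgkin-Huxley-style membrane mechanisms,
// event-driven double-exponential synapses, threshold-crossing event
// detection, and the online STDP + BCM-metaplasticity weight update.
//
// Units: time ms, voltage mV, conductance uS, current nA, capacitance nF,
// concentration mM.  Compartments are ordered so that parent(i) < i, which
// makes the Hines elimination a single backward + forward sweep.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// x/(exp(x)-1) with the removable singularity handled
static inline double expdiv(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - 0.5 * x;
  return x / (std::exp(x) - 1.0);
}

static inline double sig(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// channel indices (must match the R-side roster)
enum { NA_CH = 0, KDRF, KDRS, KA, CAT, CAN, CAL, SK, BK, NCHAN };

struct Gates {
  // per-compartment gating variables, one vector per gate
  std::vector<double> na_m, na_h, kf_n, ks_n, ka_a, ka_b,
      ct_m, ct_h, cn_m, cl_m, sk_z, bk_m;
};

struct RateOut { double inf, tau; };

// Na activation/inactivation, Traub-style, rest ~ -75 mV, threshold ~ -52 mV
static inline RateOut na_m_rate(double v) {
  double a = 1.28 * expdiv(-(v + 54.0) / 4.0);
  double b = 1.40 * expdiv((v + 27.0) / 5.0);
  return { a / (a + b), 1.0 / (a + b) };
}
// scale < 1 slows Na inactivation/recovery uniformly (h_inf unchanged),
// lengthening the relative refractory period during sustained depolarization
static inline RateOut na_h_rate(double v, double scale) {
  double a = scale * 0.128 * std::exp(-(v + 50.0) / 18.0);
  double b = scale * 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
  return { a / (a + b), 1.0 / (a + b) };
}
static inline RateOut kdr_rate(double v) {
  double a = 0.16 * expdiv(-(v + 52.0) / 5.0);
  double b = 0.5 * std::exp(-(v + 57.0) / 40.0);
  return { a / (a + b), 1.0 / (a + b) };
}

struct EngineParams {
  double dt, t_stop;
  double syn_tau_r, syn_tau_d, syn_e, syn_norm;
  // plasticity
  bool plas_on;
  double a_p0, a_d0, tau_p, tau_d, tau_c_ms, alpha, v_syn_thresh,
      v_soma_thresh, max_change, c_floor, debounce, c0, warmup_ms, lapse;
  bool freeze_ap, freeze_ad;
};

// [[Rcpp::export]]
List engine_run(List comp, List mech, List syn, List drive, List plas,
                List ctl) {
  // ---- topology / passive ----
  IntegerVector parent = comp["parent"];        // 0-based, -1 for root
  NumericVector C_nF = comp["C_nF"];
  NumericVector g_ax = comp["g_axial_uS"];      // conductance to parent
  IntegerVector layer = comp["layer"];          // 0..4
  NumericVector gl = mech["g_leak_uS"];
  double el = as<double>(mech["e_leak"]);
  NumericMatrix gchan = mech["g_chan_uS"];      // NCHAN x ncomp, base values
  NumericVector erev = mech["e_rev"];           // per channel
  NumericVector vshift = mech["vshift"];        // per channel
  NumericVector caB = mech["ca_B"];             // per comp, mM per nA*ms
  double ca_tau = as<double>(mech["ca_tau"]);
  double ca0 = as<double>(mech["ca0"]);
  double na_h_scale = as<double>(mech["na_h_scale"]);
  double na_h_shift = as<double>(mech["na_h_shift"]);
  NumericMatrix block0 = mech["block"];         // NCHAN x 5 factors
  NumericMatrix sched = mech["block_schedule"]; // rows: time, chan, layer, factor

  const int n = parent.size();

  // ---- synapses ----
  IntegerVector syn_comp = syn["comp"];         // 0-based
  NumericVector w_init = syn["weight"];
  const int nsyn = syn_comp.size();

  // ---- drive (merged, time-sorted presynaptic spikes) ----
  NumericVector pre_t = drive["time"];
  IntegerVector pre_s = drive["syn"];           // 0-based
  const int npre = pre_t.size();

  // ---- parameters ----
  EngineParams P;
  P.dt = as<double>(ctl["dt"]);
  P.t_stop = as<double>(ctl["t_stop"]);
  P.syn_tau_r = as<double>(syn["tau_rise"]);
  P.syn_tau_d = as<double>(syn["tau_decay"]);
  P.syn_e = as<double>(syn["e_rev"]);
  {
    double tr = P.syn_tau_r, td = P.syn_tau_d;
    double tp = tr * td / (td - tr) * std::log(td / tr);
    P.syn_norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }
  P.plas_on = as<bool>(plas["enabled"]);
  P.a_p0 = as<double>(plas["a_p0"]);
  P.a_d0 = as<double>(plas["a_d0"]);
  P.tau_p = as<double>(plas["tau_p"]);
  P.tau_d = as<double>(plas["tau_d"]);
  P.tau_c_ms = as<double>(plas["tau_c_ms"]);
  P.alpha = as<double>(plas["alpha"]);
  P.v_syn_thresh = as<double>(plas["v_syn_thresh"]);
  P.v_soma_thresh = as<double>(plas["v_soma_thresh"]);
  P.max_change = as<double>(plas["max_change"]);
  P.c_floor = as<double>(plas["c_floor"]);
  P.debounce = as<double>(plas["debounce"]);
  P.c0 = as<double>(plas["c0"]);
  P.warmup_ms = as<double>(plas["warmup_ms"]);
  const long long warmup_steps = (long long)std::llround(P.warmup_ms / P.dt);
  P.lapse = 5.0 * P.tau_p;
  P.freeze_ap = as<bool>(plas["freeze_ap"]);
  P.freeze_ad = as<bool>(plas["freeze_ad"]);

  IntegerVector probes = ctl["probes"];         // 0-based comp indices
  int probe_stride = as<int>(ctl["probe_stride"]);
  double snapshot_ms = as<double>(ctl["snapshot_ms"]);
  bool record_gsyn = as<bool>(ctl["record_gsyn"]);
  bool record_events = as<bool>(ctl["record_events"]);
  NumericMatrix iclamp = ctl["iclamp"];         // rows: comp, t0, t1, amp

  // ---- state ----
  std::vector<double> V(n, el), Vnew(n), ca(n, ca0);
  std::vector<double> synA(n, 0.0), synB(n, 0.0);
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> w0(w.begin(), w.end());

  // block factors per channel x layer (5 layers)
  double blk[NCHAN][5];
  for (int c = 0; c < NCHAN; ++c)
    for (int l = 0; l < 5; ++l) blk[c][l] = block0(c, l);
  int sched_ptr = 0;

  Gates g;
  g.na_m.assign(n, 0); g.na_h.assign(n, 0); g.kf_n.assign(n, 0);
  g.ks_n.assign(n, 0); g.ka_a.assign(n, 0); g.ka_b.assign(n, 0);
  g.ct_m.assign(n, 0); g.ct_h.assign(n, 0); g.cn_m.assign(n, 0);
  g.cl_m.assign(n, 0); g.sk_z.assign(n, 0); g.bk_m.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    double v = V[i];
    g.na_m[i] = na_m_rate(v - vshift[NA_CH]).inf;
    g.na_h[i] = na_h_rate(v - vshift[NA_CH] + na_h_shift, na_h_scale).inf;
    g.kf_n[i] = kdr_rate(v - vshift[KDRF]).inf;
    g.ks_n[i] = kdr_rate(v - vshift[KDRS]).inf;
    g.ka_a[i] = sig(v, -35.0, 10.0);
    g.ka_b[i] = sig(v, -70.0, -6.0);
    g.ct_m[i] = sig(v, -50.0, 5.0);
    g.ct_h[i] = sig(v, -70.0, -6.0);
    g.cn_m[i] = sig(v, -20.0, 7.0);
    g.cl_m[i] = sig(v, -10.0, 6.0);
    g.sk_z[i] = 0.0;
    g.bk_m[i] = sig(v, -10.0, 8.0);
  }

  // per-channel active compartment lists (base conductance > 0)
  std::vector< std::vector<int> > active(NCHAN);
  for (int c = 0; c < NCHAN; ++c)
    for (int i = 0; i < n; ++i)
      if (gchan(c, i) > 0) active[c].push_back(i);

  // synapse lists per compartment, and which comps host synapses
  std::vector< std::vector<int> > comp_syn(n);
  for (int s = 0; s < nsyn; ++s) comp_syn[syn_comp[s]].push_back(s);
  std::vector<int> ev_comps;
  for (int i = 0; i < n; ++i) if (!comp_syn[i].empty()) ev_comps.push_back(i);

  // synapse decay factors
  const double fA = std::exp(-P.dt / P.syn_tau_r);
  const double fB = std::exp(-P.dt / P.syn_tau_d);

  // <c> recursion constants
  const double c_decay = std::exp(-P.dt / P.tau_c_ms);
  const double c_inc = P.alpha * P.dt / P.tau_c_ms;
  double c_avg = P.c0;
  double A_p = P.freeze_ap ? P.a_p0 : P.a_p0 / std::max(c_avg, P.c_floor);
  double A_d = P.freeze_ad ? P.a_d0 : P.a_d0 * std::max(c_avg, P.c_floor);

  // plasticity pairing state
  std::vector<double> last_post(n, -1e30), last_event(n, -1e30);
  double last_soma_spike = -1e30, last_soma_event = -1e30;
  std::vector< std::vector<double> > pending(nsyn);

  // outputs
  std::vector<double> soma_spikes;
  std::vector<int> post_ev_comp;
  std::vector<double> post_ev_time;
  const int nstep = (int)std::llround(P.t_stop / P.dt);
  const int nprobe = probes.size();
  int nsamp = (nprobe > 0) ? nstep / probe_stride + 1 : 0;
  NumericMatrix Vrec(nsamp, nprobe), Grec(record_gsyn ? nsamp : 0,
                                          record_gsyn ? nprobe : 0);
  NumericVector Trec(nsamp);
  int rec_row = 0;
  if (nprobe > 0) {
    Trec[0] = 0.0;
    for (int p = 0; p < nprobe; ++p) {
      Vrec(0, p) = V[probes[p]];
      if (record_gsyn) Grec(0, p) = 0.0;
    }
    rec_row = 1;
  }
  int nsnap = (snapshot_ms > 0) ? (int)(P.t_stop / snapshot_ms) + 1 : 0;
  NumericMatrix Wsnap(nsnap, nsnap > 0 ? nsyn : 0);
  NumericVector snap_t(nsnap), snap_c(nsnap), snap_ap(nsnap), snap_ad(nsnap);
  int snap_row = 0;
  if (nsnap > 0) {
    snap_t[0] = 0.0; snap_c[0] = c_avg; snap_ap[0] = A_p; snap_ad[0] = A_d;
    for (int s = 0; s < nsyn; ++s) Wsnap(0, s) = w[s];
    snap_row = 1;
  }

  // scratch for the Hines solve
  std::vector<double> d(n), rhs(n), Gm(n), Sm(n), Iinj(n), Ica(n);

  // per-step event buffers (comp/syn index, exact time)
  struct Ev { double t; int idx; int type; }; // type 0 = post, 1 = pre
  std::vector<Ev> step_ev;
  step_ev.reserve(64);

  int pre_ptr = 0;
  const double clamp_eps = 1e-9;

  for (int step = 0; step < nstep; ++step) {
    double t = step * P.dt;
    double t_next = t + P.dt;

    // scheduled channel block changes take effect at the next step
    while (sched_ptr < sched.nrow() && sched(sched_ptr, 0) <= t) {
      blk[(int)sched(sched_ptr, 1)][(int)sched(sched_ptr, 2)] =
          sched(sched_ptr, 3);
      ++sched_ptr;
    }

    // synaptic conductance decay, then deliver this step's spikes
    for (int i = 0; i < n; ++i) { synA[i] *= fA; synB[i] *= fB; }
    step_ev.clear();
    while (pre_ptr < npre && pre_t[pre_ptr] <= t_next) {
      int s = pre_s[pre_ptr];
      double inc = w[s] * P.syn_norm;
      synA[syn_comp[s]] += inc;
      synB[syn_comp[s]] += inc;
      step_ev.push_back({ pre_t[pre_ptr], s, 1 });
      ++pre_ptr;
    }

    // membrane conductances and gate updates
    std::fill(Gm.begin(), Gm.end(), 0.0);
    std::fill(Sm.begin(), Sm.end(), 0.0);
    std::fill(Ica.begin(), Ica.end(), 0.0);

    for (size_t k = 0; k < active[NA_CH].size(); ++k) {
      int i = active[NA_CH][k];
      double v = V[i] - vshift[NA_CH];
      RateOut rm = na_m_rate(v), rh = na_h_rate(v + na_h_shift, na_h_scale);
      g.na_m[i] += (rm.inf - g.na_m[i]) * (1.0 - std::exp(-P.dt / rm.tau));
      g.na_h[i] += (rh.inf - g.na_h[i]) * (1.0 - std::exp(-P.dt / rh.tau));
      double gv = gchan(NA_CH, i) * blk[NA_CH][layer[i]] *
                  g.na_m[i] * g.na_m[i] * g.na_m[i] * g.na_h[i];
      Gm[i] += gv; Sm[i] += gv * erev[NA_CH];
    }
    for (size_t k = 0; k < active[KDRF].size(); ++k) {
      int i = active[KDRF][k];
      RateOut rn = kdr_rate(V[i] - vshift[KDRF]);
      g.kf_n[i] += (rn.inf - g.kf_n[i]) * (1.0 - std::exp(-P.dt / rn.tau));
      double n4 = g.kf_n[i] * g.kf_n[i]; n4 *= n4;
      double gv = gchan(KDRF, i) * blk[KDRF][layer[i]] * n4;
      Gm[i] += gv; Sm[i] += gv * erev[KDRF];
    }
    for (size_t k = 0; k < active[KDRS].size(); ++k) {
      int i = active[KDRS][k];
      RateOut rn = kdr_rate(V[i] - vshift[KDRS]);
      double tau = 10.0 * rn.tau;  // slow delayed rectifier
      g.ks_n[i] += (rn.inf - g.ks_n[i]) * (1.0 - std::exp(-P.dt / tau));
      double n4 = g.ks_n[i] * g.ks_n[i]; n4 *= n4;
      double gv = gchan(KDRS, i) * blk[KDRS][layer[i]] * n4;
      Gm[i] += gv; Sm[i] += gv * erev[KDRS];
    }
    for (size_t k = 0; k < active[KA].size(); ++k) {
      int i = active[KA][k];
      double v = V[i] - vshift[KA];
      g.ka_a[i] += (sig(v, -35.0, 10.0) - g.ka_a[i]) * (1.0 - std::exp(-P.dt / 5.0));
      g.ka_b[i] += (sig(v, -70.0, -6.0) - g.ka_b[i]) * (1.0 - std::exp(-P.dt / 30.0));
      double gv = gchan(KA, i) * blk[KA][layer[i]] * g.ka_a[i] * g.ka_b[i];
      Gm[i] += gv; Sm[i] += gv * erev[KA];
    }
    for (size_t k = 0; k < active[CAT].size(); ++k) {
      int i = active[CAT][k];
      double v = V[i] - vshift[CAT];
      g.ct_m[i] += (sig(v, -50.0, 5.0) - g.ct_m[i]) * (1.0 - std::exp(-P.dt / 5.0));
      g.ct_h[i] += (sig(v, -70.0, -6.0) - g.ct_h[i]) * (1.0 - std::exp(-P.dt / 50.0));
      double gv = gchan(CAT, i) * blk[CAT][layer[i]] *
                  g.ct_m[i] * g.ct_m[i] * g.ct_h[i];
      Gm[i] += gv; Sm[i] += gv * erev[CAT];
      Ica[i] += gv * (V[i] - erev[CAT]);
    }
    for (size_t k = 0; k < active[CAN].size(); ++k) {
      int i = active[CAN][k];
      double v = V[i] - vshift[CAN];
      g.cn_m[i] += (sig(v, -20.0, 7.0) - g.cn_m[i]) * (1.0 - std::exp(-P.dt / 2.0));
      double gv = gchan(CAN, i) * blk[CAN][layer[i]] * g.cn_m[i] * g.cn_m[i];
      Gm[i] += gv; Sm[i] += gv * erev[CAN];
      Ica[i] += gv * (V[i] - erev[CAN]);
    }
    for (size_t k = 0; k < active[CAL].size(); ++k) {
      int i = active[CAL][k];
      double v = V[i] - vshift[CAL];
      g.cl_m[i] += (sig(v, -10.0, 6.0) - g.cl_m[i]) * (1.0 - std::exp(-P.dt / 2.0));
      double gv = gchan(CAL, i) * blk[CAL][layer[i]] * g.cl_m[i] * g.cl_m[i];
      Gm[i] += gv; Sm[i] += gv * erev[CAL];
      Ica[i] += gv * (V[i] - erev[CAL]);
    }
    for (size_t k = 0; k < active[SK].size(); ++k) {
      int i = active[SK][k];
      double c2 = ca[i] * ca[i];
      double zinf = c2 / (c2 + 4e-8);           // half-activation 0.2 uM
      g.sk_z[i] += (zinf - g.sk_z[i]) * (1.0 - std::exp(-P.dt / 5.0));
      double gv = gchan(SK, i) * blk[SK][layer[i]] * g.sk_z[i];
      Gm[i] += gv; Sm[i] += gv * erev[SK];
    }
    for (size_t k = 0; k < active[BK].size(); ++k) {
      int i = active[BK][k];
      double v = V[i] - vshift[BK];
      g.bk_m[i] += (sig(v, -10.0, 8.0) - g.bk_m[i]) * (1.0 - std::exp(-P.dt / 1.0));
      double hill = ca[i] / (ca[i] + 1e-3);
      double gv = gchan(BK, i) * blk[BK][layer[i]] * g.bk_m[i] * hill;
      Gm[i] += gv; Sm[i] += gv * erev[BK];
    }

    // leak + synapses + injected current
    std::fill(Iinj.begin(), Iinj.end(), 0.0);
    for (int r = 0; r < iclamp.nrow(); ++r) {
      if (t_next > iclamp(r, 1) && t_next <= iclamp(r, 2))
        Iinj[(int)iclamp(r, 0)] += iclamp(r, 3);
    }
    for (int i = 0; i < n; ++i) {
      Gm[i] += gl[i]; Sm[i] += gl[i] * el;
      double gs = synB[i] - synA[i];
      if (gs > 0) { Gm[i] += gs; Sm[i] += gs * P.syn_e; }
    }

    // backward-Euler Hines solve
    for (int i = 0; i < n; ++i) {
      d[i] = C_nF[i] / P.dt + Gm[i];
      rhs[i] = C_nF[i] / P.dt * V[i] + Sm[i] + Iinj[i];
    }
    for (int i = 1; i < n; ++i) { d[i] += g_ax[i]; d[parent[i]] += g_ax[i]; }
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_ax[i] / d[i];
      d[p] -= g_ax[i] * f;
      rhs[p] += rhs[i] * f;
    }
    Vnew[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      Vnew[i] = (rhs[i] + g_ax[i] * Vnew[parent[i]]) / d[i];

    if (!std::isfinite(Vnew[0]))
      stop("non-finite membrane state at t = %f ms", t_next);

    // calcium pools (explicit, driven by the updated voltage's currents
    // computed with the pre-solve conductances)
    for (int i = 0; i < n; ++i) {
      if (caB[i] > 0 && (Ica[i] != 0.0 || ca[i] != ca0)) {
        ca[i] += P.dt * (-caB[i] * Ica[i] - (ca[i] - ca0) / ca_tau);
        if (ca[i] < 1e-9) ca[i] = 1e-9;
      }
    }

    // somatic spike detection (rising crossing of the soma threshold)
    bool spike_now = false;
    if (V[0] < P.v_soma_thresh && Vnew[0] >= P.v_soma_thresh) {
      double frac = (P.v_soma_thresh - V[0]) / (Vnew[0] - V[0]);
      double ts = t + frac * P.dt;
      if (ts - last_soma_event >= P.debounce) {
        soma_spikes.push_back(ts);
        last_soma_event = ts;
        last_soma_spike = ts;
        spike_now = true;
      }
    }

    // dendritic postsynaptic events at synapse-bearing compartments
    for (size_t k = 0; k < ev_comps.size(); ++k) {
      int i = ev_comps[k];
      if (V[i] < P.v_syn_thresh && Vnew[i] >= P.v_syn_thresh) {
        double frac = (P.v_syn_thresh - V[i]) / (Vnew[i] - V[i]);
        double ts = t + frac * P.dt;
        if (ts - last_event[i] >= P.debounce) {
          last_event[i] = ts;
          step_ev.push_back({ ts, i, 0 });
          if (record_events) {
            post_ev_comp.push_back(i + 1);
            post_ev_time.push_back(ts);
          }
        }
      }
    }

    // ---- plasticity ----
    if (P.plas_on) {
      c_avg = c_avg * c_decay + (spike_now ? c_inc : 0.0);
      double cc = std::max(c_avg, P.c_floor);
      A_p = P.freeze_ap ? P.a_p0 : P.a_p0 / cc;
      A_d = P.freeze_ad ? P.a_d0 : P.a_d0 * cc;

      std::sort(step_ev.begin(), step_ev.end(),
                [](const Ev& a, const Ev& b) {
                  return a.t < b.t || (a.t == b.t && a.type < b.type);
                });
      bool learn = (long long)(step + 1) > warmup_steps;
      for (size_t e = 0; e < step_ev.size(); ++e) {
        const Ev& ev = step_ev[e];
        if (ev.type == 0) {
          // postsynaptic event at compartment ev.idx: potentiate pending
          const std::vector<int>& list = comp_syn[ev.idx];
          for (size_t q = 0; q < list.size(); ++q) {
            int s = list[q];
            std::vector<double>& pq = pending[s];
            if (!pq.empty()) {
              if (learn) {
                for (size_t j = 0; j < pq.size(); ++j) {
                  double dta = ev.t - pq[j];
                  if (dta > 0 && dta <= P.lapse) {
                    double wn = w[s] * (1.0 + A_p * std::exp(-dta / P.tau_p));
                    double lo = std::max(w0[s] * (1.0 - P.max_change),
                                         w0[s] * clamp_eps);
                    double hi = w0[s] * (1.0 + P.max_change);
                    w[s] = std::min(hi, std::max(lo, wn));
                  }
                }
              }
              // every pre earlier than this event has now met its first
              // following post (or lapsed); simultaneous pairs stay pending
              std::vector<double> keep;
              for (size_t j = 0; j < pq.size(); ++j)
                if (pq[j] >= ev.t) keep.push_back(pq[j]);
              pq.swap(keep);
            }
          }
          last_post[ev.idx] = ev.t;
        } else {
          // presynaptic spike at synapse ev.idx: depress against the
          // latest earlier postsynaptic event, then await the next one
          int s = ev.idx;
          double lp = last_post[syn_comp[s]];
          if (learn && lp > -1e29 && ev.t - lp > 0) {
            double wn = w[s] * (1.0 - A_d * std::exp(-(ev.t - lp) / P.tau_d));
            double lo = std::max(w0[s] * (1.0 - P.max_change),
                                 w0[s] * clamp_eps);
            double hi = w0[s] * (1.0 + P.max_change);
            w[s] = std::min(hi, std::max(lo, wn));
          }
          std::vector<double>& pq = pending[s];
          std::vector<double> keep;
          for (size_t j = 0; j < pq.size(); ++j)
            if (ev.t - pq[j] <= P.lapse) keep.push_back(pq[j]);
          keep.push_back(ev.t);
          pq.swap(keep);
        }
      }
    }

    std::copy(Vnew.begin(), Vnew.end(), V.begin());

    // recording
    if (nprobe > 0 && (step + 1) % probe_stride == 0 && rec_row < nsamp) {
      Trec[rec_row] = t_next;
      for (int p = 0; p < nprobe; ++p) {
        Vrec(rec_row, p) = V[probes[p]];
        if (record_gsyn) Grec(rec_row, p) = synB[probes[p]] - synA[probes[p]];
      }
      ++rec_row;
    }
    if (nsnap > 0 && snap_row < nsnap &&
        t_next + 1e-9 >= snap_row * snapshot_ms) {
      snap_t[snap_row] = t_next;
      snap_c[snap_row] = c_avg; snap_ap[snap_row] = A_p; snap_ad[snap_row] = A_d;
      for (int s = 0; s < nsyn; ++s) Wsnap(snap_row, s) = w[s];
      ++snap_row;
    }
  }

  (void)last_soma_spike;

  return List::create(
    _["probe_times"] = Trec,
    _["V"] = Vrec,
    _["g_syn"] = Grec,
    _["soma_spikes"] = NumericVector(soma_spikes.begin(), soma_spikes.end()),
    _["post_event_comp"] = IntegerVector(post_ev_comp.begin(), post_ev_comp.end()),
    _["post_event_time"] = NumericVector(post_ev_time.begin(), post_ev_time.end()),
    _["snap_times"] = snap_t, _["snap_c"] = snap_c,
    _["snap_ap"] = snap_ap, _["snap_ad"] = snap_ad,
    _["W"] = Wsnap,
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["V_final"] = NumericVector(V.begin(), V.end()),
    _["c_final"] = c_avg,
    _["n_snap"] = snap_row,
    _["n_rec"] = rec_row
  );
}
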