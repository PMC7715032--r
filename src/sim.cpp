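// Conductance-based reduced-compartment network simulator.
//
// Cells are chains of 8 compartments (one per dendritic layer plus soma)
// with Hodgkin-Huxley style channels: Na, delayed-rectifier K, A-type K,
// M-type K, high-threshold Ca, fast Ca-and-voltage dependent K (BK-like),
// slow Ca-dependent K (AHP), HCN and leak. Voltage is integrated with a
// fixed-step implicit (backward Euler) scheme solving the compartmental
// tridiagonal system each step; gates use exponential Euler with
// tabulated rates. Synapses are peak-normalized double-exponential AMPA
// and triple-exponential NMDA (with magnesium block) conductances driven
// by delayed presynaptic events.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

const double VMIN = -120.0, VMAX = 60.0, DV = 0.05;
const int NT = (int)((VMAX - VMIN) / DV) + 2;

// x / (exp(x) - 1), stable near 0
inline double vtrap(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x / 2.0;
  return x / (std::exp(x) - 1.0);
}

struct GateTable {
  std::vector<double> xinf, edt;  // steady state and exp(-dt/tau)
  bool inst = false;              // instantaneous gate: only xinf used
  void build(double dt, void (*rates)(double, double&, double&),
             bool instantaneous = false) {
    inst = instantaneous;
    xinf.resize(NT);
    edt.resize(NT);
    for (int i = 0; i < NT; ++i) {
      double v = VMIN + i * DV, xi, tau;
      rates(v, xi, tau);
      xinf[i] = xi;
      edt[i] = instantaneous ? 0.0 : std::exp(-dt / tau);
    }
  }
  inline void lookup(double v, double& xi, double& ed) const {
    double p = (v - VMIN) / DV;
    if (p < 0) p = 0;
    if (p > NT - 2) p = NT - 2;
    int i = (int)p;
    double f = p - i;
    xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    ed = edt[i] + f * (edt[i + 1] - edt[i]);
  }
};

// Kinetics (Pinsky-Rinzel / Traub-derived, absolute voltage; the original
// formulations are expressed relative to a -60 mV rest)
inline double shift(double v) { return v + 60.0; }

void na_m_rates(double v, double& xinf, double& tau) {
  double vs = shift(v);
  double am = 0.32 * 4.0 * vtrap((13.1 - vs) / 4.0);
  double bm = 0.28 * 5.0 * vtrap((vs - 40.1) / 5.0);
  xinf = am / (am + bm);
  tau = 1.0;  // treated as instantaneous
}
void na_h_rates(double v, double& xinf, double& tau) {
  double vs = shift(v);
  double ah = 0.128 * std::exp((17.0 - vs) / 18.0);
  double bh = 4.0 / (1.0 + std::exp((40.0 - vs) / 5.0));
  xinf = ah / (ah + bh);
  tau = 1.0 / (ah + bh);
}
void kdr_n_rates(double v, double& xinf, double& tau) {
  double vs = shift(v);
  double an = 0.016 * 5.0 * vtrap((35.1 - vs) / 5.0);
  double bn = 0.25 * std::exp(0.5 - 0.025 * vs);
  xinf = an / (an + bn);
  tau = 1.0 / (an + bn);
}
void ka_a_rates(double v, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp(-(v + 30.0) / 10.0));
  tau = 2.0;
}
void ka_b_rates(double v, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((v + 70.0) / 6.0));
  tau = 50.0;
}
void km_m_rates(double v, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  tau = 1000.0 / (3.3 * (std::exp((v + 35.0) / 20.0) +
                         std::exp(-(v + 35.0) / 20.0)));
}
void ca_s_rates(double v, double& xinf, double& tau) {
  double vs = shift(v);
  double as = 1.6 / (1.0 + std::exp(-0.072 * (vs - 65.0)));
  double bs = 0.02 * 5.0 * vtrap((vs - 51.1) / 5.0);
  xinf = as / (as + bs);
  tau = 1.0 / (as + bs);
}
void kc_c_rates(double v, double& xinf, double& tau) {
  double vs = shift(v);
  double ac, bc;
  if (vs <= 50.0) {
    ac = std::exp((vs - 10.0) / 11.0 - (vs - 6.5) / 27.0) / 18.975;
    bc = 2.0 * std::exp((6.5 - vs) / 27.0) - ac;
  } else {
    ac = 2.0 * std::exp((6.5 - vs) / 27.0);
    bc = 0.0;
  }
  xinf = ac / (ac + bc);
  tau = 1.0 / (ac + bc);
}
void hcn_m_rates(double v, double& xinf, double& tau) {
  xinf = 1.0 / (1.0 + std::exp((v + 80.0) / 7.0));
  tau = 60.0;
}

enum Chan { CH_NA = 0, CH_KDR, CH_KA, CH_KM, CH_CA, CH_KC, CH_KAHP,
            CH_HCN, CH_LEAK, NCHAN };

const double E_NA = 60.0, E_K = -75.0, E_CA = 80.0, E_H = -30.0;

struct Preset {
  std::vector<double> C, g_ax, ca_phi;   // nF, uS, Ca units per nA
  std::vector<double> gbar;              // ncomp x NCHAN, uS
  double e_leak, ca_beta, v_init;
  int soma, ncomp;
  inline double g(int comp, int ch) const { return gbar[comp * NCHAN + ch]; }
};

struct Kin {
  double a_scale, a_e1, a_e2;                    // AMPA unit & decays
  double n_scale, n_e1, n_e2, n_e3, n_w, mg;     // NMDA
};

struct Group { int cell, comp, kin; double A1, A2, N1, N2, N3; };

}  // namespace

// [[Rcpp::export]]
List sim_network_cpp(List presets_in, IntegerVector cell_preset,
                     List edges_in, List kin_in, List ext_in,
                     List inj_in, List opts) {
  const double dt = as<double>(opts["dt"]);
  const double duration = as<double>(opts["duration"]);
  const double thr = as<double>(opts["threshold"]);
  const double lockout = as<double>(opts["lockout"]);
  const int rec_every = as<int>(opts["rec_every"]);
  IntegerVector rec_cells = opts["rec_cells"];
  const int rec_comp = as<int>(opts["rec_comp"]);
  const int n_cells = cell_preset.size();
  const int n_steps = (int)std::ceil(duration / dt);

  // presets
  std::vector<Preset> presets;
  for (int p = 0; p < presets_in.size(); ++p) {
    List pl = presets_in[p];
    Preset ps;
    ps.C = as<std::vector<double> >(pl["C"]);
    ps.g_ax = as<std::vector<double> >(pl["g_ax"]);
    ps.ca_phi = as<std::vector<double> >(pl["ca_phi"]);
    NumericMatrix gb = pl["gbar"];
    ps.ncomp = gb.nrow();
    ps.gbar.resize(ps.ncomp * NCHAN);
    for (int i = 0; i < ps.ncomp; ++i)
      for (int c = 0; c < NCHAN; ++c) ps.gbar[i * NCHAN + c] = gb(i, c);
    ps.e_leak = as<double>(pl["e_leak"]);
    ps.ca_beta = as<double>(pl["ca_beta"]);
    ps.v_init = as<double>(pl["v_init"]);
    ps.soma = as<int>(pl["soma"]);
    presets.push_back(ps);
  }
  int ncomp_max = 0;
  for (size_t p = 0; p < presets.size(); ++p)
    ncomp_max = std::max(ncomp_max, presets[p].ncomp);

  // gate tables (dt-specific)
  GateTable T_nam, T_nah, T_kdr, T_kaa, T_kab, T_km, T_cas, T_kcc, T_hcn;
  T_nam.build(dt, na_m_rates, true);
  T_nah.build(dt, na_h_rates);
  T_kdr.build(dt, kdr_n_rates);
  T_kaa.build(dt, ka_a_rates);
  T_kab.build(dt, ka_b_rates);
  T_km.build(dt, km_m_rates);
  T_cas.build(dt, ca_s_rates);
  T_kcc.build(dt, kc_c_rates);
  T_hcn.build(dt, hcn_m_rates);

  // kinetics
  std::vector<Kin> kins;
  for (int k = 0; k < kin_in.size(); ++k) {
    List kl = kin_in[k];
    Kin kk;
    double a_g = as<double>(kl["ampa_g"]), a_norm = as<double>(kl["ampa_norm"]);
    kk.a_scale = a_norm > 0 ? a_g / a_norm : 0.0;
    kk.a_e1 = std::exp(-dt / as<double>(kl["ampa_tau1"]));
    kk.a_e2 = std::exp(-dt / as<double>(kl["ampa_tau2"]));
    double n_g = as<double>(kl["nmda_g"]), n_norm = as<double>(kl["nmda_norm"]);
    kk.n_scale = n_norm > 0 ? n_g / n_norm : 0.0;
    kk.n_e1 = std::exp(-dt / as<double>(kl["nmda_tau1"]));
    kk.n_e2 = std::exp(-dt / as<double>(kl["nmda_tau2"]));
    kk.n_e3 = std::exp(-dt / as<double>(kl["nmda_tau3"]));
    kk.n_w = as<double>(kl["nmda_w"]);
    kk.mg = as<double>(kl["mg"]);
    kins.push_back(kk);
  }
  const int nkin = std::max((int)kins.size(), 1);

  // edges -> synapse groups keyed by (post, comp, kin)
  IntegerVector e_kind = edges_in["pre_kind"], e_pre = edges_in["pre"],
    e_post = edges_in["post"], e_comp = edges_in["comp"],
    e_kin = edges_in["kin"];
  NumericVector e_delay = edges_in["delay"], e_w = edges_in["weight"];
  const int n_edges = e_post.size();
  std::unordered_map<long long, int> gmap;
  std::vector<Group> groups;
  std::vector<int> edge_group(n_edges);
  double max_delay = 0.0;
  for (int e = 0; e < n_edges; ++e) {
    long long key = ((long long)e_post[e] * ncomp_max + e_comp[e]) * nkin +
      e_kin[e];
    std::unordered_map<long long, int>::iterator it = gmap.find(key);
    int gid;
    if (it == gmap.end()) {
      gid = groups.size();
      gmap[key] = gid;
      Group g;
      g.cell = e_post[e]; g.comp = e_comp[e]; g.kin = e_kin[e];
      g.A1 = g.A2 = g.N1 = g.N2 = g.N3 = 0.0;
      groups.push_back(g);
    } else gid = it->second;
    edge_group[e] = gid;
    if (e_kind[e] == 1 && e_delay[e] > max_delay) max_delay = e_delay[e];
  }
  const int n_groups = groups.size();

  // internal adjacency (cell -> outgoing internal edges)
  std::vector<std::vector<int> > out_edges(n_cells);
  for (int e = 0; e < n_edges; ++e)
    if (e_kind[e] == 1) out_edges[e_pre[e]].push_back(e);

  // external deliveries: (arrival time = spike + delay, edge), presorted
  // by time in R; weight and group come from the edge
  NumericVector xt = ext_in["time"];
  IntegerVector xe = ext_in["edge"];
  const int n_ext = xt.size();
  int ext_ptr = 0;

  // step-calendar ring for internal deliveries
  const int ring = std::max(2, (int)std::ceil(max_delay / dt) + 2);
  std::vector<std::vector<std::pair<int, double> > > calendar(ring);

  // current injections
  IntegerVector ij_cell = inj_in["cell"], ij_comp = inj_in["comp"];
  NumericVector ij_amp = inj_in["amp"], ij_t0 = inj_in["start"],
    ij_t1 = inj_in["end"];

  // state
  std::vector<double> v(n_cells * ncomp_max), vprev(n_cells * ncomp_max);
  std::vector<double> g_h(n_cells * ncomp_max), g_n(n_cells * ncomp_max),
    g_aa(n_cells * ncomp_max), g_ab(n_cells * ncomp_max),
    g_km(n_cells * ncomp_max), g_s(n_cells * ncomp_max),
    g_c(n_cells * ncomp_max), g_q(n_cells * ncomp_max),
    g_hc(n_cells * ncomp_max), ca(n_cells * ncomp_max, 0.0);
  for (int i = 0; i < n_cells; ++i) {
    const Preset& ps = presets[cell_preset[i]];
    for (int c = 0; c < ps.ncomp; ++c) {
      int ix = i * ncomp_max + c;
      double vi = ps.v_init, xi, ed;
      v[ix] = vprev[ix] = vi;
      T_nah.lookup(vi, xi, ed); g_h[ix] = xi;
      T_kdr.lookup(vi, xi, ed); g_n[ix] = xi;
      T_kaa.lookup(vi, xi, ed); g_aa[ix] = xi;
      T_kab.lookup(vi, xi, ed); g_ab[ix] = xi;
      T_km.lookup(vi, xi, ed); g_km[ix] = xi;
      T_cas.lookup(vi, xi, ed); g_s[ix] = xi;
      T_kcc.lookup(vi, xi, ed); g_c[ix] = xi;
      T_hcn.lookup(vi, xi, ed); g_hc[ix] = xi;
    }
  }
  std::vector<double> gsyn_a(n_cells * ncomp_max, 0.0),
    gsyn_n(n_cells * ncomp_max, 0.0);
  std::vector<double> last_spike(n_cells, -1e9);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  const int n_rec = rec_cells.size();
  const int n_rec_steps = n_rec > 0 ? n_steps / rec_every + 1 : 0;
  NumericMatrix vrec(n_rec_steps, n_rec);
  NumericVector trec(n_rec_steps);
  int rec_row = 0;

  std::vector<double> aa(ncomp_max), bb(ncomp_max), cc(ncomp_max),
    dd(ncomp_max), sol(ncomp_max);

  for (int step = 0; step < n_steps; ++step) {
    double t_next = (step + 1) * dt;
    // decay synapse states
    for (int g = 0; g < n_groups; ++g) {
      const Kin& kk = kins[groups[g].kin];
      groups[g].A1 *= kk.a_e1; groups[g].A2 *= kk.a_e2;
      groups[g].N1 *= kk.n_e1; groups[g].N2 *= kk.n_e2;
      groups[g].N3 *= kk.n_e3;
    }
    // deliver external events due this step
    while (ext_ptr < n_ext && xt[ext_ptr] < t_next) {
      int e = xe[ext_ptr];
      Group& g = groups[edge_group[e]];
      double w = e_w[e];
      g.A1 += w; g.A2 += w; g.N1 += w; g.N2 += w; g.N3 += w;
      ++ext_ptr;
    }
    // deliver internal events due this step
    std::vector<std::pair<int, double> >& slot = calendar[step % ring];
    for (size_t q = 0; q < slot.size(); ++q) {
      Group& g = groups[slot[q].first];
      double w = slot[q].second;
      g.A1 += w; g.A2 += w; g.N1 += w; g.N2 += w; g.N3 += w;
    }
    slot.clear();
    // collect synaptic conductances
    std::fill(gsyn_a.begin(), gsyn_a.end(), 0.0);
    std::fill(gsyn_n.begin(), gsyn_n.end(), 0.0);
    for (int g = 0; g < n_groups; ++g) {
      const Group& gr = groups[g];
      const Kin& kk = kins[gr.kin];
      int ix = gr.cell * ncomp_max + gr.comp;
      double ga = kk.a_scale * (gr.A2 - gr.A1);
      if (ga > 0) gsyn_a[ix] += ga;
      double gn = kk.n_scale *
        (kk.n_w * gr.N3 + (1.0 - kk.n_w) * gr.N2 - gr.N1);
      if (gn > 0) {
        double vloc = vprev[ix];
        double block = 1.0 / (1.0 + std::exp(-0.062 * vloc) * kk.mg / 3.57);
        gsyn_n[ix] += gn * block;
      }
    }
    // integrate cells
    for (int i = 0; i < n_cells; ++i) {
      const Preset& ps = presets[cell_preset[i]];
      const int nc = ps.ncomp;
      for (int c = 0; c < nc; ++c) {
        int ix = i * ncomp_max + c;
        double vo = vprev[ix], xi, ed;
        double G = 0.0, D = 0.0;
        double gb;
        if ((gb = ps.g(c, CH_NA)) > 0) {
          T_nam.lookup(vo, xi, ed);
          double minf = xi;
          T_nah.lookup(vo, xi, ed);
          g_h[ix] = xi + (g_h[ix] - xi) * ed;
          double gna = gb * minf * minf * g_h[ix];
          G += gna; D += gna * E_NA;
        }
        if ((gb = ps.g(c, CH_KDR)) > 0) {
          T_kdr.lookup(vo, xi, ed);
          g_n[ix] = xi + (g_n[ix] - xi) * ed;
          double gk = gb * g_n[ix];
          G += gk; D += gk * E_K;
        }
        if ((gb = ps.g(c, CH_KA)) > 0) {
          T_kaa.lookup(vo, xi, ed);
          g_aa[ix] = xi + (g_aa[ix] - xi) * ed;
          T_kab.lookup(vo, xi, ed);
          g_ab[ix] = xi + (g_ab[ix] - xi) * ed;
          double gk = gb * g_aa[ix] * g_ab[ix];
          G += gk; D += gk * E_K;
        }
        if ((gb = ps.g(c, CH_KM)) > 0) {
          T_km.lookup(vo, xi, ed);
          g_km[ix] = xi + (g_km[ix] - xi) * ed;
          double gk = gb * g_km[ix];
          G += gk; D += gk * E_K;
        }
        if ((gb = ps.g(c, CH_CA)) > 0) {
          T_cas.lookup(vo, xi, ed);
          g_s[ix] = xi + (g_s[ix] - xi) * ed;
          double gca = gb * g_s[ix] * g_s[ix];
          G += gca; D += gca * E_CA;
        }
        if ((gb = ps.g(c, CH_KC)) > 0) {
          T_kcc.lookup(vo, xi, ed);
          g_c[ix] = xi + (g_c[ix] - xi) * ed;
          double sat = ca[ix] / 250.0;
          if (sat > 1.0) sat = 1.0;
          double gk = gb * g_c[ix] * sat;
          G += gk; D += gk * E_K;
        }
        if ((gb = ps.g(c, CH_KAHP)) > 0) {
          double aq = 2e-5 * ca[ix];
          if (aq > 0.01) aq = 0.01;
          g_q[ix] += dt * (aq * (1.0 - g_q[ix]) - 0.001 * g_q[ix]);
          double gk = gb * g_q[ix];
          G += gk; D += gk * E_K;
        }
        if ((gb = ps.g(c, CH_HCN)) > 0) {
          T_hcn.lookup(vo, xi, ed);
          g_hc[ix] = xi + (g_hc[ix] - xi) * ed;
          double gh = gb * g_hc[ix];
          G += gh; D += gh * E_H;
        }
        gb = ps.g(c, CH_LEAK);
        G += gb; D += gb * ps.e_leak;
        // synapses (reversal 0 mV)
        G += gsyn_a[ix] + gsyn_n[ix];
        double cap = ps.C[c] / dt;
        bb[c] = cap + G;
        dd[c] = cap * vo + D;
        aa[c] = c > 0 ? -ps.g_ax[c - 1] : 0.0;
        cc[c] = c < nc - 1 ? -ps.g_ax[c] : 0.0;
        if (c > 0) bb[c] += ps.g_ax[c - 1];
        if (c < nc - 1) bb[c] += ps.g_ax[c];
      }
      // injections (rare; linear scan)
      for (int q = 0; q < ij_cell.size(); ++q) {
        if (ij_cell[q] == i && t_next > ij_t0[q] && t_next <= ij_t1[q])
          dd[ij_comp[q]] += ij_amp[q];
      }
      // Thomas solve
      for (int c = 1; c < nc; ++c) {
        double m = aa[c] / bb[c - 1];
        bb[c] -= m * cc[c - 1];
        dd[c] -= m * dd[c - 1];
      }
      sol[nc - 1] = dd[nc - 1] / bb[nc - 1];
      for (int c = nc - 2; c >= 0; --c)
        sol[c] = (dd[c] - cc[c] * sol[c + 1]) / bb[c];
      for (int c = 0; c < nc; ++c) {
        int ix = i * ncomp_max + c;
        v[ix] = sol[c];
        if (!(std::fabs(sol[c]) <= 200.0)) {
          stop("numeric divergence (|v| > 200 mV) in cell %d at t = %f ms",
               i, t_next);
        }
        // calcium pool follows the updated Ca current
        double gb2 = ps.g(c, CH_CA);
        if (gb2 > 0 || ca[ix] > 0) {
          double ica = gb2 * g_s[ix] * g_s[ix] * (sol[c] - E_CA);  // nA
          ca[ix] += dt * (-ps.ca_phi[c] * ica - ps.ca_beta * ca[ix]);
          if (ca[ix] < 0) ca[ix] = 0;
        }
      }
      // spike detection at the soma
      int sx = i * ncomp_max + ps.soma;
      if (vprev[sx] < thr && v[sx] >= thr &&
          t_next - last_spike[i] > lockout) {
        last_spike[i] = t_next;
        sp_t.push_back(t_next);
        sp_id.push_back(i);
        const std::vector<int>& oe = out_edges[i];
        for (size_t q = 0; q < oe.size(); ++q) {
          int e = oe[q];
          int dstep = step + std::max(1, (int)std::lround(e_delay[e] / dt));
          calendar[dstep % ring].push_back(
            std::make_pair(edge_group[e], e_w[e]));
        }
      }
    }
    std::swap(v, vprev);  // vprev now holds the new state
    if (n_rec > 0 && step % rec_every == 0) {
      for (int r = 0; r < n_rec; ++r)
        vrec(rec_row, r) = vprev[rec_cells[r] * ncomp_max + rec_comp];
      trec[rec_row] = t_next;
      ++rec_row;
    }
  }
  List out;
  out["spike_t"] = wrap(sp_t);
  out["spike_id"] = wrap(sp_id);
  if (n_rec > 0) {
    out["v"] = vrec;
    out["t"] = trec;
    out["rec_rows"] = rec_row;
  }
  return out;
}
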