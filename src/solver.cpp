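// Fixed-step implicit integrator for branched compartmental neuron models.
//
// Units used throughout the compiled core:
//   time ms, voltage mV, capacitance nF, conductance uS, current nA,
//   calcium mM.  Channel densities (S/cm2) and synaptic conductances (pS)
//   are converted to absolute uS on the R side before dispatch.
//
// The voltage update is a theta-method (theta = 0.5 Crank-Nicolson by
// default, theta = 1 backward Euler) on the tree-structured cable system,
// solved directly with a Hines elimination.  Gating variables are advanced
// by exact exponential integration against (inf, tau) evaluated at the
// current voltage/calcium (staggered update).  Calcium pools are advanced
// after the voltage solve.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// gating machinery

struct GateTable {               // voltage gate tabulated on a uniform grid
  double v0, dv;
  std::vector<double> inf, tau, fac;   // fac = exp(-dt/tau), filled at setup
  int n;
  inline void eval(double v, double &gi, double &gt) const {
    double x = (v - v0) / dv;
    if (x <= 0) { gi = inf.front(); gt = tau.front(); return; }
    if (x >= n - 1) { gi = inf.back(); gt = tau.back(); return; }
    int k = (int)x; double f = x - k;
    gi = inf[k] + f * (inf[k + 1] - inf[k]);
    gt = tau[k] + f * (tau[k + 1] - tau[k]);
  }
  inline void eval_fac(double v, double &gi, double &gf) const {
    double x = (v - v0) / dv;
    if (x <= 0) { gi = inf.front(); gf = fac.front(); return; }
    if (x >= n - 1) { gi = inf.back(); gf = fac.back(); return; }
    int k = (int)x; double f = x - k;
    gi = inf[k] + f * (inf[k + 1] - inf[k]);
    gf = fac[k] + f * (fac[k + 1] - fac[k]);
  }
};

// gate kinds
enum { GATE_VTABLE = 0, GATE_CA_HILL = 1, GATE_BK = 2 };

struct Gate {
  int kind;
  int power;
  GateTable tab;                  // GATE_VTABLE
  double kd, hill, tau_ca;        // GATE_CA_HILL
  double vh0, kslope, cashift, caref, tau_bk; // GATE_BK
  double state;
  double fac_fixed;               // exp(-dt/tau) for fixed-tau gate kinds
  inline void prime(double dt) {
    if (kind == GATE_VTABLE) {
      tab.fac.resize(tab.n);
      for (int k = 0; k < tab.n; ++k) tab.fac[k] = std::exp(-dt / tab.tau[k]);
    } else {
      fac_fixed = std::exp(-dt / (kind == GATE_CA_HILL ? tau_ca : tau_bk));
    }
  }
  inline void advance(double v, double ca) {
    double gi, gf;
    if (kind == GATE_VTABLE) {
      tab.eval_fac(v, gi, gf);
    } else if (kind == GATE_CA_HILL) {
      double r = std::pow(ca > 1e-12 ? ca / kd : 1e-12 / kd, hill);
      gi = r / (1.0 + r); gf = fac_fixed;
    } else {
      double vh = vh0 - cashift * std::log10((ca > 1e-12 ? ca : 1e-12) / caref);
      gi = 1.0 / (1.0 + std::exp(-(v - vh) / kslope));
      gf = fac_fixed;
    }
    state = gi + (state - gi) * gf;
  }
  inline void target(double v, double ca, double &gi, double &gt) const {
    switch (kind) {
    case GATE_VTABLE: tab.eval(v, gi, gt); return;
    case GATE_CA_HILL: {
      double r = std::pow(std::max(ca, 1e-12) / kd, hill);
      gi = r / (1.0 + r); gt = tau_ca; return;
    }
    default: { // GATE_BK: activation half-voltage shifts with log10([Ca])
      double vh = vh0 - cashift * std::log10(std::max(ca, 1e-12) / caref);
      gi = 1.0 / (1.0 + std::exp(-(v - vh) / kslope));
      gt = tau_bk; return;
    }
    }
  }
};

struct Channel {
  int comp;
  double gbar;                    // uS (absolute, already scaled by area)
  double erev;                    // mV
  bool is_ca;                     // contributes to the calcium pool
  std::vector<Gate> gates;
  inline double open_fraction() const {
    double o = 1.0;
    for (const Gate &g : gates)
      for (int p = 0; p < g.power; ++p) o *= g.state;
    return o;
  }
};

// ---------------------------------------------------------------------------
// calcium pools (one sub-membrane shell per flagged compartment)

struct CaPool {
  int comp;
  double ca, rest;
  double fca;        // nA -> mM/ms conversion for this compartment's shell
  double tau_ex;     // extrusion time constant ms
  double btot, kf, kb, bound;     // single buffer species
};

// ---------------------------------------------------------------------------
// synapses: Tsodyks-Markram presynaptic stage + two-state receptor

enum { REC_EXP = 0, REC_DUALEXP = 1 };

struct Synapse {
  int comp;
  int rec_kind;
  double gmax;                    // uS
  double erev;
  double tau_rise, tau_decay;
  double po, act_max;             // per-release efficacy and saturation cap
  double des_per_rel, tau_des, D, decD;  // use-dependent desensitization
  bool mg_block; double mg, mg_k, mg_gamma;
  // TM parameters/state
  double p, tau_rec, tau_fac;
  double R, u, t_last;
  // receptor state (A fast/rise, B slow/decay); g = gmax*(B - A)/norm
  double A, B, norm, decA, decB;
  // presynaptic drive
  int src;                        // spike-source id, -1 = external events
  double delay;
  std::vector<double> events;    // external (pre-scheduled) event times
  size_t next_ev;
  std::vector<double> pending;   // spike-driven scheduled events
  size_t next_pending;

  void init_norm() {
    if (rec_kind == REC_EXP || tau_rise <= 0) { norm = 1.0; return; }
    double tp = (tau_rise * tau_decay) / (tau_decay - tau_rise) *
                std::log(tau_decay / tau_rise);
    norm = std::exp(-tp / tau_decay) - std::exp(-tp / tau_rise);
  }
  // exact TM update at a presynaptic event; returns released fraction
  inline double tm_release(double t) {
    if (t_last >= 0) {
      double dt = t - t_last;
      R = 1.0 - (1.0 - R) * ((tau_rec > 0) ? std::exp(-dt / tau_rec) : 0.0);
      u = (tau_fac > 0) ? u * std::exp(-dt / tau_fac) : 0.0;
    }
    u += p * (1.0 - u);
    double rel = u * R;
    R -= rel;
    t_last = t;
    return rel;
  }
  inline void deliver(double t) {
    double rel = tm_release(t) * po;
    double open = rel * (1.0 - D);
    if (rec_kind == REC_EXP) { B += open; }
    else { A += open / norm; B += open / norm; }
    D += des_per_rel * rel * (1.0 - D);
    if (D > 1) D = 1;
  }
  inline double conductance(double v) const {
    // receptor activation saturates at act_max (low-open-probability
    // receptors such as NR2B never open their full complement)
    double act = (rec_kind == REC_EXP) ? B : B - A;
    if (act < 0) act = 0;
    if (act > act_max) act = act_max;
    double g = gmax * act;
    if (mg_block)
      g /= (1.0 + mg / mg_k * std::exp(-mg_gamma * v));
    return g;
  }
};

// ---------------------------------------------------------------------------

struct Stim { int comp; double t0, t1, amp; };   // amp in nA

struct SpikeSource { int comp; double thresh, refrac, last; std::vector<double> times; bool above; };

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List model, List protocol, List recording) {
  // ---- unpack compartments -------------------------------------------------
  NumericVector cap = model["cap_nF"];
  IntegerVector parent = model["parent"];        // 0-based, -1 root
  NumericVector gax = model["g_axial_uS"];       // coupling to parent
  NumericVector v_init = model["v_init"];
  const int n = cap.size();

  // ---- channels ------------------------------------------------------------
  List chl = model["channels"];
  std::vector<Channel> channels;
  channels.reserve(chl.size());
  for (int i = 0; i < chl.size(); ++i) {
    List c = chl[i];
    Channel ch;
    ch.comp = as<int>(c["comp"]);
    ch.gbar = as<double>(c["g_uS"]);
    ch.erev = as<double>(c["erev"]);
    ch.is_ca = as<bool>(c["is_ca"]);
    List gl = c["gates"];
    for (int j = 0; j < gl.size(); ++j) {
      List g = gl[j];
      Gate gt;
      gt.kind = as<int>(g["kind"]);
      gt.power = as<int>(g["power"]);
      if (gt.kind == GATE_VTABLE) {
        gt.tab.v0 = as<double>(g["v0"]);
        gt.tab.dv = as<double>(g["dv"]);
        NumericVector gi = g["inf"], gtau = g["tau"];
        gt.tab.inf.assign(gi.begin(), gi.end());
        gt.tab.tau.assign(gtau.begin(), gtau.end());
        gt.tab.n = gi.size();
      } else if (gt.kind == GATE_CA_HILL) {
        gt.kd = as<double>(g["kd"]); gt.hill = as<double>(g["hill"]);
        gt.tau_ca = as<double>(g["tau"]);
      } else {
        gt.vh0 = as<double>(g["vh0"]); gt.kslope = as<double>(g["k"]);
        gt.cashift = as<double>(g["cashift"]); gt.caref = as<double>(g["caref"]);
        gt.tau_bk = as<double>(g["tau"]);
      }
      ch.gates.push_back(gt);
    }
    channels.push_back(ch);
  }

  // ---- calcium pools -------------------------------------------------------
  List pl = model["ca_pools"];
  std::vector<CaPool> pools;
  std::vector<int> pool_of(n, -1);
  for (int i = 0; i < pl.size(); ++i) {
    List p = pl[i];
    CaPool cp;
    cp.comp = as<int>(p["comp"]);
    cp.rest = as<double>(p["rest"]);
    cp.fca = as<double>(p["fca"]);
    cp.tau_ex = as<double>(p["tau_ex"]);
    cp.btot = as<double>(p["btot"]);
    cp.kf = as<double>(p["kf"]);
    cp.kb = as<double>(p["kb"]);
    cp.ca = cp.rest;
    cp.bound = (cp.kb > 0) ? cp.btot * cp.kf * cp.ca / (cp.kf * cp.ca + cp.kb) : 0.0;
    pool_of[cp.comp] = i;
    pools.push_back(cp);
  }

  // ---- synapses ------------------------------------------------------------
  List syl = model["synapses"];
  std::vector<Synapse> syns;
  for (int i = 0; i < syl.size(); ++i) {
    List s = syl[i];
    Synapse sy;
    sy.comp = as<int>(s["comp"]);
    sy.rec_kind = as<int>(s["rec_kind"]);
    sy.gmax = as<double>(s["g_uS"]);
    sy.erev = as<double>(s["erev"]);
    sy.tau_rise = as<double>(s["tau_rise"]);
    sy.tau_decay = as<double>(s["tau_decay"]);
    sy.po = s.containsElementNamed("po") ? as<double>(s["po"]) : 1.0;
    sy.act_max = s.containsElementNamed("act_max") ? as<double>(s["act_max"]) : 1.0;
    sy.des_per_rel = s.containsElementNamed("des_per_rel") ? as<double>(s["des_per_rel"]) : 0.0;
    sy.tau_des = s.containsElementNamed("tau_des") ? as<double>(s["tau_des"]) : 50.0;
    sy.D = 0.0;
    sy.mg_block = as<bool>(s["mg_block"]);
    sy.mg = as<double>(s["mg"]);
    sy.mg_k = as<double>(s["mg_k"]);
    sy.mg_gamma = as<double>(s["mg_gamma"]);
    sy.p = as<double>(s["p"]);
    sy.tau_rec = as<double>(s["tau_rec"]);
    sy.tau_fac = as<double>(s["tau_fac"]);
    sy.R = 1.0; sy.u = 0.0; sy.t_last = -1.0;
    sy.A = 0.0; sy.B = 0.0;
    sy.src = as<int>(s["src"]);
    sy.delay = as<double>(s["delay"]);
    NumericVector ev = s["events"];
    sy.events.assign(ev.begin(), ev.end());
    std::sort(sy.events.begin(), sy.events.end());
    sy.next_ev = 0; sy.next_pending = 0;
    sy.init_norm();
    syns.push_back(sy);
  }

  // ---- protocol ------------------------------------------------------------
  double dt = as<double>(protocol["dt"]);
  double t_end = as<double>(protocol["t_end"]);
  double theta = protocol.containsElementNamed("theta") ? as<double>(protocol["theta"]) : 0.5;
  List stl = protocol["stim"];
  std::vector<Stim> stims;
  for (int i = 0; i < stl.size(); ++i) {
    List s = stl[i];
    stims.push_back({as<int>(s["comp"]), as<double>(s["t0"]),
                     as<double>(s["t1"]), as<double>(s["amp"])});
  }
  int clamp_comp = -1; double clamp_v = 0, clamp_t0 = 0, clamp_t1 = 0;
  if (protocol.containsElementNamed("clamp") && !Rf_isNull(protocol["clamp"])) {
    List cl = protocol["clamp"];
    clamp_comp = as<int>(cl["comp"]);
    clamp_v = as<double>(cl["v"]);
    clamp_t0 = as<double>(cl["t0"]);
    clamp_t1 = as<double>(cl["t1"]);
  }

  // ---- recordings ----------------------------------------------------------
  IntegerVector rec_v = recording["v_comps"];
  IntegerVector rec_ca = recording["ca_comps"];
  int stride = recording.containsElementNamed("stride") ? as<int>(recording["stride"]) : 1;
  IntegerVector spike_comps = recording["spike_comps"];
  double spk_thresh = as<double>(recording["spike_threshold"]);
  double spk_refrac = as<double>(recording["spike_refractory"]);

  std::vector<SpikeSource> sources;
  for (int i = 0; i < spike_comps.size(); ++i)
    sources.push_back({spike_comps[i], spk_thresh, spk_refrac, -1e9, {}, false});
  // map source id -> synapses it drives
  std::vector<std::vector<int>> fanout(sources.size());
  for (size_t i = 0; i < syns.size(); ++i)
    if (syns[i].src >= 0) fanout[syns[i].src].push_back((int)i);

  NumericVector area = model["area_cm2"];

  std::vector<std::vector<int>> children(n);
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0) children[parent[i]].push_back(i);

  for (auto &ch : channels)
    for (auto &g : ch.gates) g.prime(dt / 2);   // Strang-split half steps

  for (auto &sy : syns) {
    sy.decB = std::exp(-dt / sy.tau_decay);
    sy.decA = (sy.rec_kind == REC_DUALEXP) ? std::exp(-dt / sy.tau_rise) : 1.0;
    sy.decD = std::exp(-dt / sy.tau_des);
  }

  const long nstep = (long)std::llround(t_end / dt);
  const long nrec = nstep / stride + 1;

  NumericMatrix Vrec(nrec, rec_v.size());
  NumericMatrix Carec(nrec, rec_ca.size());
  NumericVector Iclamp(clamp_comp >= 0 ? nrec : 0);
  NumericVector tvec(nrec);

  // ---- state ---------------------------------------------------------------
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> ca_of_comp(n, 0.0);
  for (auto &p : pools) ca_of_comp[p.comp] = p.ca;
  for (auto &ch : channels)
    for (auto &g : ch.gates) {
      double gi, gt;
      g.target(V[ch.comp], ca_of_comp[ch.comp], gi, gt);
      g.state = gi;
    }

  // Hines ordering: compartments are required (on the R side) to be ordered
  // so that parent(i) < i; elimination proceeds from the last compartment up.
  std::vector<double> Ad(n), Ao(n), b(n);   // diagonal, off-diag to parent, rhs
  std::vector<double> Ad0(n), Ao0(n), b0(n);
  double max_resid = 0.0;

  long irec = 0;
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;

    // record state
    if (step % stride == 0) {
      tvec[irec] = t;
      for (int j = 0; j < rec_v.size(); ++j) Vrec(irec, j) = V[rec_v[j]];
      for (int j = 0; j < rec_ca.size(); ++j) Carec(irec, j) = ca_of_comp[rec_ca[j]];
      if (clamp_comp >= 0) {
        // electrode current = total membrane + axial current at clamped node
        double ie = 0.0;
        for (auto &ch : channels)
          if (ch.comp == clamp_comp)
            ie += ch.gbar * ch.open_fraction() * (V[clamp_comp] - ch.erev);
        for (auto &sy : syns)
          if (sy.comp == clamp_comp)
            ie += sy.conductance(V[clamp_comp]) * (V[clamp_comp] - sy.erev);
        for (int i = 0; i < n; ++i) {
          if (parent[i] == clamp_comp) ie += gax[i] * (V[clamp_comp] - V[i]);
          if (i == clamp_comp && parent[i] >= 0)
            ie += gax[i] * (V[i] - V[parent[i]]);
        }
        for (auto &s : stims)
          if (s.comp == clamp_comp && t >= s.t0 && t < s.t1) ie -= s.amp;
        Iclamp[irec] = ie * 1e3;           // uS*mV = nA -> pA
      }
      ++irec;
    }
    if (step == nstep) break;

    // deliver presynaptic events that fall in (t, t+dt]
    for (auto &sy : syns) {
      while (sy.next_ev < sy.events.size() && sy.events[sy.next_ev] <= t + dt) {
        if (sy.events[sy.next_ev] > t - 1e-9) sy.deliver(sy.events[sy.next_ev]);
        ++sy.next_ev;
      }
      while (sy.next_pending < sy.pending.size() &&
             sy.pending[sy.next_pending] <= t + dt) {
        sy.deliver(sy.pending[sy.next_pending]);
        ++sy.next_pending;
      }
    }

    // gate update: first half-step at the pre-solve state
    for (auto &ch : channels) {
      double v = V[ch.comp], cc = ca_of_comp[ch.comp];
      for (auto &g : ch.gates) g.advance(v, cc);
    }

    // receptor state decay over dt
    for (auto &sy : syns) {
      sy.B *= sy.decB;
      if (sy.rec_kind == REC_DUALEXP) sy.A *= sy.decA;
      sy.D *= sy.decD;
    }

    // assemble theta-method system
    for (int i = 0; i < n; ++i) {
      Ad[i] = cap[i] / dt;
      Ao[i] = 0.0;
      b[i] = cap[i] / dt * V[i];
    }
    for (auto &ch : channels) {
      double g = ch.gbar * ch.open_fraction();
      Ad[ch.comp] += theta * g;
      b[ch.comp] += g * (ch.erev - (1.0 - theta) * V[ch.comp]);
    }
    for (auto &sy : syns) {
      double g = sy.conductance(V[sy.comp]);
      Ad[sy.comp] += theta * g;
      b[sy.comp] += g * (sy.erev - (1.0 - theta) * V[sy.comp]);
    }
    for (int i = 0; i < n; ++i) {
      int pa = parent[i];
      if (pa < 0) continue;
      double g = gax[i];
      Ad[i] += theta * g;
      Ad[pa] += theta * g;
      Ao[i] = -theta * g;
      double ax = g * (V[i] - V[pa]);
      b[i] -= (1.0 - theta) * ax;
      b[pa] += (1.0 - theta) * ax;
    }
    for (auto &s : stims)
      if (t >= s.t0 && t < s.t1) b[s.comp] += s.amp;

    bool clamped = clamp_comp >= 0 && t >= clamp_t0 && t < clamp_t1;
    if (clamped) {
      // pin the clamped node: identity row, remove couplings into it
      for (int i = 0; i < n; ++i) {
        int pa = parent[i];
        if (i == clamp_comp && pa >= 0) {
          b[pa] -= Ao[i] * clamp_v;   // child row i eliminated below anyway
        }
      }
      Ad[clamp_comp] = 1.0; b[clamp_comp] = clamp_v;
      // zero couplings touching the clamped row
      for (int i = 0; i < n; ++i) {
        if (parent[i] == clamp_comp && i != clamp_comp) {
          b[i] -= Ao[i] * clamp_v;
          Ao[i] = 0.0;
        }
        if (i == clamp_comp) Ao[i] = 0.0;
      }
    }

    bool check_resid = (step % 16 == 0);
    if (check_resid) { Ad0 = Ad; Ao0 = Ao; b0 = b; }

    // Hines solve (children have larger indices than parents)
    for (int i = n - 1; i >= 0; --i) {
      int pa = parent[i];
      if (pa < 0) continue;
      double f = Ao[i] / Ad[i];
      Ad[pa] -= f * Ao[i];
      b[pa] -= f * b[i];
    }
    for (int i = 0; i < n; ++i) {
      int pa = parent[i];
      if (pa < 0) V[i] = b[i] / Ad[i];
      else V[i] = (b[i] - Ao[i] * V[pa]) / Ad[i];
      if (!std::isfinite(V[i]))
        stop("integration failure (non-finite voltage) at t = %f ms", t);
    }

    // charge-balance residual of the accepted step (density units, mA/cm2)
    if (check_resid)
    for (int i = 0; i < n; ++i) {
      double r = Ad0[i] * V[i] - b0[i];
      if (parent[i] >= 0) r += Ao0[i] * V[parent[i]];
      for (int c : children[i]) r += Ao0[c] * V[c];
      double rd = std::fabs(r) * 1e-6 / area[i];
      if (rd > max_resid) max_resid = rd;
    }

    // gate update: second half-step at the post-solve voltage
    for (auto &ch : channels) {
      double v = V[ch.comp], cc = ca_of_comp[ch.comp];
      for (auto &g : ch.gates) g.advance(v, cc);
    }

    // calcium pools: influx from Ca channels at updated V, buffer, extrusion
    for (auto &p : pools) {
      double ica = 0.0;
      for (auto &ch : channels)
        if (ch.is_ca && ch.comp == p.comp)
          ica += ch.gbar * ch.open_fraction() * (V[p.comp] - ch.erev);
      double influx = -ica * p.fca;          // nA -> mM/ms (inward is negative)
      if (influx < 0) influx = 0;
      double bfree = p.btot - p.bound;
      double dbound = (p.kf * p.ca * bfree - p.kb * p.bound) * dt;
      p.bound += dbound;
      if (p.bound < 0) { dbound -= p.bound; p.bound = 0; }
      if (p.bound > p.btot) { dbound -= (p.bound - p.btot); p.bound = p.btot; }
      p.ca += (influx - (p.ca - p.rest) / p.tau_ex) * dt - dbound;
      if (p.ca < 1e-12) p.ca = 1e-12;
      ca_of_comp[p.comp] = p.ca;
    }

    // spike detection at recorded sources; drive spike-triggered synapses
    for (size_t si = 0; si < sources.size(); ++si) {
      SpikeSource &ss = sources[si];
      double v = V[ss.comp];
      if (!ss.above && v >= ss.thresh) {
        ss.above = true;
        if (t + dt - ss.last >= ss.refrac) {
          double ts = t + dt;
          ss.times.push_back(ts);
          ss.last = ts;
          for (int k : fanout[si]) syns[k].pending.push_back(ts + syns[k].delay);
        }
      } else if (ss.above && v < ss.thresh) ss.above = false;
    }
  }

  List spikes(sources.size());
  for (size_t i = 0; i < sources.size(); ++i)
    spikes[i] = NumericVector(sources[i].times.begin(), sources[i].times.end());

  return List::create(
    _["t"] = tvec,
    _["v"] = Vrec,
    _["ca"] = Carec,
    _["i_clamp"] = (clamp_comp >= 0) ? (SEXP)Iclamp : R_NilValue,
    _["spikes"] = spikes,
    _["max_residual"] = max_resid);
}
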