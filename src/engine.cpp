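// Clock-driven integrate-and-fire network engine.
//
// Internal unit system (consistent, no conversions inside the loop):
//   voltage mV, conductance nS, capacitance pF, time ms, current pA.
//   (pF/nS = ms and pA/nS = mV, so the membrane equation needs no unit
//   constants.)
//
// The R layer flattens a network specification into plain vectors (see
// build_engine_input() in R/network.R) and this translation stays dumb on
// purpose: all validation happens R-side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift128+ with splitmix64 seeding; deterministic across platforms,
// independent of R's RNG (simulation seeds are explicit arguments).
// Gaussian draws use the Marsaglia-Tsang ziggurat (tables built once),
// which is several times faster than Box-Muller in the noise-heavy
// synfire simulations.
struct Xorshift {
  uint64_t s0, s1;
  double zig_x[257];
  double zig_r[256];
  explicit Xorshift(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9E3779B97F4A7C15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
    // ziggurat tables (256 layers, tail at x = 3.6541528853610088)
    const double R = 3.6541528853610088;
    const double V = 0.00492867323399;
    double f = std::exp(-0.5 * R * R);
    zig_x[0] = V / f;
    zig_x[1] = R;
    zig_x[256] = 0.0;
    for (int i = 2; i < 256; ++i)
      zig_x[i] = std::sqrt(-2.0 * std::log(V / zig_x[i - 1] +
                                           std::exp(-0.5 * zig_x[i - 1] *
                                                    zig_x[i - 1])));
    for (int i = 0; i < 256; ++i) zig_r[i] = zig_x[i + 1] / zig_x[i];
  }
  uint64_t next_u64() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {  // in (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    for (;;) {
      uint64_t u = next_u64();
      int i = (int)(u & 255);
      int64_t j = (int64_t)(u >> 8) - (int64_t)(1ULL << 55);
      double x = (double)j * (1.0 / 36028797018963968.0) * zig_x[i];
      if (std::fabs(x) < zig_x[i + 1]) return x;
      if (i == 0) {  // tail
        const double R = 3.6541528853610088;
        double xx, yy;
        do {
          xx = -std::log(unif()) / R;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return x > 0 ? R + xx : -(R + xx);
      }
      double fx = std::exp(-0.5 * x * x);
      double f0 = std::exp(-0.5 * zig_x[i] * zig_x[i]);
      double f1 = std::exp(-0.5 * zig_x[i + 1] * zig_x[i + 1]);
      if (unif() * (f0 - f1) < fx - f1) return x;
    }
  }
};

struct Projection {
  int src0 = 0, n_src = 0;
  std::vector<int> row_ptr;   // n_src + 1
  std::vector<int> tgt;       // per edge, global neuron index
  std::vector<double> w;      // per edge, nS
  int receptor = 0;           // 0 AMPA, 1 NMDA, 2 GABA
  int delay_steps = 0;
  // short-term depression (per presynaptic neuron)
  double pv = 0.0, tau_D = 1.0;
  std::vector<double> D;
  std::vector<double> D_last; // time (ms) of last presynaptic spike
  // plasticity
  bool plastic = false;
  double A_plus = 0.0, A_minus = 0.0, tau_A = 20.0, w_min = 0.0, w_max = 0.0;
  int tgt0 = 0, n_tgt = 0;
  std::vector<int> in_ptr;    // n_tgt + 1 (CSC over targets)
  std::vector<int> in_edge;   // edge index per CSC entry
  std::vector<int> in_src;    // local source index per CSC entry
  std::vector<double> Apre, Apre_t;   // per source neuron trace + last time
  std::vector<double> Apost, Apost_t; // per target neuron trace + last time
  // weight-trajectory recording
  std::vector<int> w_group;   // per edge, group id (or empty)
  int n_groups = 0;
};

struct Pending { int proj; int src_local; double factor; };

inline double decay_trace(double val, double &t_last, double t_now, double tau) {
  if (t_now > t_last) {
    val *= std::exp(-(t_now - t_last) / tau);
    t_last = t_now;
  }
  return val;
}

}  // namespace

// [[Rcpp::export(name = ".simulate_engine")]]
List simulate_engine(List eng) {
  const double dt = as<double>(eng["dt"]);
  const int n_steps = as<int>(eng["n_steps"]);
  const uint64_t seed = (uint64_t)as<double>(eng["seed"]);

  List nr = eng["neuron"];
  const NumericVector Cm = nr["Cm"], gL = nr["gL"], EL = nr["EL"],
                      Vth = nr["Vth"], Vreset = nr["Vreset"],
                      noise_sd = nr["noise_sd"], V0 = nr["V0"];
  const IntegerVector tref_steps = nr["tref_steps"];
  const int N = Cm.size();

  List kin = eng["kin"];
  const double tau_a = as<double>(kin["tau_ampa"]);
  const double tau_n = as<double>(kin["tau_nmda"]);
  const double tau_g = as<double>(kin["tau_gaba"]);
  const double E_exc = as<double>(kin["E_exc"]);
  const double E_inh = as<double>(kin["E_inh"]);
  const bool mg_block = as<bool>(kin["mg_block"]);
  const double mg_mM = as<double>(kin["mg_mM"]);
  const double dec_a = std::exp(-dt / tau_a);
  const double dec_n = std::exp(-dt / tau_n);
  const double dec_g = std::exp(-dt / tau_g);

  // square-pulse current schedule as step-indexed diffs, sorted by step
  List pl = eng["pulses"];
  const IntegerVector p_step = pl["step"], p_neuron = pl["neuron"];
  const NumericVector p_damp = pl["d_amp"];
  const int n_pulse_ev = p_step.size();

  // projections
  List projs_in = eng["projections"];
  const int n_proj = projs_in.size();
  std::vector<Projection> P((size_t)n_proj);
  int max_delay = 0;
  for (int p = 0; p < n_proj; ++p) {
    List pi = projs_in[p];
    Projection &pr = P[p];
    pr.src0 = as<int>(pi["src0"]);
    pr.n_src = as<int>(pi["n_src"]);
    pr.row_ptr = as<std::vector<int>>(pi["row_ptr"]);
    pr.tgt = as<std::vector<int>>(pi["tgt"]);
    pr.w = as<std::vector<double>>(pi["w"]);
    pr.receptor = as<int>(pi["receptor"]);
    pr.delay_steps = as<int>(pi["delay_steps"]);
    pr.pv = as<double>(pi["pv"]);
    pr.tau_D = as<double>(pi["tau_D"]);
    if (pr.pv > 0) {
      pr.D.assign(pr.n_src, 1.0);
      pr.D_last.assign(pr.n_src, -1e30);
    }
    pr.plastic = as<bool>(pi["plastic"]);
    if (pr.plastic) {
      pr.A_plus = as<double>(pi["A_plus"]);
      pr.A_minus = as<double>(pi["A_minus"]);
      pr.tau_A = as<double>(pi["tau_A"]);
      pr.w_min = as<double>(pi["w_min"]);
      pr.w_max = as<double>(pi["w_max"]);
      pr.tgt0 = as<int>(pi["tgt0"]);
      pr.n_tgt = as<int>(pi["n_tgt"]);
      pr.in_ptr = as<std::vector<int>>(pi["in_ptr"]);
      pr.in_edge = as<std::vector<int>>(pi["in_edge"]);
      pr.in_src = as<std::vector<int>>(pi["in_src"]);
      pr.Apre.assign(pr.n_src, 0.0);
      pr.Apre_t.assign(pr.n_src, 0.0);
      pr.Apost.assign(pr.n_tgt, 0.0);
      pr.Apost_t.assign(pr.n_tgt, 0.0);
    }
    if (pi.containsElementNamed("w_group")) {
      pr.w_group = as<std::vector<int>>(pi["w_group"]);
      pr.n_groups = as<int>(pi["n_groups"]);
    }
    if (pr.delay_steps > max_delay) max_delay = pr.delay_steps;
  }

  // neuron -> projections where it is a source / a plastic target
  std::vector<std::vector<int>> out_projs((size_t)N), post_projs((size_t)N);
  for (int p = 0; p < n_proj; ++p) {
    for (int i = 0; i < P[p].n_src; ++i) out_projs[P[p].src0 + i].push_back(p);
    if (P[p].plastic)
      for (int i = 0; i < P[p].n_tgt; ++i) post_projs[P[p].tgt0 + i].push_back(p);
  }

  // delivery ring buffer: events pushed at spike step s act at step s+1+delay
  const int ring_n = max_delay + 2;
  std::vector<std::vector<Pending>> ring((size_t)ring_n);

  // voltage recording
  IntegerVector rec_v_idx = eng["record_v"];
  const int n_rec_v = rec_v_idx.size();
  NumericMatrix v_trace(n_rec_v > 0 ? n_steps + 1 : 0, n_rec_v);

  // weight recording
  const int w_every = as<int>(eng["w_every_steps"]);
  int total_groups = 0;
  for (int p = 0; p < n_proj; ++p) total_groups += P[p].n_groups;
  const int n_snap = (w_every > 0 && total_groups > 0) ? n_steps / w_every + 1 : 0;
  NumericMatrix w_means(n_snap, total_groups);
  NumericVector w_times(n_snap);

  // state
  std::vector<double> V(Cm.begin(), Cm.end());
  for (int i = 0; i < N; ++i) V[i] = V0[i];
  std::vector<double> gA((size_t)N, 0.0), gN((size_t)N, 0.0), gG((size_t)N, 0.0);
  std::vector<double> leak_decay((size_t)N);
  for (int i = 0; i < N; ++i) leak_decay[i] = std::exp(-dt * gL[i] / Cm[i]);
  std::vector<double> I_ext((size_t)N, 0.0);
  std::vector<int> refr((size_t)N, 0);
  Xorshift rng(seed);

  std::vector<int> spike_step, spike_neuron;
  spike_step.reserve(1 << 16);
  spike_neuron.reserve(1 << 16);
  std::vector<int> step_spikes;  // spiking neurons of the current step

  // per-500-ms total spike counts (runaway diagnostics)
  const int bin_steps = std::max(1, (int)std::lround(500.0 / dt));
  std::vector<double> bin_counts((size_t)(n_steps / bin_steps + 1), 0.0);

  int pulse_ptr = 0, snap_i = 0;
  auto take_snapshot = [&](double t_now) {
    if (snap_i >= n_snap) return;
    int col0 = 0;
    for (int p = 0; p < n_proj; ++p) {
      if (P[p].n_groups == 0) continue;
      std::vector<double> acc((size_t)P[p].n_groups, 0.0);
      std::vector<int> cnt((size_t)P[p].n_groups, 0);
      for (size_t e = 0; e < P[p].w.size(); ++e) {
        acc[P[p].w_group[e]] += P[p].w[e];
        cnt[P[p].w_group[e]] += 1;
      }
      for (int g = 0; g < P[p].n_groups; ++g)
        w_means(snap_i, col0 + g) = cnt[g] > 0 ? acc[g] / cnt[g] : NA_REAL;
      col0 += P[p].n_groups;
    }
    w_times[snap_i] = t_now;
    ++snap_i;
  };

  if (n_rec_v > 0)
    for (int k = 0; k < n_rec_v; ++k) v_trace(0, k) = V[rec_v_idx[k]];
  if (n_snap > 0) take_snapshot(0.0);

  for (int s = 0; s < n_steps; ++s) {
    const double t_next = (s + 1) * dt;

    // 1. pulse-schedule diffs taking effect at this step
    while (pulse_ptr < n_pulse_ev && p_step[pulse_ptr] == s) {
      I_ext[p_neuron[pulse_ptr]] += p_damp[pulse_ptr];
      ++pulse_ptr;
    }

    // 2. deliver due synaptic events (conductance jumps at start of step)
    std::vector<Pending> &due = ring[s % ring_n];
    for (const Pending &ev : due) {
      const Projection &pr = P[ev.proj];
      const int e0 = pr.row_ptr[ev.src_local], e1 = pr.row_ptr[ev.src_local + 1];
      switch (pr.receptor) {
        case 0: for (int e = e0; e < e1; ++e) gA[pr.tgt[e]] += pr.w[e] * ev.factor; break;
        case 1: for (int e = e0; e < e1; ++e) gN[pr.tgt[e]] += pr.w[e] * ev.factor; break;
        default: for (int e = e0; e < e1; ++e) gG[pr.tgt[e]] += pr.w[e] * ev.factor; break;
      }
    }
    due.clear();

    // 3. integrate membrane (exponential Euler, conductances frozen over
    // dt). Fast path: with no synaptic conductance the decay factor
    // exp(-dt gL / Cm) is a per-neuron constant (precomputed).
    step_spikes.clear();
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { --refr[i]; V[i] = Vreset[i]; continue; }
      double I = I_ext[i];
      if (noise_sd[i] > 0) I += noise_sd[i] * rng.normal();
      const double gsyn = gA[i] + gN[i] + gG[i];
      double Vinf, decay;
      if (gsyn < 1e-10) {
        Vinf = EL[i] + I / gL[i];
        decay = leak_decay[i];
      } else {
        double gn_eff = gN[i];
        if (mg_block && gn_eff > 1e-12)
          gn_eff /= 1.0 + mg_mM / 3.57 * std::exp(-0.062 * V[i]);
        const double gtot = gL[i] + gA[i] + gn_eff + gG[i];
        Vinf = (gL[i] * EL[i] + (gA[i] + gn_eff) * E_exc + gG[i] * E_inh +
                I) / gtot;
        decay = std::exp(-dt * gtot / Cm[i]);
      }
      V[i] = Vinf + (V[i] - Vinf) * decay;
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential for neuron %d at t = %.3f ms", i + 1, t_next);
      if (V[i] >= Vth[i]) {
        step_spikes.push_back(i);
        V[i] = Vreset[i];
        refr[i] = tref_steps[i];
      }
    }

    // 4. spike bookkeeping: record, queue deliveries, depression, STDP
    if (!step_spikes.empty()) {
      bin_counts[s / bin_steps] += (double)step_spikes.size();
      for (int i : step_spikes) {
        spike_step.push_back(s + 1);
        spike_neuron.push_back(i);
        for (int p : out_projs[i]) {
          Projection &pr = P[p];
          const int loc = i - pr.src0;
          double factor = 1.0;
          if (pr.pv > 0) {
            double D = pr.D[loc];
            if (pr.D_last[loc] > -1e29)
              D = 1.0 - (1.0 - D) * std::exp(-(t_next - pr.D_last[loc]) / pr.tau_D);
            factor = D;                    // efficacy uses D just before release
            pr.D[loc] = D * (1.0 - pr.pv); // multiplicative decrement
            pr.D_last[loc] = t_next;
          }
          ring[(s + 1 + pr.delay_steps) % ring_n].push_back({p, loc, factor});
        }
      }
      // STDP: all presynaptic roles first, then all postsynaptic roles, so
      // that simultaneous pre/post spikes resolve as pre-before-post.
      for (int i : step_spikes) {
        for (int p : out_projs[i]) {
          Projection &pr = P[p];
          if (!pr.plastic) continue;
          const int loc = i - pr.src0;
          const int e0 = pr.row_ptr[loc], e1 = pr.row_ptr[loc + 1];
          for (int e = e0; e < e1; ++e) {
            const int tl = pr.tgt[e] - pr.tgt0;
            pr.Apost[tl] = decay_trace(pr.Apost[tl], pr.Apost_t[tl], t_next, pr.tau_A);
            double w = pr.w[e] + pr.Apost[tl];
            pr.w[e] = w < pr.w_min ? pr.w_min : (w > pr.w_max ? pr.w_max : w);
          }
          pr.Apre[loc] = decay_trace(pr.Apre[loc], pr.Apre_t[loc], t_next, pr.tau_A);
          pr.Apre[loc] += pr.A_plus;
        }
      }
      for (int i : step_spikes) {
        for (int p : post_projs[i]) {
          Projection &pr = P[p];
          const int tl = i - pr.tgt0;
          const int c0 = pr.in_ptr[tl], c1 = pr.in_ptr[tl + 1];
          for (int c = c0; c < c1; ++c) {
            const int sl = pr.in_src[c];
            pr.Apre[sl] = decay_trace(pr.Apre[sl], pr.Apre_t[sl], t_next, pr.tau_A);
            const int e = pr.in_edge[c];
            double w = pr.w[e] + pr.Apre[sl];
            pr.w[e] = w < pr.w_min ? pr.w_min : (w > pr.w_max ? pr.w_max : w);
          }
          pr.Apost[tl] = decay_trace(pr.Apost[tl], pr.Apost_t[tl], t_next, pr.tau_A);
          pr.Apost[tl] += pr.A_minus;
        }
      }
    }

    // 5. conductance decay (zero-flushed well below any spiking effect)
    for (int i = 0; i < N; ++i) {
      if (gA[i] > 1e-12) gA[i] *= dec_a; else gA[i] = 0.0;
      if (gN[i] > 1e-12) gN[i] *= dec_n; else gN[i] = 0.0;
      if (gG[i] > 1e-12) gG[i] *= dec_g; else gG[i] = 0.0;
    }

    if (n_rec_v > 0)
      for (int k = 0; k < n_rec_v; ++k) v_trace(s + 1, k) = V[rec_v_idx[k]];
    if (n_snap > 0 && (s + 1) % w_every == 0) take_snapshot(t_next);
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  List final_w(n_proj);
  for (int p = 0; p < n_proj; ++p)
    if (P[p].plastic) final_w[p] = wrap(P[p].w);

  return List::create(
    _["spike_step"] = wrap(spike_step),
    _["spike_neuron"] = wrap(spike_neuron),
    _["v_trace"] = v_trace,
    _["w_times"] = w_times,
    _["w_means"] = w_means,
    _["final_w"] = final_w,
    _["bin_counts"] = wrap(bin_counts),
    _["bin_ms"] = bin_steps * dt);
}
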