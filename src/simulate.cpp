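#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// One pending synaptic delivery.
struct Arrival {
  int post;      // 0-based compact index
  double w;      // signed weight frozen at emission time
  long arr;      // absolute arrival step
};

// Fixed-timestep forward-Euler integration of an Izhikevich network with
// delayed current-based synapses, post-spike input desensitization,
// Poisson/gamma background drive and (optionally) additive pair-based STDP
// at excitatory-excitatory synapses implemented through exponentially
// decaying pre/post eligibility traces.
//
// Per-step order of operations (documented contract, mirrored by the R-level
// single-operation helpers):
//   1. decay STDP traces, 2. decay synaptic accumulators, 3. deliver due
//   queued spikes (scaled by the target's desensitization factor),
//   4. inject background/external events, 5. Euler-update all neurons and
//   detect threshold crossings (reset applied within the step; spike time =
//   step start), 6. STDP (potentiate incoming E->E of post-spikers from pre
//   traces; bump post traces; depress outgoing E->E of pre-spikers from post
//   traces, so a same-step pair falls on the depression branch; bump pre
//   traces), 7. enqueue outgoing spikes at t + delay with the current weight,
//   8. update desensitization factors.
//
// Randomness comes from R's RNG (set.seed() upstream).
// [[Rcpp::export]]
List sim_core(IntegerVector pre, IntegerVector post, NumericVector weight0,
              IntegerVector delay_steps, LogicalVector is_exc,
              NumericVector a, NumericVector b, NumericVector c_, NumericVector d,
              NumericVector v0, NumericVector u0,
              NumericVector ge0, NumericVector gi0, NumericVector s0,
              NumericVector x0, NumericVector y0,
              NumericMatrix queue0,
              double duration_ms, double dt,
              double tau_syn, double desens_floor, double desens_tau,
              double stim_rate_hz, double stim_k, double stim_theta,
              double stim_gain, bool stim_impulse,
              IntegerVector ext_step, IntegerVector ext_neuron, NumericVector ext_amp,
              bool stdp_on, double stdp_tau, double a_plus, double a_minus,
              double w_min, double w_max,
              bool record) {
  const int n = a.size();
  const int ne = pre.size();
  const long nsteps = (long) std::lround(duration_ms / dt);

  NumericVector w = clone(weight0);
  std::vector<double> v(v0.begin(), v0.end()), u(u0.begin(), u0.end());
  std::vector<double> ge(ge0.begin(), ge0.end()), gi(gi0.begin(), gi0.end());
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());

  // CSR over outgoing edges; incoming restricted to E->E (the only synapses
  // subject to plasticity).
  std::vector<int> out_ptr(n + 1, 0), in_ee_ptr(n + 1, 0);
  for (int e = 0; e < ne; ++e) out_ptr[pre[e]]++;
  for (int e = 0; e < ne; ++e)
    if (is_exc[pre[e] - 1] && is_exc[post[e] - 1]) in_ee_ptr[post[e]]++;
  for (int i = 0; i < n; ++i) { out_ptr[i + 1] += out_ptr[i]; in_ee_ptr[i + 1] += in_ee_ptr[i]; }
  std::vector<int> out_edge(ne), in_ee_edge(in_ee_ptr[n]);
  {
    std::vector<int> op(out_ptr.begin(), out_ptr.end() - 1),
                     ip(in_ee_ptr.begin(), in_ee_ptr.end() - 1);
    for (int e = 0; e < ne; ++e) {
      out_edge[op[pre[e] - 1]++] = e;
      if (is_exc[pre[e] - 1] && is_exc[post[e] - 1]) in_ee_edge[ip[post[e] - 1]++] = e;
    }
  }

  // Delay ring buffer sized to hold the longest in-flight interval.
  int max_del = 1;
  for (int e = 0; e < ne; ++e) max_del = std::max(max_del, delay_steps[e]);
  for (int r = 0; r < queue0.nrow(); ++r) max_del = std::max(max_del, (int) queue0(r, 0));
  const int slots = max_del + 1;
  std::vector< std::vector<Arrival> > ring(slots);
  for (int r = 0; r < queue0.nrow(); ++r) {
    int sl = ((int) queue0(r, 0)) % slots;
    ring[sl].push_back({(int) queue0(r, 1) - 1, queue0(r, 2), (long) queue0(r, 0)});
  }

  // Background drive: per-neuron next-event clocks (homogeneous Poisson).
  const double mean_int_ms = stim_rate_hz > 0 ? 1000.0 / stim_rate_hz : R_PosInf;
  std::vector<double> next_ev(n, R_PosInf);
  RNGScope rng;
  if (stim_rate_hz > 0)
    for (int i = 0; i < n; ++i) next_ev[i] = R::rexp(mean_int_ms);

  // Deterministic external events (always one-step current impulses), sorted
  // by step on the R side.
  int ext_i = 0;
  const int n_ext = ext_step.size();

  const double dec_syn = std::exp(-dt / tau_syn);
  const double dec_des = std::exp(-dt / desens_tau);
  const double dec_tr  = stdp_on ? std::exp(-dt / stdp_tau) : 1.0;

  std::vector<double> iext(n, 0.0);
  std::vector<char> spiked(n, 0);
  std::vector<int> fired;
  std::vector<int> sp_id;
  std::vector<double> sp_t;

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    if (stdp_on)
      for (int i = 0; i < n; ++i) { x[i] *= dec_tr; y[i] *= dec_tr; }
    for (int i = 0; i < n; ++i) { ge[i] *= dec_syn; gi[i] *= dec_syn; }

    // due deliveries
    std::vector<Arrival> &sl = ring[step % slots];
    for (size_t k = 0; k < sl.size(); ++k) {
      const Arrival &ev = sl[k];
      if (ev.w > 0) ge[ev.post] += s[ev.post] * ev.w;
      else          gi[ev.post] += s[ev.post] * ev.w;
    }
    sl.clear();

    // stochastic background
    if (stim_rate_hz > 0) {
      for (int i = 0; i < n; ++i) {
        while (next_ev[i] < t + dt) {
          double amp = stim_gain * R::rgamma(stim_k, stim_theta);
          if (stim_impulse) iext[i] += amp; else ge[i] += amp;
          next_ev[i] += R::rexp(mean_int_ms);
        }
      }
    }
    // scheduled external events
    while (ext_i < n_ext && ext_step[ext_i] == step) {
      iext[ext_neuron[ext_i] - 1] += ext_amp[ext_i];
      ++ext_i;
    }

    // Euler update + threshold/reset
    fired.clear();
    for (int i = 0; i < n; ++i) {
      const double I = ge[i] + gi[i] + iext[i];
      const double vo = v[i], uo = u[i];
      double vn = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 - uo + I);
      double un = uo + dt * a[i] * (b[i] * vo - uo);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("non-finite membrane state for neuron %d at t = %.1f ms", i + 1, t);
      if (vn >= 30.0) {
        spiked[i] = 1; fired.push_back(i);
        vn = c_[i]; un += d[i];
        if (record) { sp_id.push_back(i + 1); sp_t.push_back(t); }
      }
      v[i] = vn; u[i] = un;
      iext[i] = 0.0;
    }

    if (stdp_on && !fired.empty()) {
      // potentiation: incoming E->E of spiking (post) neurons, using pre
      // traces that do not yet include same-step pre spikes -> a same-step
      // pair is handled exclusively by the depression branch (dt <= 0).
      for (size_t k = 0; k < fired.size(); ++k) {
        const int i = fired[k];
        if (!is_exc[i]) continue;
        for (int p = in_ee_ptr[i]; p < in_ee_ptr[i + 1]; ++p) {
          const int e = in_ee_edge[p];
          w[e] = std::min(w_max, w[e] + a_plus * x[pre[e] - 1]);
        }
      }
      for (size_t k = 0; k < fired.size(); ++k)
        if (is_exc[fired[k]]) y[fired[k]] += 1.0;
      // depression: outgoing E->E of spiking (pre) neurons
      for (size_t k = 0; k < fired.size(); ++k) {
        const int j = fired[k];
        if (!is_exc[j]) continue;
        for (int p = out_ptr[j]; p < out_ptr[j + 1]; ++p) {
          const int e = out_edge[p];
          if (!is_exc[post[e] - 1]) continue;
          w[e] = std::max(w_min, w[e] - a_minus * y[post[e] - 1]);
        }
      }
      for (size_t k = 0; k < fired.size(); ++k)
        if (is_exc[fired[k]]) x[fired[k]] += 1.0;
    }

    // enqueue outgoing spikes with the weight current at emission
    for (size_t k = 0; k < fired.size(); ++k) {
      const int j = fired[k];
      for (int p = out_ptr[j]; p < out_ptr[j + 1]; ++p) {
        const int e = out_edge[p];
        const long arr = step + delay_steps[e];
        ring[arr % slots].push_back({post[e] - 1, w[e], arr});
      }
    }

    // desensitization: hard reset on spike, exponential relaxation to 1
    for (int i = 0; i < n; ++i) {
      if (spiked[i]) { s[i] = desens_floor; spiked[i] = 0; }
      else s[i] = 1.0 - (1.0 - s[i]) * dec_des;
    }
  }

  // export still-pending deliveries
  int n_pend = 0;
  for (int sl2 = 0; sl2 < slots; ++sl2) n_pend += ring[sl2].size();
  NumericMatrix qout(n_pend, 3);
  int r = 0;
  for (int sl2 = 0; sl2 < slots; ++sl2)
    for (size_t k = 0; k < ring[sl2].size(); ++k) {
      qout(r, 0) = (double)(ring[sl2][k].arr - nsteps);
      qout(r, 1) = ring[sl2][k].post + 1;
      qout(r, 2) = ring[sl2][k].w;
      ++r;
    }

  return List::create(
    _["spike_neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["spike_time"]   = NumericVector(sp_t.begin(), sp_t.end()),
    _["weights"]      = w,
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["g_exc"] = NumericVector(ge.begin(), ge.end()),
    _["g_inh"] = NumericVector(gi.begin(), gi.end()),
    _["s"] = NumericVector(s.begin(), s.end()),
    _["x_trace"] = NumericVector(x.begin(), x.end()),
    _["y_trace"] = NumericVector(y.begin(), y.end()),
    _["queue"] = qout,
    _["n_steps"] = (double) nsteps);
}

// Local maxima of a count trace with topographic prominence, minimum peak
// separation, and prominence-referenced full width at half maximum by linear
// interpolation of the flank crossings.
// [[Rcpp::export]]
List find_peaks_cpp(NumericVector xx, double prom_min, int min_sep,
                    bool absolute_half = false) {
  const long n = xx.size();
  std::vector<long> cand;
  long i = 1;
  while (i < n - 1) {
    if (xx[i - 1] < xx[i]) {
      long j = i;
      while (j < n - 1 && xx[j + 1] == xx[i]) ++j;
      if (j < n - 1 && xx[j + 1] < xx[i]) { cand.push_back((i + j) / 2); i = j + 1; continue; }
      i = j + 1;
    } else ++i;
  }

  std::vector<long> keep;
  std::vector<double> proms;
  for (size_t k = 0; k < cand.size(); ++k) {
    const long p = cand[k];
    double lmin = xx[p], rmin = xx[p];
    for (long q = p - 1; q >= 0; --q) { if (xx[q] > xx[p]) break; lmin = std::min(lmin, xx[q]); }
    for (long q = p + 1; q < n; ++q)  { if (xx[q] > xx[p]) break; rmin = std::min(rmin, xx[q]); }
    const double prom = xx[p] - std::max(lmin, rmin);
    if (prom >= prom_min) { keep.push_back(p); proms.push_back(prom); }
  }

  // enforce minimum separation, keeping higher (then more prominent) peaks
  std::vector<size_t> ord(keep.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](size_t a2, size_t b2) {
    if (xx[keep[a2]] != xx[keep[b2]]) return xx[keep[a2]] > xx[keep[b2]];
    if (proms[a2] != proms[b2]) return proms[a2] > proms[b2];
    return keep[a2] < keep[b2];
  });
  std::vector<char> ok(keep.size(), 1);
  std::vector<long> taken;
  for (size_t k = 0; k < ord.size(); ++k) {
    const long p = keep[ord[k]];
    bool clash = false;
    for (size_t m = 0; m < taken.size(); ++m)
      if (std::labs(taken[m] - p) < min_sep) { clash = true; break; }
    if (clash) ok[ord[k]] = 0; else taken.push_back(p);
  }

  std::vector<long> idx;
  std::vector<double> height, prom_out, lips, rips, width;
  for (size_t k = 0; k < keep.size(); ++k) {
    if (!ok[k]) continue;
    const long p = keep[k];
    const double level = absolute_half ? xx[p] / 2.0 : xx[p] - 0.5 * proms[k];
    double li = 0, ri = n - 1;
    for (long q = p - 1; q >= 0; --q) {
      if (xx[q] > xx[p]) { li = q + 1; break; }          // reached a higher flank
      if (xx[q] <= level) {
        li = (xx[q + 1] == xx[q]) ? q : q + (level - xx[q]) / (xx[q + 1] - xx[q]);
        break;
      }
      if (q == 0) li = 0;
    }
    for (long q = p + 1; q < n; ++q) {
      if (xx[q] > xx[p]) { ri = q - 1; break; }
      if (xx[q] <= level) {
        ri = (xx[q - 1] == xx[q]) ? q : q - (level - xx[q]) / (xx[q - 1] - xx[q]);
        break;
      }
      if (q == n - 1) ri = n - 1;
    }
    idx.push_back(p + 1);
    height.push_back(xx[p]);
    prom_out.push_back(proms[k]);
    lips.push_back(li + 1);
    rips.push_back(ri + 1);
    width.push_back(ri - li);
  }

  return List::create(_["idx"] = idx, _["height"] = height,
                      _["prominence"] = prom_out,
                      _["left_ip"] = lips, _["right_ip"] = rips,
                      _["width_steps"] = width);
}
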