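#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// splitmix64: seeds one well-mixed engine per (master seed, neuron, stream),
// so every neuron's background and stimulus event streams are independent
// substreams that do not depend on iteration order or on whether other
// streams are consumed. Adding a stimulus therefore leaves the background
// input of every neuron bit-identical.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Leaky integrate-and-fire network with delta-current synapses.
// Exact exponential membrane update per dt; presynaptic spikes arrive as
// instantaneous voltage jumps after a fixed delay (ring buffer); threshold
// crossing -> spike, reset, absolute refractory clamp. Background and
// stimulus drive are independent Poisson event streams per neuron.
// [[Rcpp::export]]
List lif_simulate_cpp(int n, IntegerVector pre, IntegerVector post,
                      LogicalVector is_inh,
                      double tau_m, double v_rest, double v_reset, double v_th,
                      double t_ref, double delay, double j_exc, double g,
                      double dt, double bg_rate, double bg_weight,
                      double drive, List stimuli, double t_stop, int seed) {
  const int m = pre.size();
  const int steps = (int)std::lround(t_stop / dt);
  const int d_steps = std::max(1, (int)std::lround(delay / dt));
  const int ref_steps = (int)std::lround(t_ref / dt);
  const double alpha = std::exp(-dt / tau_m);
  const double mu = v_rest + drive;
  const double v_sane = 1e3;

  // CSR out-adjacency
  std::vector<int> off(n + 1, 0), tgt(m);
  for (int e = 0; e < m; ++e) off[pre[e] - 1 + 1]++;
  for (int v = 0; v < n; ++v) off[v + 1] += off[v];
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < m; ++e) tgt[cur[pre[e] - 1]++] = post[e] - 1;
  }
  std::vector<double> w_out(n);
  for (int v = 0; v < n; ++v) w_out[v] = is_inh[v] ? -g * j_exc : j_exc;

  // stimuli: per-neuron flag + step windows
  const int n_stim = stimuli.size();
  std::vector<int> stim_on(n_stim), stim_off(n_stim);
  std::vector<double> stim_lambda(n_stim), stim_w(n_stim);
  std::vector< std::vector<char> > stim_flag(n_stim, std::vector<char>(n, 0));
  for (int s = 0; s < n_stim; ++s) {
    List st = stimuli[s];
    IntegerVector targets = st["targets"];
    double onset = as<double>(st["onset"]);
    double duration = as<double>(st["duration"]);
    stim_on[s] = (int)std::lround(onset / dt);
    stim_off[s] = (int)std::lround((onset + duration) / dt);
    stim_lambda[s] = as<double>(st["rate"]) * dt / 1000.0;
    stim_w[s] = as<double>(st["weight"]);
    for (int i = 0; i < targets.size(); ++i) stim_flag[s][targets[i] - 1] = 1;
  }

  std::vector<std::mt19937_64> bg_rng(n), st_rng(n);
  for (int v = 0; v < n; ++v) {
    uint64_t base = (uint64_t)(uint32_t)seed;
    bg_rng[v].seed(splitmix64(base * 2654435761ULL + (uint64_t)v * 2ULL));
    st_rng[v].seed(splitmix64(base * 2654435761ULL + (uint64_t)v * 2ULL + 1ULL));
  }
  const bool has_bg = bg_rate > 0.0;
  std::poisson_distribution<int> bg_pois(has_bg ? bg_rate * dt / 1000.0 : 1.0);

  std::vector<double> v_m(n, v_rest);
  std::vector<int> refr(n, 0);
  std::vector<double> buf((size_t)n * d_steps, 0.0);
  std::vector<double> sp_t; std::vector<int> sp_i, fired;
  fired.reserve(n);

  for (int t = 0; t < steps; ++t) {
    const int slot = t % d_steps;
    fired.clear();
    for (int v = 0; v < n; ++v) {
      // always consume the event streams so substreams stay aligned across
      // conditions regardless of refractory state
      double ext = 0.0;
      if (has_bg) ext += bg_weight * bg_pois(bg_rng[v]);
      for (int s = 0; s < n_stim; ++s) {
        if (stim_lambda[s] > 0.0 && stim_flag[s][v] && t >= stim_on[s] && t < stim_off[s]) {
          std::poisson_distribution<int> sp(stim_lambda[s]);
          ext += stim_w[s] * sp(st_rng[v]);
        }
      }
      double inc = buf[(size_t)v * d_steps + slot];
      buf[(size_t)v * d_steps + slot] = 0.0;
      if (refr[v] > 0) {
        refr[v]--;
        v_m[v] = v_reset;
        continue;
      }
      double vm = mu + (v_m[v] - mu) * alpha + inc + ext;
      if (vm >= v_th) {
        sp_t.push_back((t + 1) * dt);
        sp_i.push_back(v + 1);
        fired.push_back(v);
        vm = v_reset;
        refr[v] = ref_steps;
      } else if (vm > v_sane || vm < -v_sane) {
        stop("membrane potential diverged (|v| > %g mV) at t = %g ms with "
             "j_exc=%g, g=%g, bg_rate=%g: unstable parameter set",
             v_sane, t * dt, j_exc, g, bg_rate);
      }
      v_m[v] = vm;
    }
    const int wslot = (t + d_steps) % d_steps; // freed slot: arrives at t + delay
    for (size_t f = 0; f < fired.size(); ++f) {
      int v = fired[f];
      double w = w_out[v];
      for (int idx = off[v]; idx < off[v + 1]; ++idx) {
        buf[(size_t)tgt[idx] * d_steps + wslot] += w;
      }
    }
  }
  return List::create(_["times"] = wrap(sp_t), _["nodes"] = wrap(sp_i));
}
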