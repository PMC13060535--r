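// Forward-Euler simulator for the stochastic E-I rate/spiking network.
//
// State per neuron: membrane potential V (mV) and synaptic input Isyn.
//   tau_m dV/dt = -(V - V_rest) + scale * (I_ext + I_syn)
//   dIsyn/dt    = -Isyn / tau_syn + sum_j J_ij * delta(t - t_j)
// Rates come from a sigmoidal transfer of V; spikes are Bernoulli with
// per-step probability r * dt (r in Hz, dt in ms). Connectivity is CSC
// (column = presynaptic neuron) so spike propagation is a column sweep.
//
// `scale` implements the input-units convention: 1 reads the external
// drive as millivolts, tau_m reads it as mV/ms integrated over the
// membrane time constant.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

namespace {

// splitmix64: seeds the xoshiro state from a single integer.
inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

} // namespace

// Rate lookup table over V - V_rest in [xlo, xhi], linear interpolation.
struct RateLut {
  double xlo, inv_step, rate_max;
  std::vector<double> tab;
  RateLut(double rate_max_, double offset, double slope,
          double xlo_ = -150.0, double xhi = 300.0, double step = 0.01)
      : xlo(xlo_), inv_step(1.0 / step), rate_max(rate_max_) {
    int n = static_cast<int>((xhi - xlo_) / step) + 2;
    tab.resize(n);
    for (int i = 0; i < n; ++i) {
      double x = xlo_ + i * step;
      tab[i] = rate_max_ / (1.0 + std::exp(-(x - offset) / slope));
    }
  }
  inline double operator()(double x) const {
    double u = (x - xlo) * inv_step;
    if (u <= 0.0) return 0.0;
    int i = static_cast<int>(u);
    if (i >= static_cast<int>(tab.size()) - 1) return rate_max;
    double f = u - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_simulate_condition(
    Rcpp::IntegerVector jp,        // CSC column pointers (length n + 1)
    Rcpp::IntegerVector ji,        // CSC row indices (postsynaptic)
    Rcpp::NumericVector jx,        // synaptic weights
    Rcpp::NumericVector tau_m,     // per neuron, ms
    Rcpp::NumericVector input_scale, // per neuron multiplier on (Iext + Isyn)
    Rcpp::NumericVector i_base,    // per neuron constant drive (incl. context)
    Rcpp::NumericVector amp_sound, // per neuron sound amplitude A_i
    Rcpp::NumericVector amp_photo, // per neuron photostim amplitude S_i (0 if off)
    double v_rest, double tau_syn, double dt,
    double rate_max, double sig_offset, double sig_slope,
    double trial_ms, double t_on,
    double sound_tau_ms, double sound_dur_ms, double photo_dur_ms,
    double pre_start_ms, double pre_end_ms,
    double post_start_ms, double post_end_ms,
    int n_trials, double seed,
    Rcpp::IntegerVector group,     // 1-based group label per neuron (for traces)
    int n_groups,
    double trace_bin_ms,           // <= 0 disables group traces
    bool syn_jump_over_tau)        // true: spikes add J/tau_syn instead of J
{
  const int n = tau_m.size();
  const int n_steps = static_cast<int>(std::lround(trial_ms / dt));
  const int on_step = static_cast<int>(std::lround(t_on / dt));

  RateLut lut(rate_max, sig_offset, sig_slope);

  std::vector<double> a(n), scale(n);
  for (int i = 0; i < n; ++i) {
    a[i] = dt / tau_m[i];
    scale[i] = input_scale[i];
  }
  const double syn_decay = 1.0 - dt / tau_syn;
  const double jump_scale = syn_jump_over_tau ? (1.0 / tau_syn) : 1.0;
  const double p_factor = dt / 1000.0; // Hz -> per-step probability

  // precompute stimulus time courses (per step)
  std::vector<double> sound_t(n_steps, 0.0), photo_t(n_steps, 0.0);
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    if (t >= t_on && t < t_on + sound_dur_ms)
      sound_t[s] = std::exp(-(t - t_on) / sound_tau_ms);
    if (t >= t_on && t <= t_on + photo_dur_ms)
      photo_t[s] = 1.0;
  }

  const int pre_a = static_cast<int>(std::lround(pre_start_ms / dt));
  const int pre_b = static_cast<int>(std::lround(pre_end_ms / dt));
  const int post_a = static_cast<int>(std::lround(post_start_ms / dt));
  const int post_b = static_cast<int>(std::lround(post_end_ms / dt));
  const double pre_cnt = static_cast<double>(pre_b - pre_a);
  const double post_cnt = static_cast<double>(post_b - post_a);

  int n_bins = 0, steps_per_bin = 1;
  if (trace_bin_ms > 0) {
    steps_per_bin = static_cast<int>(std::lround(trace_bin_ms / dt));
    n_bins = n_steps / steps_per_bin;
  }
  Rcpp::NumericMatrix trace(n_groups, std::max(n_bins, 1));
  std::vector<double> group_size(n_groups, 0.0);
  for (int i = 0; i < n; ++i) group_size[group[i] - 1] += 1.0;

  Rcpp::NumericVector pre_mean(n), post_mean(n);
  std::vector<double> V(n), Isyn(n), pre_sum(n), post_sum(n);
  std::vector<int> spikes;
  spikes.reserve(256);
  double max_rate = 0.0;

  uint64_t seed_base = static_cast<uint64_t>(seed);

  for (int trial = 0; trial < n_trials; ++trial) {
    uint64_t mix = seed_base;
    for (int k = 0; k <= trial; ++k) splitmix64(mix);
    Xoshiro256pp rng(mix);

    std::fill(V.begin(), V.end(), v_rest);
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    std::fill(pre_sum.begin(), pre_sum.end(), 0.0);
    std::fill(post_sum.begin(), post_sum.end(), 0.0);

    for (int s = 0; s < n_steps; ++s) {
      const double st = sound_t[s], pt = photo_t[s];
      const bool in_pre = (s >= pre_a && s < pre_b);
      const bool in_post = (s >= post_a && s < post_b);
      const int bin = (n_bins > 0) ? (s / steps_per_bin) : -1;
      spikes.clear();
      for (int i = 0; i < n; ++i) {
        double iext = i_base[i] + amp_sound[i] * st + amp_photo[i] * pt;
        V[i] += a[i] * (-(V[i] - v_rest) + scale[i] * (iext + Isyn[i]));
        Isyn[i] *= syn_decay;
        double r = lut(V[i] - v_rest);
        if (r > max_rate) max_rate = r;
        if (in_pre) pre_sum[i] += r;
        if (in_post) post_sum[i] += r;
        if (bin >= 0 && bin < n_bins) trace(group[i] - 1, bin) += r;
        if (rng.unif() < r * p_factor) spikes.push_back(i);
      }
      for (int idx : spikes) {
        for (int k = jp[idx]; k < jp[idx + 1]; ++k)
          Isyn[ji[k]] += jx[k] * jump_scale;
      }
      (void)on_step;
    }
    for (int i = 0; i < n; ++i) {
      pre_mean[i] += pre_sum[i] / pre_cnt;
      post_mean[i] += post_sum[i] / post_cnt;
    }
    Rcpp::checkUserInterrupt();
  }

  const double inv_trials = 1.0 / n_trials;
  for (int i = 0; i < n; ++i) {
    pre_mean[i] *= inv_trials;
    post_mean[i] *= inv_trials;
  }
  if (n_bins > 0) {
    for (int g = 0; g < n_groups; ++g)
      for (int b = 0; b < n_bins; ++b)
        trace(g, b) *= inv_trials / (steps_per_bin * group_size[g]);
  }

  return Rcpp::List::create(
      Rcpp::Named("pre") = pre_mean,
      Rcpp::Named("post") = post_mean,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("max_rate") = max_rate,
      Rcpp::Named("n_bins") = n_bins,
      Rcpp::Named("bin_ms") = trace_bin_ms);
}

// Rolling percentile with edge-clipped windows; interpolation matches
// stats::quantile type 7.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_rolling_quantile(Rcpp::NumericVector x,
                                         int half_window, double prob) {
  const int n = x.size();
  Rcpp::NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * half_window + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_window);
    int hi = std::min(n - 1, i + half_window);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double h = (m - 1) * prob;
    int k = static_cast<int>(std::floor(h));
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double qk = buf[k];
    if (k + 1 < m && h > k) {
      double qk1 = *std::min_element(buf.begin() + k + 1, buf.end());
      qk += (h - k) * (qk1 - qk);
    }
    out[i] = qk;
  }
  return out;
}
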