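// Conductance-based leaky integrate-and-fire network on a 2-D lattice with
// periodic boundaries, Gaussian distance-dependent connectivity, and
// per-synapse conduction delays tau_ij = tau_s + d_ij / v_c. Forward Euler
// at dt = 0.1 ms with delayed spike delivery through a circular event
// buffer. The RNG is an explicitly seeded mt19937_64 so builds and runs are
// bit-reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double torus_delta(double a, double b, double span) {
  double d = std::fabs(a - b);
  return d > span / 2 ? span - d : d;
}

// [[Rcpp::export]]
List cw_build_network(int nx, int ny, double spacing_um, double frac_exc,
                      int k_syn, double sigma_um, double tau_s_ms,
                      double v_c_mps, double dt_ms, int seed) {
  const int n = nx * ny;
  if (k_syn >= n) stop("synapses per cell exceed the population");
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, sigma_um / spacing_um);

  // E/I types: exactly round(frac_exc * n) excitatory, randomly placed
  IntegerVector type(n); // 0 = E, 1 = I
  {
    int n_exc = (int)std::lround(frac_exc * n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif(rng) * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n; ++i) type[idx[i]] = (i < n_exc) ? 0 : 1;
  }

  NumericVector pos_x(n), pos_y(n);
  for (int i = 0; i < n; ++i) {
    pos_x[i] = (i % nx) * spacing_um;
    pos_y[i] = (i / nx) * spacing_um;
  }
  const double span_x = nx * spacing_um, span_y = ny * spacing_um;

  IntegerVector targets(n * k_syn);
  IntegerVector delay_steps(n * k_syn);
  const double mps_to_um_per_ms = 1000.0; // 1 m/s = 1000 um/ms
  for (int i = 0; i < n; ++i) {
    const int cx = i % nx, cy = i / nx;
    for (int s = 0; s < k_syn; ++s) {
      int dx = 0, dy = 0;
      do {
        dx = (int)std::lround(gauss(rng));
        dy = (int)std::lround(gauss(rng));
      } while (dx == 0 && dy == 0);
      int tx = ((cx + dx) % nx + nx) % nx;
      int ty = ((cy + dy) % ny + ny) % ny;
      int j = ty * nx + tx;
      double ddx = torus_delta(pos_x[i], pos_x[j], span_x);
      double ddy = torus_delta(pos_y[i], pos_y[j], span_y);
      double dist_um = std::sqrt(ddx * ddx + ddy * ddy);
      double delay_ms = tau_s_ms + dist_um / (v_c_mps * mps_to_um_per_ms);
      targets[i * k_syn + s] = j;
      delay_steps[i * k_syn + s] =
          std::max(1, (int)std::lround(delay_ms / dt_ms));
    }
  }
  return List::create(
      _["n"] = n, _["nx"] = nx, _["ny"] = ny, _["spacing_um"] = spacing_um,
      _["type"] = type, _["pos_x_um"] = pos_x, _["pos_y_um"] = pos_y,
      _["targets"] = targets, _["delay_steps"] = delay_steps,
      _["k_syn"] = k_syn, _["dt_ms"] = dt_ms, _["tau_s_ms"] = tau_s_ms,
      _["v_c_mps"] = v_c_mps);
}

// [[Rcpp::export]]
List cw_simulate(List net, double duration_ms, List dyn, List feedback,
                 int seed) {
  const int n = as<int>(net["n"]);
  const int nx = as<int>(net["nx"]);
  const int ny = as<int>(net["ny"]);
  const int k_syn = as<int>(net["k_syn"]);
  const double dt = as<double>(net["dt_ms"]);
  IntegerVector type = net["type"];
  IntegerVector targets = net["targets"];
  IntegerVector delay_steps = net["delay_steps"];
  NumericVector pos_x = net["pos_x_um"], pos_y = net["pos_y_um"];

  // dynamics parameters (conductances in units of the leak conductance)
  const double taum = as<double>(dyn["tau_m_ms"]);
  const double El = as<double>(dyn["E_leak_mv"]);
  const double Ee = as<double>(dyn["E_exc_mv"]);
  const double Ei = as<double>(dyn["E_inh_mv"]);
  const double Vt = as<double>(dyn["v_thresh_mv"]);
  const double Vr = as<double>(dyn["v_reset_mv"]);
  const double taue = as<double>(dyn["tau_e_ms"]);
  const double taui = as<double>(dyn["tau_i_ms"]);
  const double we = as<double>(dyn["w_exc"]);
  const double wi = as<double>(dyn["w_inh"]);
  const double t_ref = as<double>(dyn["t_ref_ms"]);
  const double kick_ms = as<double>(dyn["kick_ms"]);
  const double kick_rate_hz = as<double>(dyn["kick_rate_hz"]);
  const double kick_w = as<double>(dyn["kick_w"]);
  const double rate_ceiling_hz = as<double>(dyn["rate_ceiling_hz"]);
  const int lfp_every = as<int>(dyn["lfp_every"]);
  const int pool = as<int>(dyn["pool"]);

  // feedback (empty list disables)
  bool fb_on = feedback.size() > 0;
  double fb_onset = 0, fb_dur = 0, fb_rate_hz = 0, fb_w = 0, fb_p_inh = 0;
  int fb_n_fibers = 0, fb_fanout = 0;
  double fb_x0 = 0, fb_x1 = 0, fb_y0 = 0, fb_y1 = 0;
  if (fb_on) {
    fb_onset = as<double>(feedback["onset_ms"]);
    fb_dur = as<double>(feedback["duration_ms"]);
    fb_rate_hz = as<double>(feedback["rate_hz"]);
    fb_w = as<double>(feedback["w"]);
    fb_p_inh = as<double>(feedback["p_target_inhibitory"]);
    fb_n_fibers = as<int>(feedback["n_fibers"]);
    fb_fanout = as<int>(feedback["fanout"]);
    NumericVector patch = feedback["patch_um"]; // x0 x1 y0 y1
    fb_x0 = patch[0]; fb_x1 = patch[1]; fb_y0 = patch[2]; fb_y1 = patch[3];
  }

  // Two independent streams: the main stream drives initial conditions and
  // the kick (identical draw counts with and without feedback), the
  // feedback stream drives fiber wiring and fiber spiking, so seed-matched
  // paired runs are identical up to the feedback onset.
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  std::mt19937_64 rng_fb(static_cast<uint64_t>(seed) + 0xD1B54A32D192ED03ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // feedback fiber -> target lists (patch neurons, I with prob fb_p_inh)
  std::vector<int> fiber_targets;
  if (fb_on) {
    std::vector<int> patch_e, patch_i;
    for (int i = 0; i < n; ++i) {
      if (pos_x[i] >= fb_x0 && pos_x[i] <= fb_x1 && pos_y[i] >= fb_y0 &&
          pos_y[i] <= fb_y1) {
        if (type[i] == 0) patch_e.push_back(i); else patch_i.push_back(i);
      }
    }
    if (patch_e.empty() && patch_i.empty()) stop("feedback patch is empty");
    fiber_targets.resize((size_t)fb_n_fibers * fb_fanout);
    for (size_t s = 0; s < fiber_targets.size(); ++s) {
      bool to_i = unif(rng_fb) < fb_p_inh;
      const std::vector<int>& poolv =
          (to_i && !patch_i.empty()) ? patch_i
          : (!to_i && !patch_e.empty()) ? patch_e
          : (patch_i.empty() ? patch_e : patch_i);
      fiber_targets[s] = poolv[(size_t)(unif(rng_fb) * poolv.size())];
    }
  }

  const int n_steps = (int)std::lround(duration_ms / dt);
  int max_delay = 1;
  for (int s = 0; s < targets.size(); ++s)
    if (delay_steps[s] > max_delay) max_delay = delay_steps[s];
  const int nbuf = max_delay + 1;

  std::vector<double> v(n), ge(n, 0.0), gi(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<double> buf_e((size_t)nbuf * n, 0.0), buf_i((size_t)nbuf * n, 0.0);
  for (int i = 0; i < n; ++i) v[i] = Vr + (Vt - Vr) * unif(rng);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(200000); spike_id.reserve(200000);

  const int pools_x = nx / pool, pools_y = ny / pool;
  const int n_pools = pools_x * pools_y;
  std::vector<int> pool_of(n);
  for (int i = 0; i < n; ++i) {
    int px = std::min((i % nx) / pool, pools_x - 1);
    int py = std::min((i / nx) / pool, pools_y - 1);
    pool_of[i] = py * pools_x + px;
  }
  const int n_lfp = n_steps / lfp_every;
  NumericMatrix sim_lfp(n_pools, std::max(n_lfp, 1));

  const int ref_steps = (int)std::lround(t_ref / dt);
  const double dec_e = dt / taue, dec_i = dt / taui;
  const double kick_p = kick_rate_hz * dt / 1000.0;
  const double fb_p = fb_rate_hz * dt / 1000.0;
  const int guard_win = (int)std::lround(10.0 / dt); // 10-ms guard window
  std::vector<int> recent(guard_win, 0);
  long recent_sum = 0;
  const double guard_max =
      rate_ceiling_hz * n * (10.0 / 1000.0); // spikes allowed per window

  int lfp_col = 0;
  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % nbuf;
    const double now_ms = t * dt;
    // deliver due events
    for (int i = 0; i < n; ++i) {
      ge[i] += buf_e[(size_t)slot * n + i];
      gi[i] += buf_i[(size_t)slot * n + i];
      buf_e[(size_t)slot * n + i] = 0.0;
      buf_i[(size_t)slot * n + i] = 0.0;
    }
    // initial Poisson kick to seed the self-sustained state
    if (now_ms < kick_ms && kick_p > 0) {
      for (int i = 0; i < n; ++i)
        if (unif(rng) < kick_p) ge[i] += kick_w;
    }
    // feedback fibers (their RNG stream is independent of the main one)
    if (fb_on && now_ms >= fb_onset && now_ms < fb_onset + fb_dur) {
      for (int f = 0; f < fb_n_fibers; ++f) {
        if (unif(rng_fb) < fb_p) {
          for (int s = 0; s < fb_fanout; ++s)
            ge[fiber_targets[(size_t)f * fb_fanout + s]] += fb_w;
        }
      }
    }

    int spikes_now = 0;
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {
        --refr[i];
        v[i] = Vr;
      } else {
        const double dv =
            ((El - v[i]) + ge[i] * (Ee - v[i]) + gi[i] * (Ei - v[i])) / taum;
        v[i] += dt * dv;
      }
      ge[i] -= dec_e * ge[i];
      gi[i] -= dec_i * gi[i];
      if (refr[i] == 0 && v[i] >= Vt) {
        ++spikes_now;
        spike_t.push_back(now_ms);
        spike_id.push_back(i + 1); // 1-based for R
        v[i] = Vr;
        refr[i] = ref_steps;
        const double w = (type[i] == 0) ? we : wi;
        const size_t base = (size_t)i * k_syn;
        if (type[i] == 0) {
          for (int s = 0; s < k_syn; ++s) {
            const int dslot = (t + delay_steps[base + s]) % nbuf;
            buf_e[(size_t)dslot * n + targets[base + s]] += w;
          }
        } else {
          for (int s = 0; s < k_syn; ++s) {
            const int dslot = (t + delay_steps[base + s]) % nbuf;
            buf_i[(size_t)dslot * n + targets[base + s]] += w;
          }
        }
      }
    }
    // runaway guard
    recent_sum += spikes_now - recent[t % guard_win];
    recent[t % guard_win] = spikes_now;
    if (t >= guard_win && recent_sum > guard_max)
      stop("runaway activity: population rate exceeded %g Hz", rate_ceiling_hz);

    if ((t + 1) % lfp_every == 0 && lfp_col < sim_lfp.ncol()) {
      for (int i = 0; i < n; ++i) {
        const double cur = std::fabs(ge[i] * (Ee - v[i])) +
                           std::fabs(gi[i] * (Ei - v[i]));
        sim_lfp(pool_of[i], lfp_col) += cur;
      }
      ++lfp_col;
    }
  }

  return List::create(
      _["spike_t_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["sim_lfp"] = sim_lfp, _["pools_x"] = pools_x, _["pools_y"] = pools_y,
      _["lfp_fs_hz"] = 1000.0 / (dt * lfp_every));
}
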