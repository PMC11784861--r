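# Balanced-state spiking network with distance-dependent conduction delays.
# Scaled-down configuration of a large-scale model: conductance-based LIF
# neurons (80% E / 20% I) on a lattice with periodic boundaries, Gaussian
# local connectivity, per-synapse delays tau_ij = tau_s + d_ij / v_c, and a
# simulated LFP pooled over adjacent non-overlapping 10x10-neuron pools.

#' Network configuration
#'
#' Defaults describe the scaled-down study network: 20,000 neurons
#' (100 x 200 lattice at 6.78 um spacing, the full-scale density), 80%
#' excitatory, synapses per cell scaled to keep the full-scale connection
#' probability (1000 of 450,000), fixed synaptic delay tau_s = 0.5 ms,
#' conduction speed 0.3 m/s (unmyelinated horizontal fibers), forward Euler
#' at dt = 0.1 ms. LIF and synaptic constants are standard cortical values
#' calibrated to hold the self-sustained asynchronous-irregular state at
#' this scale (membrane 20 ms, threshold -50 mV, reset -65 mV, leak -60 mV,
#' E/I reversals 0/-80 mV, synaptic decay 5/10 ms, refractory 10 ms
#' lumping absolute and relative refractoriness); synaptic weights are in
#' units of the leak conductance and follow a 1/sqrt(K) calibration from
#' the K = 80 balanced-state reference values (0.6, 6.7).
#'
#' @param grid_shape `c(ny, nx)` lattice dimensions.
#' @param spacing_um Lattice spacing (um).
#' @param frac_excitatory Excitatory fraction.
#' @param synapses_per_cell Outgoing synapses per neuron; `NULL` scales the
#'   full-scale 1000/450,000 probability to this network's size.
#' @param connectivity_sigma_um Gaussian connectivity length scale (um).
#' @param tau_s_ms Fixed synaptic delay (ms).
#' @param v_c_mps Axonal conduction speed (m/s).
#' @param dt_ms Euler time step (ms), at most 0.1.
#' @param w_exc,w_inh Synaptic conductance increments (units of leak
#'   conductance); `NULL` applies the 1/sqrt(K) calibration.
#' @param seed Build seed.
#' @return A `network_config` list (includes all LIF constants; edit fields
#'   directly for non-default dynamics).
#' @export
network_config <- function(grid_shape = c(100, 200), spacing_um = 6.78,
                           frac_excitatory = 0.8, synapses_per_cell = NULL,
                           connectivity_sigma_um = 300, tau_s_ms = 0.5,
                           v_c_mps = 0.3, dt_ms = 0.1, w_exc = NULL,
                           w_inh = NULL, seed = 1) {
  if (dt_ms > 0.1) stop("`dt_ms` must be <= 0.1 ms", call. = FALSE)
  if (frac_excitatory <= 0 || frac_excitatory >= 1)
    stop("`frac_excitatory` must be in (0, 1)", call. = FALSE)
  n <- prod(grid_shape)
  if (is.null(synapses_per_cell))
    synapses_per_cell <- max(40L, round(1000 / 450000 * n))
  k <- synapses_per_cell
  # 1/sqrt(K) scaling from the K = 80 reference weights
  scale <- sqrt(80 / k)
  if (is.null(w_exc)) w_exc <- 0.6 * scale
  if (is.null(w_inh)) w_inh <- 6.7 * scale
  structure(
    list(grid_shape = as.integer(grid_shape), spacing_um = spacing_um,
         frac_excitatory = frac_excitatory,
         synapses_per_cell = as.integer(k),
         connectivity_sigma_um = connectivity_sigma_um,
         tau_s_ms = tau_s_ms, v_c_mps = v_c_mps, dt_ms = dt_ms,
         w_exc = w_exc, w_inh = w_inh,
         tau_m_ms = 20, E_leak_mv = -60, E_exc_mv = 0, E_inh_mv = -80,
         v_thresh_mv = -50, v_reset_mv = -65, tau_e_ms = 5, tau_i_ms = 10,
         t_ref_ms = 10, kick_ms = 50, kick_rate_hz = 300, kick_w = 0.6,
         rate_ceiling_hz = 80, pool = 10L, lfp_fs_hz = 1000,
         seed = as.integer(seed)),
    class = "network_config"
  )
}

#' Build a network instance
#'
#' Places neurons on the lattice, assigns E/I types (exact split), and
#' samples `synapses_per_cell` outgoing synapses per neuron with Gaussian
#' distance fall-off on the torus; each synapse stores the delay
#' `tau_s + d_ij / v_c` rounded to integration steps.
#'
#' @param cfg A [network_config()].
#' @return A `network` list wrapping the connectivity arrays plus the
#'   config.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  net <- cw_build_network(
    nx = cfg$grid_shape[2], ny = cfg$grid_shape[1],
    spacing_um = cfg$spacing_um, frac_exc = cfg$frac_excitatory,
    k_syn = cfg$synapses_per_cell, sigma_um = cfg$connectivity_sigma_um,
    tau_s_ms = cfg$tau_s_ms, v_c_mps = cfg$v_c_mps, dt_ms = cfg$dt_ms,
    seed = cfg$seed
  )
  net$cfg <- cfg
  class(net) <- "network"
  net
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %d neurons (%d E / %d I), %d synapses/cell, v_c = %g m/s\n",
              x$n, sum(x$type == 0), sum(x$type == 1), x$k_syn,
              x$cfg$v_c_mps))
  invisible(x)
}

dyn_params <- function(cfg) {
  list(tau_m_ms = cfg$tau_m_ms, E_leak_mv = cfg$E_leak_mv,
       E_exc_mv = cfg$E_exc_mv, E_inh_mv = cfg$E_inh_mv,
       v_thresh_mv = cfg$v_thresh_mv, v_reset_mv = cfg$v_reset_mv,
       tau_e_ms = cfg$tau_e_ms, tau_i_ms = cfg$tau_i_ms,
       w_exc = cfg$w_exc, w_inh = cfg$w_inh, t_ref_ms = cfg$t_ref_ms,
       kick_ms = cfg$kick_ms, kick_rate_hz = cfg$kick_rate_hz,
       kick_w = cfg$kick_w, rate_ceiling_hz = cfg$rate_ceiling_hz,
       lfp_every = max(1L, round(1000 / (cfg$lfp_fs_hz * cfg$dt_ms))),
       pool = cfg$pool)
}

#' Simulate the network
#'
#' Forward-Euler integration with delayed spike delivery through a circular
#' event buffer. A brief Poisson kick (default first 50 ms) seeds the
#' self-sustained asynchronous-irregular state; there is no external drive
#' afterwards. Aborts with a diagnostic if the population rate exceeds the
#' configured ceiling.
#'
#' @param net A [build_network()] result.
#' @param duration_s Simulated time (s).
#' @param feedback `NULL`, or a [feedback_spec()].
#' @param seed Simulation seed.
#' @return A `spike_record`: `spikes` (data.frame `t_s`, `neuron`),
#'   `positions` (um), `types` (`"E"`/`"I"`), `sim_lfp` (pools x samples),
#'   `lfp_fs`, `pool_grid`, `pool_coords_mm`, `cfg`, `duration_s`.
#' @export
simulate_network <- function(net, duration_s = 5, feedback = NULL, seed = 1) {
  stopifnot(inherits(net, "network"))
  fb <- if (is.null(feedback)) list() else unclass(feedback)
  res <- cw_simulate(net, duration_s * 1000, dyn_params(net$cfg), fb,
                     as.integer(seed))
  pool_pitch_mm <- net$cfg$pool * net$spacing_um * 1e-3
  coords <- grid_coords(res$pools_y, res$pools_x, pool_pitch_mm)
  structure(
    list(spikes = data.frame(t_s = res$spike_t_ms / 1000,
                             neuron = res$spike_id),
         positions = cbind(x_um = net$pos_x_um, y_um = net$pos_y_um),
         types = c("E", "I")[net$type + 1L],
         sim_lfp = res$sim_lfp, lfp_fs = res$lfp_fs_hz,
         pool_grid = c(res$pools_y, res$pools_x),
         pool_coords_mm = coords, cfg = net$cfg, duration_s = duration_s,
         feedback = feedback),
    class = "spike_record"
  )
}

#' @export
print.spike_record <- function(x, ...) {
  n <- nrow(x$positions)
  rate <- nrow(x$spikes) / n / x$duration_s
  cat(sprintf("<spike_record> %d spikes from %d neurons over %.1f s (mean %.2f Hz)\n",
              nrow(x$spikes), n, x$duration_s, rate))
  invisible(x)
}

#' Feedback input specification
#'
#' External Poisson fibers delivered to a local patch for a short window,
#' targeting inhibitory neurons with probability `p_target_inhibitory`.
#'
#' @param patch_center_um,patch_size_um Patch center and edge length (um).
#' @param onset_s Feedback onset (s); set from a wave arrival at the patch.
#' @param duration_ms Window length (default 20 ms).
#' @param rate_hz Poisson rate per fiber.
#' @param n_fibers Number of fibers.
#' @param fanout Synapses per fiber.
#' @param p_target_inhibitory Probability a feedback synapse lands on an
#'   inhibitory neuron.
#' @param w Synaptic weight of feedback synapses (leak-conductance units).
#' @return A `feedback_spec` list.
#' @export
feedback_spec <- function(patch_center_um, patch_size_um = 400,
                          onset_s, duration_ms = 20, rate_hz = 500,
                          n_fibers = 300, fanout = 20,
                          p_target_inhibitory = 0.8, w = 0.8) {
  if (p_target_inhibitory < 0 || p_target_inhibitory > 1)
    stop("`p_target_inhibitory` must be in [0, 1]", call. = FALSE)
  if (duration_ms <= 0) stop("`duration_ms` must be positive", call. = FALSE)
  structure(
    list(patch_um = c(patch_center_um[1] - patch_size_um / 2,
                      patch_center_um[1] + patch_size_um / 2,
                      patch_center_um[2] - patch_size_um / 2,
                      patch_center_um[2] + patch_size_um / 2),
         onset_ms = onset_s * 1000, duration_ms = duration_ms,
         rate_hz = rate_hz, n_fibers = as.integer(n_fibers),
         fanout = as.integer(fanout),
         p_target_inhibitory = p_target_inhibitory, w = w),
    class = "feedback_spec"
  )
}

#' Paired simulation with and without feedback
#'
#' Runs two seed-matched simulations differing only in the feedback input
#' and returns both records plus patch firing-rate time courses (1-ms
#' bins, split by cell type).
#'
#' @param net A network.
#' @param fb A [feedback_spec()].
#' @param duration_s Simulated time (s).
#' @param seed Shared simulation seed.
#' @return List `with`, `without` (spike records), `patch_rates`
#'   (data.frame: `t_ms`, `with_e`, `with_i`, `without_e`, `without_i`,
#'   rates in Hz per neuron), `patch_neurons`.
#' @export
apply_feedback <- function(net, fb, duration_s = 1.5, seed = 1) {
  stopifnot(inherits(fb, "feedback_spec"))
  r_fb <- simulate_network(net, duration_s, feedback = fb, seed = seed)
  r_no <- simulate_network(net, duration_s, feedback = NULL, seed = seed)
  patch <- which(net$pos_x_um >= fb$patch_um[1] & net$pos_x_um <= fb$patch_um[2] &
                   net$pos_y_um >= fb$patch_um[3] & net$pos_y_um <= fb$patch_um[4])
  is_i <- net$type[patch] == 1
  rate_tc <- function(rec, ids) {
    br <- seq(0, duration_s, by = 0.001)
    sp <- rec$spikes[rec$spikes$neuron %in% ids, "t_s"]
    h <- hist(sp, breaks = br, plot = FALSE)$counts
    h / max(1, length(ids)) * 1000  # Hz per neuron
  }
  patch_rates <- data.frame(
    t_ms = (seq_len(round(duration_s * 1000))) - 0.5,
    with_e = rate_tc(r_fb, patch[!is_i]), with_i = rate_tc(r_fb, patch[is_i]),
    without_e = rate_tc(r_no, patch[!is_i]), without_i = rate_tc(r_no, patch[is_i])
  )
  list(with = r_fb, without = r_no, patch_rates = patch_rates,
       patch_neurons = patch)
}

#' Asynchronous-irregular state diagnostics
#'
#' Mean coefficient of variation of inter-spike intervals (cells with >= 3
#' spikes) and mean pairwise spike-count correlation (random cell subset,
#' binned counts), computed after discarding a burn-in.
#'
#' @param record A `spike_record`.
#' @param burn_s Burn-in discarded from the start (s).
#' @param bin_s Count bin for correlations (s).
#' @param n_cells Subsample size for the correlation matrix.
#' @param seed Subsample seed.
#' @return List `cv_isi`, `mean_corr`, `mean_rate_hz`.
#' @export
ai_state_metrics <- function(record, burn_s = 0.5, bin_s = 0.02,
                             n_cells = 200, seed = 1) {
  sp <- record$spikes[record$spikes$t_s >= burn_s, ]
  n <- nrow(record$positions)
  dur <- record$duration_s - burn_s
  cvs <- vapply(split(sp$t_s, sp$neuron), function(ts) {
    if (length(ts) < 3L) return(NA_real_)
    isi <- diff(sort(ts))
    sd(isi) / mean(isi)
  }, numeric(1))
  br <- seq(burn_s, record$duration_s, by = bin_s)
  active <- as.integer(names(which(table(sp$neuron) >= 2)))
  pick <- with_seed(seed, sample(active, min(n_cells, length(active))))
  counts <- vapply(pick, function(id)
    hist(sp$t_s[sp$neuron == id], breaks = br, plot = FALSE)$counts,
    numeric(length(br) - 1L))
  cm <- suppressWarnings(cor(counts))
  list(cv_isi = mean(cvs, na.rm = TRUE),
       mean_corr = mean(cm[upper.tri(cm)], na.rm = TRUE),
       mean_rate_hz = nrow(sp) / n / dur)
}

#' Detect traveling waves in the simulated LFP
#'
#' Wraps the pooled simulated LFP as a [grid_lfp()] and runs the standard
#' wave pipeline (wideband filter, generalized phase, shuffle null,
#' classification), returning speed estimates comparable to the conduction
#' speed.
#'
#' @param record A `spike_record`.
#' @param burn_s Burn-in excluded from the record (s).
#' @param band Analysis band (default wideband 3-40 Hz).
#' @param n_shuffles Null shuffles.
#' @param seed Null seed.
#' @return A wave-event data.frame (see [detect_waves()]).
#' @export
detect_sim_waves <- function(record, burn_s = 0.5, band = "wideband",
                             n_shuffles = 200, seed = 1) {
  i0 <- round(burn_s * record$lfp_fs) + 1L
  dat <- record$sim_lfp[, i0:ncol(record$sim_lfp), drop = FALSE]
  dat <- dat - rowMeans(dat)
  lfp <- grid_lfp(dat, record$pool_coords_mm, record$lfp_fs, t0 = burn_s)
  wb <- bandpass(lfp, band)
  detect_waves(wb, n_shuffles = n_shuffles, band = band, seed = seed)
}

#' Per-wave-pass sparsity metrics over a patch
#'
#' For each wave pass (a supplied pass time), counts the fraction of patch
#' neurons that spike within the pass window, the mean rate, and, across
#' passes, each neuron's spike reliability (fraction of passes with a
#' spike).
#'
#' @param record A `spike_record`.
#' @param patch Neuron ids of the patch.
#' @param pass_times Wave-pass times at the patch (s).
#' @param window_s Half-window around each pass (s).
#' @return List `per_pass` (data.frame `t_s`, `fraction`, `mean_rate_hz`),
#'   `reliability` (per patch neuron).
#' @export
sparsity_metrics <- function(record, patch, pass_times, window_s = 0.025) {
  if (!length(pass_times))
    return(list(per_pass = data.frame(t_s = numeric(0), fraction = numeric(0),
                                      mean_rate_hz = numeric(0)),
                reliability = numeric(0)))
  sp <- record$spikes[record$spikes$neuron %in% patch, ]
  hits <- matrix(FALSE, length(patch), length(pass_times))
  per_pass <- data.frame(t_s = pass_times, fraction = NA_real_,
                         mean_rate_hz = NA_real_)
  for (j in seq_along(pass_times)) {
    t0 <- pass_times[j] - window_s; t1 <- pass_times[j] + window_s
    w <- sp[sp$t_s >= t0 & sp$t_s <= t1, ]
    hits[, j] <- patch %in% w$neuron
    per_pass$fraction[j] <- mean(hits[, j])
    per_pass$mean_rate_hz[j] <- nrow(w) / length(patch) / (t1 - t0)
  }
  list(per_pass = per_pass, reliability = rowMeans(hits))
}
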