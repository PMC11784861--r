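# Synthetic grid LFP with planted traveling waves and evoked trial structure.
# The generators define the study conditions for every downstream wave test:
# each channel carries a phase-shifted oscillation whose lag is set exactly by
# the planted propagation geometry, so wave kinematics are recoverable in
# closed form.

#' Specification of a planted traveling-wave field
#'
#' Describes a phase-propagating oscillation on a 2-D electrode grid. The
#' phase model is `phi(x, t) = 2*pi*f0*t - k*d(x)` with wavenumber
#' `k = 2*pi*f0 / speed`; `d(x)` is the signed projection onto the propagation
#' direction for plane waves and the Euclidean distance from the source
#' electrode for radial waves.
#'
#' @param grid_shape Integer `c(rows, cols)` of the electrode lattice (>= 2
#'   each).
#' @param pitch Electrode spacing in mm.
#' @param fs Sampling rate in Hz.
#' @param f0 Oscillation frequency in Hz; must lie in the wideband analysis
#'   range (3-40 Hz).
#' @param speed Planted propagation speed in m/s (> 0).
#' @param geometry `"plane"` or `"radial"`.
#' @param direction Propagation direction in radians (plane waves).
#' @param source Source electrode index (radial waves); default grid center.
#' @param amplitude Oscillation amplitude in uV.
#' @param noise_sd SD of additive white Gaussian channel noise in uV.
#' @param duration Record duration in seconds.
#' @param seed RNG seed; identical specs and seeds give identical records.
#' @return A `wave_field_spec` list.
#' @export
wave_field_spec <- function(grid_shape = c(8, 8), pitch = 0.2, fs = 1000,
                            f0 = 10, speed = 0.3,
                            geometry = c("plane", "radial"),
                            direction = 0, source = NULL,
                            amplitude = 50, noise_sd = 5,
                            duration = 1, seed = 1) {
  geometry <- match.arg(geometry)
  if (length(grid_shape) != 2L || any(grid_shape < 2))
    stop("`grid_shape` must be two dimensions >= 2", call. = FALSE)
  stopifnot_scalar(speed, "speed", positive = TRUE)
  stopifnot_scalar(f0, "f0", positive = TRUE)
  if (f0 < 3 || f0 > 40)
    stop("`f0` must lie within the wideband analysis range (3-40 Hz)",
         call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(pitch, "pitch", positive = TRUE)
  n_ch <- prod(grid_shape)
  if (is.null(source)) {
    # electrode nearest the grid center
    ctr_row <- ceiling(grid_shape[1] / 2); ctr_col <- ceiling(grid_shape[2] / 2)
    source <- (ctr_row - 1L) * grid_shape[2] + ctr_col
  }
  if (source < 1 || source > n_ch)
    stop("`source` outside the grid", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape), pitch = pitch, fs = fs, f0 = f0,
         speed = speed, geometry = geometry, direction = direction,
         source = as.integer(source), amplitude = amplitude,
         noise_sd = noise_sd, duration = duration, seed = seed),
    class = "wave_field_spec"
  )
}

# Signed/absolute propagation distance of each electrode under a spec, in m.
planted_distance_m <- function(spec, coords_mm) {
  if (spec$geometry == "plane") {
    u <- c(cos(spec$direction), sin(spec$direction))
    d <- coords_mm %*% u
  } else {
    src <- coords_mm[spec$source, ]
    d <- sqrt((coords_mm[, 1] - src[1])^2 + (coords_mm[, 2] - src[2])^2)
  }
  as.numeric(d) * 1e-3
}

#' Generate a grid LFP with a planted traveling wave
#'
#' Each channel carries `amplitude * cos(2*pi*f0*t - k*d_channel)` plus white
#' Gaussian noise. The ground truth attached to the record lists the planted
#' kinematics so downstream recovery can be checked in closed form.
#'
#' @param spec A [wave_field_spec()].
#' @return A [grid_lfp()] with attribute `ground_truth`: a list with the
#'   planted `speed` (m/s), `f0` (Hz), wavenumber `k` (rad/m), `geometry`,
#'   `source` channel and `direction`.
#' @export
generate_wave_lfp <- function(spec) {
  stopifnot(inherits(spec, "wave_field_spec"))
  coords <- grid_coords(spec$grid_shape[1], spec$grid_shape[2], spec$pitch)
  k <- 2 * pi * spec$f0 / spec$speed           # rad/m
  d <- planted_distance_m(spec, coords)
  t <- seq(0, spec$duration - 1 / spec$fs, by = 1 / spec$fs)
  phase <- outer(-k * d, 2 * pi * spec$f0 * t, `+`)
  data <- spec$amplitude * cos(phase)
  if (spec$noise_sd > 0) {
    data <- data + with_seed(spec$seed,
      matrix(rnorm(length(data), sd = spec$noise_sd), nrow = nrow(data)))
  }
  out <- grid_lfp(data, coords, spec$fs)
  attr(out, "ground_truth") <- list(
    speed = spec$speed, f0 = spec$f0, k = k, geometry = spec$geometry,
    source = spec$source, direction = spec$direction
  )
  out
}

#' Specification of an evoked trial set
#'
#' Trial structure with an early (< 50 ms) touch-evoked deflection and a late
#' component inside `late_window`, both with per-trial planted amplitudes.
#'
#' @param n_trials Number of trials.
#' @param touch_times Touch onset times in seconds; equally spaced by default.
#' @param early_amp Early-deflection amplitude(s), uV (scalar or per trial).
#' @param late_amp Late-component amplitude(s), uV (scalar or per trial).
#' @param late_window `c(start, end)` of the late component in seconds
#'   post-touch; start must be > 0.
#' @param responsive_fraction Fraction of trials given a detectable early
#'   deflection; the flagged subset is seed-determined.
#' @param iti Inter-trial spacing in seconds when `touch_times` is derived.
#' @param seed RNG seed.
#' @return A `trial_set_spec` list.
#' @export
trial_set_spec <- function(n_trials = 20, touch_times = NULL,
                           early_amp = 80, late_amp = 40,
                           late_window = c(0.10, 0.20),
                           responsive_fraction = 1, iti = 2, seed = 1) {
  if (late_window[1] <= 0)
    stop("`late_window` must start after touch", call. = FALSE)
  if (any(c(early_amp, late_amp) < 0))
    stop("amplitudes must be >= 0", call. = FALSE)
  if (is.null(touch_times)) touch_times <- seq_len(n_trials) * iti
  if (length(touch_times) != n_trials)
    stop("`touch_times` must have `n_trials` entries", call. = FALSE)
  if (is.unsorted(touch_times, strictly = TRUE))
    stop("`touch_times` must be strictly increasing", call. = FALSE)
  if (any(diff(touch_times) < 1))
    stop("trials overlap: touches closer than 1 s", call. = FALSE)
  structure(
    list(n_trials = as.integer(n_trials), touch_times = touch_times,
         early_amp = rep_len(early_amp, n_trials),
         late_amp = rep_len(late_amp, n_trials),
         late_window = late_window,
         responsive_fraction = responsive_fraction, seed = seed),
    class = "trial_set_spec"
  )
}

#' Generate a grid LFP with evoked trial structure
#'
#' Builds a continuous record with noise plus, for each trial, an early
#' negative-going deflection ~20 ms after touch and a slow late component
#' inside the spec's late window. Both components propagate across the grid
#' with lags given by the wave spec's planted geometry. Ground-truth
#' strong/weak late-wave labels mirror the downstream analysis threshold:
#' strong iff the planted late amplitude exceeds 3x the channel noise SD.
#'
#' @param spec A [trial_set_spec()].
#' @param wave A [wave_field_spec()] describing the propagation geometry and
#'   grid (its `f0`/`duration` are ignored).
#' @return A [grid_lfp()] with attribute `ground_truth`: list with
#'   `touch_times`, logical `responsive` and `strong_late` per trial, and the
#'   planted amplitudes.
#' @export
generate_trial_lfp <- function(spec, wave = wave_field_spec()) {
  stopifnot(inherits(spec, "trial_set_spec"), inherits(wave, "wave_field_spec"))
  coords <- grid_coords(wave$grid_shape[1], wave$grid_shape[2], wave$pitch)
  n_ch <- nrow(coords)
  fs <- wave$fs
  dur <- max(spec$touch_times) + 1.5
  if (min(spec$touch_times) < 0.75)
    stop("touch times must leave >= 0.75 s of pre-touch record", call. = FALSE)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs

  lag_s <- planted_distance_m(wave, coords) / wave$speed
  lag_s <- lag_s - min(lag_s)

  n_resp <- round(spec$responsive_fraction * spec$n_trials)
  responsive <- rep(FALSE, spec$n_trials)
  responsive[with_seed(spec$seed, sample.int(spec$n_trials, n_resp))] <- TRUE

  data <- with_seed(
    spec$seed + 1L,
    matrix(rnorm(n_ch * n, sd = wave$noise_sd), nrow = n_ch)
  )
  lw <- spec$late_window
  f_late <- 1 / (2 * (lw[2] - lw[1]))  # half-sine spanning the late window
  for (tr in seq_len(spec$n_trials)) {
    tt <- spec$touch_times[tr]
    for (ch in seq_len(n_ch)) {
      tc <- t - tt - lag_s[ch]
      if (responsive[tr] && spec$early_amp[tr] > 0) {
        # biphasic early deflection peaking ~20-35 ms post-touch
        data[ch, ] <- data[ch, ] +
          spec$early_amp[tr] * (exp(-((tc - 0.020) / 0.006)^2) -
                                0.6 * exp(-((tc - 0.035) / 0.009)^2))
      }
      if (spec$late_amp[tr] > 0) {
        in_lw <- tc >= lw[1] & tc <= lw[2]
        data[ch, in_lw] <- data[ch, in_lw] +
          spec$late_amp[tr] * sin(2 * pi * f_late * (tc[in_lw] - lw[1]))
      }
    }
  }
  out <- grid_lfp(data, coords, fs)
  attr(out, "ground_truth") <- list(
    touch_times = spec$touch_times,
    responsive = responsive,
    strong_late = spec$late_amp > 3 * wave$noise_sd,
    early_amp = spec$early_amp, late_amp = spec$late_amp,
    late_window = lw
  )
  out
}
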