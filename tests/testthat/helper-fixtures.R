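# Shared fixture builders. Everything is generated in code at test time.

# Wideband-filtered planted plane wave plus its corrected phase field.
make_wave_field <- function(f0 = 10, speed = 0.3, noise_sd = 5,
                            amplitude = 50, geometry = "plane",
                            direction = 0, duration = 1, seed = 1, ...) {
  spec <- wave_field_spec(f0 = f0, speed = speed, noise_sd = noise_sd,
                          amplitude = amplitude, geometry = geometry,
                          direction = direction, duration = duration,
                          seed = seed, ...)
  lfp <- generate_wave_lfp(spec)
  wb <- bandpass(lfp, "wideband")
  list(spec = spec, lfp = lfp, wb = wb,
       field = gp_correct(analytic_signal(wb)))
}

# Raster with k disjoint planted ensembles of `size` cells.
make_ensemble_raster <- function(k = 2, size = 8, n_cells = 200,
                                 n_frames = 1200, p_active = 0.3,
                                 background_rate = 0.005, seed = 1) {
  members <- split(seq_len(k * size), rep(seq_len(k), each = size))
  spec <- ensemble_raster_spec(
    n_cells = n_cells, n_frames = n_frames, frame_rate = 20,
    ensembles = lapply(members, function(m)
      list(members = m, p_active = p_active, amplitude = 0.5)),
    background_rate = background_rate, seed = seed
  )
  generate_calcium_raster(spec)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Mean best-match Jaccard of recovered vs planted memberships.
membership_jaccard <- function(recovered, planted) {
  mean(vapply(planted, function(g) {
    v <- vapply(recovered, function(m) jaccard(g, m), numeric(1))
    if (length(v)) max(v) else 0
  }, numeric(1)))
}

# Dominant FFT frequency of a vector.
peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * fs / n
}

# Band power from the FFT, for filter oracles.
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  sum(Mod(fft(x))[keep]^2)
}

# Tiny network for structural tests.
small_network <- function(ny = 20, nx = 20, seed = 1, ...) {
  build_network(network_config(grid_shape = c(ny, nx), seed = seed, ...))
}
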