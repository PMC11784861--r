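# CSD, spectrograms, band-power ratios, laminar power profiles, sink
# bootstrap.

test_that("CSD annihilates affine depth profiles and is linear", {
  z <- 1:16
  affine <- outer(3 + 2 * z, rep(1, 50))
  lam <- laminar_lfp(affine, dz_um = 50, fs = 1000)
  cs <- csd(lam)
  interior <- 3:14  # boundary rows are Vaknin estimates, not second differences
  expect_lt(max(abs(cs[interior, ])), 1e-9)
  # linearity to machine precision
  set.seed(3)
  v1 <- matrix(rnorm(16 * 50), 16)
  v2 <- matrix(rnorm(16 * 50), 16)
  lhs <- csd(2 * v1 - 3 * v2, dz_um = 50)
  rhs <- 2 * csd(v1, dz_um = 50) - 3 * csd(v2, dz_um = 50)
  expect_equal(unclass(lhs), unclass(rhs), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("CSD recovers curvature of a quadratic profile", {
  # V = z^2 (dz = 1 mm): second derivative is 2 at interior channels
  v <- outer((1:12)^2, rep(1, 5))
  cs <- csd(v, n = 2, dz_um = 1000)
  expect_equal(unname(cs[3:10, 1]), rep(2, 8), tolerance = 1e-9)
})

test_that("planted dipole sink is localized at the planted channel", {
  lam <- generate_laminar_lfp(laminar_dipole_spec(sink_depth = 8,
                                                  source_depth = 12))
  gt <- attr(lam, "ground_truth")
  cs <- csd(lam, n = 1)
  pk <- which.max(abs(colSums(abs(lam$data))))
  expect_equal(which.min(cs[, pk]), gt$sink_depth)
  expect_equal(which.max(cs[, pk]), gt$source_depth)
  # adding a depth-linear trend leaves the CSD unchanged
  lam2 <- lam
  lam2$data <- lam$data + outer(5 * seq_len(nrow(lam$data)),
                                rep(1, ncol(lam$data)))
  int1 <- 2:15
  expect_equal(unclass(csd(lam2, n = 1))[int1, ],
               unclass(csd(lam, n = 1))[int1, ], tolerance = 1e-9)
})

test_that("Morlet spectrogram ridges track tones and chirps", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  expect_warning(
    tf <- time_frequency(cos(2 * pi * 20 * t), fs, f_range = c(2, 100)),
    "support")
  ridge <- tf$freq[apply(tf$power[, 200:800], 2, which.max)]
  expect_true(all(abs(ridge - 20) / 20 < 0.1))
  # chirp 5 -> 40 Hz: monotonically rising ridge
  f_inst <- 5 + (40 - 5) * t / max(t)
  chirp <- cos(2 * pi * cumsum(f_inst) / fs)
  tfc <- suppressWarnings(time_frequency(chirp, fs, f_range = c(2, 100)))
  ridge_c <- tfc$freq[apply(tfc$power[, seq(100, 900, 50)], 2, which.max)]
  expect_true(all(diff(ridge_c) >= 0))
  expect_true(all(suppressWarnings(
    time_frequency(numeric(500), fs, f_range = c(5, 100)))$power == 0))
})

test_that("band-power ratios respond to planted band structure", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  # equal-amplitude beta (20 Hz) and gamma (60 Hz) tones -> ratio ~ 1
  x <- cos(2 * pi * 20 * t) + cos(2 * pi * 60 * t)
  tf <- suppressWarnings(time_frequency(x, fs, f_range = c(3, 100)))
  tf$t <- t - 0.3
  r <- band_power_ratios(tf, windows = list(early = c(0, 0.06),
                                            late = c(0.1, 0.2)))
  expect_equal(r$beta_gamma[1], r$beta_gamma[2], tolerance = 0.2)
  # theta injected late only raises the late theta/gamma ratio
  x2 <- cos(2 * pi * 60 * t) + 2 * cos(2 * pi * 8 * t) * (t > 0.4)
  tf2 <- suppressWarnings(time_frequency(x2, fs, f_range = c(3, 100)))
  tf2$t <- t - 0.3
  r2 <- band_power_ratios(tf2, windows = list(early = c(0, 0.06),
                                              late = c(0.15, 0.25)))
  expect_gt(r2$theta_gamma[2], 2 * r2$theta_gamma[1])
  # pure gamma -> both ratios near zero
  tf3 <- suppressWarnings(time_frequency(cos(2 * pi * 60 * t), fs, f_range = c(3, 100)))
  tf3$t <- t - 0.3
  r3 <- band_power_ratios(tf3)
  expect_lt(max(r3$beta_gamma, r3$theta_gamma), 0.05)
})

test_that("relative power profile is gain-invariant with column maxima 1", {
  spec <- laminar_dipole_spec(sink_depth = 5, source_depth = 11,
                              noise_sd = 0.5, seed = 2)
  lam <- generate_laminar_lfp(spec)
  rp <- relative_power_profile(lam, touch_time = 0.15, window = c(-0.1, 0.2))
  expect_true(all(apply(rp$rel_power, 2, max, na.rm = TRUE) == 1))
  expect_true(all(rp$rel_power >= 0 & rp$rel_power <= 1, na.rm = TRUE))
  lam2 <- lam
  lam2$data <- lam$data * 7.3
  rp2 <- relative_power_profile(lam2, touch_time = 0.15, window = c(-0.1, 0.2))
  expect_equal(rp$rel_power, rp2$rel_power, tolerance = 1e-12)
})

test_that("sink bootstrap recovers a planted magnitude ratio", {
  # trials x channels x samples with sink amplitude 3:1 between classes
  base <- generate_laminar_lfp(laminar_dipole_spec(
    sink_depth = 4, source_depth = 10,
    time_course = function(t) exp(-((t - 0.15) / 0.03)^2)))
  v <- base$data
  n_tr <- 24
  trials <- array(0, c(n_tr, nrow(v), ncol(v)))
  set.seed(9)
  for (i in 1:n_tr) {
    amp <- if (i <= 12) 3 else 1
    trials[i, , ] <- amp * v + matrix(rnorm(length(v), sd = 0.005), nrow(v))
  }
  labels <- rep(c("strong", "weak"), each = 12)
  bs <- sink_bootstrap(trials, labels, dz_um = 50, fs = 1000,
                       touch_idx = 500, late_window = c(0.1, 0.3),
                       superficial_channels = 2:6, n_iter = 20,
                       n_per_draw = 10, seed = 4)
  expect_equal(median(bs$strong) / median(bs$weak), 3, tolerance = 0.15)
  expect_true(all(bs$strong < 0))
  # deterministic under a fixed seed
  bs2 <- sink_bootstrap(trials, labels, dz_um = 50, fs = 1000,
                        touch_idx = 500, late_window = c(0.1, 0.3),
                        superficial_channels = 2:6, n_iter = 20,
                        n_per_draw = 10, seed = 4)
  expect_identical(bs, bs2)
})
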