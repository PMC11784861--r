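# Filtering, notch bank, downsampling, and the trial-inclusion rule.

tone_lfp <- function(f, fs = 1000, dur = 2, extra = NULL) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * f * t)
  if (!is.null(extra)) x <- x + extra(t)
  grid_lfp(matrix(rep(x, 4), nrow = 4, byrow = TRUE),
           cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)), fs)
}

test_that("named bands match the canonical definitions", {
  expect_equal(analysis_band("gamma"), c(30, 90))
  expect_equal(analysis_band("beta"), c(15, 30))
  expect_equal(analysis_band("theta"), c(4, 12))
  expect_equal(analysis_band("wideband"), c(3, 40))
})

test_that("in-band tones pass with unit gain and zero phase shift", {
  lfp <- tone_lfp(10)
  out <- bandpass(lfp, "wideband")
  mid <- 500:1500
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.01)
  # zero-phase: cross-correlation peak lag is 0 samples
  cc <- ccf(out$data[1, mid], lfp$data[1, mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("out-of-band power is attenuated by at least 20 dB", {
  lfp <- tone_lfp(80)  # 2x the 40 Hz wideband edge
  out <- bandpass(lfp, "wideband")
  p_in <- fft_band_power(lfp$data[1, ], 1000, 78, 82)
  p_out <- fft_band_power(out$data[1, ], 1000, 78, 82)
  expect_lt(10 * log10(p_out / p_in), -20)
})

test_that("notch bank removes 30 Hz harmonics and preserves the rest", {
  fs <- 2000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 90 * t) + cos(2 * pi * 10 * t)
  lfp <- grid_lfp(matrix(x, nrow = 1), cbind(0, 0), fs)
  out <- remove_scan_artifact(lfp)
  p90 <- fft_band_power(out$data[1, ], fs, 89, 91) /
    fft_band_power(lfp$data[1, ], fs, 89, 91)
  p10 <- fft_band_power(out$data[1, ], fs, 9, 11) /
    fft_band_power(lfp$data[1, ], fs, 9, 11)
  expect_lt(10 * log10(p90), -20)
  expect_equal(p10, 1, tolerance = 0.05)
  # harmonic-free content is nearly untouched
  x2 <- cos(2 * pi * 7 * t) + cos(2 * pi * 44 * t)
  lfp2 <- grid_lfp(matrix(x2, nrow = 1), cbind(0, 0), fs)
  out2 <- remove_scan_artifact(lfp2)
  mid <- 500:3500  # away from filter edge transients
  rel_rms <- sqrt(mean((out2$data[1, mid] - lfp2$data[1, mid])^2)) /
    sqrt(mean(lfp2$data[1, mid]^2))
  expect_lt(rel_rms, 0.02)
  # zero in, zero out
  z <- grid_lfp(matrix(0, 1, fs), cbind(0, 0), fs)
  expect_true(all(remove_scan_artifact(z)$data == 0))
})

test_that("downsampling preserves sample count ratio and tone amplitude", {
  fs <- 25000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  lfp <- grid_lfp(matrix(cos(2 * pi * 5 * t), nrow = 1), cbind(0, 0), fs)
  out <- downsample(lfp, 1000)
  expect_equal(ncol(out$data), ncol(lfp$data) / 25)
  expect_equal(out$fs, 1000)
  expect_equal(max(abs(out$data[1, 200:800])), 1, tolerance = 0.01)
  expect_identical(downsample(lfp, fs), lfp)
})

test_that("trial-inclusion rule follows the 3x prestimulus SD threshold", {
  wave <- wave_field_spec(noise_sd = 5)
  # evoked peak ~16x the baseline SD in one trial, absent in the other
  spec <- trial_set_spec(n_trials = 10, early_amp = 80,
                         responsive_fraction = 0.5, late_amp = 0, seed = 11)
  lfp <- generate_trial_lfp(spec, wave)
  gt <- attr(lfp, "ground_truth")
  ep <- epoch_and_filter_trials(lfp, gt$touch_times)
  expect_identical(unname(ep$responsive_mask), gt$responsive)
  # without an evoked deflection the rule almost never fires
  spec2 <- trial_set_spec(n_trials = 6, early_amp = 0, late_amp = 0, seed = 2)
  lfp2 <- generate_trial_lfp(spec2, wave)
  ep2 <- epoch_and_filter_trials(lfp2, attr(lfp2, "ground_truth")$touch_times)
  expect_lte(sum(ep2$responsive_mask), 1)
})

test_that("out-of-record trials are dropped with a message", {
  wave <- wave_field_spec(noise_sd = 5)
  spec <- trial_set_spec(n_trials = 4, seed = 1)
  lfp <- generate_trial_lfp(spec, wave)
  expect_message(
    ep <- epoch_and_filter_trials(lfp, c(attr(lfp, "ground_truth")$touch_times,
                                         1e4)),
    "dropped")
  expect_equal(length(ep$touch_times), 4)
  expect_equal(ep$dropped, 5L)
})
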