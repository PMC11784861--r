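# Evaluation points, source localization, circular-linear correlation,
# kinematics, PGD, late-wave classification, and the count bootstrap.

test_that("a 1-s 10 Hz tone yields ten -pi/2 crossings minus edge exclusion", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  lfp <- grid_lfp(matrix(rep(cos(2 * pi * 10 * t), 4), 4, byrow = TRUE),
                  cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)), fs)
  fld <- gp_correct(analytic_signal(lfp))
  ep <- find_evaluation_points(fld)
  # 10 crossings in 1 s, minus up to 2 lost to the 100-ms edge exclusion
  expect_gte(length(ep), 8)
  expect_lte(length(ep), 10)
  # each crossing sits where the phase passes -pi/2 rising
  expect_true(all(fld$phase[1, ep] >= -pi / 2 - 0.1))
  expect_true(all(fld$phase[1, ep - 1L] < -pi / 2))
})

test_that("radial source is localized on the planted electrode", {
  wf <- make_wave_field(geometry = "radial", noise_sd = 0, seed = 3)
  src <- attr(wf$lfp, "ground_truth")$source
  ep <- find_evaluation_points(wf$field)
  hits <- vapply(ep, function(t) source_point(wf$field, t) == src, logical(1))
  expect_true(all(hits))
})

test_that("divergence is ~0 for a plane wave (direct finite-difference oracle)", {
  wf <- make_wave_field(noise_sd = 0, seed = 1)
  ep <- find_evaluation_points(wf$field)
  s <- source_point(wf$field, ep[3], smooth = FALSE)
  D <- attr(s, "divergence")
  # oracle: the planted phase is linear in x, so any second difference of
  # the gradient field is 0; allow tiny numerical residue away from edges
  expect_lt(max(abs(D), na.rm = TRUE), 1e-4 * max(abs(wf$field$phase)))
})

test_that("circular-linear correlation matches a grid-search oracle", {
  set.seed(5)
  d <- runif(30)
  phase <- ((4 * d + 0.7 + rnorm(30, sd = 0.2)) + pi) %% (2 * pi) - pi
  rho <- circ_linear_corr(phase, d)
  # independent oracle: maximize Pearson cor(d, cos(phase - a)) over a
  a_grid <- seq(0, 2 * pi, length.out = 2000)
  oracle <- max(vapply(a_grid, function(a) cor(d, cos(phase - a)), numeric(1)))
  expect_equal(rho, oracle, tolerance = 1e-3)
  # perfect linear phase-distance relation
  expect_gt(circ_linear_corr(2 * d, d), 0.999)
  # invariances: global phase offset and rigid coordinate translation
  expect_equal(circ_linear_corr(((phase + 1.1 + pi) %% (2 * pi)) - pi, d), rho,
               tolerance = 1e-10)
  expect_lt(circ_linear_corr(phase, d + 100) - rho, 1e-10)
  expect_true(is.na(circ_linear_corr(phase[1:4], d[1:4])))
})

test_that("wavenumber/speed follow v = 2*pi*f/k on planted waves", {
  # formula arithmetic: k = 209.4 rad/m at 10 Hz gives 0.300 m/s
  expect_equal(2 * pi * 10 / 209.4395, 0.3, tolerance = 1e-6)
  wf <- make_wave_field(f0 = 10, speed = 0.3, noise_sd = 5, seed = 2)
  wv <- detect_waves(wf$wb, field = wf$field, n_shuffles = 200, seed = 1)
  expect_gt(nrow(wv), 0)
  expect_true(all(abs(wv$v_m_per_s - 0.3) / 0.3 < 0.15))
  expect_true(all(wv$rho >= attr(wv, "null")$threshold))
})

test_that("below-threshold candidates are rejected", {
  wf <- make_wave_field(noise_sd = 0, seed = 1)
  ep <- find_evaluation_points(wf$field)
  null_hi <- structure(list(rho = 1, threshold = 1.01, n_shuffles = 0),
                       class = "wave_null")
  expect_null(classify_and_measure(ep[1], wf$field, wf$wb, null_hi))
})

test_that("null threshold is reproducible and controls false positives", {
  wf <- make_wave_field(seed = 6)
  ep <- find_evaluation_points(wf$field)
  n1 <- build_null(wf$field, ep, n_shuffles = 100, seed = 9)
  n2 <- build_null(wf$field, ep, n_shuffles = 100, seed = 9)
  expect_identical(n1$threshold, n2$threshold)
  expect_true(n1$threshold > 0 && n1$threshold < 1)
  # channel-shuffled phases almost never reach the threshold
  d <- sqrt(rowSums(wf$field$coords^2))
  hits <- with_seed(31, {
    vapply(1:300, function(i) {
      ph <- wf$field$phase[sample.int(64), ep[1]]
      circ_linear_corr(ph, d) >= n1$threshold
    }, logical(1))
  })
  expect_lte(mean(hits), 0.03)
})

test_that("PGD is 1 for a plane wave and low for random gradients", {
  wf <- make_wave_field(noise_sd = 0, seed = 1)
  ep <- find_evaluation_points(wf$field)
  expect_equal(pgd(wf$field, ep[2]), 1, tolerance = 1e-6)
  # radial wave has lower PGD than the plane wave on the same grid
  wr <- make_wave_field(geometry = "radial", noise_sd = 0, seed = 1)
  epr <- find_evaluation_points(wr$field)
  expect_lt(pgd(wr$field, epr[2]), pgd(wf$field, ep[2]))
  # i.i.d. random directions on 64 sites concentrate near 1/sqrt(64)
  draws <- with_seed(8, vapply(1:2000, function(i) {
    a <- runif(64, 0, 2 * pi)
    pgd_vectors(cos(a), sin(a))
  }, numeric(1)))
  expect_equal(mean(draws), 0.11, tolerance = 0.02)
  expect_lt(quantile(draws, 0.99), 0.35)
})

test_that("late-wave classification uses the strict 3 SD rule", {
  wave <- wave_field_spec(noise_sd = 5)
  spec <- trial_set_spec(n_trials = 6, early_amp = 60,
                         late_amp = c(0, 50, 0, 50, 0, 50),
                         late_window = c(0.1, 0.18), seed = 3)
  lfp <- generate_trial_lfp(spec, wave)
  gt <- attr(lfp, "ground_truth")
  ep <- epoch_and_filter_trials(lfp, gt$touch_times)
  lab <- classify_late_wave(ep, late_window = c(0.08, 0.2))
  expect_identical(as.vector(lab == "strong"), gt$strong_late)
  # exact ties are weak: synthetic epochs object with a flat peak at 3 SD
  fake <- structure(
    list(epochs = array(rep(c(numeric(500), rep(3, 200)), each = 1),
                        c(1, 1, 700)),
         baseline_sd = matrix(1, 1, 1), reference_channel = 1L,
         window = c(0.5, 0.2), fs = 1000,
         responsive_mask = TRUE, touch_times = 0.5),
    class = "trial_epochs")
  expect_identical(as.vector(classify_late_wave(fake)), "weak")
})

test_that("late-wave amplitude is trough-to-peak and linear", {
  fs <- 1000
  t <- seq(-0.5, 0.5, by = 1 / fs)
  x <- numeric(length(t))
  x[t >= 0.10 & t < 0.12] <- -20
  x[t >= 0.17 & t < 0.19] <- 40
  amp <- late_wave_amplitude(x, fs, touch_idx = which(t == 0))
  expect_equal(amp, 60)
  expect_equal(late_wave_amplitude(2 * x, fs, which(t == 0)), 120)
  expect_lt(abs(late_wave_amplitude(numeric(length(t)) + 1e-9, fs,
                                    which(t == 0))), 1e-6)
})

test_that("windowed wave-count bootstrap recovers a planted rate ratio", {
  set.seed(12)
  # Poisson wave trains with a 2:1 rate ratio between interval classes
  w1 <- cumsum(rexp(400, rate = 40))
  w2 <- cumsum(rexp(400, rate = 20))
  res <- windowed_wave_count_bootstrap(
    c(w1, 100 + w2),
    intervals = list(pre = rbind(c(0, min(9, max(w1)))),
                     post = rbind(c(100, 100 + min(18, max(w2))))),
    n_iter = 3000, seed = 5)
  expect_equal(mean(res$pre) / mean(res$post), 2, tolerance = 0.25)
  # single iteration with a fixed seed is deterministic
  a <- windowed_wave_count_bootstrap(w1, list(a = rbind(c(0, 5)),
                                              b = rbind(c(5, 9))),
                                     n_iter = 1, seed = 2)
  b <- windowed_wave_count_bootstrap(w1, list(a = rbind(c(0, 5)),
                                              b = rbind(c(5, 9))),
                                     n_iter = 1, seed = 2)
  expect_identical(a, b)
  # intervals shorter than the window are skipped
  expect_message(
    windowed_wave_count_bootstrap(w1, list(a = rbind(c(0, 0.01), c(1, 2)),
                                           b = rbind(c(3, 4))),
                                  n_iter = 10, seed = 1),
    "skipped")
})
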