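# Whisker kinematics, touch detection, interval filtering, outcomes, d'.

test_that("Menger curvature matches hand-computed cases and invariances", {
  expect_equal(menger_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  # points on the unit circle: curvature 1
  expect_equal(menger_curvature(c(1, 0), c(0, 1), c(-1, 0)), 1,
               tolerance = 1e-12)
  expect_true(is.na(menger_curvature(c(1, 1), c(1, 1), c(0, 0))))
  # rigid rotation/translation invariance; similarity scaling law c -> c/s
  rot <- function(p, a, d) c(cos(a) * p[1] - sin(a) * p[2] + d[1],
                             sin(a) * p[1] + cos(a) * p[2] + d[2])
  p1 <- c(0.3, 1); p2 <- c(1.1, 0.2); p3 <- c(2, 1.4)
  c0 <- menger_curvature(p1, p2, p3)
  c1 <- menger_curvature(rot(p1, 0.7, c(5, -2)), rot(p2, 0.7, c(5, -2)),
                         rot(p3, 0.7, c(5, -2)))
  expect_equal(c0, c1, tolerance = 1e-12)
  expect_equal(menger_curvature(3 * p1, 3 * p2, 3 * p3), c0 / 3,
               tolerance = 1e-12)
})

test_that("whisker phase advances one cycle per whisking period", {
  spec <- behavior_spec(whisk_freq = 8, duration = 2, touch_episodes = NULL,
                        whisk_amp = 60)
  pose <- generate_whisker_traces(spec)
  wp <- whisker_phase(pose, 500, pad = c(0, 0), angle_label = 1)
  interior <- 200:800
  ph <- wp$phase[interior]
  un <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi))
  cycles <- (un[length(un)] - un[1]) / (2 * pi)
  expect_equal(cycles, 8 * (length(interior) - 1) / 500 / 1, tolerance = 0.1)
  # phase ~0 at maximal protraction (angle maxima)
  peaks <- which(diff(sign(diff(wp$filtered))) == -2) + 1L
  peaks <- peaks[peaks > 200 & peaks < 800]
  expect_lt(max(abs(wp$phase[peaks])), 0.2)
})

test_that("ROI touch detection recovers the planted episodes", {
  spec <- behavior_spec(touch_episodes = rbind(c(0.5, 0.6), c(1.2, 1.35)),
                        duration = 2, frame_rate = 500)
  pose <- generate_whisker_traces(spec)
  gt <- attr(pose, "ground_truth")
  touches <- detect_touches(pose, gt$roi_polygon)
  expect_equal(nrow(touches), 2)
  expect_equal(touches$touch_frame, c(251, 601))
  # two one-frame grazes 10 frames apart are two touches
  graze <- pose
  inframe <- pose$frame %in% c(50, 60) & pose$label == 4
  graze$x_px[inframe] <- mean(gt$roi_polygon[, 1])
  graze$y_px[inframe] <- mean(gt$roi_polygon[, 2])
  t2 <- detect_touches(graze, gt$roi_polygon)
  expect_true(all(c(50, 60) %in% t2$touch_frame))
})

test_that("interval filter keeps first touch and >100 ms gaps, idempotently", {
  # touches at 0, 50, 200 ms -> keep 0 and 200
  kept <- filter_touch_intervals(c(0, 50, 200), frame_rate = 1000)
  expect_equal(kept, c(0, 200))
  all_far <- c(0, 150, 300, 450)
  expect_equal(filter_touch_intervals(all_far, 1000), all_far)
  # idempotence and brute-force oracle on a Poisson train
  set.seed(7)
  train <- sort(cumsum(rexp(200, rate = 20)))  # seconds, rate 20 Hz
  kept1 <- filter_touch_intervals(train, frame_rate = 1)
  expect_identical(filter_touch_intervals(kept1, frame_rate = 1), kept1)
  oracle <- train[1]
  for (tt in train[-1]) if (tt - oracle[length(oracle)] > 0.1)
    oracle <- c(oracle, tt)
  expect_equal(kept1, oracle)
})

test_that("d-prime matches the normal-quantile oracle and is antisymmetric", {
  expect_equal(dprime(0.8, 0.2), qnorm(0.8) - qnorm(0.2), tolerance = 1e-12)
  expect_equal(dprime(0.8, 0.2), 1.683, tolerance = 1e-3)
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.7, 0.3), -dprime(0.3, 0.7), tolerance = 1e-12)
  expect_message(d <- dprime(1, 0.2, n_go = 50), "clamped")
  expect_equal(d, qnorm(1 - 1 / 100) - qnorm(0.2), tolerance = 1e-12)
  expect_error(dprime(1, 0.2), "trial count")
})

test_that("outcome classification reproduces planted rates and d-prime", {
  set.seed(4)
  n <- 100
  stimuli <- rep(c("go", "nogo"), each = n / 2)
  starts <- seq_len(n) * 3
  # planted: hit rate 0.8, false-alarm rate 0.3
  lick <- c(runif(n / 2) < 0.8, runif(n / 2) < 0.3)
  lick_times <- starts[lick] + 0.6
  out <- classify_outcomes(stimuli, starts, lick_times)
  hr <- attr(out, "hit_rate"); fr <- attr(out, "fa_rate")
  expect_equal(sum(out$outcome == "hit"), hr * n / 2)
  expect_equal(attr(out, "dprime"), qnorm(hr) - qnorm(fr), tolerance = 1e-12)
  expect_identical(out$outcome[out$stimulus == "nogo" & !out$lick][1], "CR")
  # a lick outside every window does not create an outcome
  out2 <- classify_outcomes("nogo", 0, lick_times = 5)
  expect_identical(out2$outcome, "CR")
})
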