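# Ensemble pipeline: centering, binarization, vectorization, similarity,
# shuffles, eigen gate, Dice connectivity, grouping, and transient onsets.

test_that("fluorescence centering follows the range-normalized formula", {
  f <- rbind(ramp = seq(0, 1, length.out = 11),
             flat = rep(2, 11),
             two = c(rep(0, 5), rep(4, 6)))
  cf <- center_fluorescence(f)
  expect_equal(range(cf[1, ]), c(-0.5, 0.5))
  expect_equal(unname(attr(cf, "excluded")), 2L)
  expect_true(all(is.na(cf[2, ])))
  # frames at the cell's own mean center to 0
  expect_equal(unname(cf[1, 6]), 0)
})

test_that("binarization keeps strong events and drops weak ones", {
  raster <- make_ensemble_raster(seed = 2)
  b <- binarize_events(raster)
  # planted amplitude (0.5) is far above 2.5x the noise floor (0.05)
  expect_equal(unname(b), unname(raster$deconv > 0), ignore_attr = TRUE)
  # events at the noise scale are dropped
  weak <- raster
  weak$deconv <- raster$deconv / 10
  bw <- binarize_events(weak)
  expect_equal(sum(bw), 0)
})

test_that("vectorization conserves event counts and bin geometry", {
  raster <- make_ensemble_raster(seed = 4, n_frames = 1203)
  b <- binarize_events(raster)
  expect_message(v <- vectorize_events(b, raster$frame_rate, 300), "partial")
  expect_equal(attr(v, "frames_per_bin"), 6L)  # 20 Hz x 0.3 s
  expect_equal(sum(v), sum(b[, 1:1200]))
  # a single event lands in exactly one vector entry
  single <- matrix(FALSE, 3, 30); single[2, 17] <- TRUE
  vs <- vectorize_events(single, 10, 300)
  expect_equal(sum(vs > 0), 1)
  expect_equal(unname(vs[2, 6]), 1)
})

test_that("cosine similarity map matches hand-computed values", {
  v <- cbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(2, 2, 0), z = c(0, 0, 0))
  si <- similarity_map(v)
  expect_equal(si["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(si["a", "c"], 1, tolerance = 1e-12)
  expect_equal(si["a", "a"], 1, tolerance = 1e-12)
  expect_true(all(is.na(si[, "z"])))
  expect_equal(si, t(si))
  # orthogonal vectors
  expect_equal(similarity_map(cbind(c(1, 0), c(0, 1)))[1, 2], 0)
})

test_that("shuffle surrogates preserve per-neuron event counts", {
  raster <- make_ensemble_raster(seed = 5, n_cells = 40, n_frames = 300)
  b <- binarize_events(raster)
  # the shuffles only permute within rows and swap whole rows, so the
  # multiset of row sums is invariant; thresholds are reproducible
  n1 <- shuffle_surrogates(b, raster$frame_rate, n_iter = 20, n_eig_iter = 5,
                           seed = 3)
  n2 <- shuffle_surrogates(b, raster$frame_rate, n_iter = 20, n_eig_iter = 5,
                           seed = 3)
  expect_identical(n1$si_threshold, n2$si_threshold)
  expect_identical(n1$eig_threshold, n2$eig_threshold)
  expect_equal(sum(n1$coactivity_null), 20 * sum(b))
})

test_that("Dice connectivity matches brute-force set arithmetic", {
  b <- matrix(FALSE, 3, 12)
  b[1, c(1, 2, 3)] <- TRUE
  b[2, c(2, 3, 5, 7)] <- TRUE
  b[3, c(10, 11)] <- TRUE
  conn <- sdc_connectivity(b, 1:12, dice_thresh = 0.25, alpha = 1)
  expect_equal(conn$dice[1, 2], 4 / 7, tolerance = 1e-12)
  expect_equal(conn$dice[1, 3], 0)
  b2 <- rbind(b[1, ], b[1, ])
  expect_equal(sdc_connectivity(b2, 1:12, alpha = 1)$dice[1, 2], 1)
})

test_that("planted ensembles are recovered and permutation-equivariant", {
  raster <- make_ensemble_raster(k = 2, seed = 6)
  es <- detect_ensembles(raster, n_shuffles = 100, seed = 7)
  gt <- attr(raster, "ground_truth")$members
  expect_equal(length(es$membership), 2)
  expect_equal(membership_jaccard(es$membership, gt), 1)
  expect_gte(es$n_components, 1)
  # relabeling neurons permutes the recovered memberships identically
  perm <- c(51:200, 1:50)  # move ensemble cells to ids 151:166
  r2 <- raster
  r2$dff <- raster$dff[perm, ]
  r2$deconv <- raster$deconv[perm, ]
  es2 <- detect_ensembles(r2, n_shuffles = 100, seed = 7)
  remapped <- lapply(es2$membership, function(m) sort(perm[m]))
  expect_setequal(
    vapply(remapped, paste, collapse = ",", FUN.VALUE = character(1)),
    vapply(es$membership, paste, collapse = ",", FUN.VALUE = character(1)))
})

test_that("structureless rasters yield no ensembles", {
  zero <- 0
  for (s in 1:5) {
    spec <- ensemble_raster_spec(n_cells = 80, n_frames = 400, frame_rate = 20,
                                 ensembles = list(), background_rate = 0.02,
                                 seed = s)
    es <- detect_ensembles(generate_calcium_raster(spec),
                           n_shuffles = 100, seed = s + 50)
    zero <- zero + (length(es$ensembles) == 0)
  }
  expect_gte(zero, 4)
})

test_that("retained eigenvector columns are orthonormal", {
  raster <- make_ensemble_raster(k = 3, seed = 8)
  b <- binarize_events(raster)
  null <- shuffle_surrogates(b, raster$frame_rate, n_iter = 100,
                             n_eig_iter = 50, seed = 9)
  v <- suppressMessages(vectorize_events(b, raster$frame_rate, 300))
  cand <- svd_ensembles(similarity_map(v), v, null)
  expect_gte(cand$n_components, 1)
  g <- crossprod(cand$components)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8)
})

test_that("group splitting recovers planted connectivity differences", {
  # strong-late frames carry co-active ensembles; weak-late frames are
  # background only, so the strong group must show more connections
  r_strong <- make_ensemble_raster(k = 2, seed = 10, n_frames = 600)
  spec_bg <- ensemble_raster_spec(n_cells = 200, n_frames = 600,
                                  frame_rate = 20, ensembles = list(),
                                  background_rate = 0.02, seed = 11)
  r_weak <- generate_calcium_raster(spec_bg)
  raster <- calcium_raster(cbind(r_strong$dff, r_weak$dff),
                           cbind(r_strong$deconv, r_weak$deconv),
                           r_strong$centroids, 20)
  trial_frames <- c(lapply(0:3, function(i) i * 150 + 1:150),
                    lapply(0:3, function(i) 600 + i * 150 + 1:150))
  labels <- rep(c("strong", "weak"), each = 4)
  grp <- split_by_late_wave(raster, trial_frames, labels,
                            n_shuffles = 100, seed = 12)
  expect_false(grp$strong$flagged)
  expect_gt(sum(grp$strong$n_connections), 0)
  expect_equal(length(grp$weak$ensembles$ensembles), 0)
  # an undersized group is flagged with no metrics
  grp2 <- split_by_late_wave(raster, trial_frames[1:4],
                             c("strong", "strong", "strong", "weak"),
                             n_shuffles = 50, seed = 13)
  expect_true(grp2$weak$flagged)
})

test_that("transient onsets land within a frame of the planted event", {
  spec <- ensemble_raster_spec(
    n_cells = 5, n_frames = 400, frame_rate = 20,
    ensembles = list(list(members = 1:5, p_active = 0, amplitude = 0.5)),
    background_rate = 0, noise_sd = 0.01, seed = 3)
  raster <- generate_calcium_raster(spec)
  # plant one clean event per cell at +150 ms after the second touch
  touch <- c(5, 10)
  ev_frame <- round((10 + 0.15) * 20) + 1L
  raster$deconv[, ev_frame] <- 0.5
  raster$dff <- raster$dff +
    t(vapply(1:5, function(i)
      0.5 * exp(-pmax(0, seq_len(400) - ev_frame) / 10) *
        (seq_len(400) >= ev_frame), numeric(400)))
  res <- transient_onsets(raster, touch, window_s = 1)
  hit <- res$onsets[res$onsets$trial == 2, ]
  expect_equal(nrow(hit), 5)
  expect_true(all(abs(hit$onset_s - 0.15) <= 0.05 + 1e-9))
  # no events in the window -> silent
  expect_equal(nrow(res$onsets[res$onsets$trial == 1, ]), 0)
})

test_that("onset-time bootstrap separates planted dispersions", {
  set.seed(21)
  tight <- rnorm(150, 0.15, 0.03)
  wide <- rnorm(150, 0.15, 0.08)
  sd_t <- onset_sd_bootstrap(tight, n_iter = 800, seed = 1)
  sd_w <- onset_sd_bootstrap(wide, n_iter = 800, seed = 2)
  expect_lt(quantile(sd_t, 0.99), quantile(sd_w, 0.01))
  p <- wilcox.test(sd_t, sd_w)$p.value
  expect_lt(p, 1e-3)
})
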