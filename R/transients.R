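# Touch-evoked calcium transient onset detection (somatic or dendritic).

#' Touch-evoked transient onsets and maximum-slope times
#'
#' Per cell, the event threshold is the 99th percentile of its deconvolved
#' event amplitudes. For each touch, the largest supra-threshold event
#' within `window_s` post-touch is located; its onset is the preceding
#' inflection point of the deconvolved trace (the last frame at which the
#' trace stops declining when walking back from the event), and the time of
#' the maximum dF/F slope around the event is also returned. Cells with no
#' supra-threshold event in the window are silent for that trial. A cell is
#' touch-responsive iff its trial-averaged evoked dF/F maximum within
#' `responsive_window_s` of touch exceeds 3x the pre-touch baseline SD.
#'
#' @param raster A [calcium_raster()].
#' @param touch_times Touch times in seconds.
#' @param window_s Event search window post-touch (default 1; use longer for
#'   dendrites).
#' @param responsive_window_s Window for the touch-responsive flag (s).
#' @param baseline_s Pre-touch baseline for the responsive flag (s).
#' @return List with `onsets`: data.frame (`cell`, `trial`, `onset_s`,
#'   `max_slope_s`, `event_s`, `amplitude`) of non-silent cell-trials
#'   (times are relative to touch); `responsive`: logical per cell;
#'   `event_threshold`: per cell.
#' @export
transient_onsets <- function(raster, touch_times, window_s = 1,
                             responsive_window_s = 2, baseline_s = 0.5) {
  fr <- raster$frame_rate
  n_cells <- nrow(raster$deconv); n_frames <- ncol(raster$deconv)
  thr <- vapply(seq_len(n_cells), function(i) {
    ev <- raster$deconv[i, raster$deconv[i, ] > 0]
    if (!length(ev)) Inf else quantile(ev, 0.99, names = FALSE)
  }, numeric(1))
  rows <- list()
  for (tr in seq_along(touch_times)) {
    f0 <- round(touch_times[tr] * fr) + 1L
    f1 <- min(f0 + round(window_s * fr), n_frames)
    if (f0 >= f1) next
    for (i in seq_len(n_cells)) {
      seg <- raster$deconv[i, f0:f1]
      supra <- which(seg >= thr[i] & seg > 0)
      if (!length(supra)) next
      pk <- supra[which.max(seg[supra])]
      pk_abs <- f0 + pk - 1L
      # preceding inflection point: walk back while the trace declines
      j <- pk_abs
      while (j > 1L && raster$deconv[i, j - 1L] < raster$deconv[i, j] &&
             raster$deconv[i, j - 1L] > 0) j <- j - 1L
      if (j > 1L && raster$deconv[i, j - 1L] == 0) j <- j - 1L
      onset_abs <- j
      # max dF/F slope between onset and shortly after the event
      s0 <- max(onset_abs - 1L, 1L)
      s1 <- min(pk_abs + round(0.2 * fr), n_frames - 1L)
      sl <- diff(raster$dff[i, s0:(s1 + 1L)])
      ms_abs <- s0 + which.max(sl) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cell = i, trial = tr,
        onset_s = (onset_abs - 1L) / fr - touch_times[tr],
        max_slope_s = (ms_abs - 1L) / fr - touch_times[tr],
        event_s = (pk_abs - 1L) / fr - touch_times[tr],
        amplitude = seg[pk]
      )
    }
  }
  onsets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), trial = integer(0), onset_s = numeric(0),
               max_slope_s = numeric(0), event_s = numeric(0),
               amplitude = numeric(0))
  # touch-responsive flag from the trial-averaged evoked dF/F
  n_pre <- round(baseline_s * fr); n_post <- round(responsive_window_s * fr)
  keep <- round(touch_times * fr) + 1L
  keep <- keep[keep - n_pre >= 1L & keep + n_post <= n_frames]
  responsive <- rep(FALSE, n_cells)
  if (length(keep)) {
    for (i in seq_len(n_cells)) {
      ep <- vapply(keep, function(f0)
        raster$dff[i, (f0 - n_pre):(f0 + n_post)], numeric(n_pre + n_post + 1L))
      avg <- rowMeans(ep)
      base_sd <- sd(avg[seq_len(n_pre)])
      evoked <- avg[(n_pre + 1L):length(avg)] - mean(avg[seq_len(n_pre)])
      responsive[i] <- base_sd > 0 && max(evoked) > 3 * base_sd
    }
  }
  list(onsets = onsets, responsive = responsive, event_threshold = thr)
}

#' Bootstrap the dispersion of transient onset times
#'
#' Resamples `n_cells_draw` onset times (with replacement) `n_iter` times
#' and returns the SD of each draw; used to compare onset-time dispersion
#' between trial classes.
#'
#' @param onset_times Vector of onset times (s).
#' @param n_iter Resamples (default 10000).
#' @param n_cells_draw Draw size (default 100).
#' @param seed RNG seed.
#' @return Numeric vector of `n_iter` SDs.
#' @export
onset_sd_bootstrap <- function(onset_times, n_iter = 10000,
                               n_cells_draw = 100, seed = 1) {
  with_seed(seed, {
    vapply(seq_len(n_iter), function(i)
      sd(sample(onset_times, n_cells_draw, replace = TRUE)), numeric(1))
  })
}
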