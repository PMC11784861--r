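# Wave-level summary metrics: phase-gradient directionality, late-wave trial
# classification, late-wave amplitude, and the windowed wave-count bootstrap.

#' Phase-gradient directionality (PGD)
#'
#' `PGD = ||mean of per-site phase-gradient vectors|| / mean of per-site
#' gradient norms`. 1 means perfectly aligned propagation; random gradient
#' directions give values near `1/sqrt(n)`.
#'
#' @param field An [analytic_field()].
#' @param t Sample index.
#' @return PGD in `[0, 1]`, or `NA` if all gradients vanish.
#' @export
pgd <- function(field, t) {
  lat <- lattice_index(field$coords)
  if (lat$rows < 3 || lat$cols < 3)
    stop("PGD needs at least a 3x3 grid", call. = FALSE)
  pv <- field$phase[, t]
  pv[!field$mask[, t]] <- NA
  g <- phase_gradient(pv, lat)
  pgd_vectors(as.numeric(g$gx), as.numeric(g$gy))
}

#' @rdname pgd
#' @param gx,gy Gradient vector components at each site.
#' @export
pgd_vectors <- function(gx, gy) {
  ok <- is.finite(gx) & is.finite(gy)
  gx <- gx[ok]; gy <- gy[ok]
  norms <- sqrt(gx^2 + gy^2)
  if (!length(norms) || mean(norms) == 0) return(NA_real_)
  sqrt(mean(gx)^2 + mean(gy)^2) / mean(norms)
}

#' Classify trials by late-wave strength
#'
#' A trial has a detectable (strong) late wave iff the maximum amplitude of
#' the prestimulus-mean-normalized LFP in the late window on the reference
#' channel strictly exceeds `k_sd` times the prestimulus SD; ties and
#' everything below are weak.
#'
#' @param epochs A `trial_epochs` from [epoch_and_filter_trials()] (epochs
#'   are already baseline-mean subtracted).
#' @param late_window `c(start, end)` seconds post-touch; default the
#'   passive-touch window 0.08-0.2 s (use ~0.05-0.1 s for active touch).
#' @param k_sd Threshold multiple of the prestimulus SD (default 3).
#' @return Character vector `"strong"`/`"weak"` per trial, with attribute
#'   `late_amp` (the measured window maxima).
#' @export
classify_late_wave <- function(epochs, late_window = c(0.08, 0.2), k_sd = 3) {
  stopifnot(inherits(epochs, "trial_epochs"))
  fs <- epochs$fs
  n_pre <- round(epochs$window[1] * fs)
  if (n_pre < 1) stop("missing prestimulus window", call. = FALSE)
  idx <- (n_pre + round(late_window[1] * fs)):(n_pre + round(late_window[2] * fs))
  idx <- idx[idx <= dim(epochs$epochs)[3]]
  ref <- epochs$reference_channel
  late_amp <- apply(epochs$epochs[, ref, idx, drop = FALSE], 1, max)
  lab <- ifelse(late_amp > k_sd * epochs$baseline_sd[, ref], "strong", "weak")
  structure(lab, late_amp = late_amp)
}

#' Trough-to-peak amplitude of the late wave
#'
#' On a trial-averaged single-channel trace, finds the late trough after the
#' annotated approximate onset, then the maximum inside the late peak window
#' (default 0.1-0.3 s post-touch); returns peak minus trough.
#'
#' @param avg_lfp Trial-averaged LFP for one channel (vector).
#' @param fs Sampling rate (Hz).
#' @param touch_idx Sample index of touch in `avg_lfp`.
#' @param onset_hint_s Approximate late-wave onset, seconds post-touch; the
#'   trough is searched between it and the peak window end.
#' @param peak_window `c(start, end)` seconds post-touch for the peak.
#' @return Trough-to-peak amplitude (uV), or `NA` if no trough precedes the
#'   peak.
#' @export
late_wave_amplitude <- function(avg_lfp, fs, touch_idx, onset_hint_s = 0.08,
                                peak_window = c(0.1, 0.3)) {
  i0 <- touch_idx + round(onset_hint_s * fs)
  i2 <- min(touch_idx + round(peak_window[2] * fs), length(avg_lfp))
  i1 <- touch_idx + round(peak_window[1] * fs)
  if (i0 >= i2 || i1 >= i2) return(NA_real_)
  seg <- avg_lfp[i0:i2]
  trough_rel <- which.min(seg)
  trough <- seg[trough_rel]
  peak_lo <- max(i1, i0 + trough_rel - 1L)
  if (peak_lo > i2) return(NA_real_)
  peak <- max(avg_lfp[peak_lo:i2])
  peak - trough
}

#' Bootstrap wave counts in random short windows
#'
#' For each interval class, draws `n_iter` random `window_s` windows inside
#' the class's intervals and counts detected waves per window; the per-class
#' count distributions feed a downstream rank-sum comparison.
#'
#' @param wave_times Numeric vector of wave times (s).
#' @param intervals Named list of interval sets, each a 2-column matrix of
#'   `(start, end)` times in seconds.
#' @param n_iter Resamples per class (default 10000).
#' @param window_s Window length in seconds (default 0.05).
#' @param seed RNG seed.
#' @return Named list of integer count vectors, one per class. Intervals
#'   shorter than the window are skipped (with a message).
#' @export
windowed_wave_count_bootstrap <- function(wave_times, intervals,
                                          n_iter = 10000, window_s = 0.05,
                                          seed = 1) {
  if (length(intervals) < 2L)
    stop("need at least two interval classes", call. = FALSE)
  with_seed(seed, {
    lapply(intervals, function(iv) {
      iv <- as.matrix(iv)
      len <- iv[, 2] - iv[, 1]
      ok <- len >= window_s
      if (any(!ok))
        message(sprintf("skipped %d interval(s) shorter than the window",
                        sum(!ok)))
      iv <- iv[ok, , drop = FALSE]
      if (!nrow(iv)) return(integer(0))
      len <- iv[, 2] - iv[, 1] - window_s
      w <- (len + 1e-12) / sum(len + 1e-12)
      pick <- sample.int(nrow(iv), n_iter, replace = TRUE, prob = w)
      start <- iv[pick, 1] + runif(n_iter) * len[pick]
      vapply(start, function(s)
        sum(wave_times >= s & wave_times < s + window_s), integer(1))
    })
  })
}
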