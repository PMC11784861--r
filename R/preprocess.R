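# Filtering, scan-artifact removal, downsampling, and the trial-inclusion
# rule. All filters are zero-phase (forward-backward Butterworth via
# signal::filtfilt); narrow bands are applied as cascaded low/high-pass
# stages for numerical robustness at high sampling rates.

filter_matrix <- function(data, filt) {
  t(apply(data, 1L, function(ch) signal::filtfilt(filt, ch)))
}

#' Zero-phase Butterworth band-pass filter of a grid record
#'
#' Forward-backward (zero-phase) Butterworth filtering, default order 4,
#' applied per channel as a low-pass/high-pass cascade. Canonical bands:
#' wideband 3-40, gamma 30-90, beta 15-30, theta 4-12 Hz (see
#' [analysis_band()]).
#'
#' @param lfp A [grid_lfp()] (or [laminar_lfp()]).
#' @param band `c(lo, hi)` in Hz, or a band name understood by
#'   [analysis_band()].
#' @param order Filter order (default 4).
#' @return The filtered record, same class as the input.
#' @export
bandpass <- function(lfp, band = "wideband", order = 4) {
  if (is.character(band)) band <- analysis_band(band)
  lo <- band[1]; hi <- band[2]
  if (!(lo > 0 && lo < hi && hi < lfp$fs / 2))
    stop("band must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  lp <- signal::butter(order, hi / (lfp$fs / 2), type = "low")
  hp <- signal::butter(order, lo / (lfp$fs / 2), type = "high")
  out <- lfp
  out$data <- filter_matrix(filter_matrix(lfp$data, lp), hp)
  out
}

#' Remove two-photon scanning artifacts with a notch bank
#'
#' Applies sixth-order Butterworth notch (band-stop) filters at 30 Hz and its
#' harmonics up to 360 Hz, zero-phase.
#'
#' @param lfp A [grid_lfp()].
#' @param f0 Fundamental artifact frequency (Hz).
#' @param f_max Highest harmonic to remove (Hz).
#' @param bw Half-width of each notch (Hz).
#' @return Filtered record.
#' @export
remove_scan_artifact <- function(lfp, f0 = 30, f_max = 360, bw = 1) {
  if (lfp$fs <= 2 * f_max)
    stop("sampling rate too low for the notch bank (need fs > 720 Hz)",
         call. = FALSE)
  out <- lfp
  for (f in seq(f0, f_max, by = f0)) {
    nf <- signal::butter(3, c(f - bw, f + bw) / (lfp$fs / 2), type = "stop")
    out$data <- filter_matrix(out$data, nf)
  }
  out
}

#' Downsample a grid record
#'
#' Anti-alias filters, then decimates (integer factors) or polyphase-resamples
#' to the target rate. Timestamps are preserved.
#'
#' @param lfp A [grid_lfp()].
#' @param target_fs Target sampling rate (Hz), must not exceed `fs`.
#' @return Resampled record.
#' @export
downsample <- function(lfp, target_fs) {
  if (target_fs > lfp$fs)
    stop("`target_fs` must not exceed the current rate", call. = FALSE)
  if (target_fs == lfp$fs) return(lfp)
  out <- lfp
  fac <- lfp$fs / target_fs
  if (abs(fac - round(fac)) < 1e-9) {
    fac <- round(fac)
    aa <- signal::butter(8, 0.8 / fac, type = "low")
    filtered <- filter_matrix(lfp$data, aa)
    out$data <- filtered[, seq(1L, ncol(filtered), by = fac), drop = FALSE]
  } else {
    p_q <- as.integer(c(target_fs, lfp$fs) /
                        gcd_int(as.integer(target_fs), as.integer(lfp$fs)))
    out$data <- t(apply(lfp$data, 1L, function(ch)
      signal::resample(ch, p_q[1], p_q[2])))
  }
  out$fs <- target_fs
  out
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Epoch trials and apply the trial-inclusion rule
#'
#' A trial is responsive iff the touch-evoked absolute deflection within
#' `resp_window_s` of touch exceeds `k_sd` times the SD of the `pre`-second
#' pre-touch baseline on the reference channel. The deflection is measured on
#' the wideband (3-40 Hz) signal after baseline-mean subtraction; the
#' reference channel is chosen deterministically as the one with the
#' largest mean evoked amplitude.
#'
#' @param lfp A [grid_lfp()].
#' @param touch_times Touch onsets in seconds.
#' @param pre Pre-touch baseline window (s), default 0.5.
#' @param post Post-touch epoch length (s).
#' @param resp_window_s Detection window post-touch (s), default 0.07.
#' @param k_sd Inclusion multiple of the baseline SD, default 3.
#' @param filter_wideband Band-limit to 3-40 Hz before measuring (default
#'   TRUE; set FALSE when the input is already filtered).
#' @return A `trial_epochs` list: `touch_times`, `window = c(pre, post)`,
#'   logical `responsive_mask`, `baseline_sd` (trials x channels),
#'   `reference_channel`, `epochs` (trials x channels x samples array),
#'   `dropped` (indices of touches whose window left the record), `fs`.
#' @export
epoch_and_filter_trials <- function(lfp, touch_times, pre = 0.5, post = 0.5,
                                    resp_window_s = 0.07, k_sd = 3,
                                    filter_wideband = TRUE) {
  if (length(touch_times) < 1L) stop("need at least one touch", call. = FALSE)
  if (pre <= 0) stop("`pre` must be positive", call. = FALSE)
  if (filter_wideband) lfp <- bandpass(lfp, "wideband")
  fs <- lfp$fs
  n <- ncol(lfp$data)
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  idx0 <- round((touch_times - lfp$t0) * fs) + 1L
  ok <- idx0 - n_pre >= 1L & idx0 + n_post <= n
  dropped <- which(!ok)
  if (length(dropped))
    message(sprintf("dropped %d trial(s) whose window exceeds the record",
                    length(dropped)))
  keep <- which(ok)
  n_tr <- length(keep)
  n_ch <- nrow(lfp$data)
  epochs <- array(NA_real_, c(n_tr, n_ch, n_pre + n_post))
  for (i in seq_len(n_tr)) {
    sl <- (idx0[keep[i]] - n_pre):(idx0[keep[i]] + n_post - 1L)
    epochs[i, , ] <- lfp$data[, sl]
  }
  pre_idx <- seq_len(n_pre)
  resp_idx <- n_pre + seq_len(round(resp_window_s * fs))
  # baseline-mean subtraction per trial/channel
  base_mean <- apply(epochs[, , pre_idx, drop = FALSE], c(1, 2), mean)
  epochs <- sweep(epochs, c(1, 2), base_mean)
  baseline_sd <- apply(epochs[, , pre_idx, drop = FALSE], c(1, 2), sd)
  # deterministic reference channel: largest mean evoked |amplitude|
  evoked <- apply(abs(epochs[, , resp_idx, drop = FALSE]), 2, mean)
  ref <- which.max(evoked)
  peak <- apply(abs(epochs[, ref, resp_idx, drop = FALSE]), 1, max)
  responsive <- peak > k_sd * baseline_sd[, ref]
  structure(
    list(touch_times = touch_times[keep], window = c(pre, post),
         responsive_mask = responsive, baseline_sd = baseline_sd,
         reference_channel = ref, epochs = epochs, dropped = dropped,
         fs = fs),
    class = "trial_epochs"
  )
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat(sprintf("<trial_epochs> %d trials (%d responsive), ref channel %d\n",
              length(x$touch_times), sum(x$responsive_mask),
              x$reference_channel))
  invisible(x)
}
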