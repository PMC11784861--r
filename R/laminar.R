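# Laminar analyses: CSD with Vaknin padding, Morlet spectrograms, band-power
# ratios, relative laminar power profiles, and the late-sink bootstrap.

#' Current source density of a laminar record
#'
#' Discrete second spatial derivative of the depth profile,
#' `I_i = (V_{i+n} + V_{i-n} - 2 V_i) / (n * dz)^2`, using a step of `n`
#' channels. Vaknin padding duplicates the top and bottom channels `n`
#' times so the estimate covers the full shank. Sinks are negative,
#' sources positive. The estimator is linear and annihilates depth-affine
#' profiles exactly.
#'
#' @param lfp A [laminar_lfp()] (or a channels x samples matrix plus
#'   `dz_um`).
#' @param n Channel step (default 2).
#' @param dz_um Spacing in um when `lfp` is a bare matrix.
#' @return A channels x samples CSD matrix (uV/mm^2 scale, with dz in mm),
#'   class `csd_map` with attributes `n` and `dz_um`.
#' @export
csd <- function(lfp, n = 2, dz_um = NULL) {
  if (inherits(lfp, "laminar_lfp")) {
    v <- lfp$data; dz_um <- lfp$dz_um
  } else {
    v <- as.matrix(lfp)
    if (is.null(dz_um)) stop("`dz_um` required for matrix input", call. = FALSE)
  }
  nc <- nrow(v)
  if (nc < 2 * n + 1)
    stop(sprintf("need at least %d channels for n = %d", 2 * n + 1, n),
         call. = FALSE)
  # Vaknin padding: duplicate boundary channels n times
  vp <- rbind(v[rep(1L, n), , drop = FALSE], v,
              v[rep(nc, n), , drop = FALSE])
  dz_mm <- dz_um * 1e-3
  i <- (n + 1L):(n + nc)
  out <- (vp[i + n, , drop = FALSE] + vp[i - n, , drop = FALSE] -
            2 * vp[i, , drop = FALSE]) / (n * dz_mm)^2
  structure(out, n = n, dz_um = dz_um, class = c("csd_map", "matrix", "array"))
}

#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with complex Morlet wavelets (center
#' frequency parameter `omega0`), computed by FFT convolution on a
#' log-spaced frequency grid.
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz).
#' @param f_range `c(min, max)` analysis frequencies (Hz); frequencies whose
#'   wavelet support exceeds the record are dropped with a warning.
#' @param n_freq Number of log-spaced frequencies.
#' @param omega0 Morlet time-bandwidth parameter (default 6).
#' @return List: `power` (n_freq x n_samples magnitude^2), `freq` (Hz).
#' @export
time_frequency <- function(x, fs, f_range = c(0.1, 100), n_freq = 60,
                           omega0 = 6) {
  if (f_range[2] > fs / 2)
    stop("max frequency above Nyquist", call. = FALSE)
  n <- length(x)
  freq <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freq))
  # drop frequencies whose wavelet (≈ omega0 / f seconds) outlasts the record
  support_ok <- omega0 / freq <= n / fs
  if (!all(support_ok)) {
    warning(sprintf("dropped %d low frequencies with support beyond the record",
                    sum(!support_ok)))
    freq <- freq[support_ok]
  }
  nfft <- nextn(2L * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  f_axis <- (seq_len(nfft) - 1L) / nfft * fs
  f_axis[f_axis > fs / 2] <- f_axis[f_axis > fs / 2] - fs
  power <- matrix(0, length(freq), n)
  for (i in seq_along(freq)) {
    sigma_f <- freq[i] / omega0      # spectral width of the wavelet
    H <- exp(-0.5 * ((f_axis - freq[i]) / sigma_f)^2) * (f_axis > 0)
    w <- fft(X * H, inverse = TRUE) / nfft
    power[i, ] <- Mod(w[seq_len(n)])^2
  }
  list(power = power, freq = freq)
}

#' Trial-averaged spectrogram of one channel
#'
#' @param epochs A `trial_epochs` (from [epoch_and_filter_trials()] with
#'   `filter_wideband = FALSE` when full-band power is wanted).
#' @param channel Channel index (default the reference channel).
#' @param responsive_only Average responsive trials only (default TRUE).
#' @param ... Passed to [time_frequency()].
#' @return As [time_frequency()], power averaged across trials, plus
#'   `t` (seconds relative to touch).
#' @export
trial_spectrogram <- function(epochs, channel = NULL, responsive_only = TRUE,
                              ...) {
  stopifnot(inherits(epochs, "trial_epochs"))
  if (is.null(channel)) channel <- epochs$reference_channel
  use <- if (responsive_only) which(epochs$responsive_mask) else
    seq_along(epochs$responsive_mask)
  if (!length(use)) stop("no trials to average", call. = FALSE)
  acc <- NULL; freq <- NULL
  for (tr in use) {
    tf <- time_frequency(epochs$epochs[tr, channel, ], epochs$fs, ...)
    acc <- if (is.null(acc)) tf$power else acc + tf$power
    freq <- tf$freq
  }
  n <- dim(epochs$epochs)[3]
  list(power = acc / length(use), freq = freq,
       t = (seq_len(n) - 1L) / epochs$fs - epochs$window[1])
}

#' Band-power ratios in early/late windows
#'
#' Sums spectrogram power inside each canonical band and each time window
#' and returns the beta/gamma and theta/gamma ratios per window.
#'
#' @param spec A spectrogram list with `power`, `freq`, `t` (see
#'   [trial_spectrogram()]).
#' @param windows Named list of `c(start, end)` windows in seconds
#'   post-touch; defaults early 0-0.06 s, late 0.1-0.2 s.
#' @return Data.frame with columns `window`, `beta_gamma`, `theta_gamma`.
#' @export
band_power_ratios <- function(spec,
                              windows = list(early = c(0, 0.06),
                                             late = c(0.1, 0.2))) {
  if (is.null(spec$t)) stop("spectrogram lacks a time axis", call. = FALSE)
  band_sum <- function(band, tw) {
    fi <- spec$freq >= band[1] & spec$freq <= band[2]
    ti <- spec$t >= tw[1] & spec$t <= tw[2]
    if (!any(ti)) stop("window outside the record", call. = FALSE)
    sum(spec$power[fi, ti])
  }
  do.call(rbind, lapply(names(windows), function(nm) {
    tw <- windows[[nm]]
    g <- band_sum(analysis_band("gamma"), tw)
    data.frame(window = nm,
               beta_gamma = band_sum(analysis_band("beta"), tw) / g,
               theta_gamma = band_sum(analysis_band("theta"), tw) / g)
  }))
}

# Welch power spectral density via averaged modified periodograms.
welch_psd <- function(x, fs, n_seg = 8, overlap = 0.5) {
  n <- length(x)
  seg_len <- max(16L, 2L * floor(n / (n_seg * (1 - overlap) + overlap) / 2))
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  scale <- sum(win^2) * fs
  nf <- seg_len %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- (x[s:(s + seg_len - 1L)] - mean(x[s:(s + seg_len - 1L)])) * win
    P <- Mod(fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Relative laminar power profile
#'
#' Welch PSD per channel inside a peri-touch window, assembled into a
#' channels x frequency matrix and normalized so each frequency column's
#' maximum across channels is 1:
#' `RelPower[n, f] = Power[n, f] / max_n Power[n, f]`.
#' Invariant to any global gain. Zero-power columns are masked (`NA`).
#'
#' @param laminar A [laminar_lfp()].
#' @param touch_time Touch time (s).
#' @param window `c(start, end)` seconds around touch (default -0.1 to 0.2).
#' @param f_max Highest frequency kept (Hz).
#' @return List: `rel_power` (channels x freq in `[0, 1]`), `freq`.
#' @export
relative_power_profile <- function(laminar, touch_time,
                                   window = c(-0.1, 0.2), f_max = 100) {
  stopifnot(inherits(laminar, "laminar_lfp"))
  fs <- laminar$fs
  i0 <- max(1L, round((touch_time + window[1] - laminar$t0) * fs) + 1L)
  i1 <- min(ncol(laminar$data), round((touch_time + window[2] - laminar$t0) * fs))
  if (i1 <= i0) stop("window outside the record", call. = FALSE)
  nc <- nrow(laminar$data)
  psds <- lapply(seq_len(nc), function(ch)
    welch_psd(laminar$data[ch, i0:i1], fs, n_seg = 4))
  freq <- psds[[1]]$freq
  keep <- freq <= f_max
  pw <- do.call(rbind, lapply(psds, function(p) p$psd[keep]))
  freq <- freq[keep]
  colmax <- apply(pw, 2, max)
  rel <- sweep(pw, 2, colmax, `/`)
  rel[, colmax == 0] <- NA_real_
  list(rel_power = rel, freq = freq)
}

#' Bootstrap the late-sink magnitude by trial class
#'
#' Per iteration and per class: resample `n_per_draw` trials (with
#' replacement when the class is smaller), average the laminar LFP, compute
#' the CSD, and record the late-sink magnitude (the most negative CSD value
#' inside the late window over the superficial channels).
#'
#' @param trials Trials x channels x samples array of laminar epochs
#'   (touch at `touch_idx`).
#' @param labels Character class labels per trial (e.g. strong/weak).
#' @param dz_um Channel spacing (um).
#' @param fs Sampling rate (Hz).
#' @param touch_idx Sample index of touch within an epoch.
#' @param late_window `c(start, end)` seconds post-touch (default 0.1-0.3).
#' @param superficial_channels Channel indices counted as L2/3.
#' @param n_iter Iterations (default 50).
#' @param n_per_draw Trials per draw (default 20).
#' @param n_csd CSD step (default 2).
#' @param seed RNG seed.
#' @return Named list of per-class numeric vectors (sink magnitudes,
#'   negative values).
#' @export
sink_bootstrap <- function(trials, labels, dz_um, fs, touch_idx,
                           late_window = c(0.1, 0.3),
                           superficial_channels = NULL,
                           n_iter = 50, n_per_draw = 20, n_csd = 2,
                           seed = 1) {
  classes <- split(seq_along(labels), labels)
  if (length(classes) < 2L) stop("need both label groups", call. = FALSE)
  nch <- dim(trials)[2]
  if (is.null(superficial_channels))
    superficial_channels <- seq_len(max(3L, nch %/% 3))
  wi <- (touch_idx + round(late_window[1] * fs)):
    min(touch_idx + round(late_window[2] * fs), dim(trials)[3])
  with_seed(seed, {
    lapply(classes, function(idx) {
      replace_draw <- length(idx) < n_per_draw
      if (replace_draw)
        message("class smaller than the draw; sampling with replacement")
      vapply(seq_len(n_iter), function(i) {
        pick <- sample(idx, n_per_draw, replace = TRUE)
        avg <- apply(trials[pick, , , drop = FALSE], c(2, 3), mean)
        cs <- csd(avg, n = n_csd, dz_um = dz_um)
        min(cs[superficial_channels, wi])
      }, numeric(1))
    })
  })
}
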