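# Generalized phase: analytic signal of the wideband LFP via the
# single-sided FFT, instantaneous phase/amplitude/frequency, and correction
# of negative-frequency intrusions (phase reversals driven by fast,
# low-amplitude riders) by masking and shape-preserving reinterpolation of
# the unwrapped phase.

# Analytic signal of one real vector via single-sided spectrum.
analytic_1d <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Analytic signal and instantaneous phase of a grid record
#'
#' Computes, per channel, the analytic signal via the single-sided FFT
#' (Hilbert transform), the instantaneous phase (arctangent), amplitude
#' (modulus) and instantaneous frequency (time derivative of the unwrapped
#' phase, central differences). Constant channels get zero amplitude and a
#' fully masked phase instead of an error. The first and last `edge_s`
#' seconds are flagged low-confidence (filter and Hilbert edge effects) and
#' excluded from wave evaluation via the mask.
#'
#' @param lfp A band-limited [grid_lfp()].
#' @param edge_s Edge exclusion in seconds (default 0.1).
#' @return An [analytic_field()].
#' @export
analytic_signal <- function(lfp, edge_s = 0.1) {
  data <- lfp$data
  n_ch <- nrow(data); n <- ncol(data)
  phase <- amp <- freq <- matrix(NA_real_, n_ch, n)
  mask <- matrix(TRUE, n_ch, n)
  for (ch in seq_len(n_ch)) {
    x <- data[ch, ]
    if (var(x) == 0) {
      amp[ch, ] <- 0
      mask[ch, ] <- FALSE
      next
    }
    z <- analytic_1d(x)
    phase[ch, ] <- Arg(z)
    amp[ch, ] <- Mod(z)
    pu <- unwrap_phase(Arg(z))
    dp <- c(pu[2] - pu[1], (pu[3:n] - pu[1:(n - 2)]) / 2, pu[n] - pu[n - 1])
    freq[ch, ] <- dp * lfp$fs / (2 * pi)
  }
  n_edge <- min(round(edge_s * lfp$fs), floor((n - 1) / 2))
  if (n_edge > 0) {
    mask[, seq_len(n_edge)] <- FALSE
    mask[, (n - n_edge + 1L):n] <- FALSE
  }
  analytic_field(phase, amp, freq, mask, lfp$fs, lfp$coords, lfp$t0)
}

gp_correct_1d <- function(phase, fs) {
  n <- length(phase)
  pu <- unwrap_phase(phase)
  keep <- pu >= cummax(pu)   # drop every sample under the running maximum
  if (sum(keep) < 2L) {
    return(list(phase = phase, freq = rep(0, n), corrected = rep(TRUE, n)))
  }
  corrected <- !keep
  if (any(corrected)) {
    idx <- which(keep)
    # shape-preserving (monotone piecewise-cubic) reinterpolation
    f <- splinefun(idx, pu[idx], method = "monoH.FC")
    pu_i <- pu
    pu_i[!keep] <- f(which(!keep))
    # nearest-valid extrapolation at record edges
    if (!keep[1]) pu_i[seq_len(idx[1] - 1L)] <- pu[idx[1]]
    if (!keep[n]) {
      last <- idx[length(idx)]
      if (last < n) pu_i[(last + 1L):n] <- pu[last]
    }
    pu <- pu_i
  }
  dp <- c(pu[2] - pu[1], (pu[3:n] - pu[1:(n - 2)]) / 2, pu[n] - pu[n - 1])
  list(phase = wrap_pi(pu), freq = pmax(dp, 0) * fs / (2 * pi),
       corrected = corrected)
}

#' Correct phase discontinuities (negative instantaneous frequencies)
#'
#' Samples where the discrete forward difference of the unwrapped phase is
#' negative (phase reversals driven by fast low-amplitude riders) are masked
#' and the unwrapped phase is re-interpolated across the masked runs with a
#' shape-preserving monotone piecewise-cubic interpolant, then re-wrapped.
#' After correction the instantaneous frequency is non-negative at every
#' sample. Masked runs touching the record edge are held at the nearest
#' valid phase.
#'
#' @param field An [analytic_field()] from [analytic_signal()] on wideband
#'   data.
#' @return The corrected [analytic_field()]; element `corrected` marks the
#'   reinterpolated samples.
#' @export
gp_correct <- function(field) {
  stopifnot(inherits(field, "analytic_field"))
  n_ch <- nrow(field$phase)
  corrected <- matrix(FALSE, n_ch, ncol(field$phase))
  for (ch in seq_len(n_ch)) {
    p <- field$phase[ch, ]
    if (all(is.na(p))) next
    res <- gp_correct_1d(p, field$fs)
    field$phase[ch, ] <- res$phase
    field$freq[ch, ] <- res$freq
    corrected[ch, ] <- res$corrected
  }
  field$corrected <- corrected
  field
}
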