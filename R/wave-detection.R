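# Single-trial traveling-wave detection from the corrected phase field:
# evaluation points at rising -pi/2 phase crossings, divergence source
# localization, circular-linear phase-distance correlation against an
# electrode-shuffle null, and wave kinematics (k, f, omega, v).

# ---- lattice geometry -------------------------------------------------------

# Reconstruct the electrode lattice from coordinates. Returns idx[row, col]
# with channel ids, plus the pitch along x and y (mm).
lattice_index <- function(coords) {
  xs <- sort(unique(coords[, 1])); ys <- sort(unique(coords[, 2]))
  if (length(xs) * length(ys) != nrow(coords))
    stop("electrode coordinates do not form a full rectangular lattice",
         call. = FALSE)
  idx <- matrix(NA_integer_, length(ys), length(xs))
  ri <- match(coords[, 2], ys); ci <- match(coords[, 1], xs)
  idx[cbind(ri, ci)] <- seq_len(nrow(coords))
  list(idx = idx, rows = length(ys), cols = length(xs),
       dx = if (length(xs) > 1) mean(diff(xs)) else 1,
       dy = if (length(ys) > 1) mean(diff(ys)) else 1)
}

# Finite differences with wrapped phase steps mapped to (-pi, pi]:
# central in the interior (mean of the two wrapped one-step differences),
# one-sided at the edges. `m` is a rows x cols matrix; returns d/dcol.
diff_cols_wrapped <- function(m, d) {
  nc <- ncol(m)
  fwd <- wrap_pi(m[, -1, drop = FALSE] - m[, -nc, drop = FALSE]) / d
  out <- matrix(NA_real_, nrow(m), nc)
  out[, 1] <- fwd[, 1]
  out[, nc] <- fwd[, nc - 1]
  if (nc > 2) out[, 2:(nc - 1)] <- (fwd[, -(nc - 1), drop = FALSE] +
                                      fwd[, -1, drop = FALSE]) / 2
  out
}

diff_cols_plain <- function(m, d) {
  nc <- ncol(m)
  fwd <- (m[, -1, drop = FALSE] - m[, -nc, drop = FALSE]) / d
  out <- matrix(NA_real_, nrow(m), nc)
  out[, 1] <- fwd[, 1]
  out[, nc] <- fwd[, nc - 1]
  if (nc > 2) out[, 2:(nc - 1)] <- (fwd[, -(nc - 1), drop = FALSE] +
                                      fwd[, -1, drop = FALSE]) / 2
  out
}

# Phase gradient (rad/mm) on the lattice at one sample. Returns list(gx, gy)
# as rows x cols matrices (NA where phase is masked).
phase_gradient <- function(phase_vec, lat) {
  pm <- matrix(phase_vec[lat$idx], lat$rows, lat$cols)
  list(gx = diff_cols_wrapped(pm, lat$dx),
       gy = t(diff_cols_wrapped(t(pm), lat$dy)))
}

# NA-aware 3x3 circular smoothing of a lattice phase matrix: average the
# unit phasors over each site's neighborhood and take the argument.
smooth_phase_lattice <- function(pm) {
  z <- exp(1i * pm)
  z[is.na(pm)] <- 0
  w <- (!is.na(pm)) * 1
  pad <- function(m) rbind(0, cbind(0, m, 0), 0)
  zp <- pad(z); wp <- pad(w)
  nr <- nrow(pm); nc <- ncol(pm)
  acc_z <- matrix(0i, nr, nc); acc_w <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    acc_z <- acc_z + zp[di + seq_len(nr), dj + seq_len(nc)]
    acc_w <- acc_w + wp[di + seq_len(nr), dj + seq_len(nc)]
  }
  out <- Arg(acc_z / pmax(acc_w, 1))
  out[acc_w == 0 | is.na(pm)] <- NA_real_
  out
}

# ---- evaluation points ------------------------------------------------------

#' Find wave evaluation points
#'
#' Rising crossings of -pi/2 of the (corrected) instantaneous phase on the
#' trigger channel; each crossing is a candidate traveling wave (a
#' positive-going LFP upswing).
#'
#' @param field An [analytic_field()] (after [gp_correct()]).
#' @param trigger_channel Channel on which crossings are detected; defaults
#'   to the channel with the largest mean amplitude.
#' @return Integer vector of sample indices of the crossings (evaluation
#'   points). The chosen trigger channel is attached as attribute
#'   `trigger_channel`.
#' @export
find_evaluation_points <- function(field, trigger_channel = NULL) {
  if (is.null(trigger_channel))
    trigger_channel <- which.max(rowMeans(field$amp))
  p <- field$phase[trigger_channel, ]
  ok <- field$mask[trigger_channel, ] & !is.na(p)
  n <- length(p)
  below <- p < -pi / 2
  cross <- which(below[-n] & !below[-1] & ok[-n] & ok[-1]) + 1L
  # rising through -pi/2, not a wrap from +pi: the step must be small
  cross <- cross[wrap_pi(p[cross] - p[cross - 1L]) > 0]
  structure(cross, trigger_channel = trigger_channel)
}

# ---- source localization ----------------------------------------------------

#' Locate the wave source by divergence of the propagation field
#'
#' Computes the discrete phase gradient on the electrode lattice and the
#' divergence `D` of the propagation field (the negative phase gradient,
#' which points in the direction of travel). The putative source `S` is the
#' electrode maximizing `D`; ties are broken by the smallest channel index.
#'
#' @param field An [analytic_field()].
#' @param t Sample index.
#' @param smooth Apply 3x3 circular smoothing to the phase lattice before
#'   the gradient (default TRUE); stabilizes the divergence against
#'   channel noise without moving the argmax on clean fields.
#' @param refine Number of top-divergence candidate electrodes among which
#'   the source is selected by the best circular-linear phase-distance fit
#'   (default 8; 1 reproduces the plain divergence argmax).
#' @return Channel id of the source, with attribute `divergence` (the full
#'   rows x cols divergence map), or `NA` if the frame is entirely masked.
#' @export
source_point <- function(field, t, smooth = TRUE, refine = 8) {
  lat <- lattice_index(field$coords)
  pv_raw <- field$phase[, t]
  pv_raw[!field$mask[, t]] <- NA
  if (all(is.na(pv_raw))) return(NA_integer_)
  pv <- pv_raw
  if (smooth) {
    pm <- smooth_phase_lattice(matrix(pv[lat$idx], lat$rows, lat$cols))
    pv[lat$idx] <- pm
  }
  g <- phase_gradient(pv, lat)
  px <- -g$gx; py <- -g$gy      # propagation field
  D <- diff_cols_plain(px, lat$dx) + t(diff_cols_plain(t(py), lat$dy))
  Dv <- rep(NA_real_, length(pv))
  Dv[lat$idx] <- D
  if (all(is.na(Dv))) return(NA_integer_)
  cand <- order(Dv, decreasing = TRUE, na.last = NA)  # ties: lowest channel
  cand <- head(cand, max(1L, refine))
  s <- cand[1]
  if (length(cand) > 1L) {
    rhos <- vapply(cand, function(c) {
      d <- sqrt(colSums((t(field$coords) - field$coords[c, ])^2))
      r <- circ_linear_corr(pv_raw, d)
      if (is.na(r)) -Inf else r
    }, numeric(1))
    s <- cand[which.max(rhos)]
  }
  structure(as.integer(s), divergence = Dv)
}

# ---- circular-linear correlation --------------------------------------------

#' Circular-linear correlation between phase and distance
#'
#' Mardia's correlation between a circular variable (phase) and a linear one
#' (distance), in `[0, 1]`:
#' `rho^2 = (r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2)` with
#' `r_cx = cor(cos(phi), d)`, `r_sx = cor(sin(phi), d)`,
#' `r_cs = cor(cos(phi), sin(phi))`. Invariant to a global phase offset and
#' to rigid motions of the electrode coordinates (through `d`).
#'
#' @param phase Per-channel phase in radians.
#' @param dist Per-channel distance (any consistent unit).
#' @return Correlation in `[0, 1]`, or `NA` if fewer than 5 valid channels.
#' @export
circ_linear_corr <- function(phase, dist) {
  ok <- is.finite(phase) & is.finite(dist)
  if (sum(ok) < 5L) return(NA_real_)
  phase <- phase[ok]; dist <- dist[ok]
  cx <- cos(phase); sx <- sin(phase)
  if (sd(dist) == 0 || sd(cx) == 0 || sd(sx) == 0) return(0)
  r_cx <- cor(cx, dist); r_sx <- cor(sx, dist); r_cs <- cor(cx, sx)
  rho2 <- (r_cx^2 + r_sx^2 - 2 * r_cx * r_sx * r_cs) / (1 - r_cs^2)
  sqrt(max(0, min(1, rho2)))
}

# ---- shuffle null -----------------------------------------------------------

#' Build the electrode-shuffle null distribution of wave correlations
#'
#' Randomly permutes the electrode locations across the grid, reruns source
#' localization and the circular-linear correlation at each evaluation
#' point, and collects the correlation values. The detection threshold is
#' the 99th percentile of this null. One null is built per dataset.
#'
#' @param field An [analytic_field()].
#' @param eval_points Evaluation points from [find_evaluation_points()].
#' @param n_shuffles Number of location shuffles (default 1000).
#' @param max_eval At most this many evaluation points are used per shuffle
#'   (subsampled deterministically) to bound cost.
#' @param seed RNG seed.
#' @return A `wave_null` list: `rho` (null samples), `threshold` (99th
#'   percentile), `n_shuffles`.
#' @export
build_null <- function(field, eval_points, n_shuffles = 1000, max_eval = 10,
                       seed = 1) {
  if (length(eval_points) == 0L) stop("no evaluation points", call. = FALSE)
  ep <- eval_points
  if (length(ep) > max_eval)
    ep <- ep[round(seq(1, length(ep), length.out = max_eval))]
  n_ch <- nrow(field$coords)
  rho <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      perm <- sample.int(n_ch)
      shuf <- field
      shuf$phase <- field$phase[perm, , drop = FALSE]
      shuf$mask <- field$mask[perm, , drop = FALSE]
      vapply(ep, function(t) {
        s <- source_point(shuf, t)
        if (is.na(s)) return(NA_real_)
        d <- sqrt(colSums((t(shuf$coords) - shuf$coords[s, ])^2))
        r <- circ_linear_corr(shuf$phase[, t][shuf$mask[, t]],
                              d[shuf$mask[, t]])
        if (is.na(r)) 0 else r
      }, numeric(1))
    }))
  })
  rho <- rho[is.finite(rho)]
  structure(
    list(rho = rho, threshold = quantile(rho, 0.99, names = FALSE),
         n_shuffles = n_shuffles),
    class = "wave_null"
  )
}

#' @export
print.wave_null <- function(x, ...) {
  cat(sprintf("<wave_null> %d shuffles, 99th-percentile threshold %.3f\n",
              x$n_shuffles, x$threshold))
  invisible(x)
}

# ---- classification and kinematics ------------------------------------------

# Least-squares wavenumber from the per-channel phase delay at one frame.
# Fits both a planar model (delay ~ x + y) and a radial model (delay ~
# distance from S) and keeps the better-fitting one. Returns k in rad/m
# (<= 0 signals an invalid/inward fit).
estimate_wavenumber <- function(delay, coords_mm, s) {
  ok <- is.finite(delay)
  if (sum(ok) < 5L) return(list(k = NA_real_, geometry = NA_character_))
  x <- coords_mm[ok, 1] * 1e-3; y <- coords_mm[ok, 2] * 1e-3
  dl <- delay[ok]
  fit_p <- lm(dl ~ x + y)
  k_p <- sqrt(sum(coef(fit_p)[2:3]^2))
  rss_p <- sum(fit_p$residuals^2)
  d <- sqrt((x - coords_mm[s, 1] * 1e-3)^2 + (y - coords_mm[s, 2] * 1e-3)^2)
  fit_r <- lm(dl ~ d)
  k_r <- coef(fit_r)[2]
  rss_r <- sum(fit_r$residuals^2)
  if (rss_p <= rss_r) list(k = k_p, geometry = "planar")
  else list(k = as.numeric(k_r), geometry = "radial")
}

#' Classify one evaluation point and measure wave kinematics
#'
#' Accepts the candidate iff its circular-linear phase-distance correlation
#' reaches the null threshold. For accepted waves: wavenumber `k` (rad/m)
#' from a least-squares fit of the phase delay (source phase minus site
#' phase); instantaneous frequency `f` = mean corrected frequency over
#' unmasked channels at the evaluation time; `v = 2*pi*f / k`; amplitude =
#' LFP value at the next zero-phase crossing on the trigger channel; epoch
#' from touch-relative time.
#'
#' @param t_eval Evaluation sample index.
#' @param field Corrected [analytic_field()].
#' @param lfp The band-limited [grid_lfp()] the field came from.
#' @param null A [build_null()] result.
#' @param trigger_channel Trigger channel id.
#' @param touch_times Touch times (s) for epoch labels, or `NULL`.
#' @param early_window,late_window Epoch windows post-touch (s).
#' @param band Band label stored in the result.
#' @return One-row data.frame (the wave event) or `NULL` with attribute-free
#'   rejection (invisible `NULL`) if rejected.
#' @export
classify_and_measure <- function(t_eval, field, lfp, null,
                                 trigger_channel = NULL,
                                 touch_times = NULL,
                                 early_window = c(0, 0.05),
                                 late_window = c(0.1, 0.3),
                                 band = "wideband") {
  if (is.null(trigger_channel))
    trigger_channel <- which.max(rowMeans(field$amp))
  ok <- field$mask[, t_eval] & is.finite(field$phase[, t_eval])
  if (mean(ok) < 0.6) return(invisible(NULL))  # participation requirement
  s <- source_point(field, t_eval)
  if (is.na(s)) return(invisible(NULL))
  d <- sqrt(colSums((t(field$coords) - field$coords[s, ])^2))
  rho <- circ_linear_corr(field$phase[ok, t_eval], d[ok])
  if (is.na(rho) || rho < null$threshold) return(invisible(NULL))
  delay <- wrap_pi(field$phase[s, t_eval] - field$phase[, t_eval])
  delay[!ok] <- NA
  kfit <- estimate_wavenumber(delay, field$coords, s)
  if (!is.finite(kfit$k) || kfit$k <= 0) return(invisible(NULL))
  f <- mean(field$freq[ok, t_eval], na.rm = TRUE)
  v <- 2 * pi * f / kfit$k
  # amplitude at the next zero-phase (rising) crossing on the trigger channel
  p_tr <- field$phase[trigger_channel, ]
  n <- length(p_tr)
  amp <- NA_real_
  if (t_eval < n) {
    seg <- t_eval:(n - 1L)
    z <- seg[p_tr[seg] < 0 & p_tr[seg + 1L] >= 0]
    if (length(z)) amp <- lfp$data[trigger_channel, z[1] + 1L]
  }
  t_s <- field$t0 + (t_eval - 1L) / field$fs
  epoch <- "prestim"
  if (!is.null(touch_times) && length(touch_times)) {
    dt <- t_s - touch_times
    dt_last <- if (any(dt >= 0)) min(dt[dt >= 0]) else NA_real_
    if (!is.na(dt_last)) {
      if (dt_last >= early_window[1] && dt_last < early_window[2])
        epoch <- "early"
      else if (dt_last >= late_window[1] && dt_last < late_window[2])
        epoch <- "late"
    }
  }
  data.frame(
    t_eval_s = t_s, source_ch = as.integer(s),
    source_x_mm = field$coords[s, 1], source_y_mm = field$coords[s, 2],
    rho = rho, k_rad_per_m = kfit$k, f_hz = f, omega_rad_per_s = 2 * pi * f,
    v_m_per_s = v, amp_uv = amp, geometry = kfit$geometry,
    band = band, epoch = epoch, stringsAsFactors = FALSE
  )
}

#' Detect traveling waves in a grid record
#'
#' Full single-record pipeline: evaluation points on the trigger channel,
#' electrode-shuffle null (unless supplied), then per-evaluation-point
#' classification and kinematics.
#'
#' @param lfp A band-limited [grid_lfp()].
#' @param field Optional precomputed corrected [analytic_field()].
#' @param null Optional precomputed [build_null()] result.
#' @param n_shuffles Shuffles for the null when it is built here.
#' @param touch_times,early_window,late_window,band Passed through to
#'   [classify_and_measure()].
#' @param seed RNG seed for the null.
#' @return A data.frame of accepted wave events (possibly 0 rows), with
#'   attributes `null`, `eval_points`, `trigger_channel`.
#' @export
detect_waves <- function(lfp, field = NULL, null = NULL, n_shuffles = 1000,
                         touch_times = NULL, early_window = c(0, 0.05),
                         late_window = c(0.1, 0.3), band = "wideband",
                         seed = 1) {
  if (is.null(field)) field <- gp_correct(analytic_signal(lfp))
  ep <- find_evaluation_points(field)
  trig <- attr(ep, "trigger_channel")
  if (length(ep) == 0L) {
    out <- empty_wave_table()
  } else {
    if (is.null(null))
      null <- build_null(field, ep, n_shuffles = n_shuffles, seed = seed)
    rows <- lapply(ep, classify_and_measure, field = field, lfp = lfp,
                   null = null, trigger_channel = trig,
                   touch_times = touch_times, early_window = early_window,
                   late_window = late_window, band = band)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows)) do.call(rbind, rows) else empty_wave_table()
  }
  attr(out, "null") <- null
  attr(out, "eval_points") <- as.integer(ep)
  attr(out, "trigger_channel") <- trig
  out
}

empty_wave_table <- function() {
  data.frame(
    t_eval_s = numeric(0), source_ch = integer(0), source_x_mm = numeric(0),
    source_y_mm = numeric(0), rho = numeric(0), k_rad_per_m = numeric(0),
    f_hz = numeric(0), omega_rad_per_s = numeric(0), v_m_per_s = numeric(0),
    amp_uv = numeric(0), geometry = character(0), band = character(0),
    epoch = character(0), stringsAsFactors = FALSE
  )
}
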