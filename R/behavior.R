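# Whisker kinematics and task metrics: whisker angle/phase, Menger
# curvature, ROI touch detection, inter-touch filtering, outcome
# classification, and d-prime.

#' Whisker angle and phase from a pose table
#'
#' Whisker angle per frame is taken from the base label relative to the
#' whisker-pad reference point; the angle is zero-phase band-pass filtered
#' (default 1-30 Hz) and the phase is the angle of its analytic signal,
#' with the convention that phase 0 falls at maximal protraction (angle
#' maxima). Frames with missing labels are masked.
#'
#' @param pose Pose data.frame (`frame`, `label`, `x_px`, `y_px`).
#' @param frame_rate Frames per second.
#' @param pad Reference point `c(x, y)` on the whisker pad.
#' @param band Filter band in Hz (default `c(1, 30)`).
#' @param angle_label Which label defines the angle (default 1, the base).
#' @return List: `angle` (radians per frame), `filtered`, `phase`
#'   (radians, 0 at protraction peaks), `frame_rate`.
#' @export
whisker_phase <- function(pose, frame_rate, pad = c(0, 0), band = c(1, 30),
                          angle_label = 1) {
  p <- pose[pose$label == angle_label, ]
  p <- p[order(p$frame), ]
  angle <- atan2(p$y_px - pad[2], p$x_px - pad[1])
  ok <- is.finite(angle)
  if (any(!ok)) angle[!ok] <- mean(angle[ok])
  bf_lo <- signal::butter(4, band[2] / (frame_rate / 2), type = "low")
  bf_hi <- signal::butter(4, band[1] / (frame_rate / 2), type = "high")
  filt <- signal::filtfilt(bf_hi, signal::filtfilt(bf_lo, angle))
  z <- analytic_1d(filt)
  phase <- Arg(z)   # 0 at the filtered-angle maxima (protraction peak)
  phase[!ok] <- NA_real_
  list(angle = angle, filtered = filt, phase = phase,
       frame_rate = frame_rate)
}

#' Menger curvature of three points
#'
#' `c = 4 A / (|x-y| |y-z| |z-x|)` where `A` is the triangle area: the
#' inverse circumradius. Zero for collinear points; rotation/translation
#' invariant; scales as 1/s under similarity scaling by s. Coincident
#' points give `NA`.
#'
#' @param x,y,z Length-2 numeric points (pixels).
#' @return Curvature in 1/pixels.
#' @export
menger_curvature <- function(x, y, z) {
  d1 <- sqrt(sum((x - y)^2)); d2 <- sqrt(sum((y - z)^2))
  d3 <- sqrt(sum((z - x)^2))
  if (d1 == 0 || d2 == 0 || d3 == 0) return(NA_real_)
  area2 <- abs((y[1] - x[1]) * (z[2] - x[2]) - (z[1] - x[1]) * (y[2] - x[2]))
  2 * area2 / (d1 * d2 * d3)
}

#' Per-frame whisker bend from the three distal labels
#'
#' @param pose Pose data.frame with labels 1-4 (base to tip).
#' @return Numeric curvature per frame (1/pixels).
#' @export
whisker_bend <- function(pose) {
  frames <- sort(unique(pose$frame))
  vapply(frames, function(f) {
    pf <- pose[pose$frame == f, ]
    get <- function(l) {
      r <- pf[pf$label == l, ]
      c(r$x_px[1], r$y_px[1])
    }
    menger_curvature(get(2), get(3), get(4))
  }, numeric(1))
}

# Even-odd rule point-in-polygon test.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + .Machine$double.eps) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Detect touches from ROI entries of the distal label
#'
#' A touch is the first frame of each entry of the tip label into the ROI
#' polygon; consecutive in-ROI frames belong to one touch episode
#' (debounced).
#'
#' @param pose Pose data.frame.
#' @param roi_polygon n x 2 polygon (pixels).
#' @param tip_label Label id of the distal point (default 4).
#' @return Data.frame `touch_frame`, `episode_end` (last in-ROI frame of the
#'   episode); empty if the label never appears.
#' @export
detect_touches <- function(pose, roi_polygon, tip_label = 4) {
  p <- pose[pose$label == tip_label, ]
  p <- p[order(p$frame), ]
  if (!nrow(p)) return(data.frame(touch_frame = integer(0),
                                  episode_end = integer(0)))
  ok <- is.finite(p$x_px) & is.finite(p$y_px)
  inroi <- rep(FALSE, nrow(p))
  inroi[ok] <- point_in_polygon(p$x_px[ok], p$y_px[ok], roi_polygon)
  r <- rle(inroi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(touch_frame = p$frame[starts[on]],
             episode_end = p$frame[ends[on]])
}

#' Filter touches by minimum inter-touch interval
#'
#' Keeps the first touch and every touch whose gap to the previous
#' *retained* touch exceeds `min_interval_ms`. Idempotent.
#'
#' @param touch_frames Sorted touch frames (or times if `frame_rate = 1000`).
#' @param frame_rate Frames per second.
#' @param min_interval_ms Minimum interval (default 100 ms).
#' @return The retained touch frames.
#' @export
filter_touch_intervals <- function(touch_frames, frame_rate,
                                   min_interval_ms = 100) {
  if (!length(touch_frames)) return(touch_frames)
  if (is.unsorted(touch_frames)) stop("touches must be sorted", call. = FALSE)
  gap <- min_interval_ms / 1000 * frame_rate
  keep <- touch_frames[1]
  last <- touch_frames[1]
  for (tf in touch_frames[-1]) {
    if (tf - last > gap) {
      keep <- c(keep, tf)
      last <- tf
    }
  }
  keep
}

#' Behavioral discriminability d-prime
#'
#' `D' = Z(hit rate) - Z(false-alarm rate)` with `Z` the standard-normal
#' quantile function. Rates of exactly 0 or 1 are clamped to the
#' `1/(2N)` convention when trial counts are supplied (otherwise an error).
#'
#' @param hit_rate,fa_rate Rates in `[0, 1]`.
#' @param n_go,n_nogo Trial counts used for clamping extreme rates.
#' @return D-prime (dimensionless).
#' @export
dprime <- function(hit_rate, fa_rate, n_go = NULL, n_nogo = NULL) {
  clamp <- function(r, n, what) {
    if (r <= 0 || r >= 1) {
      if (is.null(n))
        stop(sprintf("%s rate of %g needs a trial count to clamp", what, r),
             call. = FALSE)
      message(sprintf("%s rate %g clamped by the 1/(2N) convention", what, r))
      r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    r
  }
  qnorm(clamp(hit_rate, n_go, "hit")) - qnorm(clamp(fa_rate, n_nogo, "false-alarm"))
}

#' Classify go/no-go trial outcomes
#'
#' go+lick = hit, go+no-lick = miss, no-go+lick = false alarm, no-go+no-lick
#' = correct rejection. A lick counts iff it falls inside the trial's
#' response window.
#'
#' @param stimuli Character vector, `"go"`/`"nogo"` per trial.
#' @param trial_starts Trial start times (s).
#' @param lick_times All lick times (s).
#' @param window Response window length after trial start (default 1.3 s).
#' @return Data.frame `stimulus`, `lick`, `outcome`, plus attributes
#'   `hit_rate`, `fa_rate`, `dprime`.
#' @export
classify_outcomes <- function(stimuli, trial_starts, lick_times,
                              window = 1.3) {
  stopifnot(length(stimuli) == length(trial_starts))
  licked <- vapply(trial_starts, function(t0)
    any(lick_times >= t0 & lick_times <= t0 + window), logical(1))
  outcome <- ifelse(stimuli == "go",
                    ifelse(licked, "hit", "miss"),
                    ifelse(licked, "FA", "CR"))
  out <- data.frame(stimulus = stimuli, lick = licked, outcome = outcome,
                    stringsAsFactors = FALSE)
  n_go <- sum(stimuli == "go"); n_nogo <- sum(stimuli != "go")
  hr <- if (n_go) sum(outcome == "hit") / n_go else NA_real_
  fr <- if (n_nogo) sum(outcome == "FA") / n_nogo else NA_real_
  attr(out, "hit_rate") <- hr
  attr(out, "fa_rate") <- fr
  attr(out, "dprime") <- if (is.na(hr) || is.na(fr)) NA_real_ else
    suppressMessages(dprime(hr, fr, n_go, n_nogo))
  out
}
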