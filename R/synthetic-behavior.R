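# Synthetic whisker pose tables: four labels per whisker following sinusoidal
# whisking, with touch episodes during which the tip enters the touch ROI and
# the whisker bends away from collinearity.

#' Specification of synthetic whisking behavior
#'
#' @param whisk_freq Whisking frequency in Hz.
#' @param whisk_amp Whisking amplitude at the tip, pixels.
#' @param duration Record duration in seconds.
#' @param frame_rate Video frame rate (fps).
#' @param touch_episodes Two-column matrix (or list of `c(start, end)`) of
#'   non-overlapping touch episodes in seconds.
#' @param whisker_length Whisker length in pixels.
#' @param pad Whisker-pad reference point `c(x, y)` in pixels.
#' @param bend_curvature Menger curvature (1/pixels) planted during touch.
#' @param roi_polygon Touch-surface polygon (n x 2, pixels); default a box
#'   around the touch-time tip position.
#' @param noise_sd Label jitter SD in pixels (applied to non-touch frames
#'   only; 0 keeps labels exactly collinear outside touch).
#' @param seed RNG seed.
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(whisk_freq = 8, whisk_amp = 60, duration = 2,
                          frame_rate = 500,
                          touch_episodes = rbind(c(0.5, 0.6), c(1.2, 1.35)),
                          whisker_length = 200, pad = c(0, 0),
                          bend_curvature = 0.002, roi_polygon = NULL,
                          noise_sd = 0, seed = 1) {
  if (is.list(touch_episodes)) touch_episodes <- do.call(rbind, touch_episodes)
  if (!is.null(touch_episodes) && nrow(touch_episodes) > 1) {
    ord <- order(touch_episodes[, 1])
    touch_episodes <- touch_episodes[ord, , drop = FALSE]
    if (any(touch_episodes[-1, 1] < touch_episodes[-nrow(touch_episodes), 2]))
      stop("touch episodes must not overlap", call. = FALSE)
  }
  structure(
    list(whisk_freq = whisk_freq, whisk_amp = whisk_amp, duration = duration,
         frame_rate = frame_rate, touch_episodes = touch_episodes,
         whisker_length = whisker_length, pad = pad,
         bend_curvature = bend_curvature, roi_polygon = roi_polygon,
         noise_sd = noise_sd, seed = seed),
    class = "behavior_spec"
  )
}

#' Generate a synthetic whisker pose table
#'
#' Four labels, ordered base to tip and evenly spaced along the whisker,
#' follow a sinusoidal angle `theta(t)`. During touch episodes the angle is
#' clamped at the protraction extreme (the tip sits inside the ROI polygon)
#' and the three distal labels are bent off the shaft line with the planted
#' Menger curvature; outside episodes the labels are exactly collinear.
#'
#' @param spec A [behavior_spec()].
#' @return A data.frame pose table with columns `frame`, `label`, `x_px`,
#'   `y_px` and attribute `ground_truth`: list with `touch_frames`,
#'   `angle_rad` per frame, `roi_polygon` and frame rate.
#' @export
generate_whisker_traces <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  n_frames <- round(spec$duration * spec$frame_rate)
  t <- (seq_len(n_frames) - 1L) / spec$frame_rate
  amp_rad <- spec$whisk_amp / spec$whisker_length
  theta <- amp_rad * sin(2 * pi * spec$whisk_freq * t)

  touch <- rep(FALSE, n_frames)
  eps <- spec$touch_episodes
  if (!is.null(eps)) {
    for (i in seq_len(nrow(eps))) {
      touch[t >= eps[i, 1] & t < eps[i, 2]] <- TRUE
    }
  }
  theta[touch] <- amp_rad  # clamped at maximal protraction against the pole

  frac <- (1:4) / 4  # label positions along the shaft, base -> tip
  x <- spec$pad[1] + outer(cos(theta), frac * spec$whisker_length)
  y <- spec$pad[2] + outer(sin(theta), frac * spec$whisker_length)

  # Bend during touch: displace labels perpendicular to the shaft by
  # c/2 * s^2 (arc of curvature c), measured from the base label.
  if (any(touch) && spec$bend_curvature > 0) {
    s <- (frac - frac[1]) * spec$whisker_length
    off <- spec$bend_curvature / 2 * s^2
    # bend beyond maximal protraction so only clamped frames reach the ROI
    nx <- -sin(amp_rad); ny <- cos(amp_rad)
    x[touch, ] <- x[touch, , drop = FALSE] + rep(off * nx, each = sum(touch))
    y[touch, ] <- y[touch, , drop = FALSE] + rep(off * ny, each = sum(touch))
  }
  if (spec$noise_sd > 0) {
    jit <- with_seed(spec$seed, matrix(rnorm(2 * length(x), sd = spec$noise_sd),
                                       ncol = 8))
    x[!touch, ] <- x[!touch, , drop = FALSE] + jit[!touch, 1:4, drop = FALSE]
    y[!touch, ] <- y[!touch, , drop = FALSE] + jit[!touch, 5:8, drop = FALSE]
  }

  roi <- spec$roi_polygon
  if (is.null(roi)) {
    # box around the touch-time (bent) tip position
    off_tip <- if (spec$bend_curvature > 0)
      spec$bend_curvature / 2 * ((1 - 1/4) * spec$whisker_length)^2 else 0
    tip <- c(spec$pad[1] + cos(amp_rad) * spec$whisker_length - off_tip * sin(amp_rad),
             spec$pad[2] + sin(amp_rad) * spec$whisker_length + off_tip * cos(amp_rad))
    half <- spec$whisker_length * 0.04
    roi <- cbind(tip[1] + c(-half, half, half, -half),
                 tip[2] + c(-half, -half, half, half))
  }

  pose <- data.frame(
    frame = rep(seq_len(n_frames), 4L),
    label = rep(1:4, each = n_frames),
    x_px = as.numeric(x), y_px = as.numeric(y)
  )
  attr(pose, "ground_truth") <- list(
    touch_frames = which(touch), angle_rad = theta, roi_polygon = roi,
    frame_rate = spec$frame_rate
  )
  pose
}
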