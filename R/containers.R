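# Core data containers. Plain lists with light S3 classes, matching how
# signal-processing pipelines in this field pass multichannel records around.

#' Construct a grid LFP record
#'
#' Holds a channels x samples surface-potential matrix together with the
#' per-channel electrode coordinates and the sampling rate. This is the
#' substrate of all wave analysis.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param coords Numeric matrix, channels x 2, electrode (x, y) in mm.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `grid_lfp`.
#' @export
grid_lfp <- function(data, coords, fs, t0 = 0) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(data))
    stop("`coords` must have one row per channel", call. = FALSE)
  if (anyDuplicated(coords))
    stop("electrode coordinates must be unique per channel", call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  structure(
    list(data = data, coords = coords, fs = fs, t0 = t0),
    class = "grid_lfp"
  )
}

#' @export
print.grid_lfp <- function(x, ...) {
  cat(sprintf("<grid_lfp> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples of a grid record
#' @param x A `grid_lfp`.
#' @return Integer count.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname n_channels
#' @export
n_samples <- function(x) ncol(x$data)

#' Time axis of a grid record
#' @param x A `grid_lfp` or `analytic_field`.
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis <- function(x) {
  n <- if (is.matrix(x$data)) ncol(x$data) else ncol(x$phase)
  x$t0 + (seq_len(n) - 1L) / x$fs
}

#' Construct an analytic field
#'
#' Phase, amplitude, instantaneous frequency, and validity mask of a
#' multichannel analytic signal, aligned with the source `grid_lfp`.
#'
#' @param phase Channels x samples matrix of instantaneous phase in
#'   (-pi, pi]; `NA` where undefined.
#' @param amp Channels x samples matrix of instantaneous amplitude (uV).
#' @param freq Channels x samples matrix of instantaneous frequency (Hz).
#' @param mask Logical channels x samples matrix; `TRUE` marks samples that
#'   are valid for wave evaluation.
#' @param fs Sampling rate (Hz).
#' @param coords Electrode coordinates (mm), channels x 2.
#' @param t0 Time of first sample (s).
#' @return An object of class `analytic_field`.
#' @export
analytic_field <- function(phase, amp, freq, mask, fs, coords, t0 = 0) {
  structure(
    list(phase = phase, amp = amp, freq = freq, mask = mask,
         fs = fs, coords = coords, t0 = t0),
    class = "analytic_field"
  )
}

#' @export
print.analytic_field <- function(x, ...) {
  cat(sprintf("<analytic_field> %d channels x %d samples @ %g Hz (%.1f%% masked)\n",
              nrow(x$phase), ncol(x$phase), x$fs, 100 * mean(!x$mask)))
  invisible(x)
}

#' Construct a calcium raster
#'
#' @param dff Cells x frames matrix of dF/F.
#' @param deconv Cells x frames matrix of deconvolved event amplitudes.
#' @param centroids Cells x 2 matrix of ROI centroids (um).
#' @param frame_rate Imaging frame rate (Hz).
#' @return An object of class `calcium_raster`.
#' @export
calcium_raster <- function(dff, deconv, centroids, frame_rate) {
  dff <- as.matrix(dff); deconv <- as.matrix(deconv)
  if (!identical(dim(dff), dim(deconv)))
    stop("`dff` and `deconv` must have the same dimensions", call. = FALSE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  structure(
    list(dff = dff, deconv = deconv, centroids = centroids,
         frame_rate = frame_rate),
    class = "calcium_raster"
  )
}

#' @export
print.calcium_raster <- function(x, ...) {
  cat(sprintf("<calcium_raster> %d cells x %d frames @ %g Hz\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate))
  invisible(x)
}

#' Construct a laminar LFP record
#'
#' @param data Channels x samples matrix (uV), ordered superficial to deep.
#' @param dz_um Uniform electrode spacing in um.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of first sample (s).
#' @return An object of class `laminar_lfp`.
#' @export
laminar_lfp <- function(data, dz_um, fs, t0 = 0) {
  data <- as.matrix(data)
  if (nrow(data) < 5L)
    stop("a laminar record needs at least 5 channels", call. = FALSE)
  stopifnot_scalar(dz_um, "dz_um", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  structure(list(data = data, dz_um = dz_um, fs = fs, t0 = t0),
            class = "laminar_lfp")
}

#' @export
print.laminar_lfp <- function(x, ...) {
  cat(sprintf("<laminar_lfp> %d channels (dz = %g um) x %d samples @ %g Hz\n",
              nrow(x$data), x$dz_um, ncol(x$data), x$fs))
  invisible(x)
}
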