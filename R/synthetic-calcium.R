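# Synthetic calcium rasters with planted co-active ensembles over a
# background event rate; ground-truth memberships make the ensemble pipeline
# testable end to end.

#' Specification of a planted-ensemble calcium raster
#'
#' Each ensemble is a set of member cells that reactivate together: in every
#' frame the ensemble fires with its co-activation probability, and when it
#' does, every member emits a deconvolved event of the given amplitude.
#' Ensembles activate independently of one another; all cells additionally
#' emit background events. dF/F is the event train convolved with an
#' exponential calcium kernel plus white noise.
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames.
#' @param frame_rate Imaging rate in Hz.
#' @param ensembles List of ensembles, each a list with `members` (cell ids),
#'   `p_active` (co-activation probability per frame, in `[0,1]`) and
#'   `amplitude` (event amplitude, dF/F units).
#' @param background_rate Background events per frame per cell.
#' @param noise_sd dF/F noise SD.
#' @param calcium_kernel Decay time constant of the calcium kernel, seconds.
#' @param seed RNG seed.
#' @return An `ensemble_raster_spec` list.
#' @export
ensemble_raster_spec <- function(n_cells = 200, n_frames = 1200,
                                 frame_rate = 20,
                                 ensembles = list(
                                   list(members = 1:8,  p_active = 0.3, amplitude = 0.5),
                                   list(members = 9:16, p_active = 0.3, amplitude = 0.5)
                                 ),
                                 background_rate = 0.005, noise_sd = 0.05,
                                 calcium_kernel = 0.5, seed = 1) {
  for (e in ensembles) {
    if (any(e$members < 1 | e$members > n_cells))
      stop("ensemble member id out of range", call. = FALSE)
    if (e$p_active < 0 || e$p_active > 1)
      stop("co-activation probability must be in [0, 1]", call. = FALSE)
  }
  all_members <- unlist(lapply(ensembles, `[[`, "members"))
  if (anyDuplicated(all_members))
    message("note: ensembles overlap in membership")
  structure(
    list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
         frame_rate = frame_rate, ensembles = ensembles,
         background_rate = background_rate, noise_sd = noise_sd,
         calcium_kernel = calcium_kernel, seed = seed),
    class = "ensemble_raster_spec"
  )
}

#' Generate a calcium raster with planted ensembles
#'
#' @param spec An [ensemble_raster_spec()].
#' @return A [calcium_raster()] with attribute `ground_truth`: a list with
#'   `members` (list of member-id vectors) and `active_frames` (list of the
#'   frames in which each ensemble reactivated).
#' @export
generate_calcium_raster <- function(spec) {
  stopifnot(inherits(spec, "ensemble_raster_spec"))
  with_seed(spec$seed, {
    deconv <- matrix(0, spec$n_cells, spec$n_frames)
    if (spec$background_rate > 0) {
      bg <- matrix(
        rbinom(spec$n_cells * spec$n_frames, 1L, min(1, spec$background_rate)),
        spec$n_cells
      )
      bg_amp <- if (length(spec$ensembles))
        mean(vapply(spec$ensembles, `[[`, 1, "amplitude")) else 0.5
      deconv <- deconv + bg * bg_amp
    }
    active_frames <- vector("list", length(spec$ensembles))
    for (i in seq_along(spec$ensembles)) {
      e <- spec$ensembles[[i]]
      act <- which(runif(spec$n_frames) < e$p_active)
      active_frames[[i]] <- act
      deconv[e$members, act] <- e$amplitude
    }
    # dF/F: events convolved with a causal exponential kernel + noise
    tau_frames <- spec$calcium_kernel * spec$frame_rate
    kern <- exp(-(0:ceiling(6 * tau_frames)) / tau_frames)
    dff <- t(apply(deconv, 1, function(row) {
      convolve(row, rev(kern), type = "open")[seq_along(row)]
    }))
    if (spec$noise_sd > 0)
      dff <- dff + matrix(rnorm(length(dff), sd = spec$noise_sd), nrow(dff))
    centroids <- cbind(runif(spec$n_cells, 0, 500), runif(spec$n_cells, 0, 500))
    out <- calcium_raster(dff, deconv, centroids, spec$frame_rate)
    attr(out, "ground_truth") <- list(
      members = lapply(spec$ensembles, `[[`, "members"),
      active_frames = active_frames
    )
    out
  })
}
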