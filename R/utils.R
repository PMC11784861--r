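# Internal helpers shared across modules.

#' @importFrom stats approx coef cor fft lm median mvfft qnorm quantile rbinom
#'   rnorm rpois runif sd splinefun var nextn
#' @importFrom utils head tail write.table read.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Named canonical frequency bands (Hz).
#' Canonical analysis frequency bands
#'
#' Band edges in Hz used throughout the pipeline: wideband 3-40 (wave
#' detection), gamma 30-90, beta 15-30, theta 4-12.
#'
#' @param name One of `"wideband"`, `"gamma"`, `"beta"`, `"theta"`.
#' @return Numeric length-2 vector `c(lo, hi)` in Hz.
#' @export
analysis_band <- function(name = c("wideband", "gamma", "beta", "theta")) {
  name <- match.arg(name)
  switch(name,
    wideband = c(3, 40),
    gamma    = c(30, 90),
    beta     = c(15, 30),
    theta    = c(4, 12)
  )
}

# Linear index helpers for a rows x cols electrode lattice stored row-major
# (channel 1 = top-left, increasing along columns first).
grid_coords <- function(rows, cols, pitch_mm) {
  xy <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cbind(x = (xy$col - 1) * pitch_mm, y = (xy$row - 1) * pitch_mm)
}
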