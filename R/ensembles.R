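# Calcium ensemble pipeline: event binarization, 300-ms activity vectors,
# cosine similarity map with shuffle-based significance, eigenvalue-gated
# state detection, and Sorensen-Dice functional connectivity.

#' Range-normalize fluorescence traces
#'
#' `F_centered = (F - F_avg) / (F_max - F_min)` per cell. Constant traces
#' cannot be normalized and are flagged and excluded.
#'
#' @param raster A [calcium_raster()] (or a cells x frames matrix).
#' @return Matrix of centered traces with attribute `excluded` (row indices
#'   of constant cells, whose rows are `NA`).
#' @export
center_fluorescence <- function(raster) {
  f <- if (inherits(raster, "calcium_raster")) raster$dff else as.matrix(raster)
  rng <- apply(f, 1, function(x) diff(range(x)))
  excluded <- which(rng == 0)
  out <- (f - rowMeans(f)) / rng
  if (length(excluded)) out[excluded, ] <- NA_real_
  structure(out, excluded = excluded)
}

# Robust per-cell noise SD of the deconvolved trace, estimated from the
# dF/F residual variability on deconv-silent frames (MAD scaled to SD).
noise_floor_sd <- function(raster) {
  vapply(seq_len(nrow(raster$deconv)), function(i) {
    silent <- raster$deconv[i, ] == 0
    if (sum(silent) < 10L) silent <- rep(TRUE, ncol(raster$deconv))
    x <- raster$dff[i, silent]
    stats::mad(diff(x)) / sqrt(2)
  }, numeric(1))
}

#' Binarize deconvolved calcium events
#'
#' Event frames are those whose deconvolved amplitude exceeds `k_sd` times
#' the per-cell noise floor (MAD-based SD of the dF/F on deconv-silent
#' frames; deconvolved amplitudes share the dF/F scale).
#'
#' @param raster A [calcium_raster()].
#' @param k_sd Threshold multiple of the noise SD (default 2.5).
#' @return Logical cells x frames matrix with attributes `threshold`
#'   (per-cell event thresholds) and `noise_sd`.
#' @export
binarize_events <- function(raster, k_sd = 2.5) {
  stopifnot(inherits(raster, "calcium_raster"))
  noise <- noise_floor_sd(raster)  # deconvolved amplitudes share dF/F units
  thr <- k_sd * noise
  out <- raster$deconv > thr
  structure(out, threshold = thr, noise_sd = noise)
}

#' Bin binary events into activity vectors
#'
#' Sums events per neuron in non-overlapping `bin_ms` bins. A partial final
#' bin is dropped (with a message). Event counts are conserved over the
#' retained bins.
#'
#' @param binary Logical/numeric cells x frames matrix.
#' @param frame_rate Frames per second.
#' @param bin_ms Bin width in milliseconds (default 300).
#' @return Numeric cells x bins matrix with attributes `frames_per_bin` and
#'   `bin_frames` (list of frame indices per bin).
#' @export
vectorize_events <- function(binary, frame_rate, bin_ms = 300) {
  fpb <- max(1L, round(bin_ms / 1000 * frame_rate))
  n_frames <- ncol(binary)
  n_bins <- n_frames %/% fpb
  if (n_bins * fpb < n_frames)
    message(sprintf("dropped a partial final bin of %d frame(s)",
                    n_frames - n_bins * fpb))
  if (n_bins == 0L) stop("record shorter than one bin", call. = FALSE)
  grp <- rep(seq_len(n_bins), each = fpb)
  m <- binary[, seq_len(n_bins * fpb), drop = FALSE] * 1
  vec <- t(apply(m, 1, function(r) tapply(r, grp, sum)))
  if (n_bins == 1L) vec <- matrix(as.numeric(vec), ncol = 1L)
  structure(vec, frames_per_bin = fpb,
            bin_frames = split(seq_len(n_bins * fpb), grp))
}

#' Cosine similarity map of activity vectors
#'
#' `SI(i, j) = (t_i . t_j) / (||t_i|| ||t_j||)` for every pair of activity
#' vectors (bins). Zero vectors are excluded (rows/columns `NA`).
#'
#' @param vectors Cells x bins matrix from [vectorize_events()].
#' @return Bins x bins symmetric similarity matrix with attribute `nonzero`
#'   (logical per bin).
#' @export
similarity_map <- function(vectors) {
  if (ncol(vectors) < 2L) stop("need at least two activity vectors", call. = FALSE)
  nrm <- sqrt(colSums(vectors^2))
  nz <- nrm > 0
  v <- sweep(vectors[, , drop = FALSE], 2, pmax(nrm, 1e-300), `/`)
  si <- crossprod(v)
  si[!nz, ] <- NA_real_; si[, !nz] <- NA_real_
  structure(si, nonzero = nz)
}

#' Shuffle surrogates and significance thresholds
#'
#' Builds spatiotemporal surrogates of the binary event matrix: each
#' neuron's events are temporally permuted across frames, then events are
#' swapped between ROI pairs (event shuffle). From `n_iter` surrogates it
#' collects the null distributions of (i) per-frame population coactivity,
#' (ii) pairwise cosine similarity, and (iii) similarity-map eigenvalues,
#' and returns their 99th-percentile thresholds.
#'
#' @param binary Logical cells x frames event matrix.
#' @param frame_rate Frames per second.
#' @param bin_ms Bin width for the similarity stage (ms).
#' @param n_iter Number of surrogates (default 1000; eigenvalue nulls use at
#'   most `n_eig_iter` of them).
#' @param n_eig_iter Surrogates used for the eigenvalue null (default 100).
#' @param seed RNG seed.
#' @return A `shuffle_null` list with `coactivity_threshold`,
#'   `si_threshold`, `eig_threshold`, and the null samples.
#' @export
shuffle_surrogates <- function(binary, frame_rate, bin_ms = 300,
                               n_iter = 1000, n_eig_iter = 100, seed = 1) {
  if (!length(binary) || !any(binary))
    stop("binary event matrix is empty", call. = FALSE)
  n <- nrow(binary); tt <- ncol(binary)
  with_seed(seed, {
    coact <- numeric(0); si_null <- numeric(0); eig_null <- numeric(0)
    for (it in seq_len(n_iter)) {
      shuf <- t(apply(binary, 1, function(r) r[sample.int(tt)]))
      # event shuffle across ROI pairs: swap the event trains of random pairs
      pr <- sample.int(n)
      half <- n %/% 2
      if (half > 0) {
        a <- pr[seq_len(half)]; b <- pr[half + seq_len(half)]
        tmp <- shuf[a, , drop = FALSE]
        shuf[a, ] <- shuf[b, , drop = FALSE]
        shuf[b, ] <- tmp
      }
      coact <- c(coact, colSums(shuf))
      if (it <= n_eig_iter) {
        vec <- suppressMessages(vectorize_events(shuf, frame_rate, bin_ms))
        si <- suppressMessages(similarity_map(vec))
        off <- si[upper.tri(si)]
        si_null <- c(si_null, off[is.finite(off)])
        si0 <- si; si0[!is.finite(si0)] <- 0; diag(si0) <- 0
        eig_null <- c(eig_null, max(eigen(si0, symmetric = TRUE,
                                          only.values = TRUE)$values))
      }
    }
    structure(
      list(coactivity_threshold = quantile(coact, 0.99, names = FALSE),
           si_threshold = quantile(si_null, 0.99, names = FALSE),
           eig_threshold = quantile(eig_null, 0.99, names = FALSE),
           coactivity_null = coact, si_null = si_null, eig_null = eig_null),
      class = "shuffle_null"
    )
  })
}

#' Eigenvalue-gated ensemble candidate states
#'
#' Eigendecomposition of the (significance-masked, zero-diagonal) similarity
#' map. Components whose eigenvalues exceed the shuffled-eigenvalue
#' threshold are retained up to 90% cumulative variance; activity vectors
#' are projected onto the retained components and bins whose similarity to
#' at least one other bin is significant form the candidate state frames.
#'
#' @param map Similarity matrix from [similarity_map()].
#' @param vectors Activity vectors (cells x bins).
#' @param null A [shuffle_surrogates()] result.
#' @param var_capture Cumulative variance cap (default 0.9).
#' @return List: `n_components`, `eigenvalues`, `components` (bins x k,
#'   orthonormal), `state_bins` (indices of significant bins),
#'   `reactivation_index` (per bin: fraction of partners with significant
#'   similarity), `reactivation_count`.
#' @export
svd_ensembles <- function(map, vectors, null, var_capture = 0.9) {
  m <- map
  m[!is.finite(m)] <- 0
  diag(m) <- 0
  eg <- eigen(m, symmetric = TRUE)
  sig <- which(eg$values > null$eig_threshold)
  if (length(sig)) {
    # smallest prefix of significant components reaching the variance cap
    pos <- pmax(eg$values, 0)
    cumvar <- cumsum(pos[sig]) / sum(pos)
    cut <- which(cumvar >= var_capture)
    keep <- sig[seq_len(if (length(cut)) cut[1] else length(sig))]
  } else keep <- integer(0)
  n_bins <- ncol(m)
  si_sig <- map > null$si_threshold
  si_sig[!is.finite(map)] <- FALSE
  diag(si_sig) <- FALSE
  react_count <- rowSums(si_sig)
  react_frac <- react_count / pmax(n_bins - 1, 1)
  state_bins <- if (length(keep)) which(react_count > 0) else integer(0)
  list(
    n_components = length(keep),
    eigenvalues = eg$values,
    components = eg$vectors[, keep, drop = FALSE],
    state_bins = state_bins,
    reactivation_index = react_frac,
    reactivation_count = react_count
  )
}

#' Sorensen-Dice functional connectivity on candidate state frames
#'
#' For each neuron pair, the Dice coefficient of their binary event trains
#' restricted to the candidate state frames: `2|A n B| / (|A| + |B|)`.
#' Pairs above `dice_thresh` form functional connections; connected neurons
#' are grouped into ensembles by deterministic greedy modularity clustering
#' of the weighted connection graph. Neurons with no events in the state
#' frames are excluded.
#'
#' @param binary Logical cells x frames event matrix.
#' @param state_frames Frame indices of the candidate states.
#' @param dice_thresh Connection threshold (default 0.25).
#' @param min_members Minimum ensemble size (default 2).
#' @param alpha Familywise significance level of the per-pair co-firing
#'   gate (hypergeometric overlap test, Bonferroni over active pairs); set
#'   to 1 to disable and use the Dice cut-off alone.
#' @return List: `dice` (full pairwise matrix), `edges` (data.frame pair
#'   list with weights), `membership` (list of member-id vectors per
#'   ensemble), `node_strength`, `n_connections` (per neuron).
#' @export
sdc_connectivity <- function(binary, state_frames, dice_thresh = 0.25,
                             min_members = 2, alpha = 0.01) {
  b <- binary[, state_frames, drop = FALSE] * 1
  counts <- rowSums(b)
  active <- counts > 0
  n <- nrow(b)
  nt <- ncol(b)
  dice <- matrix(0, n, n)
  sig <- matrix(TRUE, n, n)
  if (sum(active) >= 2) {
    ba <- b[active, , drop = FALSE]
    inter <- tcrossprod(ba)
    ca <- rowSums(ba)
    tot <- outer(ca, ca, `+`)
    dice[active, active] <- 2 * inter / tot
    if (alpha < 1) {
      # overlap above chance for the pair's event counts (hypergeometric),
      # Bonferroni-corrected over the active pairs
      n_pairs <- sum(active) * (sum(active) - 1) / 2
      p <- stats::phyper(inter - 1, outer(ca, rep(1, length(ca))),
                         nt - outer(ca, rep(1, length(ca))),
                         outer(rep(1, length(ca)), ca),
                         lower.tail = FALSE)
      sig[active, active] <- p < alpha / max(1, n_pairs)
    }
  }
  diag(dice) <- 0
  adj <- dice > dice_thresh & sig
  edges_idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = edges_idx[, 1], to = edges_idx[, 2],
                      weight = dice[edges_idx])
  membership <- list()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    grp <- split(as.integer(igraph::V(g)$name), igraph::membership(comm))
    membership <- Filter(function(m) length(m) >= min_members, grp)
    membership <- unname(membership[order(vapply(membership, min, 1L))])
  }
  w <- dice * adj
  list(dice = dice, edges = edges, membership = membership,
       node_strength = rowSums(w), n_connections = rowSums(adj))
}

#' Full ensemble-detection pipeline
#'
#' Binarize, vectorize (300-ms bins), similarity map, shuffle-based
#' significance, eigenvalue gate, then Dice connectivity on candidate state
#' frames. Returns an empty set when no eigenvalue beats the shuffled null.
#'
#' @param raster A [calcium_raster()].
#' @param bin_ms Bin width (ms).
#' @param dice_thresh Dice connection threshold (default 0.25).
#' @param n_shuffles Surrogates for thresholds (default 1000).
#' @param seed RNG seed.
#' @return An `ensemble_set` list: `ensembles` (per ensemble: `members`,
#'   `size`, `n_connections`, `weights`, `reactivation`), `membership`,
#'   `n_components`, `reactivation_index` (per bin), `null`, `connectivity`.
#' @export
detect_ensembles <- function(raster, bin_ms = 300, dice_thresh = 0.25,
                             n_shuffles = 1000, seed = 1) {
  binary <- binarize_events(raster)
  if (!any(binary)) return(empty_ensemble_set())
  null <- shuffle_surrogates(binary, raster$frame_rate, bin_ms,
                             n_iter = n_shuffles, seed = seed)
  vectors <- suppressMessages(vectorize_events(binary, raster$frame_rate, bin_ms))
  map <- similarity_map(vectors)
  cand <- svd_ensembles(map, vectors, null)
  if (cand$n_components == 0L || !length(cand$state_bins))
    return(empty_ensemble_set(null = null, candidates = cand))
  state_frames <- unlist(attr(vectors, "bin_frames")[cand$state_bins],
                         use.names = FALSE)
  conn <- sdc_connectivity(binary, state_frames, dice_thresh)
  ens <- lapply(conn$membership, function(m) {
    w <- conn$dice[m, m, drop = FALSE]
    wvec <- w[upper.tri(w)]
    # ensemble reactivation: over state frames where member coactivity
    # exceeds the ensemble's share of the shuffled coactivity threshold,
    # the mean proportion of members that are coactive
    co <- colSums(binary[m, state_frames, drop = FALSE])
    chance <- max(1, null$coactivity_threshold * length(m) / nrow(binary))
    hit <- co > chance
    list(members = m, size = length(m),
         n_connections = sum(conn$n_connections[m]) / 2,
         weights = wvec[wvec > dice_thresh],
         reactivation = if (any(hit)) mean(co[hit]) / length(m) else 0)
  })
  structure(
    list(ensembles = ens, membership = conn$membership,
         n_components = cand$n_components,
         reactivation_index = cand$reactivation_index,
         null = null, connectivity = conn),
    class = "ensemble_set"
  )
}

empty_ensemble_set <- function(null = NULL, candidates = NULL) {
  structure(
    list(ensembles = list(), membership = list(),
         n_components = if (is.null(candidates)) 0L else candidates$n_components,
         reactivation_index = numeric(0), null = null,
         connectivity = NULL),
    class = "ensemble_set"
  )
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %d ensemble(s), %d significant component(s)\n",
              length(x$ensembles), x$n_components))
  invisible(x)
}

#' Split ensemble metrics by late-wave trial class
#'
#' Runs the ensemble pipeline separately on the frames belonging to each
#' late-wave class and returns per-group summary metrics. Groups with fewer
#' than `min_trials` trials are flagged unstable (metrics `NA`).
#'
#' @param raster A [calcium_raster()].
#' @param trial_frames List (per trial) of frame-index vectors for the
#'   ensemble-extraction window (e.g. -0.5 s to +4 s around touch).
#' @param labels Character vector per trial, `"strong"`/`"weak"` (from
#'   [classify_late_wave()]).
#' @param min_trials Minimum trials per group (default 3).
#' @param ... Passed to [detect_ensembles()].
#' @return Named list per group: `n_trials`, `flagged`, `ensembles` (the
#'   `ensemble_set`), and summary vectors `size`, `n_connections`,
#'   `reactivation`, `weights`.
#' @export
split_by_late_wave <- function(raster, trial_frames, labels, min_trials = 3,
                               ...) {
  stopifnot(length(trial_frames) == length(labels))
  out <- lapply(split(seq_along(labels), labels), function(tr_idx) {
    frames <- sort(unique(unlist(trial_frames[tr_idx])))
    flagged <- length(tr_idx) < min_trials
    if (flagged || length(frames) < 2L)
      return(list(n_trials = length(tr_idx), flagged = TRUE,
                  ensembles = NULL, size = NA_real_,
                  n_connections = NA_real_, reactivation = NA_real_,
                  weights = numeric(0)))
    sub <- calcium_raster(raster$dff[, frames, drop = FALSE],
                          raster$deconv[, frames, drop = FALSE],
                          raster$centroids, raster$frame_rate)
    es <- detect_ensembles(sub, ...)
    list(
      n_trials = length(tr_idx), flagged = FALSE, ensembles = es,
      size = vapply(es$ensembles, `[[`, numeric(1), "size"),
      n_connections = vapply(es$ensembles, `[[`, numeric(1), "n_connections"),
      reactivation = vapply(es$ensembles, `[[`, numeric(1), "reactivation"),
      weights = unlist(lapply(es$ensembles, `[[`, "weights"))
    )
  })
  out
}
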