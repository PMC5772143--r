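#' Tracking parameter set
#'
#' Defaults follow the study settings: 0.2 mm steps, FOD amplitude
#' stopping criterion 0.1, streamline length restricted to 10-200 mm.
#'
#' @param angular_threshold maximum turning angle per step (degrees),
#'   in (0, 90\\].
#' @param step_size step length (mm), > 0.
#' @param stop_amplitude minimum FOD amplitude for a direction to remain
#'   eligible.
#' @param min_length,max_length streamline length bounds (mm).
#' @param n_streamlines number of streamlines to keep.
#' @param seed integer RNG seed, recorded in provenance.
#' @return Object of class `tracking_params`.
#' @export
tracking_params <- function(angular_threshold = 47.2, step_size = 0.2,
                            stop_amplitude = 0.1, min_length = 10,
                            max_length = 200, n_streamlines = 5000L,
                            seed = 1L) {
  if (step_size <= 0) stop("step_size must be > 0")
  if (angular_threshold <= 0 || angular_threshold > 90)
    stop("angular_threshold must be in (0, 90]")
  if (min_length >= max_length) stop("min_length must be < max_length")
  structure(list(angular_threshold = angular_threshold,
                 step_size = step_size, stop_amplitude = stop_amplitude,
                 min_length = min_length, max_length = max_length,
                 n_streamlines = as.integer(n_streamlines),
                 seed = as.integer(seed)),
            class = "tracking_params")
}

#' Probabilistic streamline tractography
#'
#' Streamlines are grown bidirectionally from points sampled uniformly
#' inside randomly selected seed voxels. At each 0.2-mm (by default) step
#' the next direction is drawn from the tessellated FOD amplitudes
#' (trilinear interpolation between voxels) restricted to the cone of
#' `angular_threshold` degrees about the incoming direction, with
#' probability proportional to amplitude. A half terminates when the
#' proposed point leaves the white-matter mask (the exit point is kept,
#' matching termination at the grey-matter interface), when no in-cone
#' direction reaches `stop_amplitude`, or when the length budget is
#' exhausted. Streamlines shorter than `min_length` are discarded.
#'
#' @param fod a `fod_volume` (from [deconvolve_fod()]) or `peak_volume`.
#' @param seed_mask logical mask of seed voxels (e.g. the GWMI).
#' @param wm_mask logical white-matter mask.
#' @param params a [tracking_params()].
#' @param max_attempts attempt budget (default 100 x n_streamlines).
#' @return A [tractogram()] with full provenance.
#' @export
track <- function(fod, seed_mask, wm_mask, params,
                  max_attempts = 100L * params$n_streamlines) {
  grid <- fod$grid
  seed_mask <- resolve_mask(seed_mask, grid)
  wm_mask <- resolve_mask(wm_mask, grid)
  seed_idx <- which(seed_mask) - 1L
  if (!length(seed_idx)) stop("empty seed mask")
  sph <- default_sphere()
  dirs <- sph$vertices
  amp <- amplitude_grid(fod, dirs)
  cth <- cos(params$angular_threshold * pi / 180)
  dp <- dirs %*% t(dirs)
  cone <- lapply(seq_len(nrow(dirs)), function(d)
    which(dp[d, ] >= cth - 1e-12) - 1L)
  antipode <- apply(-dirs %*% t(dirs), 1L, which.max) - 1L
  set.seed(params$seed)
  res <- track_cpp(amp, dirs, cone, antipode, grid$shape, grid$affine[1:3, ],
                   solve(grid$affine)[1:3, ],
                   as.integer(wm_mask), as.integer(seed_idx),
                   params$step_size, params$stop_amplitude,
                   params$min_length, params$max_length,
                   params$n_streamlines, as.integer(max_attempts))
  if (!length(res$streamlines))
    warning("no streamline survived the length and amplitude criteria")
  tractogram(res$streamlines,
             provenance = c(unclass(params),
                            list(attempts = res$attempts,
                                 n_seed_voxels = length(seed_idx))))
}

# nvox x ndir FOD amplitude grid on a signed direction set (clamped at 0)
amplitude_grid <- function(fod, dirs) {
  nvox <- prod(fod$grid$shape)
  amp <- matrix(0, nvox, nrow(dirs))
  if (inherits(fod, "fod_volume")) {
    amp[fod$voxel_index, ] <- pmax(0, fod_amplitudes(fod, dirs))
  } else if (inherits(fod, "peak_volume")) {
    # assign each peak's amplitude to its nearest tessellation direction
    # and that direction's antipode
    for (v in seq_along(fod$voxel_index)) {
      k <- fod$n_peaks[v]
      if (!k) next
      for (q in seq_len(k)) {
        d <- fod$directions[v, q, ]
        s <- dirs %*% d
        amp[fod$voxel_index[v], which.max(s)] <- fod$amplitudes[v, q]
        amp[fod$voxel_index[v], which.max(-s)] <- fod$amplitudes[v, q]
      }
    }
  } else stop("fod must be a fod_volume or peak_volume")
  amp
}

#' Multi-angular-threshold tracking ensemble
#'
#' Runs [track()] once per angular threshold (defaults to the four study
#' settings 5.7, 11.5, 23.1 and 47.2 degrees) with distinct RNG
#' substreams derived from the base seed, producing one candidate
#' tractogram per setting.
#'
#' @param fod,seed_mask,wm_mask as in [track()].
#' @param base_params a [tracking_params()]; its angular threshold is
#'   overridden per setting.
#' @param angular_thresholds numeric vector of cone half-angles (degrees).
#' @param n_per_setting streamlines per setting (overrides
#'   `base_params$n_streamlines` when given).
#' @return list of [tractogram()]s, one per threshold.
#' @export
generate_ensemble <- function(fod, seed_mask, wm_mask,
                              base_params = tracking_params(),
                              angular_thresholds = c(5.7, 11.5, 23.1, 47.2),
                              n_per_setting = NULL) {
  if (!length(angular_thresholds)) stop("need at least one angular threshold")
  lapply(seq_along(angular_thresholds), function(i) {
    p <- base_params
    p$angular_threshold <- angular_thresholds[i]
    if (!is.null(n_per_setting)) p$n_streamlines <- as.integer(n_per_setting)
    p$seed <- base_params$seed + 1000L * i
    track(fod, seed_mask, wm_mask, p)
  })
}
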