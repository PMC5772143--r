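#' Bundle geometry for the synthetic phantom
#'
#' A tube of constant radius around a polyline centerline, carrying a
#' within-tube fibre volume fraction.
#'
#' @param name bundle name.
#' @param centerline c x 3 matrix of control points (mm), >= 3 rows.
#' @param radius tube radius (mm), > 0.
#' @param volume_fraction intra-bundle fibre volume fraction in (0, 1].
#' @return Object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(name, centerline, radius, volume_fraction = 0.8) {
  centerline <- matrix(as.numeric(centerline), ncol = 3L)
  if (nrow(centerline) < 3L) stop("centerline needs >= 3 control points")
  if (radius <= 0) stop("radius must be positive")
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be in (0, 1]")
  arc <- sum(sqrt(rowSums(diff(centerline)^2)))
  if (arc < 4 * radius)
    stop("centerline arc length must be >= 4 x radius")
  structure(list(name = name, centerline = centerline, radius = radius,
                 volume_fraction = volume_fraction, arc_length = arc),
            class = "bundle_geometry")
}

#' Phantom specification
#'
#' Collects everything needed to simulate a multi-session single-shell
#' acquisition over a voxel grid: bundle geometries, grey-matter ROI
#' spheres, compartment diffusivities, the Rician noise scale and the
#' gradient table.
#'
#' Diffusivity defaults are typical white-matter / free-water literature
#' values (mm^2/s). `noise_sigma` is the Gaussian channel scale of the
#' Rician noise in signal units (same units as `s0`).
#'
#' @param grid an [image_grid()].
#' @param bundles list of [bundle_geometry()] objects.
#' @param rois list of ROI spheres, each `list(name=, center=, radius=)`
#'   (mm); the first two are the endpoint ROIs of the target bundle.
#' @param gtab a [gradient_table()].
#' @param s0 unweighted signal level.
#' @param d_axial,d_radial,d_iso stick/ball diffusivities (mm^2/s).
#' @param noise_sigma Rician noise scale (signal units), >= 0.
#' @param n_sessions number of repeated acquisitions, >= 1.
#' @param seed integer RNG seed recorded and used by [generate_phantom()].
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, bundles, rois, gtab,
                         s0 = 100, d_axial = 1.7e-3, d_radial = 0.2e-3,
                         d_iso = 3.0e-3, noise_sigma = 2, n_sessions = 2L,
                         seed = 1L) {
  if (!(d_axial > d_radial && d_radial >= 0))
    stop("need d_axial > d_radial >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_sessions < 1L) stop("n_sessions must be >= 1")
  structure(list(grid = grid, bundles = bundles, rois = rois, gtab = gtab,
                 s0 = s0, d_axial = d_axial, d_radial = d_radial,
                 d_iso = d_iso, noise_sigma = noise_sigma,
                 n_sessions = as.integer(n_sessions), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default U-bundle phantom specification
#'
#' Builds the study phantom: a curved (U-shaped) target bundle running
#' from a superior-parietal-like ROI patch around a sulcus-like fold to a
#' supramarginal-like ROI patch, plus a straight distractor bundle
#' crossing the U at its apex at ~90 degrees (emulating a crossing major
#' fasciculus), isotropic background, and two grey-matter distractor ROIs
#' at the distractor's ends. Geometry scales with the grid so the U arc
#' length sits near 47 mm on the default 30^3 grid of 2-mm voxels.
#'
#' @param grid_shape 3 integers, >= 20 per axis.
#' @param voxel_size voxel edge (mm).
#' @param seed integer seed stored in the spec.
#' @param noise_sigma Rician noise scale (signal units; default 2, i.e.
#'   2% of the default s0 = 100).
#' @param n_sessions number of sessions (default 2: one for tracking, one
#'   held out for cross-validation).
#' @param include_u_bundle set `FALSE` for the negative-control phantom
#'   (same ROIs and distractor, no target bundle).
#' @param ... passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
make_u_bundle_spec <- function(grid_shape = c(30L, 30L, 30L), voxel_size = 2,
                               seed = 1L, noise_sigma = 2, n_sessions = 2L,
                               include_u_bundle = TRUE, ...) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (any(grid_shape < 20L))
    stop("grid too small to contain the bundles (need >= 20 voxels per axis)")
  grid <- image_grid(grid_shape, voxel_size)
  ext <- (grid_shape - 1) * voxel_size
  s <- min(ext) / 58                      # geometry scale factor
  cx <- ext[1] / 2; cy <- ext[2] * 0.48; cz <- 36 * s
  R <- 13 * s; tail <- 4 * s
  # U-bundle: semicircle in the x-z plane, apex up, short straight tails
  ang <- seq(pi, 0, length.out = 41L)
  arc <- cbind(cx + R * cos(ang), cy, cz + R * sin(ang))
  tails_a <- cbind(cx - R, cy, cz - seq(tail, 0.5 * s, length.out = 4L))
  tails_b <- cbind(cx + R, cy, cz - seq(0.5 * s, tail, length.out = 4L))
  u_line <- rbind(tails_a, arc, tails_b)
  u <- bundle_geometry("u", u_line, radius = 3 * s)
  # straight distractor along y through the U apex
  apex <- c(cx, cy, cz + R)
  dist_line <- cbind(apex[1], seq(4 * s, ext[2] - 4 * s, length.out = 21L),
                     apex[3])
  straight <- bundle_geometry("distractor", dist_line, radius = 3 * s)
  rois <- list(
    list(name = "superior-parietal-like",
         center = c(cx - R, cy, cz - tail - 2.5 * s), radius = 4.5 * s),
    list(name = "supramarginal-like",
         center = c(cx + R, cy, cz - tail - 2.5 * s), radius = 4.5 * s),
    list(name = "distractor-a",
         center = c(apex[1], 2 * s, apex[3]), radius = 4 * s),
    list(name = "distractor-b",
         center = c(apex[1], ext[2] - 2 * s, apex[3]), radius = 4 * s))
  bundles <- if (include_u_bundle) list(u, straight) else list(straight)
  phantom_spec(grid, bundles, rois, default_gradient_table(),
               noise_sigma = noise_sigma, n_sessions = n_sessions,
               seed = seed, ...)
}

#' Ground truth of a phantom specification
#'
#' Deterministically derives, from the geometry alone: the per-voxel fibre
#' orientations and volume fractions (tangent of the nearest centerline
#' point; fractions proportional to the share of 27 within-voxel
#' subsamples falling inside each tube), the grey-matter ROI label volume,
#' the white-matter mask and the grey-matter/white-matter interface (GWMI)
#' seed mask (white-matter voxels 6-adjacent to a grey voxel).
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom_truth` with fields `orientations`
#'   (nvox x K x 3), `fractions` (nvox x K), `bundle_names`,
#'   `wm_mask`, `gwmi_mask` (logical [volume()]s), `roi_labels`
#'   (a [label_volume()]).
#' @export
phantom_truth <- function(spec) {
  grid <- spec$grid
  nvox <- prod(grid$shape)
  centers <- grid_centers(grid)
  K <- length(spec$bundles)
  frac <- matrix(0, nvox, max(K, 1L))
  orient <- array(0, c(nvox, max(K, 1L), 3L))
  off1 <- spec$grid$voxel_size[1] * c(-1, 0, 1) / 3
  off <- as.matrix(expand.grid(off1, off1, off1))
  # per-bundle candidate voxels, dense centerlines and tangents
  cand <- vector("list", K); cl <- vector("list", K); tan_cl <- vector("list", K)
  for (k in seq_len(K)) {
    b <- spec$bundles[[k]]
    cl[[k]] <- densify_polyline(b$centerline, 0.5)
    tan_cl[[k]] <- polyline_tangents(cl[[k]])
    bb_lo <- apply(b$centerline, 2L, min) - b$radius - max(grid$voxel_size)
    bb_hi <- apply(b$centerline, 2L, max) + b$radius + max(grid$voxel_size)
    cand[[k]] <- which(centers[, 1] >= bb_lo[1] & centers[, 1] <= bb_hi[1] &
                       centers[, 2] >= bb_lo[2] & centers[, 2] <= bb_hi[2] &
                       centers[, 3] >= bb_lo[3] & centers[, 3] <= bb_hi[3])
  }
  all_cand <- sort(unique(unlist(cand)))
  if (K > 0L && length(all_cand)) {
    inside <- matrix(0, length(all_cand), K)     # subsample counts
    for (o in seq_len(nrow(off))) {
      p <- sweep(centers[all_cand, , drop = FALSE], 2L, off[o, ], "+")
      # distance of every subsample to every tube (Inf outside bbox)
      d2 <- matrix(Inf, length(all_cand), K)
      for (k in seq_len(K)) {
        rows <- match(cand[[k]], all_cand)
        nn <- nearest_point(p[rows, , drop = FALSE], cl[[k]])
        d2[rows, k] <- ifelse(nn$d2 <= spec$bundles[[k]]$radius^2,
                              nn$d2, Inf)
      }
      # a subsample belongs to its nearest containing tube only
      win <- max.col(-d2, ties.method = "first")
      hit <- is.finite(d2[cbind(seq_along(win), win)])
      idx <- cbind(seq_along(win)[hit], win[hit])
      inside[idx] <- inside[idx] + 1
    }
    for (k in seq_len(K)) {
      frac[all_cand, k] <- inside[, k] / nrow(off) *
        spec$bundles[[k]]$volume_fraction
      rows <- match(cand[[k]], all_cand)
      nnc <- nearest_point(centers[cand[[k]], , drop = FALSE], cl[[k]])
      orient[cand[[k]], k, ] <- tan_cl[[k]][nnc$idx, ]
    }
  }
  # grey-matter ROI labels: spheres around the ROI centers; grey wins
  labels <- integer(nvox)
  for (r in seq_along(spec$rois)) {
    roi <- spec$rois[[r]]
    d2 <- rowSums(sweep(centers, 2L, roi$center, "-")^2)
    labels[d2 <= roi$radius^2] <- r
  }
  grey <- labels > 0L
  frac[grey, ] <- 0
  wm <- rowSums(frac) > 0.05 & !grey
  gwmi <- wm & as.vector(adjacent6(array(grey, grid$shape)))
  names <- stats::setNames(vapply(spec$rois, `[[`, "", "name"),
                           seq_along(spec$rois))
  structure(list(
    orientations = orient, fractions = frac,
    bundle_names = vapply(spec$bundles, `[[`, "", "name"),
    wm_mask = volume(grid, array(wm, grid$shape)),
    gwmi_mask = volume(grid, array(gwmi, grid$shape)),
    roi_labels = label_volume(grid, array(labels, grid$shape), names)),
    class = "phantom_truth")
}

# voxels 6-adjacent to a TRUE voxel of a logical 3D array (excluding self)
adjacent6 <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by == 1L) { src[[ax]] <- 1:(d[ax] - 1L); dst[[ax]] <- 2:d[ax] }
    else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1L) }
    r <- array(FALSE, d)
    r[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(1L, -1L)) out <- out | shift(a, ax, by)
  out
}

densify_polyline <- function(p, step = 0.5) {
  len <- sum(sqrt(rowSums(diff(p)^2)))
  resample_streamline(p, max(2L, ceiling(len / step) + 1L))
}

polyline_tangents <- function(p) {
  n <- nrow(p)
  t <- rbind(p[2L, ] - p[1L, ],
             p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
             p[n, ] - p[n - 1L, ])
  t / sqrt(rowSums(t^2))
}

# nearest vertex of polyline `cl` for each row of `p` (chunked)
nearest_point <- function(p, cl) {
  n <- nrow(p)
  idx <- integer(n); d2 <- numeric(n)
  cl2 <- rowSums(cl^2)
  chunk <- 4000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    pp <- p[s:e, , drop = FALSE]
    d <- outer(rowSums(pp^2), cl2, "+") - 2 * pp %*% t(cl)
    j <- max.col(-d, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- d[cbind(seq_len(e - s + 1L), j)]
  }
  list(idx = idx, d2 = pmax(0, d2))
}

#' Simulate the multi-session diffusion acquisition of a phantom
#'
#' Noiseless signal in voxel v for gradient direction theta at weighting b:
#' \deqn{S = s_0 [ f_{iso} e^{-b d_{iso}} + \sum_k f_k
#'   e^{-b (d_r + (d_a - d_r)(\theta \cdot t_k)^2)} ]}
#' with t_k the voxel's ground-truth stick orientations. Rician noise of
#' scale sigma is applied independently per session (two independent
#' Gaussian channels added in quadrature); all sessions share the truth.
#'
#' @param spec a [phantom_spec()].
#' @param truth optional precomputed [phantom_truth()] (recomputed if
#'   missing).
#' @return list with `sessions` (list of 4D [volume()]s, one per session),
#'   `truth`, and `gtab`.
#' @export
generate_phantom <- function(spec, truth = NULL) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(truth)) truth <- phantom_truth(spec)
  gtab <- spec$gtab
  nvox <- prod(spec$grid$shape)
  nmeas <- length(gtab$bvals)
  S <- matrix(0, nvox, nmeas)
  f_tot <- rowSums(truth$fractions)
  f_iso <- 1 - f_tot
  iso_att <- exp(-gtab$bvals * spec$d_iso)
  S <- spec$s0 * (f_iso %o% iso_att)
  for (k in seq_len(ncol(truth$fractions))) {
    fk <- truth$fractions[, k]
    sel <- which(fk > 0)
    if (!length(sel)) next
    dot <- truth$orientations[sel, k, , drop = FALSE]
    dim(dot) <- c(length(sel), 3L)
    proj2 <- (dot %*% t(gtab$bvecs))^2
    att <- exp(-outer(rep(1, length(sel)), gtab$bvals) *
                 (spec$d_radial + (spec$d_axial - spec$d_radial) * proj2))
    S[sel, ] <- S[sel, ] + spec$s0 * fk[sel] * att
  }
  set.seed(spec$seed)
  sessions <- vector("list", spec$n_sessions)
  for (ses in seq_len(spec$n_sessions)) {
    if (spec$noise_sigma > 0) {
      e1 <- matrix(stats::rnorm(nvox * nmeas, 0, spec$noise_sigma), nvox)
      e2 <- matrix(stats::rnorm(nvox * nmeas, 0, spec$noise_sigma), nvox)
      noisy <- sqrt((S + e1)^2 + e2^2)
    } else noisy <- S
    sessions[[ses]] <- volume(spec$grid,
                              array(noisy, c(spec$grid$shape, nmeas)))
  }
  list(sessions = sessions, truth = truth, gtab = gtab)
}
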