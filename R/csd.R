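#' Single-fibre response function for spherical deconvolution
#'
#' Estimates the axially symmetric signal profile of a coherent fibre
#' population from high-FA voxels: each voxel's attenuations are rotated
#' so its principal diffusion direction lies on the polar axis, samples
#' are pooled across voxels, and even-degree zonal harmonics are fitted
#' by least squares. If fewer than `min_voxels` voxels exceed
#' `fa_threshold`, falls back to the analytic stick/tensor response with
#' the supplied diffusivities (with a warning).
#'
#' @param dwi 4D [volume()].
#' @param gtab a [gradient_table()].
#' @param tensor a [fit_tensor()] result on the same grid.
#' @param fa_threshold FA cutoff selecting single-fibre voxels.
#' @param lmax even maximum harmonic degree.
#' @param min_voxels minimum number of high-FA voxels.
#' @param d_axial,d_radial fallback stick diffusivities (mm^2/s).
#' @return Object of class `sh_response`: zonal coefficients `r_l` (one
#'   per even degree), `lmax`, `bval`, `n_voxels` used.
#' @export
estimate_response <- function(dwi, gtab, tensor, fa_threshold = 0.7,
                              lmax = 8L, min_voxels = 20L,
                              d_axial = 1.7e-3, d_radial = 0.2e-3) {
  bval <- max(gtab$bvals)
  fa <- tensor$fa$data[tensor$voxel_index]
  hi <- which(fa >= fa_threshold)
  if (length(hi) < min_voxels) {
    warning("fewer than ", min_voxels, " voxels above FA ", fa_threshold,
            "; using analytic stick response")
    return(analytic_response(bval, d_axial, d_radial, lmax))
  }
  sig <- matrix(dwi$data, prod(dwi$grid$shape))[tensor$voxel_index[hi], ,
                                                drop = FALSE]
  s0 <- rowMeans(sig[, gtab$b0, drop = FALSE])
  att <- sig[, !gtab$b0, drop = FALSE] / pmax(s0, .Machine$double.eps)
  g <- gtab$bvecs[!gtab$b0, , drop = FALSE]
  ct <- abs(tensor$pdd[hi, , drop = FALSE] %*% t(g))   # |cos| angle to PDD
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(as.vector(st), 0, as.vector(ct))
  B <- sh_basis(dirs, lmax)
  m0 <- sh_m_orders(lmax) == 0L
  # column-major vectorisation matches the ordering of `dirs` above
  r_l <- stats::lm.fit(B[, m0, drop = FALSE], as.vector(att))$coefficients
  structure(list(r_l = unname(r_l), lmax = lmax, bval = bval,
                 n_voxels = length(hi)),
            class = "sh_response")
}

#' Analytic stick/tensor response at a given b-value
#' @param bval shell b-value (s/mm^2).
#' @param d_axial,d_radial stick diffusivities (mm^2/s).
#' @param lmax even maximum degree.
#' @return An `sh_response`.
#' @export
analytic_response <- function(bval, d_axial = 1.7e-3, d_radial = 0.2e-3,
                              lmax = 8L) {
  r_l <- zonal_coefficients(
    function(ct) exp(-bval * (d_radial + (d_axial - d_radial) * ct^2)), lmax)
  structure(list(r_l = unname(r_l), lmax = lmax, bval = bval, n_voxels = 0L),
            class = "sh_response")
}

#' @exportS3Method
print.sh_response <- function(x, ...) {
  cat("sh_response: lmax", x$lmax, "b", x$bval, "from", x$n_voxels,
      "voxels; r_l =", paste(signif(x$r_l, 3), collapse = " "), "\n")
  invisible(x)
}

#' Constrained spherical deconvolution
#'
#' Per voxel, solves the regularised linear deconvolution of the measured
#' attenuations by the single-fibre response with iterated non-negativity
#' constraints: starting from an unconstrained low-order (lmax = 4) fit,
#' sphere points where the current FOD amplitude falls below
#' `tau_rel` x (mean initial amplitude) are penalised with weight
#' `lambda`, and the constraint set is iterated until stable or
#' `max_iter` passes (non-convergence returns the last iterate and sets a
#' flag).
#'
#' @param dwi 4D [volume()].
#' @param gtab a [gradient_table()].
#' @param response an `sh_response` from [estimate_response()] or
#'   [analytic_response()].
#' @param lmax even maximum degree of the estimated FOD.
#' @param mask optional logical mask.
#' @param lambda regularisation weight of the constraint rows.
#' @param tau_rel amplitude threshold relative to the mean initial FOD
#'   amplitude.
#' @param max_iter maximum constraint iterations per voxel.
#' @return Object of class `fod_volume`: `grid`, `mask`, `voxel_index`,
#'   `coef` (n_masked x ncoef), `lmax`, `converged` (logical per voxel),
#'   `sphere` (the constraint tessellation).
#' @export
deconvolve_fod <- function(dwi, gtab, response, lmax = 8L, mask = NULL,
                           lambda = 1.0, tau_rel = 0.1, max_iter = 50L) {
  if (lmax %% 2L != 0L) stop("lmax must be even")
  grid <- dwi$grid
  mask <- resolve_mask(mask, grid)
  midx <- which(mask)
  sig <- matrix(dwi$data, prod(grid$shape))[midx, , drop = FALSE]
  s0 <- rowMeans(sig[, gtab$b0, drop = FALSE])
  att <- sig[, !gtab$b0, drop = FALSE] / pmax(s0, .Machine$double.eps)
  g <- gtab$bvecs[!gtab$b0, , drop = FALSE]
  fwd <- sh_basis(g, lmax) *
    rep(convolution_factors(response$r_l[seq_len(lmax / 2 + 1)], lmax),
        each = nrow(g))
  sph <- default_sphere()
  hemi <- sph$vertices[hemisphere_mask(sph$vertices), , drop = FALSE]
  Bcon <- sh_basis(hemi, lmax)
  init_cols <- sh_degrees(lmax) <= 4L
  res <- csd_fit_cpp(t(att), fwd, Bcon, which(init_cols), lambda, tau_rel,
                     as.integer(max_iter))
  if (any(!res$converged))
    warning(sum(!res$converged), " voxels did not reach a stable ",
            "constraint set; last iterate returned")
  structure(list(grid = grid, mask = mask, voxel_index = midx,
                 coef = t(res$coef), lmax = lmax,
                 converged = as.logical(res$converged), sphere = sph),
            class = "fod_volume")
}

#' @exportS3Method
print.fod_volume <- function(x, ...) {
  cat("fod_volume: lmax", x$lmax, ",", length(x$voxel_index), "voxels,",
      sum(!x$converged), "unconverged\n")
  invisible(x)
}

#' FOD amplitudes on a direction set
#'
#' @param fod a `fod_volume`.
#' @param dirs m x 3 unit vectors (defaults to the 642-point tessellation).
#' @return n_masked x m matrix of amplitudes.
#' @export
fod_amplitudes <- function(fod, dirs = NULL) {
  if (is.null(dirs)) dirs <- default_sphere()$vertices
  fod$coef %*% t(sh_basis(dirs, fod$lmax))
}

#' Extract FOD peaks
#'
#' Local maxima of the FOD amplitude over the 642-point tessellation,
#' refined by gradient ascent on the sphere; peaks closer than
#' `min_separation` degrees are merged keeping the larger, peaks below
#' `min_relative_amplitude` of the voxel's largest are dropped (the
#' default 0.25 also suppresses truncation sidelobes of sharp lobes). Directions
#' are antipodally canonicalised (first nonzero component >= 0) and
#' returned with amplitudes in descending order.
#'
#' @param fod a `fod_volume`.
#' @param max_peaks maximum number of peaks kept per voxel.
#' @param min_relative_amplitude relative amplitude cutoff.
#' @param min_separation merge angle (degrees).
#' @return Object of class `peak_volume`: `grid`, `voxel_index`,
#'   `directions` (n x max_peaks x 3), `amplitudes` (n x max_peaks,
#'   descending, 0 where absent), `n_peaks` (integer per voxel).
#' @export
extract_peaks <- function(fod, max_peaks = 3L, min_relative_amplitude = 0.25,
                          min_separation = 25) {
  sph <- default_sphere()
  keep <- hemisphere_mask(sph$vertices)
  verts <- sph$vertices[keep, , drop = FALSE]
  amp <- fod_amplitudes(fod, verts)                  # n x m
  nbr <- sphere_neighbors(sph, keep)
  n <- nrow(amp); m <- ncol(amp)
  nbr_max <- matrix(-Inf, n, m)
  for (v in seq_len(m))
    for (u in nbr[[v]])
      nbr_max[, v] <- pmax(nbr_max[, v], amp[, u])
  # >= admits exact ties (axially symmetric FODs put equal-amplitude
  # vertices next to each other); duplicates collapse in the merge step
  is_peak <- amp >= nbr_max & amp > 0
  # gather all candidate peaks over all voxels, refine them in one batch
  pk <- which(is_peak, arr.ind = TRUE)
  dirs <- array(0, c(n, max_peaks, 3L))
  amps <- matrix(0, n, max_peaks)
  npk <- integer(n)
  if (nrow(pk) > 0L) {
    co <- fod$coef[pk[, 1L], , drop = FALSE]
    ref <- refine_peaks(co, verts[pk[, 2L], , drop = FALSE], fod$lmax)
    for (i in unique(pk[, 1L])) {
      rows <- which(pk[, 1L] == i)
      cd <- ref$dirs[rows, , drop = FALSE]
      ca <- ref$amps[rows]
      ord <- order(ca, decreasing = TRUE)
      cd <- cd[ord, , drop = FALSE]; ca <- ca[ord]
      sel <- integer(0)
      for (j in seq_along(ca)) {
        if (!length(sel) ||
            all(fiber_angle(cd[sel, , drop = FALSE], cd[j, ]) >
                  min_separation))
          sel <- c(sel, j)
        if (length(sel) >= max_peaks) break
      }
      cd <- cd[sel, , drop = FALSE]; ca <- ca[sel]
      ok <- ca >= min_relative_amplitude * ca[1] & ca > 0
      cd <- cd[ok, , drop = FALSE]; ca <- ca[ok]
      k <- nrow(cd)
      if (!k) next
      dirs[i, seq_len(k), ] <- canonical_direction(cd)
      amps[i, seq_len(k)] <- ca
      npk[i] <- k
    }
  }
  structure(list(grid = fod$grid, voxel_index = fod$voxel_index,
                 directions = dirs, amplitudes = amps, n_peaks = npk),
            class = "peak_volume")
}

#' @exportS3Method
print.peak_volume <- function(x, ...) {
  cat("peak_volume:", length(x$n_peaks), "voxels; peak count table:\n")
  print(table(x$n_peaks))
  invisible(x)
}

# Derivative-free refinement of FOD maxima: shrinking spherical-cap grid
# search around each candidate direction. `co` holds one SH coefficient row
# per candidate; all candidates advance in lock-step, vectorised.
refine_peaks <- function(co, dirs, lmax,
                         cap_deg = c(5, 2, 0.8, 0.32), n_cap = 32L) {
  np <- nrow(dirs)
  best_amp <- rowSums(sh_basis(dirs, lmax) * co)
  golden <- pi * (3 - sqrt(5))
  for (cap in cap_deg * pi / 180) {
    # spiral of n_cap trial offsets within the cap, common to all candidates
    i <- seq_len(n_cap)
    polar <- cap * sqrt(i / n_cap)
    azim <- golden * i
    # build tangent frames
    up <- matrix(rep(c(0, 0, 1), each = np), ncol = 3L)
    swap <- abs(dirs[, 3]) > 0.9
    up[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3L)
    t1 <- cross3(dirs, up); t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cross3(dirs, t1)
    for (k in i) {
      trial <- cos(polar[k]) * dirs +
        sin(polar[k]) * (cos(azim[k]) * t1 + sin(azim[k]) * t2)
      trial <- trial / sqrt(rowSums(trial^2))
      a <- rowSums(sh_basis(trial, lmax) * co)
      better <- a > best_amp
      dirs[better, ] <- trial[better, , drop = FALSE]
      best_amp[better] <- a[better]
    }
  }
  list(dirs = dirs, amps = best_amp)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# adjacency lists on the hemisphere vertex set (antipodal edges folded in);
# cached, since the default tessellation never changes within a session
sphere_neighbors <- local({
  cache <- NULL
  function(sph, keep) {
    if (!is.null(cache)) return(cache)
    cache <<- sphere_neighbors_impl(sph, keep)
    cache
  }
})

sphere_neighbors_impl <- function(sph, keep) {
  v <- sph$vertices
  map <- integer(nrow(v))          # index into hemisphere set
  hemi_idx <- which(keep)
  # match each vertex (or its antipode) to a hemisphere vertex
  hv <- v[hemi_idx, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    d1 <- colSums((t(hv) - v[i, ])^2)
    d2 <- colSums((t(hv) + v[i, ])^2)
    map[i] <- which.min(pmin(d1, d2))
  }
  nbr <- vector("list", length(hemi_idx))
  add <- function(a, b) {
    if (a != b) nbr[[a]] <<- c(nbr[[a]], b)
  }
  for (f in seq_len(nrow(sph$faces))) {
    tri <- map[sph$faces[f, ]]
    add(tri[1], tri[2]); add(tri[2], tri[1])
    add(tri[2], tri[3]); add(tri[3], tri[2])
    add(tri[1], tri[3]); add(tri[3], tri[1])
  }
  lapply(nbr, unique)
}
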