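#' Binary visitation map of a bundle
#'
#' A voxel is 1 iff any streamline intersects it. Streamlines are first
#' resampled to at most half-voxel point spacing so no voxel along the
#' path is skipped, then each point is assigned to its nearest voxel.
#'
#' @param bundle a `tract_bundle` or [tractogram()].
#' @param grid an [image_grid()].
#' @param subject_id optional identifier stored with the map.
#' @return Object of class `visitation_map`: a binary [volume()] plus
#'   `subject_id`.
#' @export
visitation_map <- function(bundle, grid, subject_id = NULL) {
  arr <- array(0L, grid$shape)
  step <- min(grid$voxel_size) / 2
  for (s in bundle$streamlines) {
    len <- sum(sqrt(rowSums(diff(s)^2)))
    n <- max(2L, ceiling(len / step) + 1L)
    p <- resample_streamline(s, n)
    v <- round(mm_to_voxel(grid, p))
    ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] < grid$shape[1] & v[, 2] < grid$shape[2] & v[, 3] < grid$shape[3]
    if (!any(ok)) next
    lin <- 1L + v[ok, 1] + grid$shape[1] * (v[ok, 2] + grid$shape[2] * v[ok, 3])
    arr[lin] <- 1L
  }
  structure(list(map = volume(grid, arr), subject_id = subject_id),
            class = "visitation_map")
}

#' Normalise a visitation map to a template grid
#'
#' Applies a subject-to-template affine and resamples onto the template
#' grid with nearest-neighbour interpolation, preserving binarity: a
#' template voxel is 1 iff its center, mapped back to subject space,
#' falls in a visited subject voxel.
#'
#' @param vmap a [visitation_map()].
#' @param affine_subject_to_template invertible 4x4 mm-to-mm matrix.
#' @param template_grid an [image_grid()].
#' @return A [visitation_map()] on the template grid.
#' @export
normalise_map <- function(vmap, affine_subject_to_template, template_grid) {
  A <- as.matrix(affine_subject_to_template)
  if (abs(det(A)) < 1e-12) stop("affine must be invertible")
  inv <- solve(A)
  tc <- grid_centers(template_grid)
  subj_mm <- t(inv[1:3, 1:3] %*% t(tc) + inv[1:3, 4])
  v <- round(mm_to_voxel(vmap$map$grid, subj_mm))
  sh <- vmap$map$grid$shape
  ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
    v[, 1] < sh[1] & v[, 2] < sh[2] & v[, 3] < sh[3]
  vals <- integer(nrow(tc))
  lin <- 1L + v[ok, 1] + sh[1] * (v[ok, 2] + sh[2] * v[ok, 3])
  vals[ok] <- as.integer(vmap$map$data[lin] != 0)
  if (!any(vals != 0L))
    warning("visitation map falls entirely outside the template grid")
  structure(list(map = volume(template_grid,
                              array(vals, template_grid$shape)),
                 subject_id = vmap$subject_id),
            class = "visitation_map")
}

#' Percentage-overlap probabilistic atlas
#'
#' Per voxel, 100 x (number of subjects whose binary visitation map is 1)
#' / n_subjects, with a thresholded variant zeroing voxels whose overlap
#' is less than or equal to `threshold_pct` (strict "greater than").
#'
#' @param maps list of [visitation_map()]s on one common grid.
#' @param threshold_pct overlap threshold (percent).
#' @return Object of class `overlap_atlas`: `overlap` ([volume()] of
#'   percentages 0-100), `thresholded` ([volume()]), `n_subjects`,
#'   `threshold_pct`.
#' @export
percentage_overlap <- function(maps, threshold_pct = 25) {
  if (!length(maps)) stop("need >= 1 visitation map")
  g <- maps[[1]]$map$grid
  for (m in maps)
    if (!all(m$map$grid$shape == g$shape) ||
        max(abs(m$map$grid$affine - g$affine)) > 1e-9)
      stop("all maps must share one grid")
  n <- length(maps)
  acc <- Reduce(`+`, lapply(maps, function(m) (m$map$data != 0) + 0))
  pct <- 100 * acc / n
  thr <- pct
  thr[pct <= threshold_pct] <- 0
  structure(list(overlap = volume(g, pct), thresholded = volume(g, thr),
                 n_subjects = n, threshold_pct = threshold_pct),
            class = "overlap_atlas")
}

#' @exportS3Method
print.overlap_atlas <- function(x, ...) {
  cat("overlap_atlas:", x$n_subjects, "subjects;",
      sum(x$overlap$data > 0), "voxels visited,",
      sum(x$thresholded$data > 0), "above", x$threshold_pct, "%\n")
  invisible(x)
}
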