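#' Segment a tract by its endpoint ROIs
#'
#' A streamline is retained iff one of its two *terminal* points lies
#' within `dist_mm` of some voxel center of ROI A and the other terminal
#' point lies within `dist_mm` of some voxel center of ROI B. Only
#' terminal points are tested: streamlines merely passing through an ROI
#' do not qualify.
#'
#' @param tract a [tractogram()].
#' @param roiA,roiB either a [label_volume()] together with `labelA` /
#'   `labelB` selections, or n x 3 matrices of ROI voxel-center mm
#'   coordinates.
#' @param labelA,labelB label values selecting the ROIs when label
#'   volumes are given.
#' @param dist_mm endpoint distance threshold (mm).
#' @param name bundle name recorded in the result.
#' @return Object of class `tract_bundle`: a [tractogram()] subset with
#'   `indices` (positions in the parent tractogram) and the segmentation
#'   parameters.
#' @export
segment_by_endpoints <- function(tract, roiA, roiB, labelA = NULL,
                                 labelB = NULL, dist_mm = 3,
                                 name = "bundle") {
  A <- roi_points(roiA, labelA)
  B <- roi_points(roiB, labelB)
  if (!nrow(A) || !nrow(B)) stop("ROIs must be non-empty")
  keep <- integer(0)
  for (i in seq_along(tract$streamlines)) {
    s <- tract$streamlines[[i]]
    p1 <- s[1L, ]; p2 <- s[nrow(s), ]
    d1A <- min_dist(p1, A); d1B <- min_dist(p1, B)
    d2A <- min_dist(p2, A); d2B <- min_dist(p2, B)
    if ((d1A <= dist_mm && d2B <= dist_mm) ||
        (d1B <= dist_mm && d2A <= dist_mm))
      keep <- c(keep, i)
  }
  if (!length(keep))
    warning("no streamline satisfies the endpoint rule; empty bundle")
  out <- subset_tractogram(tract, keep)
  structure(c(unclass(out),
              list(indices = keep, name = name,
                   segmentation = list(dist_mm = dist_mm))),
            class = c("tract_bundle", "tractogram"))
}

roi_points <- function(roi, label = NULL) {
  if (inherits(roi, "label_volume")) return(label_centers(roi, label))
  matrix(as.numeric(roi), ncol = 3L)
}

min_dist <- function(p, pts) sqrt(min(colSums((t(pts) - p)^2)))

#' @exportS3Method
print.tract_bundle <- function(x, ...) {
  cat("tract_bundle '", x$name, "': ", length(x$streamlines),
      " streamlines\n", sep = "")
  invisible(x)
}

#' Remove outlier streamlines from a bundle
#'
#' Applies, in order: (a) removal of streamlines shorter than
#' `min_len_mm`; (b) removal of streamlines longer than the mean length
#' by `len_sd` SD or more; (c) removal of streamlines whose positions
#' are `pos_sd` SD or more away from the mean position of the tract. Each
#' criterion uses the statistics of the set entering that step. For the
#' position criterion every streamline is resampled to `n_nodes`
#' equidistant nodes, orientation-aligned so corresponding nodes match
#' ends (each streamline is flipped so its first node is nearer the
#' bundle's first-endpoint centroid), the mean streamline is computed,
#' and a streamline is removed when its mean node distance to the mean
#' streamline exceeds the population mean of these distances by
#' `pos_sd` SD or more. With fewer than 3 members the SD-based criteria are
#' skipped (only the minimum length applies) with a warning.
#'
#' @param bundle a `tract_bundle` (or [tractogram()]).
#' @param len_sd length SD multiplier.
#' @param min_len_mm minimum streamline length (mm).
#' @param pos_sd position SD multiplier.
#' @param n_nodes resampling nodes for the position criterion.
#' @return The filtered `tract_bundle` (indices relative to the original
#'   parent retained).
#' @export
remove_outliers <- function(bundle, len_sd = 3, min_len_mm = 15,
                            pos_sd = 3, n_nodes = 100L) {
  if (!length(bundle$streamlines)) stop("bundle is empty")
  idx <- if (!is.null(bundle$indices)) bundle$indices
         else seq_along(bundle$streamlines)
  sl <- bundle$streamlines
  # (a) minimum length
  len <- streamline_lengths(sl)
  keep <- len >= min_len_mm
  sl <- sl[keep]; idx <- idx[keep]; len <- len[keep]
  small <- length(sl) < 3L
  if (small && length(sl))
    warning("fewer than 3 streamlines; SD-based criteria skipped")
  if (!small) {
    # (b) overlong relative to the current set
    keep <- len < mean(len) + len_sd * stats::sd(len) |
      rep(stats::sd(len) == 0, length(len))
    sl <- sl[keep]; idx <- idx[keep]
    if (length(sl) >= 3L) {
      # (c) positional deviation from the mean streamline
      res <- align_resample(sl, n_nodes)
      mean_sl <- Reduce(`+`, res) / length(res)
      dev <- vapply(res, function(s)
        mean(sqrt(rowSums((s - mean_sl)^2))), numeric(1))
      sdd <- stats::sd(dev)
      if (sdd > 0) {
        keep <- dev < mean(dev) + pos_sd * sdd
        sl <- sl[keep]; idx <- idx[keep]
      }
    }
  }
  out <- bundle
  out$streamlines <- sl
  out$indices <- idx
  out$outlier_params <- list(len_sd = len_sd, min_len_mm = min_len_mm,
                             pos_sd = pos_sd, n_nodes = n_nodes)
  out
}

# resample each streamline to n nodes and flip for node correspondence:
# first node nearer the centroid of current first endpoints
align_resample <- function(sl, n_nodes) {
  res <- lapply(sl, resample_streamline, n = n_nodes)
  anchor <- colMeans(do.call(rbind, lapply(res, function(s) s[1L, ])))
  lapply(res, function(s) {
    if (sum((s[1L, ] - anchor)^2) > sum((s[n_nodes, ] - anchor)^2))
      s[n_nodes:1L, , drop = FALSE]
    else s
  })
}

#' Endpoint density over grey-matter voxels
#'
#' For each selected grey-matter voxel, counts the streamline terminal
#' points (two per streamline) within `dist_mm` of the voxel center, and
#' returns the counts plus the max-normalised map.
#'
#' @param bundle a `tract_bundle` or [tractogram()].
#' @param grey a [label_volume()] (optionally with `label`) or logical
#'   mask [volume()] selecting grey voxels.
#' @param label optional label selection.
#' @param dist_mm distance threshold (mm).
#' @return Object of class `endpoint_density`: `counts` ([volume()] of
#'   integers), `normalised` ([volume()], values between 0 and 1).
#' @export
endpoint_density <- function(bundle, grey, label = NULL, dist_mm = 3) {
  grid <- grey$grid
  if (inherits(grey, "label_volume")) {
    sel <- if (is.null(label)) grey$data != 0L
           else array(grey$data %in% label, dim = dim(grey$data))
  } else sel <- resolve_mask(grey, grid)
  vidx <- which(sel)
  if (!length(vidx)) stop("grey selection is empty")
  centers <- grid_centers(grid)[vidx, , drop = FALSE]
  counts <- integer(length(vidx))
  ep <- streamline_endpoints(bundle)
  if (nrow(ep)) {
    for (e in seq_len(nrow(ep)))
      counts <- counts + (colSums((t(centers) - ep[e, ])^2) <= dist_mm^2)
  }
  arr <- array(0L, grid$shape); arr[vidx] <- counts
  norm <- array(0, grid$shape)
  if (max(counts) > 0) norm[vidx] <- counts / max(counts)
  structure(list(counts = volume(grid, arr), normalised = volume(grid, norm),
                 dist_mm = dist_mm),
            class = "endpoint_density")
}

#' Proportion of ROI voxels near bundle endpoints
#'
#' For each ROI and each distance threshold, the proportion of ROI voxel
#' centers lying within the threshold of at least one streamline terminal
#' point. Monotone non-decreasing in the threshold by construction.
#'
#' @param bundle a `tract_bundle` or [tractogram()].
#' @param rois named list of ROI selections (each a [label_volume()]
#'   paired via `list(volume=, label=)`, or an n x 3 matrix of voxel
#'   centers).
#' @param thresholds_mm numeric thresholds (defaults 3 and 4.5 mm).
#' @return data.frame with columns `roi`, `threshold_mm`, `proportion`
#'   (class `proximity_report`).
#' @export
roi_proximity <- function(bundle, rois, thresholds_mm = c(3, 4.5)) {
  ep <- streamline_endpoints(bundle)
  out <- data.frame()
  for (nm in names(rois)) {
    r <- rois[[nm]]
    pts <- if (is.list(r) && !is.null(r$volume))
      label_centers(r$volume, r$label) else roi_points(r)
    if (!nrow(pts)) stop("ROI '", nm, "' is empty")
    dmin <- if (nrow(ep)) apply(pts, 1L, function(p) min_dist(p, ep))
            else rep(Inf, nrow(pts))
    for (th in thresholds_mm)
      out <- rbind(out, data.frame(roi = nm, threshold_mm = th,
                                   proportion = mean(dmin <= th)))
  }
  class(out) <- c("proximity_report", "data.frame")
  out
}
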