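#' Linear fascicle evaluation (LiFE) model
#'
#' Predicts the demeaned diffusion-weighted attenuations in every
#' white-matter voxel a candidate tractogram traverses as a non-negative
#' linear combination of per-streamline stick contributions. For a
#' streamline segment with unit tangent t inside voxel v, the predicted
#' attenuation for gradient direction theta at weighting b is
#' exp(-b d_axial (theta . t)^2); a streamline's contribution to v is the
#' mean over its segments in v, demeaned across v's diffusion-weighted
#' directions. The measured signal vector y is the attenuation
#' (signal / mean b=0 signal) demeaned the same way.
#'
#' `life()` builds the design and optimises the weights in one call;
#' [build_life_model()] and [optimize_weights()] expose the two stages.
#'
#' @param tractogram a non-empty [tractogram()].
#' @param dwi session-1 4D [volume()].
#' @param gtab a [gradient_table()] matching `dwi`.
#' @param wm_mask logical white-matter mask.
#' @param d_axial stick axial diffusivity (mm^2/s).
#' @param ... passed to [optimize_weights()].
#' @return An object of class `life`; see [build_life_model()] for fields.
#' @export
life <- function(tractogram, dwi, gtab, wm_mask, d_axial = 1.7e-3, ...) {
  optimize_weights(build_life_model(tractogram, dwi, gtab, wm_mask,
                                    d_axial), ...)
}

#' @rdname life
#' @return `build_life_model` returns an unweighted `life` object with
#'   fields `tractogram`, `M` (sparse design, one column per streamline),
#'   `y` (demeaned measured attenuations), `voxels` (1-based linear
#'   indices of traversed white-matter voxels, row-block order), `ndir`,
#'   `zero_columns` (streamlines entirely outside the mask), plus the
#'   inputs needed for refits; `w` is `NULL` until optimised.
#' @export
build_life_model <- function(tractogram, dwi, gtab, wm_mask,
                             d_axial = 1.7e-3) {
  if (!length(tractogram)) stop("tractogram is empty")
  grid <- dwi$grid
  wm_mask <- resolve_mask(wm_mask, grid)
  g <- gtab$bvecs[!gtab$b0, , drop = FALSE]
  b <- gtab$bvals[!gtab$b0]
  trip <- life_matrix_cpp(tractogram$streamlines, solve(grid$affine)[1:3, ],
                          grid$shape, as.integer(wm_mask), g, b, d_axial)
  if (length(trip$zero_columns))
    warning(length(trip$zero_columns),
            " streamlines lie entirely outside the white-matter mask ",
            "(all-zero columns kept)")
  voxels <- trip$voxels + 1L
  ndir <- nrow(g)
  M <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(voxels) * ndir,
                                     length(tractogram)))
  y <- as.vector(t(demeaned_signals(dwi, gtab, voxels)))
  structure(list(tractogram = tractogram, M = M, y = y, voxels = voxels,
                 ndir = ndir, gtab = gtab, grid = grid, d_axial = d_axial,
                 wm_mask = wm_mask, zero_columns = trip$zero_columns,
                 w = NULL, objective = NA_real_, iterations = 0L,
                 converged = NA),
            class = "life")
}

#' Demeaned diffusion-weighted attenuations of selected voxels
#'
#' Signals of the diffusion-weighted directions are normalised by the
#' voxel's mean b = 0 signal and demeaned across directions.
#'
#' @param dwi 4D [volume()]; @param gtab matching [gradient_table()].
#' @param voxels 1-based linear voxel indices.
#' @return length(voxels) x ndir matrix.
#' @export
demeaned_signals <- function(dwi, gtab, voxels) {
  sig <- matrix(dwi$data, prod(dwi$grid$shape))[voxels, , drop = FALSE]
  s0 <- rowMeans(sig[, gtab$b0, drop = FALSE])
  att <- sig[, !gtab$b0, drop = FALSE] / pmax(s0, .Machine$double.eps)
  att - rowMeans(att)
}

#' Optimise LiFE weights by non-negative least squares
#'
#' Cyclic coordinate descent on 0.5 ||y - M w||^2 subject to w >= 0
#' (each coordinate update is the exact one-dimensional constrained
#' minimiser, so the objective never increases). Converges when the
#' relative objective decrease over a full pass falls below `tol`.
#'
#' @param model a `life` object.
#' @param max_iter maximum full passes.
#' @param tol relative objective-decrease tolerance.
#' @param warm_start reuse existing weights as the starting point.
#' @return The model with `w`, `objective`, `iterations`, `converged` set.
#' @export
optimize_weights <- function(model, max_iter = 500L, tol = 1e-6,
                             warm_start = TRUE) {
  M <- model$M
  w0 <- if (warm_start && !is.null(model$w)) model$w
        else numeric(ncol(M))
  res <- nnls_cd_cpp(M@p, M@i, M@x, nrow(M), ncol(M), model$y, w0,
                     as.integer(max_iter), tol)
  if (!res$converged)
    warning("weight optimisation did not converge in ", max_iter,
            " passes; best iterate returned")
  model$w <- res$w
  model$objective <- res$objective
  model$iterations <- res$iterations
  model$converged <- res$converged
  model
}

#' @exportS3Method
print.life <- function(x, ...) {
  cat("LiFE model:", ncol(x$M), "streamlines over", length(x$voxels),
      "voxels x", x$ndir, "directions\n")
  if (!is.null(x$w))
    cat(sprintf("  optimised: %d nonzero weights, objective %.6g (%d passes)\n",
                sum(x$w > 0), x$objective, x$iterations))
  else cat("  weights not optimised yet\n")
  invisible(x)
}

#' @exportS3Method
summary.life <- function(object, ...) {
  out <- list(n_streamlines = ncol(object$M), n_voxels = length(object$voxels),
              ndir = object$ndir, n_nonzero = if (is.null(object$w)) NA_integer_
                else sum(object$w > 0),
              objective = object$objective,
              rmse = if (is.null(object$w)) NA_real_ else
                sqrt(mean((object$y - fitted(object))^2)),
              converged = object$converged)
  class(out) <- "summary.life"
  out
}

#' @exportS3Method
print.summary.life <- function(x, ...) {
  cat("LiFE model summary\n")
  cat("  streamlines:", x$n_streamlines, "( nonzero:", x$n_nonzero, ")\n")
  cat("  voxels:", x$n_voxels, "x", x$ndir, "directions\n")
  cat("  objective:", format(x$objective), " rmse:", format(x$rmse), "\n")
  invisible(x)
}

#' @export
coef.life <- function(object, ...) object$w

#' @export
fitted.life <- function(object, ...) {
  if (is.null(object$w)) stop("model not optimised")
  as.vector(object$M %*% object$w)
}

#' @export
residuals.life <- function(object, ...) object$y - fitted(object)

#' Predicted demeaned attenuations per voxel
#'
#' @param object a fitted `life` model.
#' @param ... unused.
#' @return length(voxels) x ndir matrix of model predictions, rows in
#'   `object$voxels` order.
#' @export
predict.life <- function(object, ...) {
  matrix(fitted(object), ncol = object$ndir, byrow = TRUE)
}

#' Prune a LiFE model to its supported streamlines
#'
#' Keeps streamlines with weight > 0, or the top `k` by weight when `k`
#' is given (never including zero-weight streamlines), preserving order.
#'
#' @param model an optimised `life` model.
#' @param k optional cap on the number of streamlines.
#' @return A [tractogram()] with pruning parameters in provenance.
#' @export
prune <- function(model, k = NULL) {
  if (is.null(model$w)) stop("model not optimised")
  keep <- which(model$w > 0)
  if (!length(keep))
    warning("all weights are zero; returning an empty tractogram")
  if (!is.null(k) && length(keep) > k)
    keep <- sort(keep[order(model$w[keep], decreasing = TRUE)[seq_len(k)]])
  tr <- subset_tractogram(model$tractogram, keep)
  tr$provenance$pruned_from <- ncol(model$M)
  tr$provenance$parent_indices <- keep
  tr$provenance$weights <- model$w[keep]
  tr
}

#' Ensemble tractography connectome (ETC)
#'
#' Concatenates the pruned top-k streamline sets of several
#' single-parameter LiFE models into one candidate connectome and
#' re-optimises it jointly (the candidate count is k x n_models, e.g.
#' 4 x 150,000 = 600,000 at full study scale).
#'
#' @param single_param_models list of >= 2 optimised `life` models fitted
#'   on the same session volume.
#' @param k_per_model per-model preselection size.
#' @param dwi,gtab,wm_mask the session-1 data (defaults: taken from the
#'   first model).
#' @param optimize re-optimise the combined connectome (default TRUE).
#' @param ... passed to [optimize_weights()].
#' @return An optimised `life` model whose `$tractogram` is the ETC.
#' @export
build_etc <- function(single_param_models, k_per_model, dwi, gtab = NULL,
                      wm_mask = NULL, optimize = TRUE, ...) {
  if (length(single_param_models) < 2L)
    stop("need >= 2 single-parameter models")
  m1 <- single_param_models[[1]]
  if (is.null(gtab)) gtab <- m1$gtab
  if (is.null(wm_mask)) wm_mask <- m1$wm_mask
  pruned <- lapply(single_param_models, prune, k = k_per_model)
  sl <- do.call(c, lapply(pruned, `[[`, "streamlines"))
  prov <- list(source_settings = lapply(single_param_models, function(m)
    m$tractogram$provenance$angular_threshold),
    k_per_model = k_per_model)
  etc <- tractogram(sl, prov)
  model <- build_life_model(etc, dwi, gtab, wm_mask, d_axial = m1$d_axial)
  if (optimize) model <- optimize_weights(model, ...)
  model
}
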