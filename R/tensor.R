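#' Log-linear least-squares diffusion tensor fit
#'
#' Fits the single diffusion tensor per voxel by ordinary least squares on
#' log-attenuations, and derives eigenvalues, eigenvectors, fractional
#' anisotropy (FA) and the principal diffusion direction (PDD).
#' Non-positive signals are clamped to 1e-6 of the voxel's mean b = 0
#' signal before the log.
#'
#' @param dwi 4D [volume()] matching `gtab`.
#' @param gtab a [gradient_table()] with >= 6 diffusion-weighted
#'   directions.
#' @param mask optional logical 3D array / [volume()]; defaults to all
#'   voxels.
#' @return Object of class `tensor_volume`: fields `grid`, `mask`
#'   (logical array), `evals` (nvox x 3, descending, mm^2/s), `evecs`
#'   (nvox x 3 x 3, columns are eigenvectors), `fa` and `pdd`
#'   (nvox x 3; first eigenvector).
#' @export
fit_tensor <- function(dwi, gtab, mask = NULL) {
  if (sum(!gtab$b0) < 6L)
    stop("tensor fit needs >= 6 diffusion-weighted directions")
  grid <- dwi$grid
  nvox <- prod(grid$shape)
  sig <- matrix(dwi$data, nvox)
  if (ncol(sig) != length(gtab$bvals))
    stop("dwi 4th dimension does not match gradient table")
  mask <- resolve_mask(mask, grid)
  midx <- which(mask)
  s0 <- rowMeans(sig[midx, gtab$b0, drop = FALSE])
  s0 <- pmax(s0, .Machine$double.eps)
  dw <- sig[midx, !gtab$b0, drop = FALSE]
  dw <- pmax(dw, 1e-6 * s0)
  y <- -log(dw / s0)
  g <- gtab$bvecs[!gtab$b0, , drop = FALSE]
  b <- gtab$bvals[!gtab$b0]
  X <- b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                 2 * g[, 2] * g[, 3])
  D <- t(solve(crossprod(X), crossprod(X, t(y))))   # n_masked x 6
  n <- length(midx)
  evals <- matrix(0, n, 3L)
  evecs <- array(0, c(n, 3L, 3L))
  for (i in seq_len(n)) {
    Dm <- matrix(D[i, c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3L)
    e <- eigen(Dm, symmetric = TRUE)
    evals[i, ] <- e$values
    evecs[i, , ] <- e$vectors
  }
  md <- rowMeans(evals)
  num <- rowSums((evals - md)^2)
  den <- rowSums(evals^2)
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.eps))
  fa[den <= 0] <- 0
  fa_arr <- array(0, grid$shape); fa_arr[midx] <- pmin(1, fa)
  structure(list(grid = grid, mask = mask, voxel_index = midx,
                 evals = evals, evecs = evecs,
                 fa = volume(grid, fa_arr),
                 pdd = evecs[, , 1L, drop = TRUE]),
            class = "tensor_volume")
}

#' @exportS3Method
print.tensor_volume <- function(x, ...) {
  cat("tensor_volume:", length(x$voxel_index), "fitted voxels; median FA",
      signif(stats::median(x$fa$data[x$voxel_index]), 3), "\n")
  invisible(x)
}

# accept NULL / logical array / volume as a mask over `grid`
resolve_mask <- function(mask, grid) {
  if (is.null(mask)) return(array(TRUE, grid$shape))
  if (inherits(mask, "volume")) mask <- mask$data
  m <- array(as.logical(mask), grid$shape)
  if (!all(dim(m) == grid$shape)) stop("mask shape mismatch")
  m
}
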