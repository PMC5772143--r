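#' Cross-validated ratio-of-RMSE model accuracy
#'
#' For each voxel, the numerator is the RMSE between the model's
#' predicted demeaned attenuations (fitted on session 1) and the held-out
#' session-2 demeaned attenuations; the denominator is the test-retest
#' RMSE between the session-1 and session-2 demeaned attenuations of the
#' same voxel. A value of 1 means the model predicts the second session
#' as well as the data replicate; voxels whose denominator falls below
#' 1e-12 are excluded and flagged.
#'
#' @param model a fitted `life` model (session 1).
#' @param dwi_session1,dwi_session2 the two session volumes on the same
#'   grid.
#' @param voxel_set 1-based linear voxel indices; must be a subset of the
#'   model's voxels. Defaults to all model voxels.
#' @param prediction optional length(voxel_set) x ndir matrix overriding
#'   the model prediction (used for definitional checks).
#' @return Object of class `rrmse_distribution`: `values` (per retained
#'   voxel), `voxels`, `excluded` (voxel indices dropped for a degenerate
#'   denominator).
#' @export
r_rmse <- function(model, dwi_session1, dwi_session2, voxel_set = NULL,
                   prediction = NULL) {
  if (is.null(voxel_set)) voxel_set <- model$voxels
  if (!length(voxel_set)) stop("empty voxel set")
  rows <- match(voxel_set, model$voxels)
  if (anyNA(rows)) stop("voxel_set contains voxels outside the model")
  y1 <- demeaned_signals(dwi_session1, model$gtab, voxel_set)
  y2 <- demeaned_signals(dwi_session2, model$gtab, voxel_set)
  if (is.null(prediction)) prediction <- predict(model)[rows, , drop = FALSE]
  num <- sqrt(rowMeans((prediction - y2)^2))
  den <- sqrt(rowMeans((y1 - y2)^2))
  bad <- den < 1e-12
  structure(list(values = num[!bad] / den[!bad], voxels = voxel_set[!bad],
                 excluded = voxel_set[bad]),
            class = "rrmse_distribution")
}

#' @exportS3Method
print.rrmse_distribution <- function(x, ...) {
  cat("R_rmse over", length(x$values), "voxels: median",
      signif(stats::median(x$values), 4))
  if (length(x$excluded)) cat(" (", length(x$excluded), "excluded )")
  cat("\n")
  invisible(x)
}

#' Virtual lesion analysis
#'
#' Removes a candidate bundle from an optimised connectome model and
#' measures the loss of cross-validated prediction accuracy in the voxels
#' the bundle traverses. The path neighbourhood is the set of all
#' streamlines with nonzero weight traversing any of those voxels; after
#' deleting the bundle's columns, the remaining path-neighbourhood
#' weights are re-optimised restricted to the lesion voxels. The strength
#' of evidence is
#' \deqn{S = (mean(R^{lesioned}_{rmse}) - mean(R^{unlesioned}_{rmse})) / sd_{pooled}}
#' with the pooled SD sqrt((var_l + var_u) / 2).
#'
#' @param model a fitted `life` model (session 1).
#' @param bundle_columns integer indices of the bundle's streamlines
#'   (columns of the model).
#' @param dwi_session1,dwi_session2 the two session volumes.
#' @param max_iter,tol settings of the restricted lesioned-model refit.
#' @return Object of class `virtual_lesion`: `unlesioned`, `lesioned`
#'   ([r_rmse()] distributions on the identical voxel set), `S`,
#'   `n_voxels`, `zero_weight_bundle` flag.
#' @export
virtual_lesion <- function(model, bundle_columns, dwi_session1,
                           dwi_session2, max_iter = 500L, tol = 1e-6) {
  if (is.null(model$w)) stop("model not optimised")
  bundle_columns <- as.integer(bundle_columns)
  if (!length(bundle_columns)) stop("empty bundle")
  ndir <- model$ndir
  # voxels traversed by the bundle = row support of its columns
  sub <- model$M[, bundle_columns, drop = FALSE]
  rows_nz <- unique(sub@i) + 1L
  vox_rank <- unique((rows_nz - 1L) %/% ndir + 1L)
  voxel_set <- model$voxels[vox_rank]
  if (!length(voxel_set)) stop("bundle traverses no model voxel")
  zero_bundle <- all(model$w[bundle_columns] == 0)
  unles <- r_rmse(model, dwi_session1, dwi_session2, voxel_set)
  if (zero_bundle) {
    res <- list(unlesioned = unles, lesioned = unles, S = 0,
                n_voxels = length(unles$values), zero_weight_bundle = TRUE)
    class(res) <- "virtual_lesion"
    return(res)
  }
  lesion_rows <- as.vector(outer(seq_len(ndir), (vox_rank - 1L) * ndir, "+"))
  # path neighbourhood: nonzero-weight streamlines traversing those voxels
  Mrows <- model$M[lesion_rows, , drop = FALSE]
  touches <- Matrix::colSums(abs(Mrows)) > 0
  pn <- setdiff(which(touches & model$w > 0), bundle_columns)
  y_rows <- model$y[lesion_rows]
  pred_les <- matrix(0, length(vox_rank), ndir)
  if (length(pn)) {
    Mpn <- Mrows[, pn, drop = FALSE]
    fit <- nnls_cd_cpp(Mpn@p, Mpn@i, Mpn@x, nrow(Mpn), ncol(Mpn), y_rows,
                       model$w[pn], as.integer(max_iter), tol)
    pred_les <- matrix(as.vector(Mpn %*% fit$w), ncol = ndir, byrow = TRUE)
  }
  les <- r_rmse(model, dwi_session1, dwi_session2, voxel_set,
                prediction = pred_les)
  # both distributions are defined over the identical retained voxel set
  stopifnot(identical(les$voxels, unles$voxels))
  mu_l <- mean(les$values); mu_u <- mean(unles$values)
  sd_pool <- sqrt((stats::var(les$values) + stats::var(unles$values)) / 2)
  S <- if (is.finite(sd_pool) && sd_pool > 0) (mu_l - mu_u) / sd_pool else 0
  structure(list(unlesioned = unles, lesioned = les, S = S,
                 n_voxels = length(unles$values),
                 zero_weight_bundle = FALSE),
            class = "virtual_lesion")
}

#' @exportS3Method
print.virtual_lesion <- function(x, ...) {
  cat(sprintf(paste0("virtual lesion: S = %.3f over %d voxels\n",
                     "  unlesioned mean R_rmse %.4f, lesioned %.4f\n"),
              x$S, x$n_voxels, mean(x$unlesioned$values),
              mean(x$lesioned$values)))
  if (x$zero_weight_bundle)
    cat("  note: bundle carried zero weight; distributions identical\n")
  invisible(x)
}
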