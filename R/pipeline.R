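#' Full-pipeline run configuration
#'
#' One object carrying every stage parameter of the phantom-cohort
#' analysis, with the study settings as defaults: 0.2-mm steps, angular
#' thresholds {5.7, 11.5, 23.1, 47.2} degrees, FOD stop amplitude 0.1,
#' length bounds 10-200 mm, 3-mm endpoint rule, 15-mm / 3-SD outlier
#' removal, proximity thresholds {3, 4.5} mm, atlas threshold > 25%, and
#' a six-subject cohort. Candidate counts are desk-scale configuration
#' values, not hard-coded study-scale numbers.
#'
#' @param grid_shape,voxel_size phantom grid (voxels / mm).
#' @param noise_sigma Rician noise scale (signal units).
#' @param include_u_bundle `FALSE` gives the negative-control cohort.
#' @param angular_thresholds tracking ensemble cone half-angles (deg).
#' @param n_per_setting candidate streamlines per threshold setting.
#' @param k_per_model per-setting preselection size entering the ETC.
#' @param step_size,stop_amplitude,min_length,max_length see
#'   [tracking_params()].
#' @param endpoint_dist_mm segmentation endpoint rule (mm).
#' @param len_sd,min_len_mm,pos_sd outlier-removal parameters.
#' @param proximity_thresholds_mm proximity report thresholds (mm).
#' @param atlas_threshold_pct percentage-overlap display threshold.
#' @param nnls_tol,nnls_max_iter weight-optimiser settings used at
#'   pipeline scale (relative objective-decrease tolerance / pass cap).
#' @param n_subjects cohort size.
#' @param master_seed master RNG seed; per-subject seeds are derived as
#'   `master_seed + 7919 * subject_index`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(grid_shape = c(30L, 30L, 30L), voxel_size = 2,
                       noise_sigma = 2, include_u_bundle = TRUE,
                       angular_thresholds = c(5.7, 11.5, 23.1, 47.2),
                       n_per_setting = 5000L, k_per_model = 500L,
                       step_size = 0.2, stop_amplitude = 0.1,
                       min_length = 10, max_length = 200,
                       endpoint_dist_mm = 3, len_sd = 3, min_len_mm = 15,
                       pos_sd = 3, proximity_thresholds_mm = c(3, 4.5),
                       atlas_threshold_pct = 25, nnls_tol = 1e-4,
                       nnls_max_iter = 1000L, n_subjects = 6L,
                       master_seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path file path.
#' @param config a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis chain for one phantom "subject"
#'
#' phantom generation (two sessions) -> tensor fit -> response estimation
#' -> CSD -> multi-threshold ensemble tracking from the GWMI -> per-setting
#' LiFE optimisation and preselection -> ETC re-optimisation -> endpoint-ROI
#' segmentation with outlier removal -> virtual lesion -> endpoint density
#' and ROI proximity -> visitation map. Fully deterministic given
#' `subject_seed`.
#'
#' @param config a [run_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier used in reports.
#' @param out_dir optional directory; when given, intermediates are
#'   persisted (TCK bundles, NIfTI maps, TSV weights, JSON lesion report).
#' @return list with `report` (one-row data.frame), `bundle`,
#'   `visitation`, `lesion`, `proximity`, `density`, `etc_model`, `truth`.
#' @export
run_subject <- function(config, subject_seed, subject_id = "S1",
                        out_dir = NULL) {
  spec <- make_u_bundle_spec(config$grid_shape, config$voxel_size,
                             seed = subject_seed,
                             noise_sigma = config$noise_sigma,
                             n_sessions = 2L,
                             include_u_bundle = config$include_u_bundle)
  ph <- generate_phantom(spec)
  s1 <- ph$sessions[[1]]; s2 <- ph$sessions[[2]]
  truth <- ph$truth; gtab <- ph$gtab
  tensor <- fit_tensor(s1, gtab, mask = truth$wm_mask)
  resp <- estimate_response(s1, gtab, tensor)
  fod <- deconvolve_fod(s1, gtab, resp, mask = truth$wm_mask)
  base <- tracking_params(step_size = config$step_size,
                          stop_amplitude = config$stop_amplitude,
                          min_length = config$min_length,
                          max_length = config$max_length,
                          n_streamlines = config$n_per_setting,
                          seed = subject_seed)
  ens <- generate_ensemble(fod, truth$gwmi_mask, truth$wm_mask, base,
                           config$angular_thresholds,
                           config$n_per_setting)
  models <- lapply(ens, function(tr)
    life(tr, s1, gtab, truth$wm_mask,
         max_iter = config$nnls_max_iter, tol = config$nnls_tol))
  etc <- build_etc(models, config$k_per_model, s1,
                   max_iter = config$nnls_max_iter, tol = config$nnls_tol)
  optimised <- prune(etc)
  seg <- segment_by_endpoints(optimised, truth$roi_labels,
                              truth$roi_labels, labelA = 1L, labelB = 2L,
                              dist_mm = config$endpoint_dist_mm,
                              name = "target")
  bundle <- if (length(seg$streamlines))
    remove_outliers(seg, config$len_sd, config$min_len_mm, config$pos_sd)
  else seg
  degenerate <- FALSE
  lesion <- NULL
  S <- NA_real_
  if (length(bundle$streamlines)) {
    cols <- optimised$provenance$parent_indices[bundle$indices]
    lesion <- tryCatch(virtual_lesion(etc, cols, s1, s2),
                       error = function(e) NULL)
    if (is.null(lesion) || !length(lesion$unlesioned$values))
      degenerate <- TRUE
    else S <- lesion$S
  }
  grey <- label_volume(spec$grid, truth$roi_labels$data,
                       truth$roi_labels$names)
  density <- endpoint_density(bundle, grey, dist_mm = config$endpoint_dist_mm)
  roi_sel <- stats::setNames(
    lapply(seq_along(spec$rois), function(r)
      list(volume = truth$roi_labels, label = r)),
    vapply(spec$rois, `[[`, "", "name"))
  prox <- roi_proximity(bundle, roi_sel, config$proximity_thresholds_mm)
  vmap <- visitation_map(bundle, spec$grid, subject_id)
  mean_len_cm <- if (length(bundle$streamlines))
    mean(streamline_lengths(bundle)) / 10 else NA_real_
  report <- data.frame(
    subject = subject_id, seed = subject_seed,
    n_candidates = sum(vapply(ens, length, 1L)),
    n_optimised = length(optimised$streamlines),
    n_bundle = length(bundle$streamlines),
    mean_length_cm = mean_len_cm, S = S, degenerate = degenerate)
  for (i in seq_len(nrow(prox)))
    report[[paste0("prox_", gsub("[^a-z0-9]+", "_", prox$roi[i]), "_",
                   prox$threshold_mm[i])]] <- prox$proportion[i]
  out <- list(report = report, bundle = bundle, visitation = vmap,
              lesion = lesion, proximity = prox, density = density,
              etc_model = etc, truth = truth, spec = spec)
  if (!is.null(out_dir)) persist_subject(out, out_dir, subject_id)
  out
}

persist_subject <- function(res, out_dir, subject_id) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(out_dir, subject_id)
  if (length(res$bundle$streamlines))
    write_tck(res$bundle, paste0(pfx, "_bundle.tck"))
  write_volume(res$visitation$map, paste0(pfx, "_visitation.nii.gz"))
  write_volume(res$density$normalised, paste0(pfx, "_endpoint_density.nii.gz"))
  utils::write.table(res$proximity, paste0(pfx, "_proximity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  w <- coef(res$etc_model)
  utils::write.table(data.frame(streamline = seq_along(w), weight = w),
                     paste0(pfx, "_weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$lesion))
    jsonlite::write_json(list(n_voxels = res$lesion$n_voxels,
                              mean_unlesioned = mean(res$lesion$unlesioned$values),
                              sd_unlesioned = stats::sd(res$lesion$unlesioned$values),
                              mean_lesioned = mean(res$lesion$lesioned$values),
                              sd_lesioned = stats::sd(res$lesion$lesioned$values),
                              S = res$lesion$S),
                         paste0(pfx, "_lesion.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(NULL)
}

#' Run a phantom cohort and build the probabilistic atlas
#'
#' Runs [run_subject()] once per subject with derived seeds. Each subject
#' receives a small known rigid jitter (its subject-to-template affine),
#' emulating imperfect inter-subject registration; visitation maps are
#' normalised to the common template grid with those affines and combined
#' into the percentage-overlap atlas. A failing subject is logged and
#' skipped; the run errors only if every subject fails.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for per-subject artefacts and
#'   `cohort_report.tsv`.
#' @return list with `report` (data.frame, one row per subject),
#'   `atlas` (an [percentage_overlap()] result), `summary` (cohort mean /
#'   SD of S), `maps`.
#' @export
run_cohort <- function(config, out_dir = NULL) {
  subjects <- seq_len(config$n_subjects)
  rows <- list(); maps <- list(); fails <- character(0)
  template_grid <- image_grid(config$grid_shape, config$voxel_size)
  for (s in subjects) {
    sid <- paste0("S", s)
    seed_s <- config$master_seed + 7919L * s
    res <- tryCatch(run_subject(config, seed_s, sid, out_dir),
                    error = function(e) {
                      message("subject ", sid, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) { fails <- c(fails, sid); next }
    # known rigid jitter: subject-to-template translation within +-1 mm
    set.seed(seed_s + 1L)
    jit <- diag(4); jit[1:3, 4] <- stats::runif(3, -1, 1)
    maps[[sid]] <- normalise_map(res$visitation, jit, template_grid)
    row <- res$report
    rows[[sid]] <- row
  }
  if (!length(rows)) stop("all subjects failed")
  report <- do.call(rbind, rows)
  atlas <- percentage_overlap(maps, config$atlas_threshold_pct)
  Sv <- report$S[!is.na(report$S)]
  summary <- list(mean_S = if (length(Sv)) mean(Sv) else NA_real_,
                  sd_S = if (length(Sv) > 1) stats::sd(Sv) else NA_real_,
                  n_failed = length(fails),
                  mean_length_cm = mean(report$mean_length_cm, na.rm = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "cohort_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_volume(atlas$overlap, file.path(out_dir, "atlas_overlap.nii.gz"))
  }
  list(report = report, atlas = atlas, summary = summary, maps = maps)
}
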