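# Shared fixtures, memoised so expensive stages run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# noiseless default phantom with fitted local models
fix_noiseless <- function() memo("noiseless", function() {
  spec <- make_u_bundle_spec(seed = 1L, noise_sigma = 0)
  ph <- generate_phantom(spec)
  s1 <- ph$sessions[[1]]
  tensor <- fit_tensor(s1, ph$gtab, ph$truth$wm_mask)
  response <- estimate_response(s1, ph$gtab, tensor)
  fod <- deconvolve_fod(s1, ph$gtab, response, mask = ph$truth$wm_mask)
  list(spec = spec, ph = ph, s1 = s1, truth = ph$truth, gtab = ph$gtab,
       tensor = tensor, response = response, fod = fod)
})

# noisy two-session phantom with a tracked ensemble member and LiFE fit
fix_noisy <- function() memo("noisy", function() {
  spec <- make_u_bundle_spec(seed = 1L, noise_sigma = 2)
  ph <- generate_phantom(spec)
  s1 <- ph$sessions[[1]]; s2 <- ph$sessions[[2]]
  tensor <- fit_tensor(s1, ph$gtab, ph$truth$wm_mask)
  fod <- deconvolve_fod(s1, ph$gtab,
                        estimate_response(s1, ph$gtab, tensor),
                        mask = ph$truth$wm_mask)
  tract <- track(fod, ph$truth$gwmi_mask, ph$truth$wm_mask,
                 tracking_params(n_streamlines = 1500L, seed = 42L))
  model <- suppressWarnings(
    life(tract, s1, ph$gtab, ph$truth$wm_mask, max_iter = 1000L,
         tol = 1e-5))
  list(spec = spec, ph = ph, s1 = s1, s2 = s2, truth = ph$truth,
       gtab = ph$gtab, fod = fod, tract = tract, model = model)
})

# exhaustive active-set NNLS oracle: scans every support set, keeps the
# feasible least-squares solution with the lowest objective
nnls_bruteforce <- function(M, y) {
  n <- ncol(M)
  best <- list(objective = 0.5 * sum(y^2), w = rep(0, n))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    Ms <- M[, S, drop = FALSE]
    ws <- tryCatch(solve(crossprod(Ms), crossprod(Ms, y)),
                   error = function(e) NULL)
    if (is.null(ws) || any(ws < 0)) next
    w <- rep(0, n); w[S] <- ws
    obj <- 0.5 * sum((y - M %*% w)^2)
    if (obj < best$objective) best <- list(objective = obj, w = w)
  }
  best
}

# mean turning angle (degrees) between consecutive steps of a tractogram
mean_turn_angle <- function(tract) {
  angs <- unlist(lapply(tract$streamlines, function(s) {
    d <- diff(s)
    d <- d / sqrt(rowSums(d^2))
    if (nrow(d) < 2L) return(numeric(0))
    dp <- pmin(1, pmax(-1, rowSums(d[-nrow(d), , drop = FALSE] *
                                     d[-1L, , drop = FALSE])))
    acos(dp) * 180 / pi
  }))
  mean(angs)
}

# straight-slab peak field pointing along +x, for geometric tracking checks
slab_peaks <- function(shape = c(40L, 10L, 10L), voxel = 2) {
  grid <- image_grid(shape, voxel)
  nvox <- prod(shape)
  dirs <- array(0, c(nvox, 1L, 3L)); dirs[, 1L, 1L] <- 1
  structure(list(grid = grid, voxel_index = seq_len(nvox),
                 directions = dirs,
                 amplitudes = matrix(1, nvox, 1L),
                 n_peaks = rep(1L, nvox)),
            class = "peak_volume")
}

# fixtures shared by bundle-operation and acceptance tests
make_endpoint_fixture <- function() {
  A <- cbind(0, 0, 0)           # single-voxel ROI centers
  B <- cbind(40, 0, 0)
  line <- function(from, to, n = 21L) {
    cbind(seq(from[1], to[1], length.out = n),
          seq(from[2], to[2], length.out = n),
          seq(from[3], to[3], length.out = n))
  }
  sl <- list(
    line(c(0, 0, 0), c(40, 0, 0)),            # compliant (exact centers)
    line(c(1, 2, 0), c(39, -2, 0)),           # compliant (within 3 mm)
    line(c(-20, 0, 0), c(60, 0, 0)),          # passes through both, ends far
    line(c(0, 0, 0), c(20, 0, 0)),            # one-sided
    line(c(100, 100, 100), c(140, 100, 100))) # remote
  list(tract = tractogram(sl), A = A, B = B)
}

straight_bundle <- function(n, length_mm = 40, jitter = 0) {
  sl <- lapply(seq_len(n), function(i) {
    off <- if (jitter > 0) stats::rnorm(2, 0, jitter) else c(0, 0)
    cbind(seq(0, length_mm, length.out = 41L), off[1] + (i - 1) * 0.1, off[2])
  })
  structure(c(unclass(tractogram(sl)),
              list(indices = seq_len(n), name = "fix",
                   segmentation = list())),
            class = c("tract_bundle", "tractogram"))
}
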