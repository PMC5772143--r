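# spherical-harmonic machinery --------------------------------------------

test_that("even-order SH basis is orthonormal and antipodally symmetric", {
  set.seed(1)
  v <- matrix(rnorm(3 * 5e4), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  B <- sh_basis(v, 6L)
  gram <- crossprod(B) / nrow(v) * 4 * pi
  expect_lt(max(abs(gram - diag(ncol(B)))), 0.05)   # Monte-Carlo estimate
  expect_equal(sh_basis(v[1:50, ], 8L), sh_basis(-v[1:50, ], 8L))
  expect_equal(sh_ncoef(8L), 45L)
})

test_that("zonal projection recovers a pure l=0 function", {
  r <- unname(zonal_coefficients(function(ct) rep(2, length(ct)), lmax = 8L))
  expect_equal(r[1], 2 * sqrt(4 * pi), tolerance = 1e-8)
  expect_lt(max(abs(r[-1])), 1e-8)
})

# tensor fit ----------------------------------------------------------------

test_that("tensor fit recovers FA and PDD from clean signals", {
  g <- lifetract:::fibonacci_sphere(30)
  gt <- gradient_table(c(0, 0, rep(1000, 30)), rbind(matrix(0, 2, 3), g))
  grid1 <- image_grid(c(1L, 1L, 1L), 2)
  sig_for <- function(D) {
    s <- c(100, 100, 100 * exp(-1000 * rowSums((g %*% D) * g)))
    volume(grid1, array(s, c(1, 1, 1, 32)))
  }
  # isotropic -> FA ~ 0
  iso <- fit_tensor(sig_for(diag(3) * 1e-3), gt)
  expect_lt(iso$fa$data[1], 1e-6)
  # closed-form FA for eigenvalues (1.7, 0.2, 0.2) x 1e-3
  ev <- c(1.7, 0.2, 0.2) * 1e-3
  fa_expected <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  tf <- fit_tensor(sig_for(diag(ev)), gt)
  expect_equal(tf$fa$data[1], fa_expected, tolerance = 1e-6)
  expect_equal(sort(tf$evals[1, ], decreasing = TRUE), sort(ev, decreasing = TRUE),
               tolerance = 1e-9)
  expect_error(fit_tensor(sig_for(diag(ev)),
                          gradient_table(c(0, rep(1000, 5)),
                                         rbind(0, g[1:5, ]))),
               ">= 6")
})

test_that("tensor PDD matches phantom truth within 1 degree (noiseless)", {
  f <- fix_noiseless()
  single <- which(f$truth$fractions[, 1] > 0.7 & f$truth$fractions[, 2] == 0)
  i <- match(single, f$tensor$voxel_index)
  ang <- fiber_angle(f$tensor$pdd[i, , drop = FALSE],
                     f$truth$orientations[single, 1, ])
  expect_lt(max(ang), 1)
})

test_that("tensor fit is invariant to global signal scaling", {
  f <- fix_noiseless()
  scaled <- volume(f$s1$grid, f$s1$data * 3.7)
  t2 <- fit_tensor(scaled, f$gtab, f$truth$wm_mask)
  expect_equal(t2$fa$data, f$tensor$fa$data, tolerance = 1e-9)
})

# response function ---------------------------------------------------------

test_that("estimated response is anisotropic the right way round", {
  f <- fix_noiseless()
  expect_gt(f$response$n_voxels, 20L)
  # kernel value = attenuation: larger perpendicular than parallel
  eval_kernel <- function(resp, ct) {
    d <- cbind(sqrt(1 - ct^2), 0, ct)
    m0 <- sh_m_orders(resp$lmax) == 0L
    as.vector(sh_basis(d, resp$lmax)[, m0, drop = FALSE] %*% resp$r_l)
  }
  expect_gt(eval_kernel(f$response, 0), eval_kernel(f$response, 1))
  # parallel attenuation of the phantom mixture in a high-FA voxel:
  # 0.8 stick (exp(-b d_axial)) + 0.2 isotropic (exp(-b d_iso))
  expected_par <- 0.8 * exp(-1.7) + 0.2 * exp(-3)
  expect_equal(eval_kernel(f$response, 1), expected_par, tolerance = 0.05)
})

test_that("analytic fallback fires when no high-FA voxels exist", {
  g <- image_grid(c(2L, 2L, 2L), 2)
  gt <- default_gradient_table()
  iso <- volume(g, array(rep(c(100, 100, rep(100 * exp(-1), 64)),
                             each = 8), c(2, 2, 2, 66)))
  tens <- fit_tensor(iso, gt)
  expect_warning(resp <- estimate_response(iso, gt, tens),
                 "analytic stick")
  expect_equal(resp$r_l, analytic_response(1000)$r_l)
})

# constrained spherical deconvolution ---------------------------------------

test_that("CSD resolves single fibres and 90-degree crossings (noiseless)", {
  f <- fix_noiseless()
  pk <- extract_peaks(f$fod)
  fr <- f$truth$fractions
  single <- which(fr[, 1] > 0.7 & fr[, 2] == 0)
  j <- match(single, pk$voxel_index)
  ang <- fiber_angle(pk$directions[j, 1L, ], f$truth$orientations[single, 1, ])
  expect_lt(max(ang), 2)
  # second peak, if any, is small
  expect_true(all(pk$amplitudes[j, 2] < 0.1 * pk$amplitudes[j, 1]))

  # equal-fraction 90-degree crossing in a constructed noiseless voxel
  g1 <- image_grid(c(1L, 1L, 1L), 2)
  gt <- default_gradient_table()
  kernel <- function(ct) exp(-1000 * (0.2e-3 + 1.5e-3 * ct^2))
  t1 <- c(1, 0, 0); t2 <- c(0, 1, 0)
  sig <- c(rep(100, 2),
           100 * (0.5 * kernel(gt$bvecs[!gt$b0, ] %*% t1) +
                    0.5 * kernel(gt$bvecs[!gt$b0, ] %*% t2)))
  vox <- volume(g1, array(sig, c(1, 1, 1, 66)))
  fod_x <- deconvolve_fod(vox, gt, analytic_response(1000))
  pk_x <- extract_peaks(fod_x)
  expect_equal(pk_x$n_peaks, 2L)
  errs <- sapply(1:2, function(q)
    min(fiber_angle(rbind(t1, t2), pk_x$directions[1, q, ])))
  expect_lt(max(errs), 10)

  # the phantom's own crossing voxels resolve two orientations too
  cross <- which(pmin(fr[, 1], fr[, 2]) > 0.15)
  expect_gt(length(cross), 0L)
  jc <- match(cross, pk$voxel_index)
  pk_all <- extract_peaks(f$fod, min_relative_amplitude = 0.1)
  expect_true(all(pk_all$n_peaks[jc] >= 2L))
})

test_that("isotropic voxels have suppressed FOD amplitude", {
  f <- fix_noiseless()
  # deconvolve a few isotropic background voxels with the same response
  bg <- which(rowSums(f$truth$fractions) == 0 & f$truth$roi_labels$data == 0)
  mask <- array(FALSE, f$spec$grid$shape); mask[bg[1:20]] <- TRUE
  fod_bg <- deconvolve_fod(f$s1, f$gtab, f$response, mask = mask)
  amp_bg <- max(fod_amplitudes(fod_bg))
  fr <- f$truth$fractions
  single <- which(fr[, 1] > 0.7 & fr[, 2] == 0)
  i <- match(single, f$fod$voxel_index)
  amp_single <- max(fod_amplitudes(f$fod)[i, ])
  expect_lt(amp_bg, 0.1 * amp_single)
})

test_that("FOD estimation is invariant to global signal scaling", {
  f <- fix_noiseless()
  scaled <- volume(f$s1$grid, f$s1$data * 0.25)
  fod2 <- deconvolve_fod(scaled, f$gtab, f$response, mask = f$truth$wm_mask)
  expect_equal(fod2$coef, f$fod$coef, tolerance = 1e-8)
})

test_that("peak recovery error decreases with SNR", {
  errs <- vapply(c(2, 1, 0.5), function(sg) {
    spec <- make_u_bundle_spec(seed = 9L, noise_sigma = sg)
    ph <- generate_phantom(spec)
    tens <- fit_tensor(ph$sessions[[1]], ph$gtab, ph$truth$wm_mask)
    fod <- deconvolve_fod(ph$sessions[[1]], ph$gtab,
                          estimate_response(ph$sessions[[1]], ph$gtab, tens),
                          mask = ph$truth$wm_mask)
    pk <- extract_peaks(fod)
    fr <- ph$truth$fractions
    single <- which(fr[, 1] > 0.7 & fr[, 2] == 0)
    j <- match(single, pk$voxel_index)
    median(fiber_angle(pk$directions[j, 1L, ],
                       ph$truth$orientations[single, 1, ]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("peak extraction handles constructed and degenerate FODs", {
  g <- image_grid(c(1L, 1L, 1L), 2)
  lobe_dir <- c(0.6, 0.8, 0)
  # delta-like lobe: SH coefficients of a delta at lobe_dir
  co <- as.vector(sh_basis(matrix(lobe_dir, 1L), 8L))
  fod1 <- structure(list(grid = g, voxel_index = 1L,
                         coef = matrix(co, 1L), lmax = 8L,
                         converged = TRUE),
                    class = "fod_volume")
  pk <- extract_peaks(fod1)
  expect_equal(pk$n_peaks, 1L)
  expect_lt(fiber_angle(pk$directions[1, 1, ], lobe_dir), 2)

  # two delta lobes at 90 degrees
  co2 <- co + as.vector(sh_basis(matrix(c(-0.8, 0.6, 0), 1L), 8L))
  fod2 <- fod1; fod2$coef <- matrix(co2, 1L)
  expect_equal(extract_peaks(fod2)$n_peaks, 2L)

  # all-zero coefficients: no peaks
  fod0 <- fod1; fod0$coef <- matrix(0, 1L, 45L)
  expect_equal(extract_peaks(fod0)$n_peaks, 0L)
})
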