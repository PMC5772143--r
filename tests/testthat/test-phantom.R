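test_that("default U-bundle spec has the expected geometry", {
  spec <- make_u_bundle_spec(seed = 5L)
  expect_length(spec$bundles, 2L)
  expect_length(spec$rois, 4L)                    # 2 endpoint + 2 distractor
  # deterministic construction
  spec2 <- make_u_bundle_spec(seed = 5L)
  expect_identical(spec$bundles, spec2$bundles)
  # centerline ends sit inside the endpoint ROI spheres
  u <- spec$bundles[[1]]$centerline
  endA <- u[1L, ]; endB <- u[nrow(u), ]
  dA <- sqrt(sum((endA - spec$rois[[1]]$center)^2))
  dB <- sqrt(sum((endB - spec$rois[[2]]$center)^2))
  expect_lt(dA, spec$rois[[1]]$radius)
  expect_lt(dB, spec$rois[[2]]$radius)
  # crossing angle at the apex is ~90 degrees
  u_dense <- resample_streamline(u, 200L)
  apex <- u_dense[which.max(u_dense[, 3]), ]
  d <- spec$bundles[[2]]$centerline
  near <- which.min(colSums((t(u_dense) - apex)^2))
  tan_u <- u_dense[near + 1L, ] - u_dense[near - 1L, ]
  tan_d <- d[2L, ] - d[1L, ]
  expect_gt(fiber_angle(tan_u, tan_d), 80)
  expect_error(make_u_bundle_spec(c(10L, 30L, 30L)), "too small")
})

test_that("U-bundle arc length matches the target tract length scale", {
  spec <- make_u_bundle_spec()
  # independent numeric arc-length integration on a dense resampling
  cl <- resample_streamline(spec$bundles[[1]]$centerline, 2000L)
  arc <- sum(sqrt(rowSums(diff(cl)^2)))
  expect_lt(abs(arc / 46.9 - 1), 0.2)
})

test_that("noiseless forward model matches hand-evaluated attenuations", {
  # b0 equals s0 exactly when sigma = 0
  f <- fix_noiseless()
  sig <- matrix(f$s1$data, prod(f$spec$grid$shape))
  expect_equal(range(sig[, f$gtab$b0]), c(100, 100))

  # single-orientation voxel, theta parallel to t, full fraction:
  # attenuation = exp(-b d_axial) = exp(-1.7)
  g <- image_grid(c(1L, 1L, 1L), 2)
  gt <- gradient_table(c(0, 1000, 1000),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  spec <- phantom_spec(g, list(), list(), gt, s0 = 100, d_axial = 1.7e-3,
                       d_radial = 0, noise_sigma = 0, seed = 1L)
  truth <- structure(list(
    orientations = array(c(1, 0, 0), c(1L, 1L, 3L)),
    fractions = matrix(1, 1L, 1L), bundle_names = "stick",
    wm_mask = volume(g, array(TRUE, c(1, 1, 1))),
    gwmi_mask = volume(g, array(FALSE, c(1, 1, 1))),
    roi_labels = label_volume(g, array(0L, c(1, 1, 1)))),
    class = "phantom_truth")
  ph <- generate_phantom(spec, truth)
  s <- as.vector(ph$sessions[[1]]$data)
  expect_equal(s[2] / s[1], exp(-1.7), tolerance = 1e-12)  # parallel
  expect_equal(s[3] / s[1], 1, tolerance = 1e-12)          # perpendicular
  expect_error(phantom_spec(g, list(), list(), gt, noise_sigma = -1),
               "noise_sigma")
})

test_that("noiseless signal is invariant to flipping orientations", {
  spec <- make_u_bundle_spec(seed = 2L, noise_sigma = 0)
  truth <- phantom_truth(spec)
  ph1 <- generate_phantom(spec, truth)
  truth$orientations <- -truth$orientations
  ph2 <- generate_phantom(spec, truth)
  expect_equal(ph1$sessions[[1]]$data, ph2$sessions[[1]]$data)
})

test_that("between-session RMSE grows with sigma and matches the Rician law", {
  spec0 <- make_u_bundle_spec(seed = 3L)
  rmse <- vapply(c(0.5, 1, 2), function(sg) {
    spec <- make_u_bundle_spec(seed = 3L, noise_sigma = sg)
    truth <- phantom_truth(spec)
    ph <- generate_phantom(spec, truth)
    sel <- which(rowSums(truth$fractions) == 0)[1:200]   # background voxels
    a <- matrix(ph$sessions[[1]]$data, prod(spec$grid$shape))[sel, ]
    b <- matrix(ph$sessions[[2]]$data, prod(spec$grid$shape))[sel, ]
    sqrt(mean((a - b)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))

  # analytic check: E[(X1 - X2)^2] = 2 Var(Rice(nu, sigma)), evaluated with
  # the Laguerre-polynomial mean formula, on >= 1e4 weighted-channel samples
  sg <- 2
  spec <- make_u_bundle_spec(seed = 11L, noise_sigma = sg)
  truth <- phantom_truth(spec)
  ph <- generate_phantom(spec, truth)
  bg <- which(rowSums(truth$fractions) == 0 & truth$roi_labels$data == 0)
  a <- matrix(ph$sessions[[1]]$data, prod(spec$grid$shape))[bg, !ph$gtab$b0]
  b <- matrix(ph$sessions[[2]]$data, prod(spec$grid$shape))[bg, !ph$gtab$b0]
  expect_gt(length(a), 1e4)
  nu <- 100 * exp(-1000 * spec$d_iso)          # common noiseless amplitude
  x <- -nu^2 / (2 * sg^2)
  L <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  m1 <- sg * sqrt(pi / 2) * L
  v <- nu^2 + 2 * sg^2 - m1^2
  expect_lt(abs(mean((a - b)^2) / (2 * v) - 1), 0.05)
})

test_that("phantom truth masks are consistent", {
  f <- fix_noiseless()
  truth <- f$truth
  wm <- truth$wm_mask$data
  grey <- truth$roi_labels$data > 0
  expect_false(any(wm & grey))                 # grey wins over white
  expect_true(all(truth$gwmi_mask$data <= wm)) # seeds are white matter
  expect_gt(sum(truth$gwmi_mask$data), 0)
  # every white-matter voxel carries at least one orientation
  widx <- which(wm)
  fr <- truth$fractions[widx, , drop = FALSE]
  expect_true(all(rowSums(fr) > 0))
  expect_true(all(rowSums(fr) <= 1 + 1e-12))
})
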