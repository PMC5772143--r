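# endpoint segmentation -------------------------------------------------------

test_that("endpoint segmentation keeps exactly the compliant streamlines", {
  fx <- make_endpoint_fixture()
  seg <- segment_by_endpoints(fx$tract, fx$A, fx$B, dist_mm = 3)
  expect_equal(seg$indices, c(1L, 2L))
  # brute-force oracle: enumerate terminal-distance conditions directly
  oracle <- which(vapply(fx$tract$streamlines, function(s) {
    e <- s[c(1L, nrow(s)), ]
    dA <- sqrt(colSums((t(e) - as.vector(fx$A))^2))
    dB <- sqrt(colSums((t(e) - as.vector(fx$B))^2))
    (dA[1] <= 3 && dB[2] <= 3) || (dA[2] <= 3 && dB[1] <= 3)
  }, logical(1)))
  expect_equal(seg$indices, oracle)
})

test_that("pass-through streamlines are excluded and order is irrelevant", {
  fx <- make_endpoint_fixture()
  seg <- segment_by_endpoints(fx$tract, fx$A, fx$B, dist_mm = 3)
  expect_false(3L %in% seg$indices)   # mid-course crossing does not count
  set.seed(4)
  perm <- sample(5L)
  seg_p <- segment_by_endpoints(subset_tractogram(fx$tract, perm),
                                fx$A, fx$B, dist_mm = 3)
  expect_equal(sort(perm[seg_p$indices]), c(1L, 2L))
  far <- subset_tractogram(fx$tract, 5L)
  expect_warning(empty <- segment_by_endpoints(far, fx$A, fx$B), "empty")
  expect_length(empty$streamlines, 0L)
})

# outlier removal --------------------------------------------------------------

test_that("outlier removal keeps identical streamlines untouched", {
  b <- straight_bundle(20L)
  out <- remove_outliers(b)
  expect_length(out$streamlines, 20L)
})

test_that("the 15-mm rule removes short members", {
  b <- straight_bundle(10L)
  b$streamlines[[4]] <- cbind(seq(0, 10, length.out = 11L), 0, 0)
  out <- remove_outliers(b)
  expect_equal(out$indices, setdiff(1:10, 4L))
})

test_that("the position rule removes exactly the displaced streamline", {
  set.seed(2)
  b <- straight_bundle(50L, jitter = 0.5)
  # plant one member displaced by 10 x the population spread
  disp <- b$streamlines[[17]]; disp[, 3] <- disp[, 3] + 10 * 0.5 * sqrt(2)
  b$streamlines[[17]] <- disp
  out <- remove_outliers(b)
  expect_equal(out$indices, setdiff(1:50, 17L))
  # brute-force check of the node-distance statistic on the fixture
  res <- lapply(b$streamlines, resample_streamline, n = 100L)
  mean_sl <- Reduce(`+`, res) / length(res)
  dev <- vapply(res, function(s) mean(sqrt(rowSums((s - mean_sl)^2))),
                numeric(1))
  expect_equal(which.max(dev), 17L)
})

test_that("outlier removal output is a subset and final set is clean", {
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  out <- remove_outliers(seg)
  expect_true(all(out$indices %in% seg$indices))
  len <- streamline_lengths(out)
  expect_true(all(len >= 15))                                  # rule (2)
  expect_true(all(len < mean(len) + 3 * stats::sd(len) | stats::sd(len) == 0))
})

test_that("tiny bundles skip the SD criteria with a warning", {
  b <- straight_bundle(2L)
  b$streamlines[[2]] <- cbind(seq(0, 10, length.out = 11L), 0, 0)
  expect_warning(out <- remove_outliers(b), "fewer than 3")
  expect_length(out$streamlines, 1L)
})

# endpoint density -------------------------------------------------------------

test_that("endpoint density counts terminal points near grey voxels", {
  g <- image_grid(c(11L, 11L, 11L), 2)
  grey <- array(0L, c(11, 11, 11)); grey[6, 6, 6] <- 1L
  lab <- label_volume(g, grey, c("1" = "patch"))
  # both endpoints of one streamline within 3 mm of the voxel center (10,10,10)
  s <- rbind(c(9, 10, 10), c(10, 14, 10), c(11, 10, 10))
  d <- endpoint_density(tractogram(list(s)), lab)
  expect_equal(d$counts$data[6, 6, 6], 2L)
  expect_equal(max(d$normalised$data), 1)
  # empty bundle gives an all-zero map
  d0 <- endpoint_density(tractogram(), lab)
  expect_true(all(d0$counts$data == 0L))
  # converging endpoints put the density argmax inside the patch
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  dd <- endpoint_density(seg, A)
  am <- which(dd$counts$data == max(dd$counts$data), arr.ind = TRUE)[1, ] - 1
  lab_at <- f$truth$roi_labels$data[am[1] + 1, am[2] + 1, am[3] + 1]
  expect_true(lab_at %in% c(1L, 2L))
})

# ROI proximity ---------------------------------------------------------------

test_that("proximity proportions behave at the extremes and monotonically", {
  fx <- make_endpoint_fixture()
  seg <- segment_by_endpoints(fx$tract, fx$A, fx$B, dist_mm = 3)
  far_roi <- cbind(0, 0, 100)
  pr <- roi_proximity(seg, list(far = far_roi))
  expect_true(all(pr$proportion == 0))
  at_ep <- rbind(c(0, 0, 0), c(40, 0, 0))
  pr2 <- roi_proximity(seg, list(hit = at_ep))
  expect_true(all(pr2$proportion == 1))
  # monotone in the threshold on a noisy realistic bundle
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg2 <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  rois <- list(a = list(volume = A, label = 1L),
               b = list(volume = A, label = 2L))
  pr3 <- roi_proximity(seg2, rois, thresholds_mm = c(3, 4.5))
  for (nm in c("a", "b")) {
    v <- pr3$proportion[pr3$roi == nm]
    expect_gte(v[2], v[1])
  }
})

test_that("the segmented bundle tracks the true centerline", {
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  bundle <- remove_outliers(seg)
  cl <- resample_streamline(f$spec$bundles[[1]]$centerline, 200L)
  devs <- vapply(bundle$streamlines, function(s) {
    p <- resample_streamline(s, 50L)
    mean(sqrt(lifetract:::nearest_point(p, cl)$d2))
  }, numeric(1))
  expect_lt(mean(devs), 2 * f$spec$grid$voxel_size[1])
})
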