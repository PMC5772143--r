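# design matrix -------------------------------------------------------------

test_that("a matched streamline explains a single-stick voxel", {
  g1 <- image_grid(c(3L, 3L, 3L), 2)
  gt <- default_gradient_table()
  # noiseless pure-stick signal along x in every voxel
  att <- exp(-1000 * 1.7e-3 * (gt$bvecs[!gt$b0, ] %*% c(1, 0, 0))^2)
  sig <- c(rep(100, 2), 100 * att)
  dwi <- volume(g1, array(rep(sig, each = 27), c(3, 3, 3, 66)))
  sl <- tractogram(list(cbind(seq(0, 4, by = 0.5), 2, 2)))  # along +x
  m <- build_life_model(sl, dwi, gt, array(TRUE, c(3, 3, 3)))
  # optimal scalar weight by closed-form least squares
  M1 <- as.vector(m$M)
  w_star <- sum(M1 * m$y) / sum(M1^2)
  resid <- sqrt(sum((m$y - w_star * M1)^2))
  expect_lt(resid, 0.01 * sqrt(sum(m$y^2)))
})

test_that("design columns are demeaned per voxel block", {
  f <- fix_noisy()
  M <- f$model$M
  ndir <- f$model$ndir
  nblock <- nrow(M) / ndir
  blk <- rep(seq_len(nblock), each = ndir)
  # per-column, per-block sums must vanish
  cs <- Matrix::t(Matrix::sparseMatrix(i = blk, j = seq_len(nrow(M)),
                                       x = 1)) # nrow x nblock indicator
  sums <- Matrix::crossprod(M, cs)             # ncol x nblock block sums
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("identical streamlines give identical columns", {
  g1 <- image_grid(c(3L, 3L, 3L), 2)
  gt <- default_gradient_table()
  dwi <- volume(g1, array(100, c(3, 3, 3, 66)))
  s <- cbind(seq(0, 4, by = 0.5), 2, 2)
  m <- build_life_model(tractogram(list(s, s)), dwi, gt,
                        array(TRUE, c(3, 3, 3)))
  expect_equal(as.vector(m$M[, 1]), as.vector(m$M[, 2]))
})

test_that("streamlines outside the mask keep flagged all-zero columns", {
  g1 <- image_grid(c(3L, 3L, 3L), 2)
  gt <- default_gradient_table()
  dwi <- volume(g1, array(100, c(3, 3, 3, 66)))
  mask <- array(TRUE, c(3, 3, 3)); mask[, , 3] <- FALSE
  inside <- cbind(seq(0, 4, by = 0.5), 2, 0)
  outside <- cbind(seq(0, 4, by = 0.5), 2, 4.2)
  expect_warning(
    m <- build_life_model(tractogram(list(inside, outside)), dwi, gt, mask),
    "outside")
  expect_equal(m$zero_columns, 2L)
  expect_equal(Matrix::colSums(abs(m$M))[2], 0)
})

# NNLS optimiser -------------------------------------------------------------

test_that("NNLS solves orthogonal and degenerate cases exactly", {
  g1 <- image_grid(c(3L, 3L, 3L), 2)
  gt <- default_gradient_table()
  dwi <- volume(g1, array(100, c(3, 3, 3, 66)))
  base <- build_life_model(tractogram(list(cbind(0:2, 2, 2))), dwi, gt,
                           array(TRUE, c(3, 3, 3)))
  # orthogonal columns, y = 2 * col1
  M <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(1, 1),
                            dims = c(4, 2))
  base$M <- M; base$y <- c(2, 0, 0, 0)
  w <- coef(optimize_weights(base))
  expect_equal(w, c(2, 0), tolerance = 1e-12)
  # y orthogonal to all columns
  base$y <- c(0, 0, 1, -1)
  expect_equal(coef(optimize_weights(base)), c(0, 0))
})

test_that("NNLS matches the exhaustive active-set oracle on random problems", {
  g1 <- image_grid(c(3L, 3L, 3L), 2)
  gt <- default_gradient_table()
  dwi <- volume(g1, array(100, c(3, 3, 3, 66)))
  base <- build_life_model(tractogram(list(cbind(0:2, 2, 2))), dwi, gt,
                           array(TRUE, c(3, 3, 3)))
  set.seed(11)
  for (rep in 1:20) {
    M <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30)
    base$M <- methods::as(M, "CsparseMatrix")
    base$y <- y
    fit <- optimize_weights(base, max_iter = 5000L, tol = 1e-12)
    oracle <- nnls_bruteforce(M, y)
    expect_lt(abs(fit$objective - oracle$objective), 1e-6)
  }
})

test_that("the optimiser descends monotonically", {
  f <- fix_noisy()
  model <- f$model
  objs <- vapply(c(1L, 2L, 5L, 10L, 25L), function(k)
    suppressWarnings(optimize_weights(model, max_iter = k,
                                      warm_start = FALSE))$objective,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

# pruning and the ETC ---------------------------------------------------------

test_that("pruning keeps supported streamlines in order", {
  f <- fix_noisy()
  model <- f$model
  model$w <- c(0.5, 0, 0.2, rep(0, ncol(model$M) - 3L))
  pr <- prune(model)
  expect_length(pr, 2L)
  expect_equal(pr$provenance$parent_indices, c(1L, 3L))
  expect_length(prune(model, k = 1L), 1L)
  expect_equal(prune(model, k = 1L)$provenance$weights, 0.5)
  expect_length(prune(model, k = 10L), 2L)   # k above the nonzero count
})

test_that("prune-and-refit reproduces the pruned objective", {
  f <- fix_noisy()
  small <- subset_tractogram(f$tract, 1:150)
  m <- suppressWarnings(life(small, f$s1, f$gtab, f$truth$wm_mask,
                             max_iter = 20000L, tol = 1e-13))
  pruned <- prune(m)
  refit <- suppressWarnings(
    life(pruned, f$s1, f$gtab, f$truth$wm_mask, max_iter = 20000L,
         tol = 1e-13))
  # voxels visited only by zero-weight streamlines drop out of the refit;
  # compare objectives on the refit's voxel rows, where the original
  # weights are feasible for the refit problem
  rows_keep <- which(rep(m$voxels, each = m$ndir) %in% refit$voxels)
  pred_orig <- as.vector(m$M %*% m$w)[rows_keep]
  obj_restr <- 0.5 * sum((m$y[rows_keep] - pred_orig)^2)
  expect_lte(refit$objective, obj_restr + 1e-9)
  expect_lt(abs(refit$objective - obj_restr), 1e-6 * max(1, obj_restr))
})

test_that("the ETC concatenates top-k sets and improves on its parents", {
  f <- fix_noisy()
  # split the fixture tractogram into 4 pseudo-settings and fit each
  n <- length(f$tract)
  parts <- split(seq_len(n), rep(1:4, length.out = n))
  models <- lapply(parts, function(idx)
    suppressWarnings(life(subset_tractogram(f$tract, idx), f$s1, f$gtab,
                          f$truth$wm_mask, max_iter = 400L, tol = 1e-6)))
  etc <- suppressWarnings(build_etc(models, k_per_model = 100L, f$s1,
                                    max_iter = 800L, tol = 1e-8))
  expect_length(etc$tractogram, 4L * 100L)
  # superset-of-columns argument: starting the ETC fit from any parent's
  # pruned weights cannot beat the re-optimised ETC
  pruned1 <- prune(models[[1]], k = 100L)
  w_pad <- numeric(ncol(etc$M))
  w_pad[seq_along(pruned1$provenance$weights)] <- pruned1$provenance$weights
  obj_pad <- 0.5 * sum((etc$y - as.vector(etc$M %*% w_pad))^2)
  expect_lte(etc$objective, obj_pad + 1e-9)
})

# R_rmse and virtual lesions --------------------------------------------------

test_that("R_rmse has its definitional fixed points", {
  f <- fix_noisy()
  vox <- f$model$voxels
  y1 <- demeaned_signals(f$s1, f$gtab, vox)
  y2 <- demeaned_signals(f$s2, f$gtab, vox)
  r1 <- r_rmse(f$model, f$s1, f$s2, prediction = y1)
  expect_lt(max(abs(r1$values - 1)), 1e-9)       # prediction == session 1
  r0 <- r_rmse(f$model, f$s1, f$s2, prediction = y2)
  expect_lt(max(abs(r0$values)), 1e-12)          # prediction == session 2
  # zero predictor is worse than test-retest reliability
  rz <- r_rmse(f$model, f$s1, f$s2, prediction = y2 * 0)
  expect_gt(median(rz$values), 1)
  expect_error(r_rmse(f$model, f$s1, f$s2, voxel_set = integer(0)), "empty")
})

test_that("R_rmse is invariant to global scaling of both sessions", {
  f <- fix_noisy()
  s1s <- volume(f$s1$grid, f$s1$data * 5)
  s2s <- volume(f$s2$grid, f$s2$data * 5)
  a <- r_rmse(f$model, f$s1, f$s2)
  b <- r_rmse(f$model, s1s, s2s)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("virtual lesion of the essential bundle shows positive evidence", {
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  bundle <- remove_outliers(seg)
  cols <- pruned$provenance$parent_indices[bundle$indices]
  vl <- virtual_lesion(f$model, cols, f$s1, f$s2)
  expect_gt(vl$S, 0)
  expect_gt(mean(vl$lesioned$values), mean(vl$unlesioned$values))
  expect_identical(vl$lesioned$voxels, vl$unlesioned$voxels)
})

test_that("lesioning zero-weight streamlines changes nothing", {
  f <- fix_noisy()
  zero_cols <- which(f$model$w == 0)[1:20]
  vl <- virtual_lesion(f$model, zero_cols, f$s1, f$s2)
  expect_identical(vl$S, 0)
  expect_true(vl$zero_weight_bundle)
  expect_identical(vl$lesioned$values, vl$unlesioned$values)
})

test_that("duplicated streamlines make a bundle redundant (S ~ 0)", {
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  cols <- pruned$provenance$parent_indices[seg$indices]
  # duplicate every bundle streamline before fitting, lesion one copy
  dup <- tractogram(c(f$model$tractogram$streamlines,
                      f$model$tractogram$streamlines[cols]))
  m2 <- suppressWarnings(life(dup, f$s1, f$gtab, f$truth$wm_mask,
                              max_iter = 1000L, tol = 1e-6))
  vl <- virtual_lesion(m2, cols, f$s1, f$s2)
  expect_lt(abs(vl$S), 2)
})

test_that("the essential bundle beats random distractor subsets", {
  f <- fix_noisy()
  pruned <- prune(f$model)
  A <- f$truth$roi_labels
  seg <- segment_by_endpoints(pruned, A, A, labelA = 1L, labelB = 2L)
  bundle_cols <- pruned$provenance$parent_indices[seg$indices]
  S_u <- virtual_lesion(f$model, bundle_cols, f$s1, f$s2)$S
  # distractor streamlines: supported, but not in the target bundle
  other <- setdiff(which(f$model$w > 0), bundle_cols)
  for (seed in 1:10) {
    set.seed(seed)
    rand_cols <- sample(other, length(bundle_cols))
    S_r <- virtual_lesion(f$model, rand_cols, f$s1, f$s2)$S
    expect_gt(S_u, S_r)
  }
})
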