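test_that("Welch t-scores match direct arithmetic and stats::t.test", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  # 3 pre frames, 3 stim frames, 1 post frame
  arr <- array(0i, c(1, 1, 7)); arr[1, 1, ] <- c(x, y, 4)
  ser <- image_series(arr, paradigm = paradigm(3, 3, 1))
  m <- tscore_map(ser)
  tt <- stats::t.test(x, y)
  expect_equal(m$t_scores[1, 1], (mean(x) - mean(y)) / sqrt(1 / 3 + 1 / 3),
               tolerance = 1e-10)
  expect_equal(m$t_scores[1, 1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(m$df[1, 1], unname(tt$parameter), tolerance = 1e-10)
})

test_that("degenerate-variance pixels get the signed sentinel", {
  arr <- array(0i, c(2, 1, 9))
  arr[1, 1, ] <- c(10, 10, 10, 10, 12, 12, 12, 12, 10)  # constant blocks
  arr[2, 1, ] <- rep(5, 9)                              # identical blocks
  ser <- image_series(arr, paradigm = paradigm(4, 4, 1))
  m <- tscore_map(ser)
  expect_equal(m$t_scores[1, 1], -1e6)               # baseline < activation
  expect_true(m$flags[1, 1])
  expect_equal(m$t_scores[2, 1], 0)                  # equal means
  expect_error(tscore_map(image_series(arr, paradigm = paradigm(1, 4, 4))),
               "at least 2")
})

test_that("cluster-extent rejection keeps the 6-pixel boundary", {
  t_scores <- matrix(0, 20, 20)
  t_scores[2:6, 2] <- 50          # 5-pixel line: rejected
  t_scores[10:15, 5] <- 50        # 6-pixel line: kept
  t_scores[18, 18] <- 50          # isolated pixel: rejected
  map <- structure(list(t_scores = t_scores, df = matrix(10, 20, 20),
                        flags = matrix(FALSE, 20, 20), n_x = 6, n_y = 6,
                        delay = 0, source = "ground_truth"),
                   class = "activation_map")
  out <- threshold_and_cluster(map, alpha = 0.05, min_cluster = 6)
  expect_false(any(out$active_mask[2:6, 2]))
  expect_true(all(out$active_mask[10:15, 5]))
  expect_false(out$active_mask[18, 18])
  expect_equal(sum(out$active_mask), 6)
  # idempotent
  twice <- threshold_and_cluster(out, alpha = 0.05, min_cluster = 6)
  expect_identical(twice$active_mask, out$active_mask)
  expect_error(threshold_and_cluster(map, alpha = 1.5), "alpha")
  # alpha near 1: every pixel with a nonzero score is supra-threshold and
  # only the cluster-size rule limits the active set
  map2 <- map; map2$t_scores[map2$t_scores == 0] <- 0.1
  loose <- threshold_and_cluster(map2, alpha = 1 - 1e-12, min_cluster = 6)
  expect_true(all(loose$active_mask))
  tight <- threshold_and_cluster(map2, alpha = 1 - 1e-12, min_cluster = 500)
  expect_false(any(tight$active_mask))
})

test_that("cluster rejection uses 4-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE      # diagonal only: two components
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  m[2, 1] <- TRUE                        # edge link: one component
  expect_equal(max(label_components(m)), 1L)
})

test_that("ROI selection mirrors the full-sampled active mask", {
  # noiseless synthetic data: activation pixels alone reject the null
  ph <- make_phantom(c(64, 48), seed = 2)
  ser <- simulate_timeseries(ph, paradigm(), acquisition_config("bssfp"))
  gt <- threshold_and_cluster(tscore_map(ser))
  roi <- select_roi(gt)
  expect_identical(roi$mask, gt$active_mask)
  expect_gte(sum(roi$mask & ph$activation_mask) / sum(ph$activation_mask), 0.9)
  empty <- gt; empty$active_mask <- matrix(FALSE, 64, 48)
  expect_error(select_roi(empty), "active")
  expect_error(select_roi(tscore_map(ser)), "threshold")
  # per-dataset provenance is independent
  roi2 <- select_roi(gt, source = "subject2")
  expect_false(identical(roi$source, roi2$source))
})

test_that("ROI time course is the per-frame mean magnitude", {
  arr <- array(0i, c(2, 1, 3))
  arr[1, 1, ] <- c(1, 5, 2); arr[2, 1, ] <- c(3, 5, 2)
  ser <- image_series(arr)
  both <- structure(list(mask = matrix(TRUE, 2, 1), source = "x"), class = "roi")
  one <- structure(list(mask = matrix(c(TRUE, FALSE), 2, 1), source = "x"), class = "roi")
  expect_equal(roi_timecourse(ser, both), c(2, 5, 2))
  expect_equal(roi_timecourse(ser, one), c(1, 5, 2))
  const <- image_series(array(7 + 0i, c(2, 2, 4)))
  expect_equal(roi_timecourse(const, matrix(TRUE, 2, 2)), rep(7, 4))
  expect_error(roi_timecourse(ser, matrix(FALSE, 2, 1)), "empty")
})

test_that("frame NMSE and average MSE follow their definitions", {
  u <- image_series(array(c(3, 4) + 0i, c(1, 2, 1)))
  uh <- image_series(array(c(3, 0) + 0i, c(1, 2, 1)))
  expect_equal(frame_nmse(u, uh), 16 / 25)
  expect_equal(frame_nmse(u, u), 0)
  expect_equal(frame_nmse(u, image_series(u$frames * 0)), 1)
  expect_error(frame_nmse(image_series(u$frames * 0), u), "zero norm")
  # 2 frames x 2 pixels with errors 1, 0, 2, 1 -> (1 + 0 + 4 + 1)/4
  tr <- image_series(array(5 + 0i, c(1, 2, 2)))
  rc <- image_series(array(5 + c(1, 0, 2, 1) + 0i, c(1, 2, 2)))
  expect_equal(average_mse(tr, rc), 6 / 4)
  expect_equal(average_mse(tr, tr), 0)
  e <- image_series(tr$frames + (0.3 + 0.4i))
  expect_equal(average_mse(tr, e), 0.25, tolerance = 1e-12)
  expect_error(average_mse(tr, u), "shapes")
})

test_that("average MSE decomposes over frame NMSE and frame energies", {
  fx <- fix_bssfp()
  recon <- image_series(fx$truth$frames +
                          rcarr(dim(fx$truth$frames), seed = 3) * 0.5,
                        paradigm = fx$paradigm)
  nm <- frame_nmse(fx$truth, recon)
  en <- vapply(1:48, function(t) sum(Mod(fx$truth$frames[, , t])^2), numeric(1))
  d <- dim(fx$truth$frames)
  expect_equal(average_mse(fx$truth, recon),
               sum(nm * en) / (d[3] * d[1] * d[2]), tolerance = 1e-10)
})

test_that("ROC sweep anchors, monotonicity and reference AUC values", {
  ktfmri:::with_seed(11, {
    gt <- matrix(FALSE, 100, 100)
    gt[sample(10000, 500)] <- TRUE
    # perfect separation
    scores <- matrix(0, 100, 100); scores[gt] <- 10 + stats::runif(500)
    scores[!gt] <- stats::runif(9500)
    roc <- roc_curve(scores, gt)
    expect_equal(roc$auc, 1)
    # independent scores: AUC 0.5 +- 0.02 over 1e4 pixels
    perm <- matrix(scores[sample(10000)], 100, 100)
    roc0 <- roc_curve(perm, gt)
    expect_lt(abs(roc0$auc - 0.5), 0.02)
    expect_true(all(diff(roc0$fpf) >= 0) && all(diff(roc0$tpf) >= -1e-12))
    expect_equal(c(roc0$fpf[1], utils::tail(roc0$fpf, 1)), c(0, 1))
    expect_equal(c(roc0$tpf[1], utils::tail(roc0$tpf, 1)), c(0, 1))
    # invariant under strictly monotone transforms of the scores
    roc_m <- roc_curve(sqrt(perm) + 3, gt)
    expect_equal(roc_m$auc, roc0$auc, tolerance = 1e-12)
    expect_error(roc_curve(scores, matrix(TRUE, 100, 100)), "both")
  })
})

test_that("trapezoidal AUC agrees with the rank-statistic oracle", {
  skip_if_not_installed("pROC")
  ktfmri:::with_seed(12, {
    gt <- matrix(stats::runif(2500) < 0.2, 50, 50)
    scores <- matrix(stats::rnorm(2500), 50, 50) + 1.5 * gt
    ours <- roc_curve(abs(scores), gt, n_thresholds = 2500)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(as.vector(gt), abs(as.vector(scores)))))
    expect_equal(ours, ref, tolerance = 5e-3)
  })
})
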