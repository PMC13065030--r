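test_that("histogram standardization maps in-mask intensities to a uniform CDF", {
  set.seed(5)
  vol <- array(rnorm(15^3, 100, 20), rep(15, 3))
  mask <- array(TRUE, rep(15, 3))
  mask[1:3, , ] <- FALSE
  std <- standardize_histogram(vol, mask)

  expect_equal(cor(std[mask], vol[mask], method = "spearman"), 1)
  expect_true(all(std[!mask] == 0))
  # Kolmogorov-Smirnov distance to uniform below 2/sqrt(n)
  v <- sort(std[mask])
  n <- length(v)
  ks <- max(abs(v - seq_len(n) / n))
  expect_lt(ks, 2 / sqrt(n))

  const <- array(7, rep(8, 3))
  cmask <- array(TRUE, rep(8, 3))
  cstd <- standardize_histogram(const, cmask)
  expect_true(all(cstd == 1))  # constant in, constant out
  expect_error(standardize_histogram(vol, array(FALSE, rep(15, 3))),
               "empty mask")
})

test_that("basal-ganglia mask refinement closes holes and only grows", {
  mask <- array(FALSE, rep(20, 3))
  mask[6:14, 6:14, 6:14] <- TRUE
  mask[10, 10, 10] <- FALSE  # one-voxel interior cavity
  refined <- refine_bg_mask(mask, radius = 2)
  expect_true(refined[10, 10, 10])
  expect_true(all(refined[mask]))  # superset of the input

  # dilation bound: extent grows by at most 2r per axis
  rng <- apply(which(refined, arr.ind = TRUE), 2, range)
  expect_true(all(rng[1, ] >= 6 - 2))
  expect_true(all(rng[2, ] <= 14 + 2))

  expect_warning(refine_bg_mask(array(FALSE, rep(8, 3)), 2), "empty")
})

test_that("the PVS threshold is the in-mask mean plus one population SD", {
  thr <- vesselness_threshold(c(0, 0, 0, 1))
  expect_equal(thr$mean, 0.25)
  expect_equal(thr$sd, 0.4330127, tolerance = 1e-6)
  expect_equal(thr$tau, 0.6830127, tolerance = 1e-6)
  expect_equal(sum(c(0, 0, 0, 1) > thr$tau), 1L)
})

test_that("uniform vesselness yields empty PVS masks", {
  const <- array(50, rep(20, 3))
  bg <- array(FALSE, rep(20, 3))
  bg[8:13, 8:13, 8:13] <- TRUE
  expect_warning(res <- segment_pvs(volume(const), bg), "zero-variance")
  expect_equal(sum(res$mask_left | res$mask_right), 0L)
  expect_equal(res$threshold_tau, res$mask_mean)
})

test_that("phantom PVS segmentation overlaps truth and reports a recomputable tau", {
  lab <- fixture_labels(64L)
  res <- fixture_pvs(64L)
  truth <- label_mask(lab, c("pvs_truth_left", "pvs_truth_right"))
  pred <- res$mask_left | res$mask_right
  expect_gte(dice_coefficient(pred, truth), 0.5)

  # tau recomputable exactly from the returned vesselness + refined mask
  thr <- vesselness_threshold(res$vesselness[res$refined_bg_mask])
  expect_identical(res$threshold_tau, thr$tau)
  expect_identical(res$mask_mean, thr$mean)

  # hemispheric masks are disjoint and on opposite sides of the midplane
  expect_equal(sum(res$mask_left & res$mask_right), 0L)
  xs <- which(res$mask_left, arr.ind = TRUE)[, 1]
  xr <- which(res$mask_right, arr.ind = TRUE)[, 1]
  expect_lt(max(xs), (64 + 1) / 2)
  expect_gt(min(xr), (64 + 1) / 2)
})

test_that("PVS Dice does not degrade as tube contrast increases", {
  lab <- fixture_labels(64L)
  bg <- label_mask(lab, c("basal_ganglia_left", "basal_ganglia_right",
                          "pvs_truth_left", "pvs_truth_right"))
  truth <- label_mask(lab, c("pvs_truth_left", "pvs_truth_right"))
  dices <- vapply(c(2400, 3200, 4000), function(pvs_t1) {
    tt <- default_tissue_t1()
    tt[c("pvs_truth_left", "pvs_truth_right")] <- pvs_t1
    imgs <- render_t1_pair(lab, default_enhancement("day"), noise_sd = 20,
                           seed = 7L, tissue_t1 = tt)
    res <- segment_pvs(imgs$t1w_pre, bg)
    dice_coefficient(res$mask_left | res$mask_right, truth)
  }, numeric(1))
  expect_true(all(diff(dices) >= -1e-12))
})

test_that("1-D GMM: closed forms, cluster recovery, monotone likelihood", {
  set.seed(10)
  v <- rnorm(200, 5, 2)
  one <- fit_gmm_1d(v, K = 1)
  expect_equal(one$means, mean(v))
  expect_equal(one$variances, var(v) * 199 / 200)

  x <- c(rnorm(500, 0, 1), rnorm(500, 10, 1))
  two <- fit_gmm_1d(x, K = 2)
  expect_equal(sort(two$means), c(0, 10), tolerance = 0.1)
  expect_true(all(diff(two$log_likelihood) >= -1e-9))
  expect_equal(sum(two$weights), 1, tolerance = 1e-12)
  expect_true(all(two$variances > 0))

  # degenerate cluster collapses onto the variance floor and is flagged
  degen <- c(rep(1, 50), rnorm(50, 20, 1e-2))
  fit <- fit_gmm_1d(degen, K = 2)
  expect_true(fit$variance_floored)
  expect_error(fit_gmm_1d(1:3, K = 2), "at least 2\\*K")
})

test_that("choroid plexus is the bright posterior-contrast component", {
  # constructed bimodal mask: CSF low, CP high, well separated
  vol <- array(0, rep(16, 3))
  mask <- array(FALSE, rep(16, 3))
  mask[4:12, 4:12, 4:12] <- TRUE
  set.seed(3)
  vals <- ifelse(runif(sum(mask)) < 0.3, rnorm(sum(mask), 800, 10),
                 rnorm(sum(mask), 100, 10))
  vol[mask] <- vals
  res <- segment_cp(volume(vol), mask)
  expect_identical(res$mask, mask & vol > 450)
  expect_true(res$separable)

  # constant-valued mask: the whole mask comes back
  cvol <- array(0, rep(10, 3))
  cmask <- array(FALSE, rep(10, 3))
  cmask[3:7, 3:7, 3:7] <- TRUE
  cvol[cmask] <- 640
  res2 <- segment_cp(volume(cvol), cmask)
  expect_identical(res2$mask, cmask)

  # overlapping components (heavy-tailed unimodal intensities: the mixture
  # fits a narrow core plus a wide tail sharing one mean) warn but still
  # return an assignment
  ovol <- array(0, rep(12, 3))
  omask <- array(FALSE, rep(12, 3))
  omask[3:9, 3:9, 3:9] <- TRUE
  set.seed(4)
  ovol[omask] <- 100 + 5 * rt(sum(omask), df = 3)
  expect_warning(res3 <- segment_cp(volume(ovol), omask), "separated")
  expect_equal(dim(res3$mask), dim(ovol))
})

test_that("phantom choroid plexus segmentation reaches Dice 0.7", {
  lab <- fixture_labels(64L)
  imgs <- fixture_rendered(64L)
  init <- label_mask(lab, c("choroid_plexus", "ventricle"))
  res <- segment_cp(imgs$t1w_post, init)
  expect_gte(dice_coefficient(res$mask, label_mask(lab, "choroid_plexus")),
             0.7)
})
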