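test_that("rigid transforms compose, invert, and serialize consistently", {
  t1 <- rigid_transform(c(3, -2, 5), c(1.5, -0.5, 2), center = c(20, 20, 20))
  m <- transform_matrix(t1)
  # rotation block is orthonormal (distances preserved)
  expect_equal(t(m[1:3, 1:3]) %*% m[1:3, 1:3], diag(3), tolerance = 1e-12)
  # composing with the inverse yields the identity within 1e-6
  comp <- compose_transforms(t1, invert_transform(t1))
  expect_equal(transform_matrix(comp), diag(4), tolerance = 1e-6)

  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(t1, path)
  expect_equal(read_transform(path), m, tolerance = 1e-8)
})

test_that("resampling honors identity, integer shifts, and label rules", {
  lab <- fixture_labels(64L)
  imgs <- fixture_rendered(64L)
  vol <- imgs$t1_pre

  ident <- rigid_transform(center = grid_center_world(dim(vol$data),
                                                      vol$voxel_size))
  expect_equal(resample(vol, ident)$data, vol$data, tolerance = 1e-12)

  # one-voxel translation with nearest neighbour is an exact shifted copy
  shift <- rigid_transform(translations = c(vol$voxel_size[1], 0, 0))
  out <- resample(vol, shift, interpolation = "nearest")
  expect_equal(out$data[2:64, , ], vol$data[1:63, , ])
  expect_true(all(out$data[1, , ] == 0))

  expect_error(resample(lab, shift, interpolation = "trilinear"),
               "nearest-neighbour")
  shifted_lab <- resample(lab, shift, interpolation = "nearest")
  expect_identical(shifted_lab$data[2:64, , ], lab$data[1:63, , ])
})

test_that("forward-then-inverse trilinear resampling stays within the interpolation bound", {
  imgs <- fixture_rendered(64L)
  vol <- gaussian_smooth(imgs$t1w_pre, 1)
  tr <- rigid_transform(c(0, 2, -3), c(1.2, -0.7, 0.4),
                        center = grid_center_world(dim(vol$data),
                                                   vol$voxel_size))
  back <- resample(resample(vol, tr), invert_transform(tr))

  # Bound from the interpolation kernel: each trilinear lookup is a convex
  # combination of the 8 surrounding voxels, so two passes keep every value
  # within the 5^3 neighbourhood range of the original. The achievable MAE
  # is bounded by the mean local half-range over that support.
  d <- dim(vol$data)
  loc_min <- vol$data
  loc_max <- vol$data
  for (off in -2:2) {
    idx <- pmin(pmax(seq_len(d[3]) + off, 1), d[3])
    loc_min <- pmin(loc_min, vol$data[, , idx])
    loc_max <- pmax(loc_max, vol$data[, , idx])
  }
  for (off in -2:2) {
    idx <- pmin(pmax(seq_len(d[1]) + off, 1), d[1])
    loc_min <- pmin(loc_min, vol$data[idx, , ])
    loc_max <- pmax(loc_max, vol$data[idx, , ])
  }
  for (off in -2:2) {
    idx <- pmin(pmax(seq_len(d[2]) + off, 1), d[2])
    loc_min <- pmin(loc_min, vol$data[, idx, ])
    loc_max <- pmax(loc_max, vol$data[, idx, ])
  }
  interior <- array(FALSE, d)
  interior[8:(d[1] - 7), 8:(d[2] - 7), 8:(d[3] - 7)] <- TRUE
  mae <- mean(abs(back$data - vol$data)[interior])
  bound <- mean(((loc_max - loc_min) / 2)[interior])
  expect_lt(mae, bound)
  expect_lt(mae, 0.05 * max(abs(vol$data)))  # and small in absolute terms
})

test_that("registering a volume to itself returns the identity", {
  imgs <- fixture_rendered(64L)
  reg <- register_rigid(imgs$t1w_post, imgs$t1w_post)
  expect_equal(reg$status, "ok")
  expect_lt(max(abs(reg$transform$rotations)), 0.05)
  expect_lt(max(abs(reg$transform$translations)), 0.05)
})

test_that("a known displacement is recovered within 0.2 mm / 0.2 deg", {
  # partial-volume-like smoothing keeps the least-squares floor low
  imgs <- fixture_rendered(64L, noise_sd = 5, seed = 3L)
  fixed <- gaussian_smooth(imgs$t1w_post, 1)
  center <- grid_center_world(dim(fixed$data), fixed$voxel_size)
  true_t <- rigid_transform(c(0, 0, 3), c(2, 0, 0), center)
  moving <- resample(fixed, invert_transform(true_t))

  reg <- register_rigid(moving, fixed)
  expect_equal(reg$status, "ok")
  expect_lt(max(abs(reg$transform$rotations - c(0, 0, 3))), 0.2)
  expect_lt(max(abs(reg$transform$translations - c(2, 0, 0))), 0.2)
  # cost bookkeeping: >= 90% reduction and non-increasing across levels
  expect_lt(reg$cost_final, 0.1 * reg$cost_initial)
  expect_true(all(diff(reg$cost_by_level) <= 1e-9))
})

test_that("random small transforms are recovered across orientations", {
  # 64^3 with 1.5-voxel pre-smoothing: at coarser grids / sharper edges the
  # least-squares minimum itself shifts by more than the 0.2 deg tolerance
  # (the phantom has no partial volume, so edges are step functions)
  imgs <- fixture_rendered(64L, noise_sd = 5, seed = 3L)
  fixed <- gaussian_smooth(imgs$t1w_post, 1.5)
  center <- grid_center_world(dim(fixed$data), fixed$voxel_size)
  set.seed(99)
  for (i in 1:10) {
    rot <- runif(3, -5, 5)
    tra <- runif(3, -4, 4)
    moving <- resample(fixed, invert_transform(rigid_transform(rot, tra,
                                                               center)))
    reg <- register_rigid(moving, fixed, polish = FALSE)
    expect_lt(max(abs(reg$transform$rotations - rot)), 0.2)
    expect_lt(max(abs(reg$transform$translations - tra)), 0.2)
  }
})

test_that("registration input checks fire", {
  a <- volume(array(rnorm(8^3), rep(8, 3)), 1)
  b <- volume(array(rnorm(8^3), rep(8, 3)), 2)
  expect_error(register_rigid(a, b), "voxel size")
  c2 <- volume(array(rnorm(9^3), rep(9, 3)), 1)
  expect_error(register_rigid(a, c2), "grid")
})
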