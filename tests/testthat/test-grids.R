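test_that("resampling preserves constants, target shape and field of view", {
  cv <- image_volume(array(40, c(12, 12, 6)), c(3, 3, 3))
  r <- resample_to_shape(cv, c(128, 128, 64))
  expect_equal(dim(r$voxels), c(128L, 128L, 64L))
  expect_lt(max(abs(r$voxels - 40)), 1e-9)
  # physical extent (edge to edge) unchanged
  expect_equal(dim(r$voxels) * r$spacing, c(12, 12, 6) * 3)

  big <- image_volume(array(rnorm(192 * 192 * 96), c(192, 192, 96)), c(1, 1, 2))
  expect_equal(dim(resample_to_shape(big, c(128, 128, 64))$voxels),
               c(128L, 128L, 64L))
  expect_error(resample_to_shape(cv, c(0, 10, 10)), "target_shape")
})

test_that("resampling a linear ramp matches the analytic ramp at new centres", {
  d <- c(20, 20, 10)
  ramp <- image_volume(array(rep(seq_len(d[3]), each = 400) * 10, d), c(2, 2, 4))
  r <- resample_to_shape(ramp, c(10, 10, 20))
  zc <- r$origin[3] + (seq_len(20) - 1) * r$spacing[3]
  expected <- (zc / 4) * 10 + 10        # value = 10 * (z_mm / 4 + 1)
  got <- r$voxels[5, 5, ]
  expect_lt(max(abs(got - expected)[2:19]), 1e-6)   # interior of the ramp
})

test_that("mask resampling is nearest neighbour and stays binary", {
  m <- ellipsoid_fixture(c(20, 20, 12), c(2, 2, 2), c(14, 12, 8))
  r <- resample_to_shape(m, c(30, 30, 18))
  expect_true(all(r$voxels %in% c(0L, 1L)))
  expect_s3_class(r, "binary_mask")
})

test_that("warp with a zero field is the bitwise identity", {
  set.seed(1)
  a <- array(rnorm(16 * 12 * 8, 0, 100), c(16, 12, 8))
  v <- image_volume(a, c(2, 2, 2))
  z <- deformation_field(array(0, c(16, 12, 8, 3)), c(2, 2, 2))
  expect_identical(warp(v, z)$voxels, v$voxels)
})

test_that("warp by exactly one voxel shifts the array and fills the border", {
  set.seed(2)
  a <- array(rnorm(16 * 12 * 8, 0, 100), c(16, 12, 8))
  v <- image_volume(a, c(2, 2, 2))
  u <- array(0, c(16, 12, 8, 3)); u[, , , 1] <- 2    # +1 voxel along x
  w <- warp(v, deformation_field(u, c(2, 2, 2)))
  expect_equal(w$voxels[1:15, , ], a[2:16, , ], tolerance = 1e-12)
  expect_true(all(w$voxels[16, , ] == -1024))
})

test_that("warp equals the nested-loop trilinear oracle on a random smooth field", {
  set.seed(3)
  d <- c(16, 16, 16)
  a <- array(rnorm(prod(d), 0, 200), d)
  v <- image_volume(a, c(1.5, 1.5, 1.5))
  dvf <- make_known_dvf(v, amplitude_mm = 3, smoothness_mm = 6, seed = 4)
  w <- warp(v, dvf)
  expect_lt(max(abs(w$voxels - warp_oracle(a, dvf$displacement, v$spacing))), 1e-6)
})

test_that("warp validates the grid contract", {
  v <- image_volume(array(0, c(8, 8, 8)))
  z <- deformation_field(array(0, c(8, 8, 4, 3)))
  expect_error(warp(v, z), "grid mismatch")
})

test_that("rigid transforms: identity, inverse round trip, exact 90-degree rotation", {
  sm <- smooth_fixture()
  expect_equal(apply_rigid(sm, rigid_transform())$voxels, sm$voxels,
               tolerance = 1e-12)

  t1 <- rigid_transform(translation = c(5, -3, 2))
  rt <- apply_rigid(apply_rigid(sm, t1), invert_rigid(t1))
  inner <- rt$voxels[6:19, 6:19, 4:9] - sm$voxels[6:19, 6:19, 4:9]
  expect_lt(max(abs(inner)), 1)   # interpolation tolerance, HU

  # inverse composes to the identity transform itself
  tc <- rigid_transform(rotation = c(4, -7, 12), translation = c(5, -3, 2))
  ti <- invert_rigid(tc)
  R <- latticeplan:::euler_matrix(tc$rotation) %*% latticeplan:::euler_matrix(ti$rotation)
  expect_lt(max(abs(R - diag(3))), 1e-9)

  # 90-degree z-rotation of a box phantom = index permutation
  d <- c(15, 15, 7)
  a <- array(0, d); a[5:8, 7:12, 3:5] <- 500
  v <- image_volume(a, c(2, 2, 2))
  got <- apply_rigid(v, rigid_transform(rotation = c(0, 0, 90)))$voxels
  # oracle: rotate indices about the centre (i,j) -> (j, n+1-i)
  perm <- array(0, d)
  for (i in 1:15) for (j in 1:15) perm[i, j, ] <- a[j, 15 + 1 - i, ]
  expect_equal(got, perm, tolerance = 1e-9)
})

test_that("NIfTI and JSON round trips preserve voxels and geometry", {
  set.seed(5)
  v <- image_volume(array(rnorm(16^3, 0, 500), c(16, 16, 16)),
                    c(1.5, 2, 2.5), c(-10, 5, 3))
  for (ext in c(".nii.gz", ".nii", ".json")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_identical(v2$voxels, v$voxels)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
    expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
  }

  dose <- dose_grid(array(runif(8^3, 0, 2400), c(8, 8, 8)), c(2, 2, 2))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(dose, f)
  expect_identical(read_dose(f)$voxels, dose$voxels)   # cGy, no rescaling

  m <- ellipsoid_fixture(c(10, 10, 10), c(2, 2, 2), c(8, 8, 8))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  expect_identical(read_mask(f)$voxels, m$voxels)

  dvf <- make_known_dvf(v, 3, 6, seed = 9)
  f <- tempfile(fileext = ".nii.gz")
  write_dvf(dvf, f)
  expect_equal(read_dvf(f)$displacement, dvf$displacement, tolerance = 1e-12)
})

test_that("I/O rejects missing files and non-positive spacing", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "image_volume", dim = c(2, 2, 2),
                            spacing = c(0, 1, 1), origin = c(0, 0, 0),
                            voxels = rep(0, 8)), f, auto_unbox = FALSE)
  expect_error(read_volume(f), "spacing")
})

test_that("type constructors enforce their invariants", {
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)), "spacing")
  expect_error(binary_mask(array(2L, c(4, 4, 4))), "0 or 1")
  expect_error(dose_grid(array(-5, c(4, 4, 4))), "cGy")
  expect_error(deformation_field(array(NA_real_, c(4, 4, 4, 3))), "finite")
  expect_error(rigid_transform(rotation = c(Inf, 0, 0)), "finite")
})
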