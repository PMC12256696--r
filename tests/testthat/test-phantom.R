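test_that("phantom generation is bit-reproducible under a fixed seed", {
  sp <- phantom_spec(seed = 7)
  b1 <- make_phantom(sp)
  b2 <- make_phantom(sp)
  expect_identical(b1$dct$voxels, b2$dct$voxels)
  expect_identical(b1$pct$voxels, b2$pct$voxels)
  expect_identical(b1$true_dvf$displacement, b2$true_dvf$displacement)
  b3 <- make_phantom(phantom_spec(seed = 8))
  expect_false(identical(b1$dct$voxels, b3$dct$voxels))
})

test_that("null deformation with matched couches leaves dCT ~ pCT at the noise level", {
  sp <- phantom_spec(deform_amplitude_mm = 0, sag_mm = 0, couch_dct = "flat",
                     couch_pct = "flat", noise_sd = 10, seed = 3)
  b <- make_phantom(sp)
  expect_lte(mae(b$dct, b$pct), 3 * sp$noise_sd)
})

test_that("deformation amplitude increases the dCT/pCT discrepancy on average", {
  m_of <- function(amp) {
    mean(vapply(1:3, function(s) {
      b <- make_phantom(phantom_spec(deform_amplitude_mm = amp, sag_mm = 0,
                                     couch_dct = "none", couch_pct = "none",
                                     noise_sd = 0, seed = 20 + s))
      mae(b$dct, b$pct)
    }, numeric(1)))
  }
  ms <- c(m_of(0), m_of(3), m_of(6))
  expect_true(all(diff(ms) > 0))
})

test_that("a pCT-only gas pocket produces localized high discrepancy", {
  sp <- phantom_spec(region = "abdomen", gas_pocket = "pct",
                     deform_amplitude_mm = 0, sag_mm = 0,
                     couch_dct = "flat", couch_pct = "flat",
                     noise_sd = 5, seed = 4)
  b <- make_phantom(sp)
  g <- latticeplan:::phantom_grid(sp)
  P <- as.matrix(expand.grid(x = g$ax[[1]], y = g$ax[[2]], z = g$ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  bc <- latticeplan:::body_center(sp, g)
  pocket <- sqrt(rowSums(sweep(P, 2, bc + sp$gas_center_mm)^2)) <= sp$gas_radius_mm - 3
  body <- b$body$voxels == 1L
  dif <- abs(b$dct$voxels - b$pct$voxels)
  expect_gte(mean(dif[pocket]), 200)
  expect_lt(mean(dif[body & !pocket]), 50)
})

test_that("phantom bundle deformation maps dCT anatomy onto pCT anatomy", {
  b <- make_phantom(phantom_spec(seed = 7, couch_dct = "none",
                                 couch_pct = "none", noise_sd = 0))
  w <- warp(b$dct, b$true_dvf)
  # evaluate away from the grid faces, where warp() takes the -1024 fill
  d <- dim(w$voxels)
  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  sel <- b$body$voxels == 1L & b$dct_body$voxels == 1L & interior
  warp_mae <- mean(abs(w$voxels[sel] - b$pct$voxels[sel]))
  dct_mae <- mean(abs(b$dct$voxels[sel] - b$pct$voxels[sel]))
  expect_lt(warp_mae, 6)              # interpolation-level residual
  expect_lt(warp_mae, 0.5 * dct_mae)  # far better than the unwarped scan
})

test_that("a GTV that pokes outside the body is rejected", {
  expect_error(make_phantom(phantom_spec(gtv_center_mm = c(85, 0, 0),
                                         gtv_semiaxes_mm = 30)),
               "invalid spec")
})

test_that("known deformation fields honour amplitude, smoothness seed contract", {
  v <- image_volume(array(0, c(24, 24, 16)), c(2.5, 2.5, 2.5))
  z <- make_known_dvf(v, amplitude_mm = 0, seed = 1)
  expect_true(all(z$displacement == 0))
  f5 <- make_known_dvf(v, amplitude_mm = 5, smoothness_mm = 15, seed = 1)
  mag <- sqrt(apply(f5$displacement^2, 1:3, sum))
  expect_lte(max(mag), 5 + 1e-9)
  expect_gt(max(mag), 4.99)
  expect_identical(make_known_dvf(v, 5, 15, seed = 1)$displacement,
                   f5$displacement)
  expect_false(identical(make_known_dvf(v, 5, 15, seed = 2)$displacement,
                         f5$displacement))
  expect_error(make_known_dvf(v, amplitude_mm = -1), "amplitude")
})

test_that("augmentation ops: rotate90 group property, centred crop, translate inverse", {
  set.seed(6)
  v <- image_volume(array(rnorm(20 * 20 * 6), c(20, 20, 6)), c(2, 2, 4))
  r4 <- augment(augment(augment(augment(v, "rotate90"), "rotate90"),
                        "rotate90"), "rotate90")
  expect_identical(r4$voxels, v$voxels)

  big <- image_volume(array(rnorm(256 * 256 * 4), c(256, 256, 4)))
  cr <- augment(big, "crop128")
  expect_equal(dim(cr$voxels)[1:2], c(128L, 128L))
  expect_equal(cr$origin[1:2], c(64, 64))   # centred window offset
  expect_identical(cr$voxels, big$voxels[65:192, 65:192, , drop = FALSE])
  expect_error(augment(v, "crop128"), "crop window")

  tshift <- augment(augment(v, "translate", shift_vox = c(2, 0, 0)),
                    "translate", shift_vox = c(-2, 0, 0))
  expect_identical(tshift$voxels[3:18, , ], v$voxels[3:18, , ])
})

test_that("synthetic lattice dose honours valley, peak and linearity", {
  gtv <- ellipsoid_fixture(c(48, 48, 32), c(2.5, 2.5, 2.5), c(45, 40, 30))
  ctr <- (c(48, 48, 32) - 1) / 2 * 2.5
  s1 <- sphere_set(matrix(ctr, 1), 15)
  dose <- synth_lattice_dose(s1, gtv, 2000, valley_ratio = 0.3)

  # minimum dose inside the GTV relative to prescription ~ valley ratio
  ratio <- min(dose$voxels[gtv$voxels == 1L]) / 2000
  expect_gte(ratio, 0.28); expect_lte(ratio, 0.32)

  # voxel at the sphere centre receives at least the prescription
  ci <- round(ctr / 2.5) + 1
  expect_gte(dose$voxels[ci[1], ci[2], ci[3]], 2000)

  # median over the sphere equals prescription within 1%
  ras <- rasterize_spheres(s1, gtv)
  med <- median(dose$voxels[ras$per_sphere[[1]]$voxels == 1L])
  expect_lt(abs(med - 2000) / 2000, 0.01)

  # linearity in the prescription
  dose2 <- synth_lattice_dose(s1, gtv, 4000, valley_ratio = 0.3)
  expect_equal(dose2$voxels, 2 * dose$voxels, tolerance = 1e-9)

  # empty sphere set: all-valley plateau with a structured warning
  expect_warning(
    d0 <- synth_lattice_dose(sphere_set(matrix(numeric(0), ncol = 3)), gtv, 2000,
                             valley_ratio = 0.3),
    class = "lp_empty_sphereset")
  expect_equal(unique(d0$voxels[gtv$voxels == 1L]), 600)
})
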