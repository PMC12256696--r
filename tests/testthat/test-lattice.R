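big_gtv <- function() ellipsoid_fixture(c(96, 96, 64), c(2.5, 2.5, 2.5),
                                        c(60, 50, 50))

# exact distances recomputed from first principles (independent of the
# package's distance transforms)
oracle_min_dist <- function(centers, mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  vc <- cbind((idx[, 1] - 1) * mask$spacing[1] + mask$origin[1],
              (idx[, 2] - 1) * mask$spacing[2] + mask$origin[2],
              (idx[, 3] - 1) * mask$spacing[3] + mask$origin[3])
  min(vapply(seq_len(nrow(centers)), function(r)
    sqrt(min(colSums((t(vc) - centers[r, ])^2))), numeric(1)))
}

test_that("placement on a feasible ellipsoid GTV honours every constraint", {
  gtv <- big_gtv()
  params <- placement_params()
  s <- place_spheres(gtv, list(), params)
  centers <- s$centers
  expect_gte(nrow(centers), 2)

  aud <- audit_placement(s, gtv, list(), params)
  expect_no_violations(aud)
  expect_gte(aud$min_center_to_gtv_surface_mm, 10)
  expect_gte(aud$min_cross_plane_spacing_mm, 30)

  # brute-force pairwise-distance oracle
  dm <- as.matrix(dist(centers))
  zplane <- round(centers[, 3] / 2.5)
  same <- outer(zplane, zplane, "==") & upper.tri(dm)
  cross <- (!outer(zplane, zplane, "==")) & upper.tri(dm)
  if (any(same)) {
    expect_gte(min(dm[same]), 60)
    # nearest same-plane neighbours within the 6-8 cm rule
    for (i in seq_len(nrow(centers))) {
      js <- setdiff(which(zplane == zplane[i]), i)
      if (length(js))
        expect_lte(min(dm[i, js]), 80)
    }
  }
  if (any(cross)) expect_gte(min(dm[cross]), 30)

  # exact surface-distance oracle agrees with the audit
  outside <- binary_mask(1L - gtv$voxels, gtv$spacing, gtv$origin)
  expect_equal(aud$min_center_to_gtv_surface_mm,
               oracle_min_dist(centers, outside), tolerance = 1e-9)
})

test_that("an infeasibly small GTV yields an empty set with a warning", {
  small <- ellipsoid_fixture(c(40, 40, 24), c(2.5, 2.5, 2.5), c(12, 12, 12))
  expect_warning(s <- place_spheres(small), class = "lp_empty_sphereset")
  expect_identical(nrow(s$centers), 0L)
})

test_that("OAR clearance is enforced with exact distances", {
  gtv <- big_gtv()
  d <- c(96L, 96L, 64L); ctr <- (d - 1) / 2 * 2.5
  yy <- rep(rep((seq_len(96) - 1) * 2.5, each = 96), 64)
  oar <- binary_mask(array(as.integer(yy >= ctr[2] + 60 & yy <= ctr[2] + 70), d),
                     c(2.5, 2.5, 2.5))
  s <- place_spheres(gtv, list(oar))
  expect_gte(oracle_min_dist(s$centers, oar), 15)
  aud <- audit_placement(s, gtv, list(oar))
  expect_no_violations(aud)
  expect_equal(aud$min_center_to_oar_mm, oracle_min_dist(s$centers, oar),
               tolerance = 1e-9)
})

test_that("placement is deterministic and monotone under GTV shrinkage", {
  gtv <- big_gtv()
  s1 <- place_spheres(gtv)
  s2 <- place_spheres(gtv)
  expect_identical(s1$centers, s2$centers)

  for (shrink in c(0.8, 0.6, 0.45)) {
    gsmall <- ellipsoid_fixture(c(96, 96, 64), c(2.5, 2.5, 2.5),
                                shrink * c(60, 50, 50))
    ssmall <- suppressWarnings(place_spheres(gsmall))
    expect_lte(nrow(ssmall$centers), nrow(s1$centers))
  }
})

test_that("rasterized spheres have the right volume and disjointness", {
  grid1 <- image_volume(array(0, c(40, 40, 40)), c(1, 1, 1))
  s <- sphere_set(matrix(c(19.5, 19.5, 19.5), 1), 15)
  ras <- rasterize_spheres(s, grid1)
  vol <- sum(ras$per_sphere[[1]]$voxels)    # 1 mm^3 voxels
  expect_lt(abs(vol - 4 / 3 * pi * 7.5^3) / (4 / 3 * pi * 7.5^3), 0.03)

  s2 <- sphere_set(rbind(c(12, 20, 20), c(12 + 30, 20, 20)), 15)
  ras2 <- rasterize_spheres(s2, grid1)
  expect_equal(sum(ras2$per_sphere[[1]]$voxels * ras2$per_sphere[[2]]$voxels), 0)

  expect_warning(ras3 <- rasterize_spheres(sphere_set(matrix(c(500, 500, 500), 1), 15),
                                           grid1),
                 class = "lp_sphere_outside")
  expect_identical(sum(ras3$per_sphere[[1]]$voxels), 0L)
})

test_that("the audit flags constructed violations", {
  gtv <- big_gtv()
  ctr <- (c(96, 96, 64) - 1) / 2 * 2.5
  # two centres 20 mm apart in different axial planes
  bad1 <- sphere_set(rbind(ctr, ctr + c(0, 0, 20)), 15)
  a1 <- audit_placement(bad1, gtv)
  expect_true(any(grepl("cross-plane", a1$violations)))

  # a centre only ~5 mm inside the GTV surface
  bad2 <- sphere_set(matrix(ctr + c(55, 0, 0), 1), 15)
  a2 <- audit_placement(bad2, gtv)
  expect_true(any(grepl("GTV surface", a2$violations)))
  expect_lt(a2$min_center_to_gtv_surface_mm, 10)

  # same-plane pair tighter than 6 cm
  bad3 <- sphere_set(rbind(ctr, ctr + c(40, 0, 0)), 15)
  a3 <- audit_placement(bad3, gtv)
  expect_true(any(grepl("same-plane", a3$violations)))
})

test_that("sphere_set validates distinct centres", {
  expect_error(sphere_set(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})
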