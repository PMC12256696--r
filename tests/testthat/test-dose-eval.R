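test_that("DVH curves: uniform step, exhaustive two-voxel case, sort oracle", {
  d <- c(10L, 10L, 10L)
  m <- binary_mask(array(1L, d), c(1, 1, 1))
  uni <- dose_grid(array(2000, d), c(1, 1, 1))
  cv <- dvh_curve(uni, m)
  expect_equal(cv$volume_fraction[cv$dose_cGy <= 2000], rep(1, 2001))
  expect_equal(cv$volume_fraction[cv$dose_cGy > 2000], 0)

  # two voxels at 100 / 300 cGy
  m2 <- binary_mask(array(0L, d), c(1, 1, 1))
  m2$voxels[1, 1, 1] <- 1L; m2$voxels[2, 1, 1] <- 1L
  dd <- dose_grid(array(0, d), c(1, 1, 1))
  dd$voxels[1, 1, 1] <- 100; dd$voxels[2, 1, 1] <- 300
  cv2 <- dvh_curve(dd, m2)
  f <- function(x) cv2$volume_fraction[match(x, cv2$dose_cGy)]
  expect_equal(f(0), 1); expect_equal(f(100), 1)
  expect_equal(f(101), 0.5); expect_equal(f(300), 0.5); expect_equal(f(301), 0)

  # random dose vs a sorted-voxel oracle at every bin
  set.seed(1)
  rd <- dose_grid(array(runif(1000, 0, 500), d), c(1, 1, 1))
  cv3 <- dvh_curve(rd, m, bin_width_cGy = 5)
  vals <- rd$voxels[m$voxels == 1L]
  oracle <- vapply(cv3$dose_cGy, function(g) mean(sort(vals) >= g), numeric(1))
  expect_equal(cv3$volume_fraction, oracle)

  expect_error(dvh_curve(uni, binary_mask(array(0L, d), c(1, 1, 1)),
                         structure_name = "cord"), "cord")
})

test_that("DVH metrics: uniform dose, analytic ramp, hand-counted DV-cc", {
  d <- c(10L, 10L, 10L)
  m <- binary_mask(array(1L, d), c(1, 1, 1))
  uni <- dose_grid(array(1234, d), c(1, 1, 1))
  mu <- dvh_metrics(uni, m, 2000, mvs_level_cGy = 740, dv_cc = 0.03)
  for (f in c("Dmax", "Dmin", "Dmean", "D10", "D50", "D90", "D0.03cc"))
    expect_equal(mu[[f]], 1234)
  expect_equal(mu$heterogeneity, 1)
  expect_equal(mu$MVS_cc, 0)

  # linear ramp 0 -> 1000 cGy across a 1 cc-per-slice box
  ramp <- dose_grid(array(rep(seq(0, 999, length.out = 10), each = 100), d),
                    c(1, 1, 1))
  mr <- dvh_metrics(ramp, m, 2000, mvs_level_cGy = 740)
  expect_lt(abs(mr$D50 - 500), 60)            # analytic D50% ~ 500 cGy
  # 7 of the 10 discrete ramp levels lie strictly below 740 cGy
  expect_equal(mr$MVS_cc, 0.7 * mr$volume_cc)

  # 1000 voxels of 1 mm^3; hottest 30 at 600 cGy -> D0.03cc = 600 by count
  hot <- array(100, d); hot[1:30] <- 600
  mh <- dvh_metrics(dose_grid(hot, c(1, 1, 1)), m, 2000)
  expect_equal(mh[["D0.03cc"]], 600)
  expect_error(dvh_metrics(uni, m, 2000, dv_cc = 5), "exceeds")
})

test_that("DVH metrics equal a sort-based oracle and keep their ordering", {
  set.seed(2)
  for (rep in 1:3) {
    d <- c(12L, 10L, 8L)
    sp <- runif(3, 0.8, 3)
    mask <- binary_mask(array(as.integer(runif(prod(d)) > 0.3), d), sp)
    dose <- dose_grid(array(rexp(prod(d), 1 / 500), d), sp)
    mm <- dvh_metrics(dose, mask, 2000, dv_cc = 0.03)
    vals <- dose$voxels[mask$voxels == 1L]
    vvox <- prod(sp) / 1000
    vol <- length(vals) * vvox
    for (pct in c(10, 50, 90)) {
      expect_equal(mm[[paste0("D", pct)]],
                   dvh_oracle_dose_at(vals, vvox, pct / 100 * vol),
                   tolerance = 1e-12)
    }
    expect_equal(mm[["D0.03cc"]], dvh_oracle_dose_at(vals, vvox, 0.03),
                 tolerance = 1e-12)
    expect_identical(mm$Dmax, max(vals))
    expect_identical(mm$Dmin, min(vals))
  }

  # ordering invariant on many random doses
  set.seed(3)
  m <- binary_mask(array(1L, c(8, 8, 8)), c(2, 2, 2))
  for (i in 1:100) {
    dv <- dose_grid(array(rgamma(512, shape = runif(1, 0.5, 4),
                                 rate = 1 / 300), c(8, 8, 8)), c(2, 2, 2))
    mm <- dvh_metrics(dv, m, 2000, dv_cc = numeric(0))
    expect_true(mm$Dmin <= mm$D90 + 1e-9 && mm$D90 <= mm$D50 + 1e-9 &&
                mm$D50 <= mm$D10 + 1e-9 && mm$D10 <= mm$Dmax + 1e-9)
  }
})

test_that("isodose sphere fitting recovers generating centres and fixed diameter", {
  gtv <- ellipsoid_fixture(c(96, 96, 64), c(2.5, 2.5, 2.5), c(60, 50, 50))
  ctr <- (c(96, 96, 64) - 1) / 2 * 2.5
  gen <- sphere_set(rbind(ctr, ctr + c(40, 0, 0), ctr + c(0, 0, 35)), 15)
  dose <- synth_lattice_dose(gen, gtv, 2000, valley_ratio = 0.3)
  fit <- fit_spheres_from_isodose(dose, 2000, level_fraction = 0.5)
  expect_identical(nrow(fit$centers), 3L)
  expect_identical(fit$diameter_mm, 15)
  err <- sqrt(rowSums((fit$centers - gen$centers)^2))
  expect_lt(max(err), 2.5)    # within one voxel

  low <- dose_grid(array(100, c(10, 10, 10)), c(2, 2, 2))
  expect_identical(nrow(fit_spheres_from_isodose(low, 2000)$centers), 0L)
})

test_that("dose profiles sample the segment correctly", {
  d <- c(20L, 20L, 20L)
  cdose <- dose_grid(array(750, d), c(2, 2, 2))
  expect_equal(dose_profile(cdose, c(2, 2, 2), c(30, 30, 30), 25), rep(750, 25))

  zero <- dose_grid(array(0, d), c(2, 2, 2))
  expect_equal(dose_profile(zero, c(0, 0, 0), c(38, 0, 0), 10), rep(0, 10))

  gtv <- ellipsoid_fixture(c(48, 48, 32), c(2.5, 2.5, 2.5), c(40, 40, 30))
  ctr <- (c(48, 48, 32) - 1) / 2 * 2.5
  dose <- synth_lattice_dose(sphere_set(matrix(ctr, 1), 15), gtv, 2000, 0.3)
  prof <- dose_profile(dose, ctr - c(30, 0, 0), ctr + c(30, 0, 0), 61)
  expect_lte(abs(which.max(prof) - 31), 1)   # peak at the centre sample
  expect_error(dose_profile(dose, c(-50, 0, 0), ctr, 10), "inside")
})

test_that("Wilcoxon signed-rank p-values match exhaustive sign enumeration", {
  set.seed(4)
  for (n in c(5, 7, 10)) {
    for (rep in 1:3) {
      x <- round(rnorm(n, 0, 4), 1)
      y <- round(rnorm(n, 0.6, 4), 1)     # rounding induces occasional ties
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
  # cross-check against the reference implementation when ties are absent
  x <- c(1.1, 2.3, -0.7, 4.2, -1.9, 0.4, 3.3)
  y <- c(0.2, 2.9, -1.5, 1.0, -0.3, 1.8, 2.2)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Wilcoxon conventions: zeros dropped, shifts give the extreme p", {
  z <- wilcoxon_signed_rank(rep(2, 6), rep(2, 6))
  expect_true(z$degenerate)
  expect_true(is.na(z$p_value))

  # constant shift: all signs agree, the smallest attainable two-sided p = 2/2^n
  set.seed(5)
  a <- rnorm(8)
  got <- wilcoxon_signed_rank(a, a + 50)
  expect_equal(got$p_value, 2 / 2^8, tolerance = 1e-12)
  expect_identical(got$statistic, 0)   # all differences negative
})

test_that("plan comparison pairs metrics by structure and flags degeneracy", {
  d <- c(10L, 10L, 10L)
  m <- binary_mask(array(1L, d), c(1, 1, 1))
  mk <- function(base) {
    list(gtv = dvh_metrics(dose_grid(array(base, d), c(1, 1, 1)), m, 2000,
                           dv_cc = 0.03),
         cord = dvh_metrics(dose_grid(array(base / 4, d), c(1, 1, 1)), m, 2000,
                            dv_cc = 0.03))
  }
  a <- lapply(c(2000, 2010, 1990, 2005, 1998, 2003), mk)
  expect_error(compare_plans(a, lapply(seq_along(a), function(i)
    list(gtv = a[[i]]$gtv))), "unmatched")

  cmp0 <- compare_plans(a, a)
  expect_true(all(cmp0$mean_dev == 0))
  expect_true(all(cmp0$degenerate))
  expect_false(any(cmp0$significant))

  b <- lapply(c(2000, 2010, 1990, 2005, 1998, 2003) + 50, mk)
  cmp <- compare_plans(a, b)
  gtv_dmean <- cmp[cmp$structure == "gtv" & cmp$metric == "Dmean", ]
  expect_equal(gtv_dmean$mean_dev, -50)
  expect_equal(gtv_dmean$p_value, 2 / 2^6, tolerance = 1e-12)
  expect_true(gtv_dmean$significant)
})
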