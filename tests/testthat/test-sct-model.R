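toy_spec <- function(...) {
  args <- utils::modifyList(list(levels = 2, start_channels = 2, epochs = 3,
                                 lr = 0.01), list(...))
  do.call(model_spec, args)
}

test_that("model shape contract and zero-initialized identity start", {
  spec <- toy_spec(seed = 5)
  m <- build_model(spec)
  v <- random_volume(c(16, 16, 8), spacing = c(2, 2, 2))
  out <- predict_sct(m, v)
  expect_equal(dim(out$dvf$displacement), c(16L, 16L, 8L, 3L))
  expect_true(all(out$dvf$displacement == 0))
  expect_identical(out$sct$voxels, v$voxels)    # identity warp before training

  # indivisible grid rejected at prediction time
  bad <- random_volume(c(15, 16, 8))
  expect_error(predict_sct(m, bad), "divisible")

  # identical spec -> identical parameter count and identical weights
  m2 <- build_model(spec)
  expect_identical(vapply(m$params, length, integer(1)),
                   vapply(m2$params, length, integer(1)))
  expect_identical(m$params, m2$params)
})

test_that("loss components behave at the fixed points", {
  spec <- toy_spec()
  v <- random_volume(c(8, 8, 8))
  z <- deformation_field(array(0, c(8, 8, 8, 3)), v$spacing)
  l0 <- sct_loss(v, v, z, spec)
  expect_identical(l0$similarity, 0)
  expect_identical(l0$regularizer, 0)
  expect_identical(l0$total, 0)

  # constant displacement: diffusion penalty vanishes
  cdvf <- deformation_field(array(2.5, c(8, 8, 8, 3)), v$spacing)
  expect_equal(sct_loss(v, v, cdvf, spec)$regularizer, 0)
})

test_that("diffusion regularizer equals a nested-loop finite-difference oracle", {
  set.seed(7)
  u <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  got <- latticeplan:::reg_value_grad(u)$value
  s <- 0; n <- 0
  for (c3 in 1:3) {
    uc <- u[, , , c3]
    for (i in 1:7) for (j in 1:8) for (k in 1:8) {
      s <- s + (uc[i + 1, j, k] - uc[i, j, k])^2; n <- n + 1
    }
    for (i in 1:8) for (j in 1:7) for (k in 1:8) {
      s <- s + (uc[i, j + 1, k] - uc[i, j, k])^2; n <- n + 1
    }
    for (i in 1:8) for (j in 1:8) for (k in 1:7) {
      s <- s + (uc[i, j, k + 1] - uc[i, j, k])^2; n <- n + 1
    }
  }
  expect_lt(abs(got - s / n), 1e-6)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(8)
  d <- c(8L, 8L, 8L)
  for (simloss in c("mse", "lncc")) {
    spec <- model_spec(levels = 2, start_channels = 2, similarity_loss = simloss,
                       lncc_window_vox = 5, epochs = 1, seed = 5)
    dct <- array(rnorm(prod(d), 0, 300), d)
    pct <- array(rnorm(prod(d), 0, 300), d)
    params <- latticeplan:::init_params(spec)
    params$out.W[] <- rnorm(length(params$out.W), 0, 0.01)
    xn <- latticeplan:::norm_hu(dct)
    lossf <- function(p) {
      fw <- latticeplan:::model_forward(p, spec, xn, d)
      latticeplan:::pair_loss_grad(spec, dct, pct, fw$raw, d, c(2, 2, 2),
                                   want_grad = FALSE)$total
    }
    fw <- latticeplan:::model_forward(params, spec, xn, d)
    lg <- latticeplan:::pair_loss_grad(spec, dct, pct, fw$raw, d, c(2, 2, 2))
    grads <- latticeplan:::model_backward(params, spec, fw$cache, lg$graw, d)
    for (nm in c("enc1.W", "dec1.W", "out.W", "out.b")) {
      i <- which.max(abs(grads[[nm]]))
      eps <- 1e-5
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossf(p2) - lossf(p3)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste(simloss, nm))
    }
  }
})

test_that("training is deterministic, validates input, and handles degenerate pairs", {
  set.seed(9)
  mkpair <- function(s) {
    b <- make_phantom(phantom_spec(seed = s, grid_shape = c(32, 32, 16),
                                   spacing = c(7.5, 7.5, 7.5),
                                   couch_dct = "none", couch_pct = "none",
                                   deform_amplitude_mm = 4, noise_sd = 5))
    list(dct = b$dct, pct = b$pct)
  }
  pairs <- lapply(1:2, mkpair)
  spec <- toy_spec(seed = 3)
  m1 <- train_sct_model(pairs, spec)
  m2 <- train_sct_model(pairs, spec)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  expect_lte(tail(m1$trace, 1), m1$trace[1])   # never worse than identity warp

  expect_error(train_sct_model(list(), spec), "at least one")

  # identical dCT = pCT pairs: learned field stays near zero
  idp <- list(list(dct = pairs[[1]]$pct, pct = pairs[[1]]$pct))
  mid <- train_sct_model(idp, toy_spec(seed = 4, epochs = 5))
  u <- predict_sct(mid, idp[[1]]$dct)$dvf$displacement
  expect_lt(mean(sqrt(apply(u^2, 1:3, sum))), 0.5)
})

test_that("serialization round trip reproduces predictions bit-exactly", {
  b <- make_phantom(phantom_spec(seed = 2, grid_shape = c(32, 32, 16),
                                 spacing = c(7.5, 7.5, 7.5),
                                 couch_dct = "none", couch_pct = "none"))
  m <- train_sct_model(list(list(dct = b$dct, pct = b$pct)), toy_spec(seed = 6))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  p1 <- predict_sct(m, b$dct)
  p2 <- predict_sct(m2, b$dct)
  expect_identical(p1$sct$voxels, p2$sct$voxels)
  expect_identical(p1$dvf$displacement, p2$dvf$displacement)
})

test_that("stronger regularization smooths the learned field monotonically", {
  mkpair <- function(s) {
    b <- make_phantom(phantom_spec(seed = s, grid_shape = c(32, 32, 16),
                                   spacing = c(7.5, 7.5, 7.5),
                                   couch_dct = "none", couch_pct = "none",
                                   deform_amplitude_mm = 5, noise_sd = 5))
    list(dct = b$dct, pct = b$pct)
  }
  pairs <- lapply(1:2, mkpair)
  gnorm <- vapply(c(0.001, 0.05, 2), function(lam) {
    m <- train_sct_model(pairs, model_spec(levels = 2, start_channels = 2,
                                           epochs = 8, lr = 0.01,
                                           reg_weight = lam, seed = 13))
    u <- predict_sct(m, pairs[[1]]$dct)$dvf$displacement
    sqrt(latticeplan:::reg_value_grad(u)$value)
  }, numeric(1))
  expect_true(all(diff(gnorm) <= 1e-12))
})
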