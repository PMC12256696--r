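# Synthetic-CT predictor: a 3D convolutional encoder-decoder that maps a
# (couch-removed, rigidly aligned) diagnostic CT to a dense deformation
# vector field; the sCT is the dCT warped by that field, so every sCT voxel
# is a trilinear combination of dCT voxels (no intensity hallucination).
# The network, backpropagation and Adam optimizer are implemented here on
# top of the compiled conv/pool/warp kernels.

#' Specification of the deformation-field network
#'
#' A residual U-Net style encoder-decoder: per resolution level one 3x3x3
#' convolution + leaky ReLU, 2x average pooling between levels, nearest
#' upsampling with additive skip connections on the way up, and a
#' zero-initialized 3-channel output convolution so training starts from the
#' identity warp. Channels double per level.
#'
#' @param levels number of resolution levels (extraction depth).
#' @param start_channels channels at the finest level (the clinical-scale
#'   description uses 32; toy fits use fewer).
#' @param in_channels input channels (1, the dCT).
#' @param similarity_loss `"mse"` (on intensities in kHU) or `"lncc"`
#'   (negative local NCC over a box window).
#' @param reg_weight nonnegative weight of the diffusion (gradient-L2)
#'   regularizer on the displacement field.
#' @param lncc_window_vox box window width for the LNCC loss.
#' @param epochs,lr training epochs and Adam learning rate.
#' @param seed RNG seed for weight initialization (training itself is
#'   deterministic).
#' @return A `model_spec` object.
#' @export
model_spec <- function(levels = 3L, start_channels = 32L, in_channels = 1L,
                       similarity_loss = c("mse", "lncc"), reg_weight = 0.01,
                       lncc_window_vox = 9L, epochs = 50L, lr = 0.01,
                       seed = 1L) {
  similarity_loss <- match.arg(similarity_loss)
  stopifnot(levels >= 1, start_channels >= 1, in_channels == 1L,
            reg_weight >= 0, epochs >= 1, lr > 0, lncc_window_vox >= 3)
  structure(list(spatial_dims = 3L, levels = as.integer(levels),
                 start_channels = as.integer(start_channels),
                 in_channels = as.integer(in_channels),
                 similarity_loss = similarity_loss,
                 reg_weight = reg_weight,
                 lncc_window_vox = as.integer(lncc_window_vox),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "model_spec")
}

model_channels <- function(spec) spec$start_channels * 2^(seq_len(spec$levels) - 1)

check_model_grid <- function(spec, d) {
  f <- 2^(spec$levels - 1)
  if (any(d %% f != 0))
    stop(sprintf("grid %s not divisible by %d (2^(levels-1))",
                 paste(d, collapse = "x"), f), call. = FALSE)
}

init_params <- function(spec) {
  with_seed(spec$seed, {
    L <- spec$levels
    ch <- model_channels(spec)
    p <- list()
    cin <- spec$in_channels
    for (l in seq_len(L)) {
      p[[paste0("enc", l, ".W")]] <-
        array(rnorm(27 * cin * ch[l], 0, sqrt(2 / (27 * cin))), c(3, 3, 3, cin, ch[l]))
      p[[paste0("enc", l, ".b")]] <- numeric(ch[l])
      cin <- ch[l]
    }
    if (L > 1) for (l in seq(L - 1, 1)) {
      p[[paste0("dec", l, ".W")]] <-
        array(rnorm(27 * ch[l + 1] * ch[l], 0, sqrt(2 / (27 * ch[l + 1]))),
              c(3, 3, 3, ch[l + 1], ch[l]))
      p[[paste0("dec", l, ".b")]] <- numeric(ch[l])
    }
    p[["out.W"]] <- array(0, c(3, 3, 3, ch[1], 3))  # identity-warp start
    p[["out.b"]] <- numeric(3)
    p
  })
}

lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_gmask <- function(pre) 0.1 + 0.9 * (pre > 0)
norm_hu <- function(a) (a + 1024) / 1000 - 1

model_forward <- function(params, spec, xn, d) {
  L <- spec$levels
  ch <- model_channels(spec)
  dims <- vector("list", L)
  dims[[1]] <- as.integer(d)
  encin <- pre <- e <- decin <- decpre <- vector("list", L)
  cur <- array(xn, c(d, 1))
  for (l in seq_len(L)) {
    if (l > 1) {
      cur <- cpp_avgpool2(e[[l - 1]], dims[[l - 1]], ch[l - 1])
      dims[[l]] <- dims[[l - 1]] %/% 2L
    }
    encin[[l]] <- cur
    z <- cpp_conv3d(cur, dims[[l]], if (l == 1) spec$in_channels else ch[l - 1],
                    params[[paste0("enc", l, ".W")]],
                    params[[paste0("enc", l, ".b")]], ch[l])
    pre[[l]] <- z
    e[[l]] <- lrelu(z)
  }
  cur <- e[[L]]
  if (L > 1) for (l in seq(L - 1, 1)) {
    up <- cpp_upsample2(cur, dims[[l + 1]], ch[l + 1])
    decin[[l]] <- up
    z <- cpp_conv3d(up, dims[[l]], ch[l + 1],
                    params[[paste0("dec", l, ".W")]],
                    params[[paste0("dec", l, ".b")]], ch[l])
    z <- z + e[[l]]
    decpre[[l]] <- z
    cur <- lrelu(z)
  }
  raw <- cpp_conv3d(cur, as.integer(d), ch[1], params[["out.W"]], params[["out.b"]], 3L)
  list(raw = raw,
       cache = list(encin = encin, pre = pre, e = e, decin = decin,
                    decpre = decpre, outin = cur, dims = dims))
}

model_backward <- function(params, spec, cache, graw, d) {
  L <- spec$levels
  ch <- model_channels(spec)
  g <- list()
  bw <- cpp_conv3d_bwd(cache$outin, as.integer(d), ch[1], params[["out.W"]], 3L, graw)
  g[["out.W"]] <- array(bw$gw, dim(params[["out.W"]]))
  g[["out.b"]] <- as.numeric(bw$gb)
  gcur <- bw$gx
  ge <- vector("list", L)
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      gz <- gcur * lrelu_gmask(cache$decpre[[l]])
      ge[[l]] <- gz  # additive skip into e[[l]]
      bwd <- cpp_conv3d_bwd(cache$decin[[l]], cache$dims[[l]], ch[l + 1],
                            params[[paste0("dec", l, ".W")]], ch[l], gz)
      g[[paste0("dec", l, ".W")]] <- array(bwd$gw, dim(params[[paste0("dec", l, ".W")]]))
      g[[paste0("dec", l, ".b")]] <- as.numeric(bwd$gb)
      gcur <- cpp_upsample2_bwd(bwd$gx, cache$dims[[l]], ch[l + 1])
    }
  }
  ge[[L]] <- gcur
  for (l in seq(L, 1)) {
    gz <- ge[[l]] * lrelu_gmask(cache$pre[[l]])
    cin <- if (l == 1) spec$in_channels else ch[l - 1]
    bwd <- cpp_conv3d_bwd(cache$encin[[l]], cache$dims[[l]], cin,
                          params[[paste0("enc", l, ".W")]], ch[l], gz)
    g[[paste0("enc", l, ".W")]] <- array(bwd$gw, dim(params[[paste0("enc", l, ".W")]]))
    g[[paste0("enc", l, ".b")]] <- as.numeric(bwd$gb)
    if (l > 1) ge[[l - 1]] <- ge[[l - 1]] + cpp_avgpool2_bwd(bwd$gx, cache$dims[[l - 1]], ch[l - 1])
  }
  g
}

# diffusion regularizer: mean squared forward difference of each displacement
# component along each axis (mm per voxel step)
reg_value_grad <- function(u) {
  d <- dim(u)[1:3]
  s <- 0; cnt <- 0
  grad <- array(0, dim(u))
  for (c3 in 1:3) {
    uc <- u[, , , c3]
    gc <- array(0, d)
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 2) next
      i1 <- slice.index(uc, ax)
      dif <- switch(ax,
                    uc[-1, , , drop = FALSE] - uc[-n, , , drop = FALSE],
                    uc[, -1, , drop = FALSE] - uc[, -n, , drop = FALSE],
                    uc[, , -1, drop = FALSE] - uc[, , -n, drop = FALSE])
      s <- s + sum(dif^2)
      cnt <- cnt + length(dif)
      switch(ax, {
        gc[-1, , ] <- gc[-1, , ] + 2 * dif
        gc[-n, , ] <- gc[-n, , ] - 2 * dif
      }, {
        gc[, -1, ] <- gc[, -1, ] + 2 * dif
        gc[, -n, ] <- gc[, -n, ] - 2 * dif
      }, {
        gc[, , -1] <- gc[, , -1] + 2 * dif
        gc[, , -n] <- gc[, , -n] - 2 * dif
      })
    }
    grad[, , , c3] <- gc
  }
  list(value = s / cnt, grad = grad / cnt)
}

# box filter along the three axes (window w voxels, zero padding) via cumsum
box_filter3 <- function(a, w) {
  r <- (w - 1) %/% 2
  for (ax in 1:3) {
    a <- apply(a, setdiff(1:3, ax), function(v) {
      cs <- c(0, cumsum(v))
      n <- length(v)
      hi <- pmin(seq_len(n) + r, n)
      lo <- pmax(seq_len(n) - r, 1)
      cs[hi + 1] - cs[lo]
    })
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  a
}

lncc_value_grad <- function(f, g, w, eps = 1e-5) {
  one <- array(1, dim(f))
  n <- box_filter3(one, w)
  Sf <- box_filter3(f, w); Sg <- box_filter3(g, w)
  Sff <- box_filter3(f * f, w); Sgg <- box_filter3(g * g, w)
  Sfg <- box_filter3(f * g, w)
  muf <- Sf / n; mug <- Sg / n
  cross <- Sfg - Sf * mug
  vf <- pmax(Sff - Sf * muf, 0)
  vg <- pmax(Sgg - Sg * mug, 0)
  den <- vf * vg + eps
  cc <- cross^2 / den
  N <- length(f)
  A <- 2 * cross / den
  B <- 2 * cross^2 * vf / den^2   # d(cc)/dvf chain: -cross^2 * vg / den^2 * dvf ... see below
  # d(cc)/df_i summed over windows:
  #   cc = cross^2 / (vf*vg + eps)
  #   dcross/df_i = g_i - mug ; dvf/df_i = 2 (f_i - muf)
  #   dcc/df_i = A (g_i - mug) - (cross^2 * vg / den^2) * 2 (f_i - muf)
  Bv <- 2 * cross^2 * vg / den^2
  gf <- g * box_filter3(A, w) - box_filter3(A * mug, w) -
        f * box_filter3(Bv, w) + box_filter3(Bv * muf, w)
  list(value = -mean(cc), grad = -gf / N)
}

#' Similarity + regularization loss of the deformation model
#'
#' `total = similarity(warped, target) + lambda * reg(dvf)` where the
#' similarity is MSE on intensities in kHU (or negative local NCC) and the
#' regularizer is the mean squared spatial forward-difference of the
#' displacement components (diffusion penalty; zero for any constant field).
#'
#' @param warped,target `image_volume`s on one grid.
#' @param dvf the `deformation_field` being penalized.
#' @param spec a [model_spec()] fixing the loss flavour and weight.
#' @return list with `total`, `similarity`, `regularizer`.
#' @export
sct_loss <- function(warped, target, dvf, spec = model_spec()) {
  if (!same_grid(warped, target) || !same_grid(warped, dvf))
    stop_grid_mismatch("warped, target and DVF")
  sim <- if (spec$similarity_loss == "mse") {
    mean(((warped$voxels - target$voxels) / 1000)^2)
  } else {
    lncc_value_grad(norm_hu(v_arr(warped)), norm_hu(v_arr(target)),
                    spec$lncc_window_vox)$value
  }
  reg <- reg_value_grad(dvf$displacement)$value
  list(total = sim + spec$reg_weight * reg, similarity = sim, regularizer = reg)
}

new_sct_model <- function(params, spec, trace = numeric(0), manifest = NULL) {
  structure(list(params = params, spec = spec, trace = trace,
                 manifest = manifest), class = "sct_model")
}

#' Build an untrained deformation model
#'
#' Weights are drawn from the spec's seed; the output convolution is
#' zero-initialized so the untrained model predicts the zero field (identity
#' warp, sCT = dCT).
#'
#' @param spec a [model_spec()].
#' @return An `sct_model`.
#' @export
build_model <- function(spec = model_spec()) new_sct_model(init_params(spec), spec)

#' @export
print.sct_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<sct_model> levels %d, start channels %d, %d parameters, %s loss%s\n",
              x$spec$levels, x$spec$start_channels, np, x$spec$similarity_loss,
              if (length(x$trace)) sprintf(", trained %d epochs", length(x$trace) - 1L) else " (untrained)"))
  invisible(x)
}

as_training_pair <- function(p) {
  dct <- if (!is.null(p$dct_ready)) p$dct_ready else if (!is.null(p$dct)) p$dct else p[[1]]
  pct <- if (!is.null(p$pct_ready)) p$pct_ready else if (!is.null(p$pct)) p$pct else p[[2]]
  stopifnot(inherits(dct, "image_volume"), inherits(pct, "image_volume"))
  if (!same_grid(dct, pct)) stop_grid_mismatch("training pair")
  list(dct = dct, pct = pct)
}

pair_loss_grad <- function(spec, dct_arr, pct_arr, raw, d, spacing, want_grad = TRUE) {
  # border-clamped sampling: keeps the loss smooth where anatomy touches the
  # grid faces (a constant-fill boundary would add a non-differentiable
  # penalty the optimizer cannot see)
  sct <- cpp_warp(dct_arr, as.integer(d), raw[, , , 1], raw[, , , 2], raw[, , , 3],
                  spacing, HU_AIR, TRUE)
  if (spec$similarity_loss == "mse") {
    resid <- sct - pct_arr
    sim <- mean((resid / 1000)^2)
    gs <- if (want_grad) 2 * resid / (length(resid) * 1e6) else NULL
  } else {
    lv <- lncc_value_grad(norm_hu(sct), norm_hu(pct_arr), spec$lncc_window_vox)
    sim <- lv$value
    gs <- if (want_grad) lv$grad / 1000 else NULL   # d(norm_hu)/dHU = 1/1000
  }
  rg <- reg_value_grad(raw)
  out <- list(sim = sim, reg = rg$value, total = sim + spec$reg_weight * rg$value,
              sct = sct)
  if (want_grad) {
    wg <- cpp_warp_grad(dct_arr, as.integer(d), raw[, , , 1], raw[, , , 2],
                        raw[, , , 3], spacing, gs, TRUE)
    graw <- array(0, c(d, 3))
    graw[, , , 1] <- wg$x; graw[, , , 2] <- wg$y; graw[, , , 3] <- wg$z
    out$graw <- graw + spec$reg_weight * rg$grad
  }
  out
}

#' Train the deformation model on image pairs
#'
#' Deterministic full-precision training: per epoch each pair is visited in
#' order and one Adam step taken from the similarity + regularization loss.
#' The epoch-mean loss trace is recorded; the returned parameters are those
#' of the best epoch, so the final loss never exceeds the initial
#' (identity-warp) loss.
#'
#' @param pairs list of training pairs; each element is a list with `dct` and
#'   `pct` (or `dct_ready`/`pct_ready`) `image_volume`s on one common grid.
#' @param spec a [model_spec()].
#' @return A trained `sct_model` with `trace` (epoch 0 = identity warp) and a
#'   training-pair `manifest`.
#' @export
train_sct_model <- function(pairs, spec = model_spec()) {
  if (length(pairs) == 0L) stop("need at least one training pair", call. = FALSE)
  pairs <- lapply(pairs, as_training_pair)
  d <- grid_shape(pairs[[1]]$dct)
  for (p in pairs) if (!all(grid_shape(p$dct) == d))
    stop_grid_mismatch("all training pairs")
  check_model_grid(spec, d)
  spacing <- pairs[[1]]$dct$spacing
  dcts <- lapply(pairs, function(p) v_arr(p$dct))
  pcts <- lapply(pairs, function(p) v_arr(p$pct))
  xns <- lapply(dcts, norm_hu)

  params <- init_params(spec)
  mstate <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  vstate <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0

  # epoch 0: identity-warp loss
  init_loss <- mean(vapply(seq_along(pairs), function(i) {
    pair_loss_grad(spec, dcts[[i]], pcts[[i]],
                   array(0, c(d, 3)), d, spacing, want_grad = FALSE)$total
  }, numeric(1)))
  trace <- init_loss
  best <- list(loss = init_loss, params = params)

  for (ep in seq_len(spec$epochs)) {
    ep_losses <- numeric(length(pairs))
    for (i in seq_along(pairs)) {
      fw <- model_forward(params, spec, xns[[i]], d)
      lg <- pair_loss_grad(spec, dcts[[i]], pcts[[i]], fw$raw, d, spacing)
      ep_losses[i] <- lg$total
      grads <- model_backward(params, spec, fw$cache, lg$graw, d)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in names(params)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * grads[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * grads[[nm]]^2
        params[[nm]] <- params[[nm]] - spec$lr * corr * mstate[[nm]] /
          (sqrt(vstate[[nm]]) + eps)
      }
    }
    ep_loss <- mean(ep_losses)
    trace <- c(trace, ep_loss)
    if (ep_loss <= best$loss) best <- list(loss = ep_loss, params = params)
  }
  new_sct_model(best$params, spec, trace = trace,
                manifest = list(n_pairs = length(pairs), grid = d,
                                spacing = spacing))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a synthetic CT from a diagnostic CT
#'
#' Runs the network on the prepared dCT to obtain a deformation field and
#' returns the warped image: `sct = warp(dct_ready, dvf)` with the model's
#' border-clamped sampling, so every sCT voxel is a trilinear combination of
#' dCT voxels (no intensity hallucination). Deterministic in evaluation
#' mode.
#'
#' @param model a (possibly untrained) `sct_model`.
#' @param dct_ready the prepared diagnostic CT (`image_volume`).
#' @return list with `sct` (`image_volume`) and `dvf` (`deformation_field`).
#' @export
predict_sct <- function(model, dct_ready) {
  stopifnot(inherits(model, "sct_model"), inherits(dct_ready, "image_volume"))
  d <- grid_shape(dct_ready)
  check_model_grid(model$spec, d)
  fw <- model_forward(model$params, model$spec, norm_hu(v_arr(dct_ready)), d)
  dvf <- deformation_field(array(fw$raw, c(d, 3)), dct_ready$spacing, dct_ready$origin)
  raw <- fw$raw
  sct <- cpp_warp(v_arr(dct_ready), as.integer(d), raw[, , , 1], raw[, , , 2],
                  raw[, , , 3], dct_ready$spacing, HU_AIR, TRUE)
  list(sct = image_volume(sct, dct_ready$spacing, dct_ready$origin), dvf = dvf)
}

#' Serialize / restore a trained model
#'
#' Round trips reproduce predictions bit-exactly.
#'
#' @param model an `sct_model`; `path` a file path.
#' @param path file path (RDS).
#' @return `load_model` returns the `sct_model`; `save_model` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sct_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sct_model")) stop("file does not contain an sct_model", call. = FALSE)
  m
}
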