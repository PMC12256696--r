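# Image similarity metrics between co-registered CT volumes: mean absolute
# error, normalized cross-correlation, global SSIM, and gradient magnitude
# similarity deviation (2D Prewitt, per axial slice).

metric_values <- function(x, y, mask = NULL) {
  if (!same_grid(x, y)) stop_grid_mismatch("the two volumes")
  if (!is.null(mask)) {
    if (!same_grid(mask, x)) stop_grid_mismatch("volumes and mask")
    sel <- mask$voxels == 1L
    if (!any(sel)) stop("evaluation mask is empty", call. = FALSE)
  } else sel <- NULL
  list(xv = as.numeric(x$voxels), yv = as.numeric(y$voxels), sel = sel)
}

pick <- function(v, sel) if (is.null(sel)) v else v[sel]

#' Mean absolute error between two volumes (HU)
#'
#' `mean(|X(i) - Y(i)|)` over the evaluation mask (or all voxels).
#'
#' @param x,y `image_volume`s on one grid.
#' @param mask optional `binary_mask` restricting the evaluation region.
#' @return MAE in HU.
#' @export
mae <- function(x, y, mask = NULL) {
  m <- metric_values(x, y, mask)
  mean(abs(pick(m$xv, m$sel) - pick(m$yv, m$sel)))
}

#' Normalized cross-correlation between two volumes
#'
#' `(1/N) * sum((X - mu_x)(Y - mu_y)) / (s_x s_y)` with population standard
#' deviations, so the result lies in `[-1, 1]` and identical non-constant
#' images score exactly 1.
#'
#' @inheritParams mae
#' @return NCC in `[-1, 1]`.
#' @export
ncc <- function(x, y, mask = NULL) {
  m <- metric_values(x, y, mask)
  xv <- pick(m$xv, m$sel); yv <- pick(m$yv, m$sel)
  n <- length(xv)
  sx <- sqrt(mean((xv - mean(xv))^2))
  sy <- sqrt(mean((yv - mean(yv))^2))
  if (sx == 0 || sy == 0)
    stop("NCC undefined: zero variance over the evaluation region", call. = FALSE)
  mean((xv - mean(xv)) * (yv - mean(yv))) / (sx * sy)
}

#' Global structural similarity index (SSIM)
#'
#' The single-window closed form
#' `(2 mu_x mu_y + c1)(2 s_xy + c2) / ((mu_x^2 + mu_y^2 + c1)(s_x^2 + s_y^2 + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and dynamic range `L` (default
#' 4095, the HU scale shifted by +1024). Ranges over `[-1, 1]`, 1 meaning
#' identical images.
#'
#' @inheritParams mae
#' @param dynamic_range positive dynamic range L.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, mask = NULL, dynamic_range = 4095) {
  if (!is.finite(dynamic_range) || dynamic_range <= 0)
    stop("dynamic_range must be > 0", call. = FALSE)
  m <- metric_values(x, y, mask)
  xv <- pick(m$xv, m$sel); yv <- pick(m$yv, m$sel)
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mx <- mean(xv); my <- mean(yv)
  vx <- mean((xv - mx)^2); vy <- mean((yv - my)^2)
  cxy <- mean((xv - mx) * (yv - my))
  (2 * mx * my + c1) * (2 * cxy + c2) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# 3x3 'same' convolution with replicated (edge) padding, applied to a
# matrix; edge replication keeps gradient magnitudes invariant to a global
# intensity offset
conv3x3_same <- function(M, K) {
  nx <- nrow(M); ny <- ncol(M)
  P <- matrix(0, nx + 2, ny + 2)
  P[2:(nx + 1), 2:(ny + 1)] <- M
  P[1, ] <- P[2, ]; P[nx + 2, ] <- P[nx + 1, ]
  P[, 1] <- P[, 2]; P[, ny + 2] <- P[, ny + 1]
  out <- matrix(0, nx, ny)
  for (a in 1:3) for (b in 1:3) {
    if (K[a, b] == 0) next
    out <- out + K[a, b] * P[a:(a + nx - 1), b:(b + ny - 1)]
  }
  out
}

prewitt_mag_slices <- function(arr) {
  kx <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3) / 3
  ky <- t(kx)
  d <- dim(arr)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    gx <- conv3x3_same(arr[, , k], kx)
    gy <- conv3x3_same(arr[, , k], ky)
    out[, , k] <- sqrt(gx^2 + gy^2)
  }
  out
}

#' Gradient magnitude similarity deviation (GMSD)
#'
#' Per axial slice, 2D Prewitt gradient magnitudes `m1`, `m2` are computed on
#' the two images after linear rescaling of the HU window `[-1024, 3071]` to
#' `[0, 255]`. The gradient magnitude similarity map is
#' `GMS(i) = (2 m1 m2 + C) / (m1^2 + m2^2 + C)` with `C = 170`, and GMSD is
#' the population standard deviation of GMS over the evaluated voxels. Larger
#' values mean wider structural distortion; identical images give 0.
#'
#' @inheritParams mae
#' @param C stabilizing constant on the `[0, 255]` intensity scale.
#' @return GMSD (>= 0).
#' @export
gmsd <- function(x, y, mask = NULL, C = 170) {
  m <- metric_values(x, y, mask)
  rescale <- function(v) (pmin(pmax(v, HU_AIR), HU_MAX) + 1024) / 4095 * 255
  m1 <- prewitt_mag_slices(array(rescale(m$xv), grid_shape(x)))
  m2 <- prewitt_mag_slices(array(rescale(m$yv), grid_shape(y)))
  gms <- (2 * m1 * m2 + C) / (m1^2 + m2^2 + C)
  g <- pick(as.numeric(gms), m$sel)
  sqrt(mean((g - mean(g))^2))
}

#' Full similarity report between two volumes
#'
#' Aggregates MAE, NCC, SSIM and GMSD with one shared evaluation mask.
#'
#' @inheritParams ssim
#' @return A `similarity_report` list with fields `mae_HU`, `ncc`, `ssim`,
#'   `gmsd`, `n_voxels`, `mask_used`.
#' @export
similarity_report <- function(x, y, mask = NULL, dynamic_range = 4095) {
  m <- metric_values(x, y, mask)
  structure(list(mae_HU = mae(x, y, mask),
                 ncc = ncc(x, y, mask),
                 ssim = ssim(x, y, mask, dynamic_range),
                 gmsd = gmsd(x, y, mask),
                 n_voxels = length(pick(m$xv, m$sel)),
                 mask_used = !is.null(mask)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> over %d voxels%s\n", x$n_voxels,
              if (x$mask_used) " (masked)" else ""))
  cat(sprintf("  MAE  %8.3f HU\n  NCC  %8.5f\n  SSIM %8.5f\n  GMSD %8.5f\n",
              x$mae_HU, x$ncc, x$ssim, x$gmsd))
  invisible(x)
}
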