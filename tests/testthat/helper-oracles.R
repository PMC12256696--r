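# Brute-force oracles and small fixture builders shared across the test
# files. Every oracle is written as plain nested-loop R so it is independent
# of the package's compiled kernels.

# trilinear interpolation at one continuous 0-based index
trilinear_oracle <- function(arr, x, y, z, fill = -1024) {
  d <- dim(arr)
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1)
    return(fill)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- min(x0 + dx, d[1] - 1); yi <- min(y0 + dy, d[2] - 1)
    zi <- min(z0 + dz, d[3] - 1)
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy) *
         (if (dz == 0) 1 - fz else fz)
    val <- val + w * arr[xi + 1, yi + 1, zi + 1]
  }
  val
}

# warp oracle: out(i) = moving(i + u(i)/spacing), nested loops
warp_oracle <- function(arr, u, spacing, fill = -1024) {
  d <- dim(arr)
  out <- array(fill, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    out[i, j, k] <- trilinear_oracle(
      arr,
      (i - 1) + u[i, j, k, 1] / spacing[1],
      (j - 1) + u[i, j, k, 2] / spacing[2],
      (k - 1) + u[i, j, k, 3] / spacing[3], fill)
  }
  out
}

# 2D 8-connected components by breadth-first search
label2d_oracle <- function(m) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || jj < 1 || ii > d[1] || jj > d[2]) next
        if (m[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Prewitt gradient magnitude per slice with replicated borders (the
# documented GMSD convention), explicit loops
prewitt_oracle_slice <- function(M) {
  d <- dim(M)
  pad <- matrix(0, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- M
  pad[1, ] <- pad[2, ]; pad[d[1] + 2, ] <- pad[d[1] + 1, ]
  pad[, 1] <- pad[, 2]; pad[, d[2] + 2] <- pad[, d[2] + 1]
  kx <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3) / 3
  ky <- t(kx)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    gx <- 0; gy <- 0
    for (a in 1:3) for (b in 1:3) {
      gx <- gx + kx[a, b] * pad[i + a - 1, j + b - 1]
      gy <- gy + ky[a, b] * pad[i + a - 1, j + b - 1]
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

gmsd_oracle <- function(xv, yv, C = 170) {
  r <- function(v) (pmin(pmax(v, -1024), 3071) + 1024) / 4095 * 255
  d <- dim(xv)
  gms <- array(0, d)
  for (k in seq_len(d[3])) {
    m1 <- prewitt_oracle_slice(r(xv[, , k]))
    m2 <- prewitt_oracle_slice(r(yv[, , k]))
    gms[, , k] <- (2 * m1 * m2 + C) / (m1^2 + m2^2 + C)
  }
  g <- as.numeric(gms)
  sqrt(mean((g - mean(g))^2))
}

# exact two-sided Wilcoxon signed-rank p by enumeration over sign
# assignments (zeros dropped, midranks)
wilcoxon_enum_oracle <- function(x, y) {
  dd <- (x - y)[x != y]
  n <- length(dd)
  if (n == 0) return(NA_real_)
  r <- rank(abs(dd))
  w_obs <- sum(r[dd > 0])
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    ws[mask + 1] <- sum(r[signs])
  }
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# sort-based DVH oracle: dose to the hottest v_cc of the structure
dvh_oracle_dose_at <- function(vals, vvox_cc, v_cc) {
  s <- sort(vals, decreasing = TRUE)
  if (v_cc <= vvox_cc) return(s[1])
  stats::approx(seq_along(s) * vvox_cc, s, xout = v_cc, rule = 2)$y
}

# ellipsoid binary mask on a zero-origin grid
ellipsoid_fixture <- function(dim, spacing, semiaxes, center = NULL) {
  ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  binary_mask(array(as.integer(
    ((g$x - center[1]) / semiaxes[1])^2 + ((g$y - center[2]) / semiaxes[2])^2 +
    ((g$z - center[3]) / semiaxes[3])^2 <= 1), dim), spacing)
}

# smooth blob image for interpolation round-trip checks
smooth_fixture <- function(dim = c(24, 24, 12), spacing = c(2, 2, 2)) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  v <- 40 * exp(-((g$x - dim[1] / 2)^2 + (g$y - dim[2] / 2)^2 +
                  (g$z - dim[3] / 2)^2) / 40)
  image_volume(array(v, dim), spacing)
}

# random small volumes for metric oracle comparisons
random_volume <- function(dim, sd = 300, spacing = c(1, 1, 1)) {
  image_volume(array(rnorm(prod(dim), 0, sd), dim), spacing)
}

expect_no_violations <- function(audit) {
  expect_length(audit$violations, 0)
}
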