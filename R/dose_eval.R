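# Dosimetric evaluation: cumulative DVH curves and metrics (Dx%, DV-cc,
# Dmax/Dmin/Dmean, mean volume sparing), 50%-isodose connected-component
# sphere fitting, dose profiles, and paired plan comparison with the exact
# Wilcoxon signed-rank test.

check_dose_mask <- function(dose, mask, structure_name = "structure") {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "binary_mask"))
  if (!same_grid(dose, mask)) stop_grid_mismatch("dose and mask")
  if (sum(mask$voxels) == 0L)
    stop(sprintf("empty mask for %s", structure_name), call. = FALSE)
  invisible(TRUE)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level;
#' exact voxel-volume weighting, starting at fraction 1 at 0 cGy.
#'
#' @param dose a `dose_grid`.
#' @param mask the structure `binary_mask` on the same grid.
#' @param bin_width_cGy dose bin width of the curve grid.
#' @param structure_name used in error messages.
#' @return A `dvh_curve` list: `dose_cGy` (ascending bin edges),
#'   `volume_fraction` (non-increasing, 1 to 0), `volume_cc`.
#' @export
dvh_curve <- function(dose, mask, bin_width_cGy = 1, structure_name = "structure") {
  check_dose_mask(dose, mask, structure_name)
  dv <- dose$voxels[mask$voxels == 1L]
  vol <- length(dv) * voxel_volume_cc(dose)
  top <- max(dv) + bin_width_cGy
  grid <- seq(0, top, by = bin_width_cGy)
  frac <- vapply(grid, function(g) mean(dv >= g), numeric(1))
  structure(list(dose_cGy = grid, volume_fraction = frac, volume_cc = vol),
            class = "dvh_curve")
}

# dose at cumulative (hottest-first) absolute volume v_cc, linear
# interpolation between sorted voxels
dose_at_volume <- function(sorted_desc, vvox_cc, v_cc) {
  n <- length(sorted_desc)
  if (v_cc <= vvox_cc) return(sorted_desc[1])
  approx(x = seq_len(n) * vvox_cc, y = sorted_desc, xout = v_cc, rule = 2)$y
}

#' DVH metrics for one structure
#'
#' `Dx%` is the minimum dose received by the hottest x% of the structure
#' volume (linear interpolation between sorted voxel doses); `DV-cc` is the
#' analogue at an absolute volume; `MVS(d)` (mean volume sparing level) is
#' the absolute volume in cc receiving strictly less than `d`. Heterogeneity
#' is `D10% / D90%`.
#'
#' @inheritParams dvh_curve
#' @param prescription_cGy recorded prescription (cGy).
#' @param mvs_level_cGy optional dose level for the MVS metric.
#' @param dv_cc absolute-volume metrics to evaluate (cc); values larger than
#'   the structure are an error.
#' @return A `dvh_metrics` list: `Dmax`, `Dmin`, `Dmean`, `D10`, `D50`,
#'   `D90`, `heterogeneity`, `D0.03cc`, `D1cc` (when requested), `MVS_cc`,
#'   `volume_cc`, `prescription_cGy`.
#' @export
dvh_metrics <- function(dose, mask, prescription_cGy = 2000,
                        mvs_level_cGy = NULL, dv_cc = c(0.03, 1),
                        structure_name = "structure") {
  check_dose_mask(dose, mask, structure_name)
  dv <- dose$voxels[mask$voxels == 1L]
  vvox <- voxel_volume_cc(dose)
  vol <- length(dv) * vvox
  srt <- sort(dv, decreasing = TRUE)
  dx <- function(pct) dose_at_volume(srt, vvox, pct / 100 * vol)
  out <- list(Dmax = srt[1], Dmin = srt[length(srt)], Dmean = mean(dv),
              D10 = dx(10), D50 = dx(50), D90 = dx(90))
  out$heterogeneity <- if (out$D90 > 0) out$D10 / out$D90 else NA_real_
  for (v in dv_cc) {
    if (v > vol + 1e-9)
      stop(sprintf("requested D%gcc exceeds the %s volume (%.2f cc)",
                   v, structure_name, vol), call. = FALSE)
    out[[sprintf("D%gcc", v)]] <- dose_at_volume(srt, vvox, v)
  }
  out$MVS_cc <- if (!is.null(mvs_level_cGy)) sum(dv < mvs_level_cGy) * vvox else NA_real_
  out$mvs_level_cGy <- mvs_level_cGy %||% NA_real_
  out$volume_cc <- vol
  out$prescription_cGy <- prescription_cGy
  structure(out, class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> volume %.2f cc\n", x$volume_cc))
  cat(sprintf("  Dmax %.1f  Dmean %.1f  Dmin %.1f cGy\n", x$Dmax, x$Dmean, x$Dmin))
  cat(sprintf("  D10%% %.1f  D50%% %.1f  D90%% %.1f cGy  (D10/D90 %.3f)\n",
              x$D10, x$D50, x$D90, x$heterogeneity))
  invisible(x)
}

#' Fit sphere contours from an isodose surface
#'
#' Thresholds the dose at `level_fraction * prescription`, finds 26-connected
#' 3D components, drops components below a minimum volume, and returns a
#' sphere of fixed diameter (default 1.5 cm) at each component's geometric
#' centroid (mean voxel-centre position).
#'
#' @param dose a `dose_grid`.
#' @param prescription_cGy prescription the isodose level refers to.
#' @param level_fraction isodose level as a fraction of prescription.
#' @param fitted_diameter_mm diameter of every fitted contour.
#' @param min_volume_cc speckle rejection threshold.
#' @return A `sphere_set` of fitted contours (empty if nothing exceeds the
#'   threshold).
#' @export
fit_spheres_from_isodose <- function(dose, prescription_cGy = 2000,
                                     level_fraction = 0.5,
                                     fitted_diameter_mm = 15,
                                     min_volume_cc = 0.1) {
  stopifnot(inherits(dose, "dose_grid"), level_fraction > 0)
  d <- grid_shape(dose)
  supra <- array(as.integer(dose$voxels >= level_fraction * prescription_cGy), d)
  if (!any(supra == 1L))
    return(sphere_set(matrix(numeric(0), ncol = 3), fitted_diameter_mm))
  lab <- cpp_label3d(supra, d, 26L)
  vvox <- voxel_volume_cc(dose)
  keep <- which(tabulate(lab[lab > 0]) * vvox >= min_volume_cc)
  if (!length(keep))
    return(sphere_set(matrix(numeric(0), ncol = 3), fitted_diameter_mm))
  centers <- t(vapply(keep, function(lb) {
    idx <- which(lab == lb, arr.ind = TRUE)
    colMeans(voxel_centers_mm(dose, idx))
  }, numeric(3)))
  centers <- centers[order(centers[, 3], centers[, 2], centers[, 1]), , drop = FALSE]
  sphere_set(centers, fitted_diameter_mm)
}

#' Dose profile along a line segment
#'
#' Evenly spaced trilinear samples between two mm positions.
#'
#' @param dose a `dose_grid`.
#' @param start_mm,end_mm segment endpoints (mm, inside the grid).
#' @param n_samples number of samples.
#' @return Numeric vector of doses (cGy).
#' @export
dose_profile <- function(dose, start_mm, end_mm, n_samples = 100) {
  stopifnot(inherits(dose, "dose_grid"), n_samples >= 2)
  tseq <- seq(0, 1, length.out = n_samples)
  pts <- outer(tseq, as.numeric(end_mm) - as.numeric(start_mm)) +
    matrix(as.numeric(start_mm), n_samples, 3, byrow = TRUE)
  idx <- mm_to_index(dose, pts)
  d <- grid_shape(dose)
  if (any(idx < -1e-9) || any(sweep(idx, 2, d - 1, "-") > 1e-9))
    stop("profile endpoints must lie inside the dose grid", call. = FALSE)
  cpp_sample_points(v_arr(dose), d, idx, 0)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired test with the classic convention: zero differences are
#' dropped, |differences| are midranked, and for n <= `exact_max` the p-value
#' comes from the exact null distribution of the positive-rank sum over all
#' 2^n sign assignments (computed by dynamic programming, valid under ties).
#' Beyond that, a normal approximation with tie correction and continuity
#' correction is used. `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired samples.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (V, positive-rank sum), `p_value`, `n_used`
#'   (pairs after dropping zeros), `exact`, `degenerate` (all differences
#'   zero).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  dd <- x - y
  dd <- dd[dd != 0]
  n <- length(dd)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                exact = NA, degenerate = TRUE))
  r <- rank(abs(dd))
  W <- sum(r[dd > 0])
  if (n <= exact_max) {
    # exact distribution of 2*W over the 2^n sign assignments (doubled
    # midranks are integers)
    R2 <- as.integer(round(2 * r))
    tot <- sum(R2)
    f <- numeric(tot + 1)   # f[w+1] = number of assignments with sum w
    f[1] <- 1
    for (ri in R2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = W, p_value = p, n_used = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = W, p_value = p, n_used = n, exact = FALSE, degenerate = FALSE)
  }
}

metric_fields <- c("Dmax", "Dmin", "Dmean", "D10", "D50", "D90",
                   "heterogeneity", "D0.03cc", "D1cc", "MVS_cc")

#' Compare two plans' DVH metrics across cases
#'
#' Per structure and metric, paired deviations `a - b` across cases and the
#' two-sided Wilcoxon signed-rank test (exact null distribution for small n,
#' zero differences dropped). Structures are matched by name; at least 5
#' paired cases are required for the test (deviations are still reported
#' below that).
#'
#' @param metrics_a,metrics_b lists (one element per case) of named lists of
#'   [dvh_metrics()] keyed by structure name.
#' @param alpha significance level (default 0.05).
#' @return A `plan_comparison`: data.frame with structure, metric, mean and
#'   median deviation, Wilcoxon statistic, p-value, significance flag, and a
#'   `deviations` attribute with per-case values.
#' @export
compare_plans <- function(metrics_a, metrics_b, alpha = 0.05) {
  stopifnot(length(metrics_a) == length(metrics_b), length(metrics_a) >= 1)
  n_cases <- length(metrics_a)
  sa <- sort(names(metrics_a[[1]]))
  for (i in seq_len(n_cases)) {
    na <- sort(names(metrics_a[[i]])); nb <- sort(names(metrics_b[[i]]))
    if (!identical(na, nb) || !identical(na, sa))
      stop(sprintf("unmatched structures in case %d: a = {%s}, b = {%s}",
                   i, paste(na, collapse = ", "), paste(nb, collapse = ", ")),
           call. = FALSE)
  }
  rows <- list(); devs <- list()
  for (st in sa) {
    for (mf in metric_fields) {
      va <- vapply(metrics_a, function(m) m[[st]][[mf]] %||% NA_real_, numeric(1))
      vb <- vapply(metrics_b, function(m) m[[st]][[mf]] %||% NA_real_, numeric(1))
      if (all(is.na(va)) || all(is.na(vb))) next
      dv <- va - vb
      wt <- if (n_cases >= 5) wilcoxon_signed_rank(va, vb)
            else list(statistic = NA_real_, p_value = NA_real_,
                      exact = NA, degenerate = all(dv == 0))
      rows[[length(rows) + 1]] <- data.frame(
        structure = st, metric = mf, n = n_cases,
        mean_dev = mean(dv), median_dev = median(dv),
        statistic = wt$statistic, p_value = wt$p_value,
        significant = !is.na(wt$p_value) && wt$p_value < alpha,
        degenerate = isTRUE(wt$degenerate),
        stringsAsFactors = FALSE)
      devs[[paste(st, mf, sep = ".")]] <- dv
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "deviations") <- devs
  attr(out, "alpha") <- alpha
  class(out) <- c("plan_comparison", class(out))
  out
}
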