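# Pre-processing pipeline: couch removal by per-slice largest-region body
# segmentation + 3D morphology, bone-based rigid alignment of the diagnostic
# to the planning CT, and field-of-view preserving resampling.

#' Couch removal parameters
#'
#' @param body_threshold_HU HU threshold segmenting the body (default -200;
#'   must be negative).
#' @param closing_radius_vox ball radius (voxels) of the 3D closing that
#'   fills skin gaps.
#' @param dilation_radius_vox ball radius (voxels) of the final 3D dilation
#'   ensuring mask continuity.
#' @return A `couch_removal_params` object. The background fill is fixed at
#'   -1024 HU.
#' @export
couch_removal_params <- function(body_threshold_HU = -200,
                                 closing_radius_vox = 3,
                                 dilation_radius_vox = 2) {
  if (!is.finite(body_threshold_HU) || body_threshold_HU >= 0)
    stop("body_threshold_HU must be negative", call. = FALSE)
  stopifnot(closing_radius_vox >= 0, dilation_radius_vox >= 0)
  structure(list(body_threshold_HU = body_threshold_HU,
                 closing_radius_vox = closing_radius_vox,
                 dilation_radius_vox = dilation_radius_vox,
                 background_fill_HU = HU_AIR),
            class = "couch_removal_params")
}

# ball-structuring-element morphology via exact distance transforms
# (radii in voxels; the EDT is run with unit spacing)
dilate_ball <- function(mask, r, d) {
  if (r <= 0) return(mask)
  array(as.integer(cpp_edt(mask, d, c(1, 1, 1)) <= r + 1e-9), d)
}
erode_ball <- function(mask, r, d) {
  if (r <= 0) return(mask)
  array(as.integer(cpp_edt(1L - mask, d, c(1, 1, 1)) > r + 1e-9), d)
}
close_ball <- function(mask, r, d) erode_ball(dilate_ball(mask, r, d), r, d)

#' Remove the CT couch and fill the background
#'
#' Per axial slice, voxels above the body threshold are segmented and only
#' the largest 8-connected 2D region kept (dropping the couch and other
#' supports); a 3D morphological closing fills skin gaps and a 3D dilation
#' ensures continuity. The returned image equals the input inside the final
#' mask and is exactly -1024 HU outside it.
#'
#' @param v an `image_volume`.
#' @param params a [couch_removal_params()].
#' @return list with `image` (couch-removed `image_volume`) and `mask` (the
#'   final body `binary_mask`).
#' @export
remove_couch <- function(v, params = couch_removal_params()) {
  stopifnot(inherits(v, "image_volume"))
  d <- grid_shape(v)
  a <- v_arr(v)
  thr <- a > params$body_threshold_HU
  if (!any(thr))
    stop("empty body: no voxel above the threshold in any slice", call. = FALSE)
  sel <- array(0L, d)
  for (k in seq_len(d[3])) {
    sl <- thr[, , k]
    if (!any(sl)) next
    lab <- cpp_label2d(matrix(as.integer(sl), d[1], d[2]))
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)   # ties: first label in scan order
    body2d <- matrix(as.integer(lab == keep), d[1], d[2])
    # fill enclosed holes (lung fields, gas pockets) so interior anatomy is
    # preserved; background components touching the slice border stay out
    holes <- cpp_label2d(1L - body2d)
    border <- unique(c(holes[1, ], holes[d[1], ], holes[, 1], holes[, d[2]]))
    body2d[holes > 0 & !(holes %in% border)] <- 1L
    sel[, , k] <- body2d
  }
  m <- close_ball(sel, params$closing_radius_vox, d)
  m <- dilate_ball(m, params$dilation_radius_vox, d)
  out <- ifelse(m == 1L, a, HU_AIR)
  list(image = image_volume(array(out, d), v$spacing, v$origin),
       mask = binary_mask(m, v$spacing, v$origin))
}

#' Rigid registration on bony anatomy
#'
#' Recovers the 6-parameter rigid transform (rotation about the grid centre,
#' translation in mm) that maximizes the normalized cross-correlation between
#' bone-emphasized images: both volumes are thresholded at
#' `bone_threshold_HU`, binarized and Gaussian-blurred, and the metric is
#' optimized from the identity by coordinate descent (Brent line searches,
#' converged when the parameter step falls below 0.01 mm / 0.01 degrees)
#' over a coarse-to-fine blur schedule.
#'
#' @param moving,fixed `image_volume`s with comparable bony anatomy.
#' @param bone_threshold_HU HU threshold isolating bone (default 200).
#' @param blur_schedule_vox Gaussian sigmas (voxels) from coarse to fine.
#' @return A `rigid_transform` `t` such that `apply_rigid(moving, t)` aligns
#'   with `fixed`.
#' @export
rigid_register <- function(moving, fixed, bone_threshold_HU = 200,
                           blur_schedule_vox = c(6, 2.5)) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  d <- grid_shape(moving)
  if (!all(grid_shape(fixed) == d))
    stop_grid_mismatch("moving and fixed images")
  bm <- array(as.double(moving$voxels > bone_threshold_HU), d)
  bf <- array(as.double(fixed$voxels > bone_threshold_HU), d)
  if (sum(bm) < 100 || sum(bf) < 100)
    stop("registration unavailable: fewer than 100 bone voxels", call. = FALSE)
  par <- rep(0, 6)   # (tx, ty, tz, rx, ry, rz)
  for (stage in seq_along(blur_schedule_vox)) {
    sig <- blur_schedule_vox[stage]
    if (stage < length(blur_schedule_vox)) {
      # coarse stages run at half resolution
      ds <- pmax(d %/% 2L, 2L)
      bms <- v_arr(resample_to_shape(image_volume(bm, moving$spacing, moving$origin), ds))
      bfs <- v_arr(resample_to_shape(image_volume(bf, fixed$spacing, fixed$origin), ds))
      dd <- ds; sp <- moving$spacing * d / ds; sigs <- sig / 2
    } else {
      bms <- bm; bfs <- bf; dd <- d; sp <- moving$spacing; sigs <- sig
    }
    smf <- cpp_gauss_blur(bfs, dd, rep(sigs, 3))
    smm <- cpp_gauss_blur(bms, dd, rep(sigs, 3))
    smf_c <- smf - mean(smf)
    denom_f <- sqrt(sum(smf_c^2))
    neg_ncc <- function(p) {
      w <- cpp_rigid_resample(smm, dd, sp, p[4:6], p[1:3], 0, FALSE)
      wc <- w - mean(w)
      den <- sqrt(sum(wc^2)) * denom_f
      if (den == 0) return(0)
      -sum(wc * smf_c) / den
    }
    # deterministic coordinate descent with Brent line searches: robust on
    # the flat directions a near-cylindrical bone map leaves in the metric
    span <- if (stage == 1) c(rep(20, 3), rep(10, 3)) else c(rep(5, 3), rep(3, 3))
    for (sweep in seq_len(8)) {
      old <- par
      for (ax in 1:6) {
        f1 <- function(v) { p <- par; p[ax] <- v; neg_ncc(p) }
        par[ax] <- stats::optimize(f1, c(par[ax] - span[ax], par[ax] + span[ax]),
                                   tol = 0.002)$minimum
      }
      if (max(abs(par - old)) < 0.01) break   # < 0.01 mm / 0.01 deg step
    }
    # ties go to the identity: never return a transform that does not beat it
    if (stage == length(blur_schedule_vox) &&
        neg_ncc(rep(0, 6)) <= neg_ncc(par) + 1e-12)
      par <- rep(0, 6)
  }
  rigid_transform(rotation = par[4:6], translation = par[1:3])
}

#' Pre-process a diagnostic/planning CT pair
#'
#' The full image-preparation chain: couch removal on both scans, bone-based
#' rigid alignment of the dCT to the pCT, and field-of-view preserving
#' resampling of both to a common target shape (default 128 x 128 x 64). If
#' the two inputs live on different grids the aligned dCT is first resampled
#' onto the pCT grid so the outputs share one geometry.
#'
#' @param dct,pct `image_volume`s.
#' @param params a [couch_removal_params()].
#' @param target_shape output grid shape.
#' @param bone_threshold_HU threshold for [rigid_register()].
#' @return list with `dct_ready`, `pct_ready` (`image_volume`s on one grid),
#'   `dct_mask`, `pct_mask` (resampled body masks), `transform` (the rigid
#'   alignment), and `stage_mae` (per-stage dCT-vs-pCT MAE log).
#' @export
preprocess_pair <- function(dct, pct, params = couch_removal_params(),
                            target_shape = c(128, 128, 64),
                            bone_threshold_HU = 200) {
  rc_d <- remove_couch(dct, params)
  rc_p <- remove_couch(pct, params)
  tr <- rigid_register(rc_d$image, rc_p$image, bone_threshold_HU)
  aligned <- apply_rigid(rc_d$image, tr)
  aligned_mask <- apply_rigid(rc_d$mask, tr)
  if (!same_grid(aligned, rc_p$image)) {
    aligned <- resample_to_grid(aligned, rc_p$image)
    aligned_mask <- resample_to_grid(aligned_mask, rc_p$image)
  }
  dct_ready <- resample_to_shape(aligned, target_shape)
  pct_ready <- resample_to_shape(rc_p$image, target_shape)
  stage_mae <- c(
    raw = if (same_grid(dct, pct)) mean(abs(dct$voxels - pct$voxels)) else NA_real_,
    couch_removed = if (same_grid(rc_d$image, rc_p$image))
      mean(abs(rc_d$image$voxels - rc_p$image$voxels)) else NA_real_,
    aligned = mean(abs(aligned$voxels - rc_p$image$voxels)),
    resampled = mean(abs(dct_ready$voxels - pct_ready$voxels)))
  list(dct_ready = dct_ready, pct_ready = pct_ready,
       dct_mask = resample_to_shape(aligned_mask, target_shape),
       pct_mask = resample_to_shape(rc_p$mask, target_shape),
       transform = tr, stage_mae = stage_mae)
}
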