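# Seeded digital phantoms: paired diagnostic/planning CT anatomy with a known
# smooth deformation, couch variants, structure masks, and a synthetic
# lattice-shaped dose painter standing in for the treatment planning system.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic CT phantom pair
#'
#' Describes the anatomy (body ellipsoid, optional lungs/spine/gas pocket),
#' couch variants on the diagnostic vs. planning scan, the tumour (GTV) and
#' organ-at-risk geometry, the smooth inter-scan deformation, and the noise
#' level. A fixed seed makes [make_phantom()] bit-reproducible.
#'
#' HU palette: air -1000, lung -700, soft tissue 40, tumour 60, bone 700,
#' couch `couch_hu` (default 200).
#'
#' @param region `"thorax"` (lungs + spine) or `"abdomen"` (no lungs,
#'   optional gas pocket).
#' @param grid_shape,spacing voxel grid and mm spacing.
#' @param body_semiaxes_mm ellipsoid semi-axes of the body (x, y, z).
#' @param gtv_center_mm,gtv_semiaxes_mm tumour ellipsoid, centre relative to
#'   the body centre; a scalar semi-axis means a sphere.
#' @param bone include bony anatomy (modulated spine + two rib blocks).
#' @param oars named list of OAR primitives; each element is a list with
#'   `type` one of `"sphere"` (`center`, `radius`), `"cylinder"` (axial,
#'   `center` x/y, `radius`), `"slab"` (`axis` 1..3, `range` lo/hi). All
#'   coordinates are mm relative to the body centre.
#' @param couch_dct,couch_pct `"none"`, `"flat"` or `"curved"`.
#' @param couch_hu,couch_thickness_mm,couch_gap_mm couch slab parameters.
#' @param gas_pocket `"none"`, `"dct"`, `"pct"` or `"both"`: which scan shows
#'   a gastric gas pocket.
#' @param gas_center_mm,gas_radius_mm gas pocket sphere (relative to body
#'   centre).
#' @param deform_amplitude_mm,deform_smoothness_mm random smooth component of
#'   the inter-scan deformation (max displacement; Gaussian kernel width).
#' @param sag_mm systematic couch-induced posterior sag amplitude shared by
#'   all phantoms (the anatomy change a flat couch induces relative to a
#'   curved diagnostic couch).
#' @param noise_sd additive Gaussian HU noise (sd).
#' @param seed integer RNG seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(region = c("thorax", "abdomen"),
                         grid_shape = c(96, 96, 48),
                         spacing = c(2.5, 2.5, 2.5),
                         body_semiaxes_mm = c(90, 70, 160),
                         gtv_center_mm = c(30, 5, 0),
                         gtv_semiaxes_mm = 25,
                         oars = list(),
                         bone = TRUE,
                         couch_dct = "curved",
                         couch_pct = "flat",
                         couch_hu = 200,
                         couch_thickness_mm = 12,
                         couch_gap_mm = 10,
                         gas_pocket = "none",
                         gas_center_mm = c(-35, -15, 20),
                         gas_radius_mm = 18,
                         deform_amplitude_mm = 4,
                         deform_smoothness_mm = 25,
                         sag_mm = 3,
                         noise_sd = 10,
                         seed = 1L) {
  region <- match.arg(region)
  if (length(gtv_semiaxes_mm) == 1L) gtv_semiaxes_mm <- rep(gtv_semiaxes_mm, 3)
  stopifnot(all(grid_shape >= 8), all(spacing > 0), noise_sd >= 0,
            deform_amplitude_mm >= 0, sag_mm >= 0)
  couch_dct <- match.arg(couch_dct, c("none", "flat", "curved"))
  couch_pct <- match.arg(couch_pct, c("none", "flat", "curved"))
  gas_pocket <- match.arg(gas_pocket, c("none", "dct", "pct", "both"))
  structure(list(
    region = region, grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    body_semiaxes_mm = as.numeric(body_semiaxes_mm),
    gtv_center_mm = as.numeric(gtv_center_mm),
    gtv_semiaxes_mm = as.numeric(gtv_semiaxes_mm),
    oars = oars, bone = isTRUE(bone),
    couch_dct = couch_dct, couch_pct = couch_pct,
    couch_hu = couch_hu, couch_thickness_mm = couch_thickness_mm,
    couch_gap_mm = couch_gap_mm,
    gas_pocket = gas_pocket,
    gas_center_mm = as.numeric(gas_center_mm), gas_radius_mm = gas_radius_mm,
    deform_amplitude_mm = deform_amplitude_mm,
    deform_smoothness_mm = deform_smoothness_mm,
    sag_mm = sag_mm, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

# mm positions of all voxel centres as an n x 3 matrix, plus grid metadata
phantom_grid <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  origin <- c(0, 0, 0)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * sp[a])
  list(dim = d, spacing = sp, origin = origin, ax = ax,
       center = origin + (d - 1) / 2 * sp)
}

# body centre: grid centre pulled anteriorly to leave room for the couch
body_center <- function(spec, g) g$center - c(0, 25, 0)

in_ellipsoid <- function(P, center, semi) {
  ((P[, 1] - center[1]) / semi[1])^2 +
  ((P[, 2] - center[2]) / semi[2])^2 +
  ((P[, 3] - center[3]) / semi[3])^2 <= 1
}

# anatomy HU at arbitrary mm positions P (n x 3); excludes couch and noise.
# Soft-tissue interfaces get a 3 mm partial-volume transition band (as real
# CT reconstruction produces) so that trilinear resampling of the rendered
# volume agrees with direct evaluation of the displaced anatomy.
phantom_hu_at <- function(spec, g, P, frame = c("dct", "pct")) {
  frame <- match.arg(frame)
  bc <- body_center(spec, g)
  pv_w <- 6
  qf <- function(center, semi)
    sqrt(((P[, 1] - center[1]) / semi[1])^2 + ((P[, 2] - center[2]) / semi[2])^2 +
         ((P[, 3] - center[3]) / semi[3])^2)
  blend <- function(center, semi) {
    # approximate signed surface distance of the ellipsoid, mm
    dlt <- (1 - qf(center, semi)) * min(semi)
    pmin(1, pmax(0, dlt / pv_w + 0.5))
  }
  body <- in_ellipsoid(P, bc, spec$body_semiaxes_mm)
  hu <- -1000 + 1040 * blend(bc, spec$body_semiaxes_mm)
  if (spec$region == "thorax") {
    for (sgn in c(-1, 1))
      hu <- hu - 740 * blend(bc + c(sgn * 45, -8, 0), c(28, 38, 70))
  }
  if (isTRUE(spec$bone)) {
    # spine with vertebra-like radius modulation plus two asymmetric rib
    # blocks: gives the bony anatomy axial structure and breaks rotational
    # symmetry so rigid alignment is well posed
    sc <- bc + c(0, 0.55 * spec$body_semiaxes_mm[2], 0)
    # chirped (aperiodic) vertebral spacing so axial alignment is unique,
    # not merely defined modulo one vertebra
    zr <- P[, 3] - bc[3]
    phase <- ((zr + 10 * sin(2 * pi * zr / 150)) %% 26) / 26
    rsp <- ifelse(phase < 0.72, 13, 6)    # vertebral bodies with disc spaces
    # bone stays clear of the axial grid ends so no scan truncates it
    inz <- abs(zr) <= 42
    bone_blend <- function(rxy, rad) {
      b <- pmin(1, pmax(0, (rad - rxy) / 2 + 0.5))   # 2 mm radial transition
      b[!inz | !body] <- 0
      b
    }
    bsp <- bone_blend(sqrt((P[, 1] - sc[1])^2 + (P[, 2] - sc[2])^2), rsp)
    hu <- hu * (1 - bsp) + 700 * bsp
    for (rod in list(c(62, 25, 7, 9), c(-60, 28, 6, -6))) {
      rc <- bc + c(rod[1], rod[2], 0)
      ph <- ((zr - rod[4] + 8 * sin(2 * pi * (zr - rod[4]) / 120)) %% 26) / 26
      rr <- rod[3] * ifelse(ph < 0.65, 1, 0.45)
      brd <- bone_blend(sqrt((P[, 1] - rc[1])^2 + (P[, 2] - rc[2])^2), rr)
      hu <- hu * (1 - brd) + 700 * brd
    }
  }
  hu <- hu + 20 * blend(bc + spec$gtv_center_mm, spec$gtv_semiaxes_mm)
  want_gas <- spec$gas_pocket == "both" || spec$gas_pocket == frame
  if (want_gas)
    hu <- hu - 1040 * blend(bc + spec$gas_center_mm, rep(spec$gas_radius_mm, 3))
  hu
}

phantom_mask_at <- function(spec, g, P, what, oar = NULL) {
  bc <- body_center(spec, g)
  switch(what,
    body = in_ellipsoid(P, bc, spec$body_semiaxes_mm),
    gtv = in_ellipsoid(P, bc + spec$gtv_center_mm, spec$gtv_semiaxes_mm),
    oar = {
      o <- oar
      ctr <- bc + if (!is.null(o$center)) o$center else c(0, 0, 0)
      switch(o$type,
        sphere = in_ellipsoid(P, ctr, rep(o$radius, 3)),
        cylinder = (P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 <= o$radius^2,
        slab = P[, o$axis] >= bc[o$axis] + o$range[1] &
               P[, o$axis] <= bc[o$axis] + o$range[2],
        stop(sprintf("unknown OAR primitive '%s'", o$type), call. = FALSE))
    })
}

couch_hu_at <- function(spec, g, P, kind) {
  if (kind == "none") return(rep(NA_real_, nrow(P)))
  bc <- body_center(spec, g)
  y0 <- bc[2] + spec$body_semiaxes_mm[2] + spec$couch_gap_mm
  halfwidth <- 110
  xr <- (P[, 1] - g$center[1]) / halfwidth
  ys <- if (kind == "curved") y0 + 15 * xr^2 else rep(y0, nrow(P))
  on_couch <- abs(xr) <= 1 & P[, 2] >= ys & P[, 2] <= ys + spec$couch_thickness_mm
  out <- rep(NA_real_, nrow(P))
  out[on_couch] <- spec$couch_hu
  out
}

# smooth random vector field on the grid using the active RNG stream
random_smooth_field <- function(d, spacing, amplitude_mm, smoothness_mm) {
  u <- array(0, c(d, 3))
  if (amplitude_mm > 0) {
    sig <- smoothness_mm / spacing
    for (c3 in 1:3) {
      w <- array(rnorm(prod(d)), d)
      u[, , , c3] <- cpp_gauss_blur(w, d, sig)
    }
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    m <- max(mag)
    if (m > 0) u <- u * (amplitude_mm / m)
  }
  u
}

#' Seeded smooth deformation field with bounded magnitude
#'
#' Gaussian-filtered white noise per component, rescaled so the maximum
#' displacement magnitude equals `amplitude_mm`. Used as ground truth for
#' deformation-recovery experiments.
#'
#' @param grid any grid-carrying object (`image_volume`, `binary_mask`, ...)
#'   whose geometry the field should live on.
#' @param amplitude_mm maximum displacement magnitude, mm (>= 0).
#' @param smoothness_mm Gaussian kernel width, mm.
#' @param seed integer seed; fixed seed gives a bit-identical field.
#' @return A `deformation_field`.
#' @export
make_known_dvf <- function(grid, amplitude_mm = 4, smoothness_mm = 25, seed = 1L) {
  if (!is.finite(amplitude_mm) || amplitude_mm < 0)
    stop("amplitude_mm must be >= 0", call. = FALSE)
  d <- grid_shape(grid)
  u <- with_seed(seed, random_smooth_field(d, grid$spacing, amplitude_mm, smoothness_mm))
  deformation_field(u, grid$spacing, grid$origin)
}

# systematic couch-induced sag: posterior tissue displaced toward the couch
sag_field <- function(spec, g) {
  u <- array(0, c(g$dim, 3))
  if (spec$sag_mm > 0) {
    bc <- body_center(spec, g)
    y_post <- bc[2] + spec$body_semiaxes_mm[2]
    yy <- g$ax[[2]]
    prof <- spec$sag_mm * exp(-((yy - y_post) / 45)^2)
    u[, , , 2] <- array(rep(rep(prof, each = g$dim[1]), g$dim[3]), g$dim)
  }
  u
}

#' Generate a paired dCT/pCT phantom bundle
#'
#' Renders the diagnostic CT (its couch variant, pre-deformation anatomy) and
#' the planning CT (flat or no couch, anatomy deformed by the bundled ground
#' truth field), together with body/GTV/OAR masks in the planning frame. The
#' true deformation maps dCT anatomy onto pCT anatomy:
#' `warp(dct_anatomy, true_dvf)` matches the pCT body to within the noise.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_bundle` list: `dct`, `pct` (`image_volume`), `true_dvf`
#'   (`deformation_field`), `body`, `gtv` (`binary_mask`s in the planning
#'   frame), `oars` (named list of `binary_mask`), `dct_body` / `dct_gtv`
#'   (masks in the diagnostic frame), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  P <- as.matrix(expand.grid(x = g$ax[[1]], y = g$ax[[2]], z = g$ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  res <- with_seed(spec$seed, {
    u <- random_smooth_field(g$dim, g$spacing, spec$deform_amplitude_mm,
                             spec$deform_smoothness_mm) + sag_field(spec, g)
    noise_d <- if (spec$noise_sd > 0) rnorm(nrow(P), 0, spec$noise_sd) else 0
    noise_p <- if (spec$noise_sd > 0) rnorm(nrow(P), 0, spec$noise_sd) else 0
    list(u = u, noise_d = noise_d, noise_p = noise_p)
  })
  u <- res$u
  Pdef <- P + cbind(as.numeric(u[, , , 1]), as.numeric(u[, , , 2]),
                    as.numeric(u[, , , 3]))

  hu_d <- phantom_hu_at(spec, g, P, "dct")
  hu_p <- phantom_hu_at(spec, g, Pdef, "pct")
  cd <- couch_hu_at(spec, g, P, spec$couch_dct)
  cp <- couch_hu_at(spec, g, P, spec$couch_pct)
  hu_d <- ifelse(is.na(cd), hu_d, pmax(hu_d, cd))
  hu_p <- ifelse(is.na(cp), hu_p, pmax(hu_p, cp))
  hu_d <- pmin(pmax(hu_d + res$noise_d, HU_AIR), HU_MAX)
  hu_p <- pmin(pmax(hu_p + res$noise_p, HU_AIR), HU_MAX)

  body_p <- phantom_mask_at(spec, g, Pdef, "body")
  gtv_p <- phantom_mask_at(spec, g, Pdef, "gtv")
  body_d <- phantom_mask_at(spec, g, P, "body")
  gtv_d <- phantom_mask_at(spec, g, P, "gtv")
  if (!any(gtv_p)) stop("invalid spec: GTV is empty on the grid", call. = FALSE)
  if (any(gtv_p & !body_p))
    stop("invalid spec: GTV extends outside the body", call. = FALSE)

  mk_img <- function(v) image_volume(array(v, g$dim), g$spacing, g$origin)
  mk_msk <- function(v) binary_mask(array(as.integer(v), g$dim), g$spacing, g$origin)
  oars <- lapply(spec$oars, function(o) mk_msk(phantom_mask_at(spec, g, Pdef, "oar", o)))

  structure(list(
    dct = mk_img(hu_d), pct = mk_img(hu_p),
    true_dvf = deformation_field(u, g$spacing, g$origin),
    body = mk_msk(body_p), gtv = mk_msk(gtv_p), oars = oars,
    dct_body = mk_msk(body_d), dct_gtv = mk_msk(gtv_d),
    spec = spec), class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> region %s, grid %s, seed %d, %d OAR(s)\n",
              x$spec$region, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$seed, length(x$oars)))
  invisible(x)
}

#' Training-set augmentation operations
#'
#' In-plane 90-degree clockwise rotation (an exact index permutation),
#' integer-voxel translation with -1024 HU fill, and a centred in-plane crop
#' window (default 128 x 128).
#'
#' @param v an `image_volume`.
#' @param op `"rotate90"`, `"translate"` or `"crop128"`.
#' @param shift_vox integer voxel shift (translate).
#' @param width in-plane crop width in voxels (crop128).
#' @return The augmented `image_volume`.
#' @export
augment <- function(v, op = c("rotate90", "translate", "crop128"),
                    shift_vox = c(0, 0, 0), width = 128L) {
  op <- match.arg(op)
  d <- grid_shape(v)
  a <- v_arr(v)
  if (op == "rotate90") {
    out <- array(0, c(d[2], d[1], d[3]))
    for (k in seq_len(d[3])) out[, , k] <- t(a[d[1]:1, , k])
    return(image_volume(out, v$spacing[c(2, 1, 3)], v$origin))
  }
  if (op == "translate") {
    shift_vox <- as.integer(round(shift_vox))
    out <- array(HU_AIR, d)
    src <- dst <- vector("list", 3)
    for (ax in 1:3) {
      s <- shift_vox[ax]
      src[[ax]] <- seq_len(d[ax]) - s
      keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
      dst[[ax]] <- seq_len(d[ax])[keep]
      src[[ax]] <- src[[ax]][keep]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    return(image_volume(out, v$spacing, v$origin))
  }
  # crop128
  width <- as.integer(width)
  if (width > d[1] || width > d[2])
    stop("crop window exceeds the in-plane grid", call. = FALSE)
  off <- as.integer(floor((d[1:2] - width) / 2))
  out <- a[off[1] + seq_len(width), off[2] + seq_len(width), , drop = FALSE]
  image_volume(out, v$spacing, v$origin + c(off * v$spacing[1:2], 0))
}

#' Paint a synthetic lattice dose distribution
#'
#' A stand-in for the treatment planning system: a valley plateau of
#' `valley_ratio * prescription` inside the GTV, spherically symmetric peaked
#' kernels at the sphere centres (smoothstep falloff reaching the valley at
#' 1.5x the sphere radius), and a Gaussian decay outside the GTV. Each
#' kernel's radial exponent is calibrated so the median dose over the
#' sphere's voxels equals the prescription to within 1%; dose scales
#' linearly with the prescription.
#'
#' @param spheres a [sphere_set()].
#' @param gtv the GTV `binary_mask` (also fixes the output grid).
#' @param prescription_cGy prescription dose per fraction, cGy.
#' @param valley_ratio valley-to-prescription ratio, in (0, 1); LRT
#'   protocols aim for 0.3-0.4.
#' @param peak_factor centre dose as a multiple of prescription (>= 1); the
#'   planning envelope is 1.2-1.5.
#' @param decay_mm Gaussian decay length of dose outside the GTV.
#' @return A `dose_grid` on the GTV grid.
#' @export
synth_lattice_dose <- function(spheres, gtv, prescription_cGy = 2000,
                               valley_ratio = 0.35, peak_factor = 1.3,
                               decay_mm = 8) {
  stopifnot(inherits(gtv, "binary_mask"))
  if (!(valley_ratio > 0 && valley_ratio < 1))
    stop("valley_ratio must be in (0, 1)", call. = FALSE)
  if (peak_factor < 1) stop("peak_factor must be >= 1", call. = FALSE)
  d <- grid_shape(gtv)
  ax <- axis_coords(gtv)
  n <- prod(d)
  maxshape <- array(0, d)
  centers <- sphere_centers(spheres)
  if (nrow(centers) == 0L) {
    warning(warningCondition("empty sphere set: painting all-valley dose",
                             class = "lp_empty_sphereset"))
  } else {
    r <- spheres$diameter_mm / 2
    v <- valley_ratio; pf <- peak_factor
    ratio <- (1 - v) / (pf - v)
    dx2 <- outer(ax[[1]], centers[, 1], function(x, c) (x - c)^2)
    dy2 <- outer(ax[[2]], centers[, 2], function(y, c) (y - c)^2)
    dz2 <- outer(ax[[3]], centers[, 3], function(z, c) (z - c)^2)
    for (j in seq_len(nrow(centers))) {
      rho <- sqrt(outer(outer(dx2[, j], dy2[, j], "+"), dz2[, j], "+"))
      tt <- pmin(rho / (1.5 * r), 1)
      S <- 1 - (3 * tt^2 - 2 * tt^3)
      Smed <- median(S[rho <= r])
      gam <- if (pf > 1 && Smed > 0 && Smed < 1 && ratio < 1)
        log(ratio) / log(Smed) else 1e-8
      maxshape <- pmax(maxshape, S^gam * (S > 0))
    }
  }
  f <- valley_ratio + (peak_factor - valley_ratio) * maxshape
  d_out <- cpp_edt(gtv$voxels, d, gtv$spacing)
  dose <- prescription_cGy * f * exp(-(d_out / decay_mm)^2)
  dose_grid(array(dose, d), gtv$spacing, gtv$origin)
}
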