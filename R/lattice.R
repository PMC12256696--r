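# Automated lattice sphere placement: 1.5 cm spheres inside a contracted GTV,
# clear of OARs, hexagonal in-plane pitch within the 6-8 cm same-plane rule,
# >= 3 cm between centres in different axial planes.

#' Sphere placement constraints
#'
#' Defaults follow the clinical protocol: 1.5 cm sphere diameter, centres at
#' least 1.0 cm inside the GTV surface and 1.5 cm from any OAR, same-plane
#' centre-to-centre spacing in 6-8 cm, and at least 3 cm between centres in
#' different axial planes.
#'
#' @param sphere_diameter_mm sphere diameter (mm).
#' @param gtv_contraction_mm minimum centre distance to the GTV surface (mm).
#' @param oar_clearance_mm minimum centre distance to any OAR voxel (mm).
#' @param axial_spacing_mm length-2 range for nearest same-plane neighbours.
#' @param out_of_plane_min_mm minimum centre distance across planes (mm).
#' @param seed recorded for provenance (the default greedy placement is
#'   deterministic and draws no random numbers).
#' @return A `placement_params` object.
#' @export
placement_params <- function(sphere_diameter_mm = 15,
                             gtv_contraction_mm = 10,
                             oar_clearance_mm = 15,
                             axial_spacing_mm = c(60, 80),
                             out_of_plane_min_mm = 30,
                             seed = 1L) {
  stopifnot(sphere_diameter_mm > 0, gtv_contraction_mm > 0,
            oar_clearance_mm > 0, out_of_plane_min_mm > 0,
            length(axial_spacing_mm) == 2L,
            axial_spacing_mm[1] <= axial_spacing_mm[2],
            axial_spacing_mm[1] > 0)
  structure(list(sphere_diameter_mm = sphere_diameter_mm,
                 gtv_contraction_mm = gtv_contraction_mm,
                 oar_clearance_mm = oar_clearance_mm,
                 axial_spacing_mm = as.numeric(axial_spacing_mm),
                 out_of_plane_min_mm = out_of_plane_min_mm,
                 seed = as.integer(seed)),
            class = "placement_params")
}

#' Lattice target: sphere centres and common diameter
#'
#' @param centers n x 3 matrix of centres, mm patient coordinates.
#' @param diameter_mm common sphere diameter (mm).
#' @param params optional [placement_params()] provenance.
#' @return A `sphere_set` object.
#' @export
sphere_set <- function(centers, diameter_mm = 15, params = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) > 1) {
    dm <- as.matrix(stats::dist(centers))
    if (min(dm[upper.tri(dm)]) <= 0)
      stop("sphere centres must be pairwise distinct", call. = FALSE)
  }
  structure(list(centers = centers, diameter_mm = diameter_mm, params = params),
            class = "sphere_set")
}

sphere_centers <- function(s) {
  stopifnot(inherits(s, "sphere_set"))
  s$centers
}

#' @export
print.sphere_set <- function(x, ...) {
  cat(sprintf("<sphere_set> %d sphere(s), diameter %.1f mm\n",
              nrow(x$centers), x$diameter_mm))
  invisible(x)
}

# exact min distance (mm) from each point (n x 3, mm) to mask==1 voxel
# centres. The minimizing voxel of a point outside the mask always lies on
# the mask's 26-neighbourhood boundary (a strictly closer neighbour toward
# the point would otherwise also be in the mask), so only boundary voxels
# need scanning; points inside the mask also check their containing voxel.
min_dist_to_mask <- function(pts, mask) {
  d <- grid_shape(mask)
  if (sum(mask$voxels) == 0L) return(rep(Inf, nrow(pts)))
  dcomp <- cpp_edt(1L - mask$voxels, d, c(1, 1, 1))
  bnd <- mask$voxels == 1L & dcomp <= sqrt(3) + 1e-9
  # voxels on the grid faces are boundary by convention
  face <- array(FALSE, d)
  face[c(1, d[1]), , ] <- TRUE; face[, c(1, d[2]), ] <- TRUE
  face[, , c(1, d[3])] <- TRUE
  idx <- which(bnd | (mask$voxels == 1L & face), arr.ind = TRUE)
  vc <- voxel_centers_mm(mask, idx)
  out <- vapply(seq_len(nrow(pts)), function(r) {
    sqrt(min((vc[, 1] - pts[r, 1])^2 + (vc[, 2] - pts[r, 2])^2 +
             (vc[, 3] - pts[r, 3])^2))
  }, numeric(1))
  ins <- inside_mask(pts, mask)
  if (any(ins)) {
    near <- round(mm_to_index(mask, pts[ins, , drop = FALSE]))
    own <- sweep(sweep(near, 2, mask$spacing, "*"), 2, mask$origin, "+")
    dd <- sqrt(rowSums((own - pts[ins, , drop = FALSE])^2))
    out[ins] <- pmin(out[ins], dd)
  }
  out
}

# is each point's nearest voxel inside the mask?
inside_mask <- function(pts, mask) {
  d <- grid_shape(mask)
  idx <- round(mm_to_index(mask, pts))
  ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
        idx[, 1] <= d[1] - 1 & idx[, 2] <= d[2] - 1 & idx[, 3] <= d[3] - 1
  out <- logical(nrow(pts))
  if (any(ok)) {
    lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
    out[ok] <- mask$voxels[lin] == 1L
  }
  out
}

# signed surface distance: distance to the nearest non-GTV voxel centre for
# points inside the GTV, 0 for points outside it; used as the
# surface-distance measure throughout placement and audit
dist_inside_gtv <- function(pts, gtv) {
  outside <- binary_mask(1L - gtv$voxels, gtv$spacing, gtv$origin)
  ifelse(inside_mask(pts, gtv), min_dist_to_mask(pts, outside), 0)
}

#' Place lattice spheres inside a GTV
#'
#' Deterministic greedy placement: the candidate region is the GTV contracted
#' by `gtv_contraction_mm` minus all OARs padded by `oar_clearance_mm`
#' (Euclidean distances in mm), with the additional feasibility rule that the
#' whole sphere must fit inside the contracted GTV (centres at least
#' `gtv_contraction_mm + diameter/2` from the surface), so targets whose
#' contraction leaves less than one sphere yield an empty set with a
#' warning. Axial planes are selected greedily by
#' candidate capacity subject to the cross-plane minimum; within each plane,
#' centres sit on a hexagonal lattice (pitch = midpoint of the same-plane
#' range, offset rows) anchored on a half-pitch grid about the volume
#' centre, taking the phase that maximizes the sphere count. Points whose
#' nearest same-plane neighbour would exceed the allowed range are pruned
#' (single-sphere planes are accepted).
#'
#' @param gtv non-empty GTV `binary_mask`.
#' @param oars list of OAR `binary_mask`s on the same grid (may be empty).
#' @param params a [placement_params()].
#' @return A `sphere_set` (possibly empty, with a warning, when the geometry
#'   is infeasible).
#' @export
place_spheres <- function(gtv, oars = list(), params = placement_params()) {
  stopifnot(inherits(gtv, "binary_mask"))
  if (!all(vapply(oars, function(o) same_grid(o, gtv), logical(1))))
    stop_grid_mismatch("GTV and OAR masks")
  if (sum(gtv$voxels) == 0L) stop("GTV mask is empty", call. = FALSE)
  d <- grid_shape(gtv)

  # candidate voxels by exact distance transforms (mm-aware); the centre
  # must honour the contraction margin AND the whole sphere must fit inside
  # the contracted GTV (infeasibly small targets yield an empty set)
  surf_min <- params$gtv_contraction_mm + params$sphere_diameter_mm / 2
  din <- cpp_edt(1L - gtv$voxels, d, gtv$spacing)      # distance to GTV exterior
  cand <- gtv$voxels == 1L & din >= surf_min
  for (o in oars) {
    if (sum(o$voxels) == 0L) next
    doar <- cpp_edt(o$voxels, d, o$spacing)
    cand <- cand & doar >= params$oar_clearance_mm
  }
  empty <- sphere_set(matrix(numeric(0), ncol = 3),
                      params$sphere_diameter_mm, params)
  if (!any(cand)) {
    warning(warningCondition(
      "no feasible candidate region: GTV too small after contraction/OAR margins",
      class = "lp_empty_sphereset"))
    return(empty)
  }
  cand <- array(cand, d)

  pitch <- mean(params$axial_spacing_mm)          # hex pitch, same-plane spacing
  row_h <- pitch * sqrt(3) / 2
  g_ctr <- gtv$origin + (d - 1) / 2 * gtv$spacing
  zs <- axis_coords(gtv)[[3]]

  plane_points_phase <- function(k, xoff0, yoff0) {
    sl <- cand[, , k]
    if (!any(sl)) return(matrix(numeric(0), ncol = 3))
    idx <- which(sl, arr.ind = TRUE)
    xs <- gtv$origin[1] + (idx[, 1] - 1) * gtv$spacing[1]
    ys <- gtv$origin[2] + (idx[, 2] - 1) * gtv$spacing[2]
    mrange <- range(round((c(min(ys), max(ys)) - g_ctr[2] - yoff0) / row_h)) + c(-1, 1)
    pts <- NULL
    for (m in seq(mrange[1], mrange[2])) {
      y <- g_ctr[2] + yoff0 + m * row_h
      xoff <- xoff0 + (abs(m) %% 2) * pitch / 2
      nrange <- range(round((c(min(xs), max(xs)) - g_ctr[1] - xoff) / pitch)) + c(-1, 1)
      for (nn in seq(nrange[1], nrange[2])) {
        x <- g_ctr[1] + xoff + nn * pitch
        pts <- rbind(pts, c(x, y, zs[k]))
      }
    }
    if (is.null(pts)) return(matrix(numeric(0), ncol = 3))
    # keep lattice points inside the candidate region (exact margin checks)
    keep <- dist_inside_gtv(pts, gtv) >= surf_min
    for (o in oars) {
      if (sum(o$voxels) == 0L) next
      keep <- keep & min_dist_to_mask(pts, o) >= params$oar_clearance_mm
    }
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0L) return(pts)
    # prune points whose nearest same-plane neighbour is beyond the range
    hi <- params$axial_spacing_mm[2]
    repeat {
      if (nrow(pts) <= 1L) break
      dm <- as.matrix(stats::dist(pts[, 1:2, drop = FALSE]))
      diag(dm) <- Inf
      nnd <- apply(dm, 1, min)
      bad <- which(nnd > hi + 1e-9)
      if (length(bad) == 0L) break
      worst <- bad[order(-nnd[bad], -pts[bad, 1], -pts[bad, 2])][1]
      pts <- pts[-worst, , drop = FALSE]
    }
    pts
  }

  # best of four half-pitch lattice phases per plane (count, then spacing);
  # per-phase counts are monotone in the candidate region, so a shrinking
  # GTV can never gain spheres
  plane_points <- function(k) {
    best <- matrix(numeric(0), ncol = 3)
    for (ph in list(c(0, 0), c(pitch / 2, 0), c(0, row_h / 2), c(pitch / 2, row_h / 2))) {
      pts <- plane_points_phase(k, ph[1], ph[2])
      if (nrow(pts) > nrow(best)) best <- pts
    }
    best
  }

  # greedy plane selection by capacity under the cross-plane minimum
  planes <- which(apply(cand, 3, any))
  caps <- integer(length(planes))
  pts_by_plane <- vector("list", length(planes))
  for (ii in seq_along(planes)) {
    pts_by_plane[[ii]] <- plane_points(planes[ii])
    caps[ii] <- nrow(pts_by_plane[[ii]])
  }
  chosen <- integer(0)
  avail <- rep(TRUE, length(planes))
  avail[caps == 0L] <- FALSE
  while (any(avail)) {
    cands <- which(avail)
    best <- cands[order(-caps[cands], planes[cands])][1]
    chosen <- c(chosen, best)
    zsel <- zs[planes[best]]
    avail <- avail & abs(zs[planes] - zsel) >= params$out_of_plane_min_mm - 1e-9
  }
  chosen <- sort(chosen)
  centers <- do.call(rbind, pts_by_plane[chosen])
  if (is.null(centers) || nrow(centers) == 0L) {
    warning(warningCondition("candidate region admits no lattice point",
                             class = "lp_empty_sphereset"))
    return(empty)
  }
  centers <- centers[order(centers[, 3], centers[, 2], centers[, 1]), , drop = FALSE]
  sphere_set(centers, params$sphere_diameter_mm, params)
}

#' Rasterize spheres onto a grid
#'
#' A voxel belongs to a sphere iff its centre lies within `diameter/2` of the
#' sphere centre.
#'
#' @param s a [sphere_set()].
#' @param grid any grid-carrying object defining the output geometry.
#' @return list with `per_sphere` (list of `binary_mask`) and `union`
#'   (`binary_mask`).
#' @export
rasterize_spheres <- function(s, grid) {
  stopifnot(inherits(s, "sphere_set"))
  d <- grid_shape(grid)
  sp <- if (inherits(grid, "lattice_grid")) grid$spacing else stop("grid required")
  if (any(sp > s$diameter_mm / 2))
    warning(warningCondition("grid spacing exceeds the sphere radius; rasterization is coarse",
                             class = "lp_coarse_grid"))
  ax <- axis_coords(grid)
  r2 <- (s$diameter_mm / 2)^2
  centers <- sphere_centers(s)
  per <- vector("list", nrow(centers))
  uni <- array(0L, d)
  for (j in seq_len(nrow(centers))) {
    rho2 <- outer(outer((ax[[1]] - centers[j, 1])^2,
                        (ax[[2]] - centers[j, 2])^2, "+"),
                  (ax[[3]] - centers[j, 3])^2, "+")
    m <- array(as.integer(rho2 <= r2), d)
    if (sum(m) == 0L)
      warning(warningCondition(sprintf("sphere %d lies outside the grid", j),
                               class = "lp_sphere_outside"))
    per[[j]] <- binary_mask(m, grid$spacing, grid$origin)
    uni <- pmax(uni, m)
  }
  list(per_sphere = per,
       union = binary_mask(array(as.integer(uni), d), grid$spacing, grid$origin))
}

#' Audit a sphere placement against the protocol constraints
#'
#' Recomputes all constraint minima with exact distances: centre-to-GTV
#' surface, centre-to-OAR, nearest same-plane neighbour spacing, and minimum
#' cross-plane centre distance. Same-plane membership is decided by the
#' centre's nearest axial voxel plane.
#'
#' @inheritParams place_spheres
#' @param s the `sphere_set` to audit.
#' @return A `placement_audit` list with the minima and a character vector of
#'   violations (empty iff all constraints hold).
#' @export
audit_placement <- function(s, gtv, oars = list(), params = placement_params()) {
  stopifnot(inherits(s, "sphere_set"), inherits(gtv, "binary_mask"))
  centers <- sphere_centers(s)
  n <- nrow(centers)
  viol <- character(0)
  if (n == 0L) {
    return(structure(list(n_spheres = 0L, min_center_to_gtv_surface_mm = NA_real_,
                          min_center_to_oar_mm = NA_real_,
                          min_same_plane_spacing_mm = NA_real_,
                          min_cross_plane_spacing_mm = NA_real_,
                          violations = viol), class = "placement_audit"))
  }
  din <- min(dist_inside_gtv(centers, gtv))
  doar <- if (length(oars)) min(vapply(oars, function(o)
    min(min_dist_to_mask(centers, o)), numeric(1))) else Inf
  # nearest axial voxel plane index per centre
  zplane <- round((centers[, 3] - gtv$origin[3]) / gtv$spacing[3])
  same_nn <- Inf; cross_min <- Inf
  if (n > 1) {
    dm <- as.matrix(stats::dist(centers))
    same <- outer(zplane, zplane, "==") & upper.tri(dm)
    cross <- !outer(zplane, zplane, "==") & upper.tri(dm)
    if (any(cross)) cross_min <- min(dm[cross])
    # nearest same-plane neighbour per sphere that has one
    nn <- vapply(seq_len(n), function(i) {
      js <- which(zplane == zplane[i]); js <- setdiff(js, i)
      if (!length(js)) return(NA_real_)
      min(sqrt(colSums((t(centers[js, , drop = FALSE]) - centers[i, ])^2)))
    }, numeric(1))
    if (any(!is.na(nn))) same_nn <- range(nn, na.rm = TRUE)
  }
  if (din < params$gtv_contraction_mm - 1e-9)
    viol <- c(viol, sprintf("centre %.2f mm from GTV surface (< %g mm)",
                            din, params$gtv_contraction_mm))
  if (doar < params$oar_clearance_mm - 1e-9)
    viol <- c(viol, sprintf("centre %.2f mm from an OAR (< %g mm)",
                            doar, params$oar_clearance_mm))
  if (is.finite(cross_min) && cross_min < params$out_of_plane_min_mm - 1e-9)
    viol <- c(viol, sprintf("cross-plane spacing %.2f mm (< %g mm)",
                            cross_min, params$out_of_plane_min_mm))
  same_rep <- NA_real_
  if (length(same_nn) == 2L || is.finite(same_nn[1])) {
    if (identical(same_nn, Inf)) {
      same_rep <- NA_real_
    } else {
      same_rep <- same_nn[1]
      if (same_nn[1] < params$axial_spacing_mm[1] - 1e-9 ||
          same_nn[2] > params$axial_spacing_mm[2] + 1e-9)
        viol <- c(viol, sprintf(
          "same-plane neighbour spacing [%.2f, %.2f] mm outside [%g, %g] mm",
          same_nn[1], same_nn[2],
          params$axial_spacing_mm[1], params$axial_spacing_mm[2]))
    }
  }
  structure(list(n_spheres = n,
                 min_center_to_gtv_surface_mm = din,
                 min_center_to_oar_mm = doar,
                 min_same_plane_spacing_mm = same_rep,
                 min_cross_plane_spacing_mm = if (is.finite(cross_min)) cross_min else NA_real_,
                 violations = viol), class = "placement_audit")
}

#' @export
print.placement_audit <- function(x, ...) {
  cat(sprintf("<placement_audit> %d sphere(s)\n", x$n_spheres))
  cat(sprintf("  min centre-to-GTV-surface: %.2f mm\n", x$min_center_to_gtv_surface_mm))
  cat(sprintf("  min centre-to-OAR:         %.2f mm\n", x$min_center_to_oar_mm))
  cat(sprintf("  min same-plane NN spacing: %.2f mm\n", x$min_same_plane_spacing_mm))
  cat(sprintf("  min cross-plane spacing:   %.2f mm\n", x$min_cross_plane_spacing_mm))
  if (length(x$violations)) cat("  VIOLATIONS:\n", paste0("   - ", x$violations, "\n"))
  else cat("  no violations\n")
  invisible(x)
}
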