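#' @useDynLib latticeplan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm median optim quantile sd approx pnorm cor
#' @importFrom utils head tail
NULL

# Coordinate conventions used throughout the package:
#   * 0-based voxel indices (i, j, k), array stored [x, y, z] with z the
#     axial slice index;
#   * patient LPS millimetres; voxel (i,j,k) centre = origin + (i,j,k)*spacing;
#   * displacement fields are stored in mm on the fixed grid;
#   * out-of-grid samples take -1024 HU (air) unless stated otherwise.

HU_AIR <- -1024
HU_MAX <- 3071

new_grid_obj <- function(voxels, spacing, origin, class) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = c(class, "lattice_grid"))
}

#' 3D CT-like image volume
#'
#' The common currency of diagnostic, planning and synthetic CTs: a 3D array
#' of Hounsfield units plus the physical grid (spacing and origin in patient
#' LPS mm, voxel-centre convention, 0-based indices).
#'
#' @param voxels 3D numeric array, dimension order x, y, z (z = axial slice).
#' @param spacing mm per axis, 3 positive numbers.
#' @param origin mm position of the centre of voxel (0,0,0).
#' @return An `image_volume` object.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new_grid_obj(voxels, spacing, origin, "image_volume")
}

#' Binary structure mask on an image grid
#'
#' @param voxels 3D array of 0/1 (logical arrays are coerced).
#' @inheritParams image_volume
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- voxels
  if (is.logical(v)) v <- array(as.integer(v), dim(voxels))
  storage.mode(v) <- "integer"
  if (!all(v == 0L | v == 1L)) stop("mask voxels must be 0 or 1", call. = FALSE)
  new_grid_obj(v, spacing, origin, "binary_mask")
}

#' Dose grid (cGy) on an image geometry
#'
#' @param voxels 3D array of dose in cGy, all values >= 0.
#' @inheritParams image_volume
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  if (any(voxels < 0)) stop("dose values must be >= 0 cGy", call. = FALSE)
  new_grid_obj(voxels, spacing, origin, "dose_grid")
}

#' Dense deformation vector field
#'
#' Per-voxel displacement in mm defined on the fixed-image grid; the zero
#' field is the identity warp.
#'
#' @param displacement 4D array `[nx, ny, nz, 3]` of mm displacements.
#' @inheritParams image_volume
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(displacement, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement must be a [nx,ny,nz,3] array", call. = FALSE)
  if (any(!is.finite(displacement)))
    stop("displacement must be finite everywhere", call. = FALSE)
  storage.mode(displacement) <- "double"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(displacement = displacement, spacing = spacing, origin = origin),
            class = c("deformation_field", "lattice_grid"))
}

#' Rigid transform (Euler angles + translation)
#'
#' Rotation angles are in degrees, applied about the grid centre in the order
#' x, y, z; translation is in mm.
#'
#' @param rotation 3 Euler angles, degrees.
#' @param translation 3-vector, mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  if (length(rotation) != 3L || any(!is.finite(rotation)))
    stop("rotation must be 3 finite angles (degrees)", call. = FALSE)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.lattice_grid <- function(x, ...) {
  v <- if (inherits(x, "deformation_field")) x$displacement else x$voxels
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(v)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (!inherits(x, "deformation_field"))
    cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%s) deg, trans (%s) mm\n",
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

grid_shape <- function(v) {
  if (inherits(v, "deformation_field")) dim(v$displacement)[1:3] else dim(v$voxels)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_shape(a) == grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_grid_mismatch <- function(what) {
  stop(sprintf("grid mismatch: %s must share shape, spacing and origin", what),
       call. = FALSE)
}

# physical voxel volume in cc (1 cc = 1000 mm^3)
voxel_volume_cc <- function(v) prod(v$spacing) / 1000

# n x 3 matrix of voxel-centre coordinates (mm) for 1-based array index list
voxel_centers_mm <- function(v, which_idx) {
  sweep(sweep(which_idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

# axis coordinate vectors (mm) of voxel centres
axis_coords <- function(v) {
  d <- grid_shape(v)
  lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$spacing[a])
}

# mm position -> continuous 0-based voxel index
mm_to_index <- function(v, pts_mm) {
  sweep(sweep(pts_mm, 2, v$origin, "-"), 2, v$spacing, "/")
}

#' Resample a volume or mask to a target shape
#'
#' Field-of-view preserving resampling (edge-aligned): the physical extent of
#' the grid is unchanged and the spacing is rescaled accordingly. Intensity
#' images are interpolated trilinearly, masks nearest-neighbour so outputs
#' remain strictly 0/1.
#'
#' @param v An `image_volume`, `binary_mask` or `dose_grid`.
#' @param target_shape integer triple, each component >= 2.
#' @return Object of the same class as `v` on the new grid.
#' @export
resample_to_shape <- function(v, target_shape) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(!is.finite(target_shape)) || any(target_shape < 2L))
    stop("target_shape must be 3 integers >= 2", call. = FALSE)
  d <- grid_shape(v)
  out_spacing <- v$spacing * d / target_shape
  # voxel-centre origin shifts so that outer grid edges coincide
  out_origin <- v$origin + (out_spacing - v$spacing) / 2
  nearest <- inherits(v, "binary_mask")
  arr <- cpp_resample_grid(array(as.double(v$voxels), d), d,
                           v$spacing, v$origin,
                           target_shape, out_spacing, out_origin,
                           nearest, TRUE, HU_AIR)
  if (inherits(v, "binary_mask"))
    binary_mask(array(as.integer(arr), target_shape), out_spacing, out_origin)
  else if (inherits(v, "dose_grid"))
    dose_grid(arr, out_spacing, out_origin)
  else image_volume(arr, out_spacing, out_origin)
}

# resample any volume onto the grid of `target` (trilinear or nearest)
resample_to_grid <- function(v, target, fill = HU_AIR) {
  d <- grid_shape(v); dt <- grid_shape(target)
  nearest <- inherits(v, "binary_mask")
  arr <- cpp_resample_grid(array(as.double(v$voxels), d), d, v$spacing, v$origin,
                           as.integer(dt), target$spacing, target$origin,
                           nearest, FALSE, if (nearest) 0 else fill)
  if (inherits(v, "binary_mask"))
    binary_mask(array(as.integer(arr), dt), target$spacing, target$origin)
  else if (inherits(v, "dose_grid"))
    dose_grid(pmax(arr, 0), target$spacing, target$origin)
  else image_volume(arr, target$spacing, target$origin)
}

#' Warp an image with a deformation field
#'
#' `out(x) = moving(x + u(x))` with trilinear interpolation; the displacement
#' field lives on the fixed (output) grid in mm. Samples falling outside the
#' moving grid take -1024 HU.
#'
#' @param moving An `image_volume`.
#' @param dvf A `deformation_field` on the output grid.
#' @param fill fill value for out-of-bounds samples.
#' @return The warped `image_volume` on the fixed grid.
#' @export
warp <- function(moving, dvf, fill = HU_AIR) {
  if (!inherits(dvf, "deformation_field")) stop("dvf must be a deformation_field", call. = FALSE)
  if (!same_grid(moving, dvf)) stop_grid_mismatch("moving image and DVF")
  d <- grid_shape(moving)
  u <- dvf$displacement
  arr <- cpp_warp(v_arr(moving), d, u[, , , 1], u[, , , 2], u[, , , 3],
                  moving$spacing, fill)
  image_volume(arr, moving$spacing, moving$origin)
}

v_arr <- function(v) array(as.double(v$voxels), grid_shape(v))

#' Apply a rigid transform to a volume
#'
#' Resamples `v` under the rigid map `T(q) = R (q - c) + c + t` (rotation
#' about the grid centre `c`), trilinear interpolation, -1024 HU fill.
#'
#' @param v An `image_volume` or `binary_mask`.
#' @param t A `rigid_transform`.
#' @return Same class as `v`, on the same grid.
#' @export
apply_rigid <- function(v, t) {
  if (!inherits(t, "rigid_transform")) stop("t must be a rigid_transform", call. = FALSE)
  if (all(t$rotation == 0) && all(t$translation == 0)) return(v)  # exact identity
  d <- grid_shape(v)
  nearest <- inherits(v, "binary_mask")
  arr <- cpp_rigid_resample(v_arr(v), d, v$spacing, t$rotation, t$translation,
                            if (nearest) 0 else HU_AIR, nearest)
  if (nearest) binary_mask(array(as.integer(arr), d), v$spacing, v$origin)
  else image_volume(arr, v$spacing, v$origin)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform (composition yields the identity).
#' @export
invert_rigid <- function(t) {
  R <- euler_matrix(t$rotation)
  # inverse of p -> R(p - c) + c + t is p -> R^T (p - c - t) + c, which in the
  # same parameterisation has rotation R^T and translation -R^T t.
  Rt <- t(R)
  ang <- matrix_to_euler(Rt)
  rigid_transform(ang, as.numeric(-Rt %*% t$translation))
}

euler_matrix <- function(rot_deg) {
  a <- rot_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ay <- asin(sy)
  if (abs(cos(ay)) > 1e-8) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {
    ax <- atan2(-R[2, 3], R[2, 2])
    az <- 0
  }
  c(ax, ay, az) * 180 / pi
}

# ---------------------------------------------------------------- file I/O

sidecar_write <- function(v, path, kind) {
  d <- grid_shape(v)
  obj <- list(kind = kind, dim = d, spacing = v$spacing, origin = v$origin,
              voxels = as.numeric(v$voxels))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

sidecar_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(obj$dim)
  list(voxels = array(as.numeric(obj$voxels), d),
       spacing = as.numeric(obj$spacing), origin = as.numeric(obj$origin))
}

is_json_path <- function(path) grepl("\\.json$", path, ignore.case = TRUE)

nifti_write <- function(v, path) {
  arr <- v_arr(v)
  aff <- rbind(cbind(diag(v$spacing), v$origin), c(0, 0, 0, 1))
  nim <- RNifti::asNifti(arr)
  nim <- RNifti::`sform<-`(nim, structure(aff, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(diag(lin)), 1))
    stop(sprintf("NIfTI affine in '%s' is not axis-aligned scaling+translation", path),
         call. = FALSE)
  spacing <- diag(lin)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("non-positive voxel spacing in '%s'", path), call. = FALSE)
  arr <- array(as.double(img), dim(img)[1:3])
  list(voxels = arr, spacing = as.numeric(spacing), origin = as.numeric(aff[1:3, 4]))
}

#' Read / write volumes, masks and dose grids
#'
#' NIfTI (`.nii` / `.nii.gz`) with the affine restricted to axis-aligned
#' scaling plus translation; a plain-JSON sidecar format (`.json`) is
#' accepted for raw-array fixtures. Round trips preserve voxels bit-exactly
#' and spacing/origin to within 1e-6 mm. Dose is stored in cGy with no unit
#' rescaling.
#'
#' @param path file path.
#' @param v object to write.
#' @return `read_volume` returns an `image_volume`; `read_mask` a
#'   `binary_mask`; `read_dose` a `dose_grid`. Writers return `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  r <- if (is_json_path(path)) sidecar_read(path) else nifti_read(path)
  if (any(r$spacing <= 0)) stop(sprintf("non-positive voxel spacing in '%s'", path), call. = FALSE)
  image_volume(r$voxels, r$spacing, r$origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  r <- if (is_json_path(path)) sidecar_read(path) else nifti_read(path)
  vox <- r$voxels
  if (!all(vox %in% c(0, 1)))
    stop(sprintf("'%s' is not a binary mask", path), call. = FALSE)
  binary_mask(array(as.integer(vox), dim(vox)), r$spacing, r$origin)
}

#' @rdname read_volume
#' @export
read_dose <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  r <- if (is_json_path(path)) sidecar_read(path) else nifti_read(path)
  dose_grid(r$voxels, r$spacing, r$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, "lattice_grid") || inherits(v, "deformation_field"))
    stop("v must be an image_volume, binary_mask or dose_grid", call. = FALSE)
  kind <- class(v)[1]
  if (is_json_path(path)) sidecar_write(v, path, kind) else nifti_write(v, path)
}

#' Write / read a deformation field (4D NIfTI, mm)
#' @param dvf a `deformation_field`.
#' @inheritParams read_volume
#' @export
write_dvf <- function(dvf, path) {
  arr <- dvf$displacement
  aff <- rbind(cbind(diag(dvf$spacing), dvf$origin), c(0, 0, 0, 1))
  nim <- RNifti::asNifti(arr)
  nim <- RNifti::`sform<-`(nim, structure(aff, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) stop("expected a 4D 3-component field", call. = FALSE)
  deformation_field(array(as.double(img), d), diag(aff[1:3, 1:3]), aff[1:3, 4])
}
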