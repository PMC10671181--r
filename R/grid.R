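#' 3D voxel grid
#'
#' The common spatial currency of the package: a 3D scalar array together
#' with its voxel spacing, world-space origin and an orthonormal direction
#' matrix. World coordinates follow the RAS convention and refer to voxel
#' centres; array indices are 1-based, so voxel \code{(1,1,1)} sits at
#' \code{origin}.
#'
#' @param values numeric 3D array.
#' @param spacing positive numeric triple, voxel edge lengths in mm.
#' @param origin numeric triple, world coordinate (mm) of the first voxel
#'   centre.
#' @param orientation 3x3 orthonormal direction matrix mapping voxel axes to
#'   world axes. Identity (the default) means array axes are aligned with
#'   R-A-S.
#' @param units unit label for the voxel values; \code{"Bq/mL"} for activity
#'   images, \code{"SUV"} after conversion, \code{"TBR"} after background
#'   normalisation.
#' @return an object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       orientation = diag(3), units = "Bq/mL") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite numeric triple")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be a 3x3 orthonormal matrix")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         orientation = orientation, units = units),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  %s voxels @ %s mm  [%s]\n",
              x$units,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste0("range ", paste(format(range(x$values), digits = 4),
                                     collapse = " .. "))))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Binary region mask
#'
#' A labelled binary region on the same geometry as a reference
#' [voxel_grid()]: biological tumour volume (BTV), contralateral control
#' VOI, contrast-enhancing tumour, liver, salivary glands, overlap region,
#' or the brain itself.
#'
#' @param values logical (or 0/1) 3D array.
#' @param reference a [voxel_grid()] supplying the geometry, or `NULL` if
#'   `spacing`/`origin`/`orientation` are given directly.
#' @param label region name.
#' @inheritParams voxel_grid
#' @return an object of class \code{pet_mask}.
#' @export
pet_mask <- function(values, reference = NULL, label = "region",
                     spacing = NULL, origin = NULL, orientation = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask `values` must be a 3D array")
  v <- as.vector(values)
  if (!is.logical(values)) {
    if (!all(v %in% c(0, 1)))
      stop("mask values must be binary (0/1); found other values")
    values <- array(v == 1, dim(values))
  }
  if (!is.null(reference)) {
    stopifnot(is_voxel_grid(reference))
    if (!all(dim(values) == dim(reference$values)))
      stop("mask shape ", paste(dim(values), collapse = "x"),
           " does not match reference grid ",
           paste(dim(reference$values), collapse = "x"))
    spacing <- reference$spacing
    origin <- reference$origin
    orientation <- reference$orientation
  }
  if (is.null(spacing) || is.null(origin))
    stop("either `reference` or explicit geometry must be supplied")
  if (is.null(orientation)) orientation <- diag(3)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = as.matrix(orientation),
         label = label),
    class = "pet_mask"
  )
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> '%s'  %d / %d voxels (%.0f mm^3)\n",
              x$label, sum(x$values), length(x$values),
              sum(x$values) * prod(x$spacing)))
  invisible(x)
}

is_pet_mask <- function(x) inherits(x, "pet_mask")

#' Number of voxels / volume of a mask
#'
#' @param mask a [pet_mask()].
#' @return `mask_voxels`: integer voxel count. `mask_volume`: volume in mm^3
#'   (voxel count times voxel volume).
#' @export
mask_voxels <- function(mask) {
  stopifnot(is_pet_mask(mask))
  sum(mask$values)
}

#' @rdname mask_voxels
#' @export
mask_volume <- function(mask) {
  stopifnot(is_pet_mask(mask))
  sum(mask$values) * prod(mask$spacing)
}

# TRUE when two grid-like objects share shape, spacing, origin and
# orientation to within tol.
same_geometry <- function(a, b, tol = 1e-4) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

check_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(what, " are not on the same voxel geometry ",
         "(shape/spacing/origin/orientation must match)")
  invisible(TRUE)
}

# World coordinates (3 x n matrix) of 1-based voxel indices (n x 3).
voxel_to_world <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3L)
  t(grid$orientation %*% (t(idx - 1) * grid$spacing) + grid$origin)
}

# Continuous 1-based voxel indices (n x 3) of world coordinates (n x 3).
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  t((crossprod(grid$orientation, t(xyz) - grid$origin)) / grid$spacing) + 1
}

# World coordinate of the geometric centre of the grid.
grid_centre <- function(grid) {
  as.numeric(voxel_to_world(grid, matrix((dim(grid$values) + 1) / 2, 1)))
}
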