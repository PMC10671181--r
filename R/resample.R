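#' Resample a grid through a rigid transform onto a reference geometry
#'
#' For every voxel centre of `reference`, the world point is pulled back
#' through the inverse of `transform` (which maps `grid` space to
#' `reference` space) and `grid` is sampled there. `"trilinear"`
#' interpolation is used for images and `"nearest"` for binary masks, so
#' masks remain binary and trilinear output never exceeds the input range.
#' Points falling outside `grid`'s field of view take `fill`.
#'
#' @param grid the moving [voxel_grid()] (or [pet_mask()]) to resample.
#' @param transform a [rigid_transform()] mapping `grid` to `reference`
#'   world space; identity by default.
#' @param reference a [voxel_grid()] (or mask) defining the output geometry.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value assigned outside the moving field of view.
#' @return a [voxel_grid()] on `reference`'s geometry (a [pet_mask()] when
#'   `grid` is a mask).
#' @export
resample <- function(grid, transform = rigid_transform(), reference,
                     interpolation = c("trilinear", "nearest"), fill = 0) {
  is_mask <- is_pet_mask(grid)
  stopifnot(is_voxel_grid(grid) || is_mask)
  if (!(is_voxel_grid(reference) || is_pet_mask(reference)))
    stop("`reference` must be a voxel_grid or pet_mask")
  if (!inherits(transform, "rigid_transform"))
    stop("`transform` must be a rigid_transform")
  interpolation <- match.arg(interpolation)
  if (is_mask && interpolation == "trilinear")
    interpolation <- "nearest"

  vals <- if (is_mask) array(as.numeric(grid$values), dim(grid$values))
          else grid$values
  dims <- dim(vals)
  ref_dims <- dim(reference$values)

  ref_idx <- as.matrix(expand.grid(i = seq_len(ref_dims[1]),
                                   j = seq_len(ref_dims[2]),
                                   k = seq_len(ref_dims[3])))
  world <- voxel_to_world(reference, ref_idx)
  moving_world <- apply_transform(invert_transform(transform), world)
  ci <- world_to_voxel(grid, moving_world)

  out <- sample_grid_at(vals, dims, ci, interpolation, fill)
  out <- array(out, ref_dims)

  if (is_mask) {
    pet_mask(array(out == 1, ref_dims), label = grid$label,
             spacing = reference$spacing, origin = reference$origin,
             orientation = reference$orientation)
  } else {
    voxel_grid(out, spacing = reference$spacing, origin = reference$origin,
               orientation = reference$orientation, units = grid$units)
  }
}

# Sample `vals` (array with dim `dims`) at continuous 1-based indices `ci`
# (n x 3). Vectorised; out-of-FOV points take `fill`.
sample_grid_at <- function(vals, dims, ci, interpolation, fill) {
  eps <- 1e-9
  n <- nrow(ci)
  out <- rep(fill, n)
  if (interpolation == "nearest") {
    ri <- round(ci)
    ok <- ri[, 1] >= 1 & ri[, 1] <= dims[1] &
          ri[, 2] >= 1 & ri[, 2] <= dims[2] &
          ri[, 3] >= 1 & ri[, 3] <= dims[3]
    lin <- ri[ok, 1] + (ri[ok, 2] - 1) * dims[1] +
      (ri[ok, 3] - 1) * dims[1] * dims[2]
    out[ok] <- vals[lin]
    return(out)
  }
  ok <- ci[, 1] >= 1 - eps & ci[, 1] <= dims[1] + eps &
        ci[, 2] >= 1 - eps & ci[, 2] <= dims[2] + eps &
        ci[, 3] >= 1 - eps & ci[, 3] <= dims[3] + eps
  if (!any(ok)) return(out)
  p <- ci[ok, , drop = FALSE]
  # clamp so that floor lands on a valid lower corner even at the far face
  p[, 1] <- pmin(pmax(p[, 1], 1), dims[1])
  p[, 2] <- pmin(pmax(p[, 2], 1), dims[2])
  p[, 3] <- pmin(pmax(p[, 3], 1), dims[3])
  i0 <- pmin(floor(p[, 1]), dims[1] - 1); fx <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), dims[2] - 1); fy <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), dims[3] - 1); fz <- p[, 3] - k0
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  base <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  v000 <- vals[base];           v100 <- vals[base + 1]
  v010 <- vals[base + nx];      v110 <- vals[base + nx + 1]
  v001 <- vals[base + nxy];     v101 <- vals[base + nxy + 1]
  v011 <- vals[base + nx + nxy]; v111 <- vals[base + nx + nxy + 1]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx       * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy       * (1 - fz) +
    v110 * fx       * fy       * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx       * (1 - fy) * fz +
    v011 * (1 - fx) * fy       * fz +
    v111 * fx       * fy       * fz
  out
}

# Block-mean downsampling by an integer factor per axis; spacing grows by
# the factor and the origin shifts to the new voxel centres. Used by the
# multi-resolution registration pyramid.
downsample_grid <- function(grid, factor) {
  stopifnot(is_voxel_grid(grid), factor >= 1)
  if (factor == 1) return(grid)
  dims <- dim(grid$values)
  nd <- pmax(dims %/% factor, 1L)
  v <- grid$values[seq_len(nd[1] * factor),
                   seq_len(nd[2] * factor),
                   seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  v <- apply(v, c(2, 4, 6), mean)
  voxel_grid(v, spacing = grid$spacing * factor,
             origin = grid$origin +
               as.numeric(grid$orientation %*% (grid$spacing * (factor - 1) / 2)),
             orientation = grid$orientation, units = grid$units)
}
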