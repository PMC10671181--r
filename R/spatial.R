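#' Restrict a grid to the brain
#'
#' Voxels outside the brain mask are marked invalid (`NA`), not zeroed, so
#' region statistics are unaffected by the masking convention: a region mean
#' is always taken over valid voxels only, and a region that strays outside
#' the brain raises an error rather than silently averaging zeros.
#'
#' @param grid a [voxel_grid()].
#' @param brain a [pet_mask()] on the same geometry.
#' @return a [voxel_grid()] with out-of-brain voxels set to `NA`.
#' @export
apply_brain_mask <- function(grid, brain) {
  stopifnot(is_voxel_grid(grid), is_pet_mask(brain))
  check_same_geometry(grid, brain, "grid and brain mask")
  v <- grid$values
  v[!brain$values] <- NA_real_
  voxel_grid(v, spacing = grid$spacing, origin = grid$origin,
             orientation = grid$orientation, units = grid$units)
}

# Array dimension most aligned with the world left-right (x) axis.
lr_axis <- function(obj) which.max(abs(obj$orientation[1, ]))

#' Mirror a mask across the mid-sagittal plane
#'
#' Reflects the mask voxel-wise across the central grid plane orthogonal to
#' the left-right axis of the reference geometry (the array axis most
#' aligned with world x). This supports contralateral control-region
#' construction; for clinical data it presumes prior AC-PC/mid-sagittal
#' alignment of the reference grid.
#'
#' @param mask a [pet_mask()].
#' @param reference optional grid-like object defining the geometry
#'   (defaults to the mask's own geometry).
#' @return the mirrored [pet_mask()]; mirroring twice returns the original.
#' @export
mirror_across_midsagittal <- function(mask, reference = NULL) {
  stopifnot(is_pet_mask(mask))
  if (!is.null(reference)) check_same_geometry(mask, reference,
                                               "mask and reference")
  ax <- lr_axis(mask)
  idx <- rev(seq_len(dim(mask$values)[ax]))
  v <- switch(ax,
              mask$values[idx, , , drop = FALSE],
              mask$values[, idx, , drop = FALSE],
              mask$values[, , idx, drop = FALSE])
  pet_mask(v, label = paste0(mask$label, "_mirrored"),
           spacing = mask$spacing, origin = mask$origin,
           orientation = mask$orientation)
}

#' Estimate a brain mask from a PET volume
#'
#' Fallback for inputs without a pre-computed brain mask (e.g. phantoms):
#' Otsu threshold, morphological closing, largest connected component,
#' interior hole filling. Dedicated skull-stripping of an anatomical image
#' is upstream tooling and should be preferred on clinical data.
#'
#' @param grid a [voxel_grid()].
#' @param closing_mm radius (mm) of the morphological closing ball.
#' @return a [pet_mask()] labelled `"brain"`.
#' @export
estimate_brain_mask <- function(grid, closing_mm = 4) {
  stopifnot(is_voxel_grid(grid))
  thr <- otsu_threshold(as.vector(grid$values))
  m <- !is.na(grid$values) & grid$values > thr
  m <- dilate_ball(m, closing_mm, grid$spacing)
  m <- erode_ball(m, closing_mm, grid$spacing)
  m <- largest_component(label_components(m, 26), grid$values)
  m <- fill_holes(m)
  pet_mask(m, reference = grid, label = "brain")
}
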