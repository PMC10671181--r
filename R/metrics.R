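#' Region summary statistics
#'
#' Volume, mean and maximum SUV of a region, and -- once a background level
#' is known -- the corresponding tumour-to-brain ratios. Volume is voxel
#' count times voxel volume (mm^3). TBR statistics are the SUV statistics
#' divided by the background, exactly.
#'
#' @param suv a [voxel_grid()] in SUV units.
#' @param region a non-empty [pet_mask()] on the same geometry.
#' @param background_suv_mean optional positive background (control VOI
#'   mean SUV); when supplied, `tbr_mean`/`tbr_max` are filled in.
#' @return a `region_stats` list: `label`, `n_voxels`, `volume_mm3`,
#'   `suv_mean`, `suv_max`, `tbr_mean`, `tbr_max`.
#' @export
region_stats <- function(suv, region, background_suv_mean = NULL) {
  stopifnot(is_voxel_grid(suv), is_pet_mask(region))
  check_same_geometry(suv, region, "SUV image and region")
  n <- mask_voxels(region)
  if (n == 0) stop("empty region: no statistics defined for '",
                   region$label, "'")
  v <- suv$values[region$values]
  if (anyNA(v))
    stop("region '", region$label,
         "' extends outside the valid (brain-masked) field of view")
  out <- list(label = region$label, n_voxels = n,
              volume_mm3 = n * prod(region$spacing),
              suv_mean = mean(v), suv_max = max(v),
              tbr_mean = NA_real_, tbr_max = NA_real_)
  if (!is.null(background_suv_mean)) {
    if (background_suv_mean <= 0) stop("background SUV must be positive")
    out$tbr_mean <- out$suv_mean / background_suv_mean
    out$tbr_max <- out$suv_max / background_suv_mean
  }
  structure(out, class = "region_stats")
}

#' Tumour-to-brain-ratio image
#'
#' Divides an SUV image voxel-wise by the mean SUV of the control VOI, so
#' region TBR statistics equal the region SUV statistics divided by the
#' background.
#'
#' @param suv a [voxel_grid()] in SUV units.
#' @param background_suv_mean positive scalar background.
#' @return a [voxel_grid()] with `units = "TBR"`.
#' @export
tbr_image <- function(suv, background_suv_mean) {
  stopifnot(is_voxel_grid(suv))
  if (!is.finite(background_suv_mean) || background_suv_mean <= 0)
    stop("background SUV mean must be a positive finite scalar")
  voxel_grid(suv$values / background_suv_mean, spacing = suv$spacing,
             origin = suv$origin, orientation = suv$orientation,
             units = "TBR")
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, in \[0, 1\]; symmetric; equal masks
#' give 1 and disjoint masks 0. Undefined (error) when both masks are
#' empty.
#'
#' @param a,b [pet_mask()] objects on the same geometry.
#' @return unitless scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(is_pet_mask(a), is_pet_mask(b))
  check_same_geometry(a, b, "masks")
  na <- mask_voxels(a); nb <- mask_voxels(b)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a$values & b$values) / (na + nb)
}

#' Volumetric ratio of two regions
#'
#' @param vol_a,vol_b volumes in mm^3 (vectorised); `vol_b` must be
#'   positive.
#' @return `vol_a / vol_b`.
#' @export
volumetric_ratio <- function(vol_a, vol_b) {
  if (any(!is.finite(vol_b)) || any(vol_b <= 0))
    stop("volumetric ratio undefined: denominator volume must be positive")
  vol_a / vol_b
}

#' Tumour-to-organ uptake ratios
#'
#' Tumour-to-liver (TLR) and tumour-to-salivary-gland (TSG) style ratios:
#' the BTV SUV mean divided by the organ SUV mean, and the BTV SUV max
#' divided by the organ SUV max.
#'
#' @param btv_stats,organ_stats `region_stats` for the BTV and the organ.
#' @return list with `mean_ratio` and `max_ratio`.
#' @export
organ_ratios <- function(btv_stats, organ_stats) {
  stopifnot(inherits(btv_stats, "region_stats"),
            inherits(organ_stats, "region_stats"))
  if (organ_stats$suv_mean <= 0 || organ_stats$suv_max <= 0)
    stop("organ uptake must be positive to form a tumour-to-organ ratio")
  list(mean_ratio = btv_stats$suv_mean / organ_stats$suv_mean,
       max_ratio = btv_stats$suv_max / organ_stats$suv_max)
}

#' Radionuclide-therapy qualification screen
#'
#' A ligand qualifies for therapeutic application when the tumour dose can
#' plausibly exceed off-target organ dose: TLR_max >= 1.5 and TSG_max >=
#' 1.0 (boundary inclusive). Returns the verdict with the list of failed
#' cutoffs.
#'
#' @param tlr_max tumour-to-liver max ratio.
#' @param tsg_max tumour-to-salivary-gland max ratio.
#' @param tlr_cutoff,tsg_cutoff minimum qualifying values.
#' @return list with `qualifies` (logical) and `reasons` (character vector
#'   of failed cutoffs, empty when qualifying).
#' @export
theranostic_qualification <- function(tlr_max, tsg_max,
                                      tlr_cutoff = 1.5, tsg_cutoff = 1.0) {
  reasons <- character(0)
  if (is.finite(tlr_max) && tlr_max < tlr_cutoff)
    reasons <- c(reasons, sprintf("TLR_max %.2f < %.2f", tlr_max, tlr_cutoff))
  if (is.finite(tsg_max) && tsg_max < tsg_cutoff)
    reasons <- c(reasons, sprintf("TSG_max %.2f < %.2f", tsg_max, tsg_cutoff))
  list(qualifies = length(reasons) == 0, reasons = reasons)
}

#' Masked voxel-wise Pearson correlation between two images
#'
#' Correlates the two tracers' SUV values over the voxels of a region
#' (typically the overlap of the two BTVs). Voxels pair by identical grid
#' index, so both images must already be resampled to the same geometry.
#' The two-tailed p-value comes from the t transform with n - 2 degrees of
#' freedom.
#'
#' @param suv_a,suv_b [voxel_grid()] objects on the region's geometry.
#' @param region a [pet_mask()] with at least 3 voxels.
#' @return list with `r`, `p_two_sided` and `n`.
#' @export
voxelwise_correlation <- function(suv_a, suv_b, region) {
  stopifnot(is_voxel_grid(suv_a), is_voxel_grid(suv_b), is_pet_mask(region))
  check_same_geometry(suv_a, region, "image A and region")
  check_same_geometry(suv_b, region, "image B and region")
  n <- mask_voxels(region)
  if (n < 3) stop("voxel-wise correlation needs at least 3 region voxels")
  x <- suv_a$values[region$values]
  y <- suv_b$values[region$values]
  pearson_with_p(x, y)
}
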