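#' Segmentation parameters for one tracer
#'
#' Thresholds for the semiautomated biological-tumour-volume (BTV)
#' delineation: an initial absolute SUV threshold identifying avid tissue
#' and a tumour-to-brain-ratio (TBR) threshold applied after background
#' normalisation. Study values: initial SUV 2.2 with TBR 1.7 for the
#' amino-acid (FET) tracer, initial SUV 1.5 with TBR 4.0 for the
#' PSMA-ligand tracer.
#'
#' @param initial_suv_threshold absolute SUV cut identifying candidate avid
#'   voxels (> 0).
#' @param tbr_threshold TBR cut defining the final BTV (> 0).
#' @param min_component_voxels connected components smaller than this are
#'   discarded from the final BTV.
#' @param control_erosion_mm erosion radius applied to the mirrored control
#'   region, mm.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(initial_suv_threshold, tbr_threshold,
                                min_component_voxels = 10,
                                control_erosion_mm = 2) {
  if (initial_suv_threshold <= 0 || tbr_threshold <= 0)
    stop("segmentation thresholds must be strictly positive")
  if (min_component_voxels < 1)
    stop("min_component_voxels must be >= 1")
  if (control_erosion_mm < 0)
    stop("control_erosion_mm must be non-negative")
  structure(list(initial_suv_threshold = initial_suv_threshold,
                 tbr_threshold = tbr_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 control_erosion_mm = control_erosion_mm),
            class = "segmentation_config")
}

#' Preset thresholds per tracer class
#'
#' @param tracer `"fet"` (amino-acid tracer: SUV 2.2 / TBR 1.7) or `"psma"`
#'   (PSMA ligand: SUV 1.5 / TBR 4.0).
#' @param ... overrides passed to [segmentation_config()].
#' @return a [segmentation_config()].
#' @export
default_segmentation_config <- function(tracer = c("fet", "psma"), ...) {
  tracer <- match.arg(tracer)
  args <- switch(tracer,
                 fet = list(initial_suv_threshold = 2.2, tbr_threshold = 1.7),
                 psma = list(initial_suv_threshold = 1.5, tbr_threshold = 4.0))
  do.call(segmentation_config, utils::modifyList(args, list(...)))
}

#' Delineate the biological tumour volume and contralateral control region
#'
#' Semiautomated threshold segmentation in five deterministic steps:
#' \enumerate{
#'   \item candidate avid voxels: brain voxels with SUV >=
#'     `initial_suv_threshold`;
#'   \item tumour seed component: the 26-connected candidate component
#'     containing `seed_point` if given, otherwise the largest candidate
#'     component (ties broken by voxel count, then SUV max, then lowest
#'     linear index);
#'   \item control VOI: the seed component mirrored across the mid-sagittal
#'     plane, eroded by `control_erosion_mm`, with any candidate (avid)
#'     voxels removed -- normal contralateral brain;
#'   \item background SUV: mean SUV over the control VOI;
#'   \item BTV: brain voxels whose SUV / background >= `tbr_threshold`,
#'     restricted to 26-connected components intersecting the seed
#'     component, holes filled, components below `min_component_voxels`
#'     discarded.
#' }
#' The BTV and control VOI are disjoint by construction.
#'
#' @param suv a [voxel_grid()] in SUV units.
#' @param brain a [pet_mask()] on the same geometry.
#' @param config a [segmentation_config()].
#' @param seed_point optional 1-based voxel index triple inside the tumour.
#' @param control_mask optional manual [pet_mask()] overriding the mirrored
#'   control VOI.
#' @return a list with elements `btv` ([pet_mask()]), `control_voi`
#'   ([pet_mask()]), `background_suv_mean` (scalar) and `no_avid_lesion`
#'   (logical). When no voxel reaches the initial threshold the result has
#'   `no_avid_lesion = TRUE` and empty masks -- a finding (enrolment
#'   requires tracer-avid disease), not an error.
#' @export
segment_btv <- function(suv, brain, config, seed_point = NULL,
                        control_mask = NULL) {
  stopifnot(is_voxel_grid(suv), is_pet_mask(brain),
            inherits(config, "segmentation_config"))
  if (!identical(suv$units, "SUV"))
    stop("segmentation expects an SUV image; got units '", suv$units, "'")
  check_same_geometry(suv, brain, "SUV image and brain mask")
  if (mask_voxels(brain) == 0) stop("brain mask is empty")
  dims <- dim(suv$values)
  vals <- suv$values
  vals[is.na(vals)] <- -Inf

  candidate <- brain$values & vals >= config$initial_suv_threshold
  empty <- pet_mask(array(FALSE, dims), reference = suv, label = "btv")
  if (!any(candidate)) {
    return(list(btv = empty,
                control_voi = pet_mask(array(FALSE, dims), reference = suv,
                                       label = "control_voi"),
                background_suv_mean = NA_real_,
                no_avid_lesion = TRUE))
  }

  comp <- label_components(candidate, connectivity = 26)
  if (!is.null(seed_point)) {
    seed_point <- as.integer(round(seed_point))
    if (length(seed_point) != 3L || any(seed_point < 1) ||
        any(seed_point > dims))
      stop("seed_point must be a voxel index triple inside the grid")
    id <- comp[seed_point[1], seed_point[2], seed_point[3]]
    if (id == 0L)
      stop("seed_point does not lie in any avid component; ",
           "pick a voxel with SUV >= the initial threshold")
    seed_comp <- comp == id
  } else {
    seed_comp <- largest_component(comp, vals)
  }

  if (is.null(control_mask)) {
    seed_mask <- pet_mask(seed_comp, reference = suv, label = "seed")
    ctrl <- mirror_across_midsagittal(seed_mask)$values
    if (config$control_erosion_mm > 0)
      ctrl <- erode_ball(ctrl, config$control_erosion_mm, suv$spacing)
    ctrl <- ctrl & brain$values & !candidate
  } else {
    stopifnot(is_pet_mask(control_mask))
    check_same_geometry(suv, control_mask, "SUV image and control mask")
    ctrl <- control_mask$values & brain$values
  }
  if (!any(ctrl))
    stop("empty control VOI: the mirrored tumour region contains no ",
         "normal contralateral voxels; supply a manual control mask")

  background <- mean(suv$values[ctrl], na.rm = FALSE)
  if (!is.finite(background) || background <= 0)
    stop("control VOI background SUV is not positive; ",
         "check brain mask and control region")

  above <- brain$values & (vals / background >= config$tbr_threshold)
  above_comp <- label_components(above, connectivity = 26)
  keep_ids <- setdiff(unique(above_comp[seed_comp & above]), 0L)
  btv <- array(above_comp %in% keep_ids, dims)
  if (any(btv)) {
    btv <- fill_holes(btv) & brain$values
    final_comp <- label_components(btv, connectivity = 26)
    sizes <- tabulate(final_comp[final_comp > 0L])
    small <- which(sizes < config$min_component_voxels)
    if (length(small)) btv[final_comp %in% small] <- FALSE
  }
  ctrl <- ctrl & !btv  # disjointness guarantee

  list(btv = pet_mask(btv, reference = suv, label = "btv"),
       control_voi = pet_mask(ctrl, reference = suv, label = "control_voi"),
       background_suv_mean = background,
       no_avid_lesion = FALSE)
}

#' Voxel-wise conjunction of two masks
#'
#' The overlap region between two BTVs, used for cross-tracer voxel-wise
#' correlation.
#'
#' @param a,b [pet_mask()] objects on the same geometry.
#' @return a [pet_mask()] labelled `"overlap"`.
#' @export
overlap_mask <- function(a, b) {
  stopifnot(is_pet_mask(a), is_pet_mask(b))
  check_same_geometry(a, b, "masks")
  pet_mask(a$values & b$values, label = "overlap",
           spacing = a$spacing, origin = a$origin,
           orientation = a$orientation)
}

#' Load a manually contoured region mask
#'
#' Ingests a pre-drawn binary region (contrast-enhancing tumour, liver,
#' salivary glands, brain) from NIfTI and aligns it to the reference grid
#' by nearest-neighbour resampling, so it remains binary. Continuous-valued
#' files are rejected.
#'
#' @param path NIfTI file with values in \{0, 1\}.
#' @param reference a [voxel_grid()] defining the target geometry.
#' @param label region label.
#' @return a [pet_mask()] on `reference`'s geometry. An empty mask is
#'   carried with a warning, not an error.
#' @export
load_region_mask <- function(path, reference, label = "region") {
  stopifnot(is_voxel_grid(reference))
  m <- read_mask_nifti(path, label = label)
  if (!same_geometry(m, reference))
    m <- resample(m, rigid_transform(), reference, interpolation = "nearest")
  if (mask_voxels(m) == 0)
    warning("region mask '", label, "' is empty after alignment")
  m
}
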