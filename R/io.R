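#' Read and write voxel grids as NIfTI-1
#'
#' Volumes are exchanged as NIfTI-1 (optionally gzipped). The world affine is
#' stored in both the qform and sform (code 2, "aligned"); on read the xform
#' is decomposed back into spacing, origin and an orthonormal direction
#' matrix.
#'
#' @param grid a [voxel_grid()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param units unit label to attach to the grid read from `path` (NIfTI
#'   carries no activity/SUV unit field).
#' @return `write_grid_nifti` returns `path` invisibly; `read_grid_nifti`
#'   returns a [voxel_grid()].
#' @export
write_grid_nifti <- function(grid, path) {
  stopifnot(is_voxel_grid(grid) || is_pet_mask(grid))
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.integer(vals), dim(vals))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  aff <- grid_affine(grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_grid_nifti
#' @export
read_grid_nifti <- function(path, units = "Bq/mL") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  geo <- affine_to_geometry(aff)
  vals <- array(as.numeric(img), dim(img)[1:3])
  voxel_grid(vals, spacing = geo$spacing, origin = geo$origin,
             orientation = geo$orientation, units = units)
}

#' Read a binary mask from NIfTI-1
#'
#' @param path NIfTI file holding a binary (0/1) volume.
#' @param label region label to attach.
#' @return a [pet_mask()].
#' @export
read_mask_nifti <- function(path, label = "region") {
  g <- read_grid_nifti(path, units = "binary")
  v <- as.vector(g$values)
  if (!all(v %in% c(0, 1)))
    stop("mask file ", path, " is not binary: values outside {0,1} found")
  pet_mask(array(v == 1, dim(g$values)), label = label,
           spacing = g$spacing, origin = g$origin,
           orientation = g$orientation)
}

# 4x4 RAS affine of a grid-like object (voxel index 0-based in NIfTI terms).
grid_affine <- function(grid) {
  rbind(cbind(grid$orientation %*% diag(grid$spacing), grid$origin),
        c(0, 0, 0, 1))
}

affine_to_geometry <- function(aff) {
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) stop("degenerate affine in NIfTI header")
  list(spacing = spacing,
       orientation = m %*% diag(1 / spacing),
       origin = aff[1:3, 4])
}

#' Read and write acquisition metadata sidecars
#'
#' One JSON sidecar per PET series carries the fields needed for SUV
#' conversion: tracer name, half-life (min), injected dose (Bq), body weight
#' (g) and ISO-8601 injection / scan-start times.
#'
#' @param acq an [acquisition_record()].
#' @param path JSON file path.
#' @return `read_acquisition_json` returns an [acquisition_record()].
#' @export
write_acquisition_json <- function(acq, path) {
  stopifnot(inherits(acq, "acquisition_record"))
  jsonlite::write_json(
    list(tracer = acq$tracer,
         half_life_min = acq$half_life_min,
         injected_dose_Bq = acq$injected_dose_Bq,
         body_weight_g = acq$body_weight_g,
         injection_time_iso8601 = format(acq$injection_time,
                                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         scan_start_time_iso8601 = format(acq$scan_start_time,
                                          "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_acquisition_json
#' @export
read_acquisition_json <- function(path) {
  if (!file.exists(path))
    stop("metadata absent: sidecar file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tracer", "half_life_min", "injected_dose_Bq", "body_weight_g",
            "injection_time_iso8601", "scan_start_time_iso8601")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("metadata absent: sidecar ", path, " lacks field(s): ",
         paste(missing, collapse = ", "))
  acquisition_record(
    tracer = x$tracer,
    half_life_min = x$half_life_min,
    injected_dose_Bq = x$injected_dose_Bq,
    body_weight_g = x$body_weight_g,
    injection_time = as.POSIXct(x$injection_time_iso8601,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    scan_start_time = as.POSIXct(x$scan_start_time_iso8601,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}
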