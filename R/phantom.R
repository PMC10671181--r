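#' Specification of a synthetic paired-tracer brain-PET phantom
#'
#' Defines a fully synthetic scene with known ground truth: a spherical
#' "brain" of low uniform uptake, an ellipsoidal "tumour" of elevated
#' uptake reaching a configurable tumour-to-brain ratio (TBR) per tracer, a
#' configurable voxel-wise cross-tracer correlation inside the tumour, a
#' rigid inter-session misalignment of the second tracer, and additive
#' Gaussian noise. Per-tracer parameters are length-2 vectors ordered
#' (tracer A, tracer B); tracer A is the amino-acid-like tracer that
#' defines the reference frame, tracer B the PSMA-ligand-like tracer.
#'
#' The grid is centred on the world origin and the brain sphere sits at the
#' origin, so the scene is left-right symmetric apart from the tumour --
#' the geometry contralateral mirroring assumes.
#'
#' Tumour voxel values for the two tracers are drawn from a bivariate
#' Gaussian with correlation `cross_tracer_rho`, marginal means
#' `background_mean * tumour_tbr_target` and marginal standard deviations
#' `background_sd * tumour_tbr_target` (uptake heterogeneity scales with
#' uptake level).
#'
#' @param grid_shape integer triple of voxel counts.
#' @param spacing_mm positive triple, mm.
#' @param brain_radius_mm brain sphere radius, mm.
#' @param tumour_centre_mm tumour ellipsoid centre in world mm (the brain
#'   is centred at the origin).
#' @param tumour_radii_mm ellipsoid semi-axes, mm.
#' @param background_mean,background_sd per-tracer normal-brain SUV level
#'   and spread.
#' @param tumour_tbr_target per-tracer target TBR (> 1).
#' @param cross_tracer_rho correlation of tumour uptake between tracers,
#'   in \[-1, 1\].
#' @param misalignment a [rigid_transform()]: the true transform mapping
#'   the acquired tracer-B grid into the tracer-A frame.
#' @param noise_sd additive Gaussian SUV noise inside the brain; length 1
#'   or 2 (per tracer).
#' @param injected_dose_Bq,body_weight_g,injection_to_scan_min,half_life_min
#'   per-tracer acquisition parameters used to encode the scene in
#'   activity units.
#' @param tracer_names length-2 character vector.
#' @param rng_seed integer seed; identical specs produce bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(2.5, 2.5, 2.5),
                         brain_radius_mm = 70,
                         tumour_centre_mm = c(28, 12, 6),
                         tumour_radii_mm = c(16, 13, 11),
                         background_mean = c(1.3, 0.10),
                         background_sd = c(0.13, 0.01),
                         tumour_tbr_target = c(2.3, 21),
                         cross_tracer_rho = 0.51,
                         misalignment = rigid_transform(
                           angles_rad = c(2, -1.5, 1) * pi / 180,
                           translation_mm = c(3, -2, 1.5)),
                         noise_sd = 0,
                         injected_dose_Bq = c(250e6, 150e6),
                         body_weight_g = c(70000, 70000),
                         injection_to_scan_min = c(20, 45),
                         half_life_min = c(109.77, 67.71),
                         tracer_names = c("FET", "PSMA-617"),
                         rng_seed = 1L) {
  two <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, 2)
    if (length(x) != 2L) stop("`", nm, "` must have length 1 or 2")
    x
  }
  spec <- list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    brain_radius_mm = brain_radius_mm,
    tumour_centre_mm = as.numeric(tumour_centre_mm),
    tumour_radii_mm = as.numeric(tumour_radii_mm),
    background_mean = two(background_mean, "background_mean"),
    background_sd = two(background_sd, "background_sd"),
    tumour_tbr_target = two(tumour_tbr_target, "tumour_tbr_target"),
    cross_tracer_rho = cross_tracer_rho,
    misalignment = misalignment,
    noise_sd = two(noise_sd, "noise_sd"),
    injected_dose_Bq = two(injected_dose_Bq, "injected_dose_Bq"),
    body_weight_g = two(body_weight_g, "body_weight_g"),
    injection_to_scan_min = two(injection_to_scan_min,
                                "injection_to_scan_min"),
    half_life_min = two(half_life_min, "half_life_min"),
    tracer_names = as.character(tracer_names),
    rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  pos <- c("spacing_mm", "brain_radius_mm", "tumour_radii_mm",
           "background_mean", "tumour_tbr_target", "injected_dose_Bq",
           "body_weight_g", "injection_to_scan_min", "half_life_min")
  for (nm in pos)
    if (any(!is.finite(s[[nm]])) || any(s[[nm]] <= 0))
      stop("phantom spec field `", nm, "` must be strictly positive")
  if (any(s$grid_shape < 8))
    stop("grid_shape must be at least 8 voxels per axis")
  if (any(s$background_sd < 0) || any(s$noise_sd < 0))
    stop("background_sd and noise_sd must be non-negative")
  if (any(s$tumour_tbr_target <= 1))
    stop("tumour_tbr_target must exceed 1 (tumour must stand out)")
  if (abs(s$cross_tracer_rho) > 1)
    stop("cross_tracer_rho must lie in [-1, 1], got ", s$cross_tracer_rho)
  if (!inherits(s$misalignment, "rigid_transform"))
    stop("misalignment must be a rigid_transform")
  # sufficient containment check: ellipsoid bounding sphere inside brain
  if (sqrt(sum(s$tumour_centre_mm^2)) + max(s$tumour_radii_mm) >
      s$brain_radius_mm)
    stop("tumour ellipsoid extends outside the brain sphere: ",
         "move tumour_centre_mm or shrink tumour_radii_mm/brain_radius_mm")
  invisible(s)
}

phantom_acquisition <- function(spec, which) {
  t0 <- as.POSIXct("2020-06-01 10:00:00", tz = "UTC")
  acquisition_record(
    tracer = spec$tracer_names[which],
    half_life_min = spec$half_life_min[which],
    injected_dose_Bq = spec$injected_dose_Bq[which],
    body_weight_g = spec$body_weight_g[which],
    injection_time = t0,
    scan_start_time = t0 + spec$injection_to_scan_min[which] * 60)
}

#' Generate a synthetic paired-tracer phantom
#'
#' Builds the SUV-scale scene defined by a [phantom_spec()], misaligns the
#' tracer-B acquisition by the spec's rigid transform, and encodes both
#' acquisitions in activity units (Bq/mL) by inverting the SUV formula with
#' the spec's dose/weight/timing -- so that downstream conversion with the
#' bundled acquisition records recovers the intended SUV scene.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_bundle`: per-tracer activity grids (`activity_a`,
#'   `activity_b`) and acquisition records (`acq_a`, `acq_b`), ground-truth
#'   `tumour_mask` and `brain_mask` on the reference (tracer A) grid, the
#'   true `misalignment` transform, the intended SUV scenes
#'   (`suv_scene_a`, `suv_scene_b`, reference frame) and the generating
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$rng_seed)

  dims <- spec$grid_shape
  origin <- -(dims - 1) / 2 * spec$spacing_mm
  ref <- voxel_grid(array(0, dims), spacing = spec$spacing_mm,
                    origin = origin, units = "SUV")
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  w <- voxel_to_world(ref, idx)
  brain <- array(rowSums(w^2) <= spec$brain_radius_mm^2, dims)
  e <- sweep(w, 2, spec$tumour_centre_mm)
  tumour <- array(rowSums(sweep(e, 2, spec$tumour_radii_mm, "/")^2) <= 1,
                  dims)
  tumour <- tumour & brain

  n_bg <- sum(brain & !tumour)
  n_tm <- sum(tumour)
  rho <- spec$cross_tracer_rho

  scene <- list()
  bg_draw <- list(stats::rnorm(n_bg), stats::rnorm(n_bg))
  z1 <- stats::rnorm(n_tm)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_tm)
  zt <- list(z1, z2)
  for (t in 1:2) {
    v <- array(0, dims)
    v[brain & !tumour] <- spec$background_mean[t] +
      spec$background_sd[t] * bg_draw[[t]]
    v[tumour] <- spec$background_mean[t] * spec$tumour_tbr_target[t] +
      spec$background_sd[t] * spec$tumour_tbr_target[t] * zt[[t]]
    if (spec$noise_sd[t] > 0)
      v[brain] <- v[brain] + stats::rnorm(sum(brain), 0, spec$noise_sd[t])
    scene[[t]] <- voxel_grid(v, spacing = spec$spacing_mm, origin = origin,
                             units = "SUV")
  }

  # acquired tracer-B image: the reference-frame scene observed on a grid
  # misaligned by the true transform (registration should recover it)
  acquired_b <- resample(scene[[2]], invert_transform(spec$misalignment),
                         reference = ref, interpolation = "trilinear")
  acquired_b$units <- "SUV"

  acq_a <- phantom_acquisition(spec, 1)
  acq_b <- phantom_acquisition(spec, 2)

  structure(
    list(activity_a = suv_to_activity(scene[[1]], acq_a),
         activity_b = suv_to_activity(acquired_b, acq_b),
         acq_a = acq_a, acq_b = acq_b,
         tumour_mask = pet_mask(tumour, reference = ref, label = "tumour"),
         brain_mask = pet_mask(brain, reference = ref, label = "brain"),
         misalignment = spec$misalignment,
         suv_scene_a = scene[[1]], suv_scene_b = scene[[2]],
         spec = spec),
    class = "phantom_bundle")
}

#' Write / read a phantom bundle as NIfTI + JSON files
#'
#' `write_phantom` emits one NIfTI-1 file per grid and mask, one JSON
#' acquisition sidecar per tracer, the true misalignment transform and a
#' manifest recording the full generating spec (including the seed), so a
#' bundle can be regenerated bit-identically from the manifest alone.
#'
#' @param bundle a `phantom_bundle` from [generate_phantom()].
#' @param directory output directory (created if needed).
#' @return `write_phantom` returns the directory invisibly; `read_phantom`
#'   returns a `phantom_bundle` re-read from disk;
#'   `phantom_spec_from_manifest` returns the [phantom_spec()] recorded in
#'   a manifest file.
#' @export
write_phantom <- function(bundle, directory) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_grid_nifti(bundle$activity_a, p("tracerA_activity.nii.gz"))
  write_grid_nifti(bundle$activity_b, p("tracerB_activity.nii.gz"))
  write_grid_nifti(bundle$tumour_mask, p("tumour_mask.nii.gz"))
  write_grid_nifti(bundle$brain_mask, p("brain_mask.nii.gz"))
  write_acquisition_json(bundle$acq_a, p("tracerA.json"))
  write_acquisition_json(bundle$acq_b, p("tracerB.json"))
  write_transform_json(bundle$misalignment, p("misalignment.json"))
  s <- bundle$spec
  manifest <- s[setdiff(names(s), "misalignment")]
  manifest$misalignment <- list(angles_rad = s$misalignment$angles_rad,
                                translation_mm = s$misalignment$translation_mm,
                                centre_mm = s$misalignment$centre_mm)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(directory)
}

#' @rdname write_phantom
#' @export
phantom_spec_from_manifest <- function(path) {
  if (!file.exists(path)) stop("metadata absent: manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$misalignment <- rigid_transform(m$misalignment$angles_rad,
                                    m$misalignment$translation_mm,
                                    m$misalignment$centre_mm)
  do.call(phantom_spec, m)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("tracerA_activity.nii.gz", "tracerB_activity.nii.gz",
              "tracerA.json", "tracerB.json"))
    if (!file.exists(p(f)))
      stop("metadata absent: required phantom file missing: ", f)
  spec <- phantom_spec_from_manifest(p("manifest.json"))
  structure(
    list(activity_a = read_grid_nifti(p("tracerA_activity.nii.gz")),
         activity_b = read_grid_nifti(p("tracerB_activity.nii.gz")),
         acq_a = read_acquisition_json(p("tracerA.json")),
         acq_b = read_acquisition_json(p("tracerB.json")),
         tumour_mask = read_mask_nifti(p("tumour_mask.nii.gz"), "tumour"),
         brain_mask = read_mask_nifti(p("brain_mask.nii.gz"), "brain"),
         misalignment = read_transform_json(p("misalignment.json")),
         suv_scene_a = NULL, suv_scene_b = NULL,
         spec = spec),
    class = "phantom_bundle")
}
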