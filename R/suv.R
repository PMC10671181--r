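#' PET acquisition metadata
#'
#' The per-series metadata that parameterises SUV conversion: isotope
#' half-life, injected dose, patient body weight and the injection and
#' scan-start timestamps whose difference is the decay interval. Reference
#' half-lives: 109.77 min for fluorine-18, 67.71 min for gallium-68.
#'
#' @param tracer tracer label, e.g. `"FET"` or `"PSMA-617"`.
#' @param half_life_min isotope half-life in minutes (> 0).
#' @param injected_dose_Bq injected activity in Bq (> 0).
#' @param body_weight_g patient body weight in grams (> 0).
#' @param injection_time,scan_start_time `POSIXct` timestamps;
#'   `scan_start_time` must not precede `injection_time`.
#' @return an object of class `acquisition_record`.
#' @export
acquisition_record <- function(tracer, half_life_min, injected_dose_Bq,
                               body_weight_g, injection_time,
                               scan_start_time) {
  num_fields <- list(half_life_min = half_life_min,
                     injected_dose_Bq = injected_dose_Bq,
                     body_weight_g = body_weight_g)
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("metadata absent: field '", nm, "' is missing or NA")
    if (!is.finite(v) || v <= 0)
      stop("field '", nm, "' must be a strictly positive number, got ", v)
  }
  injection_time <- as.POSIXct(injection_time, tz = "UTC")
  scan_start_time <- as.POSIXct(scan_start_time, tz = "UTC")
  if (is.na(injection_time) || is.na(scan_start_time))
    stop("metadata absent: injection/scan timestamps missing or unparsable")
  if (scan_start_time < injection_time)
    stop("scan_start_time precedes injection_time: ",
         "scan acquired before tracer injection is not physical")
  structure(
    list(tracer = as.character(tracer), half_life_min = half_life_min,
         injected_dose_Bq = injected_dose_Bq, body_weight_g = body_weight_g,
         injection_time = injection_time, scan_start_time = scan_start_time),
    class = "acquisition_record"
  )
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf(
    "<acquisition_record> %s: t1/2 %.2f min, dose %.3g Bq, weight %.0f g, dt %.1f min\n",
    x$tracer, x$half_life_min, x$injected_dose_Bq, x$body_weight_g,
    uptake_interval_min(x)))
  invisible(x)
}

#' Injection-to-scan interval in minutes
#'
#' @param acq an [acquisition_record()].
#' @return non-negative minutes between injection and scan start.
#' @export
uptake_interval_min <- function(acq) {
  as.numeric(difftime(acq$scan_start_time, acq$injection_time,
                      units = "mins"))
}

#' Radioactive decay factor
#'
#' Fraction of activity remaining after `delta_t_min` minutes of decay:
#' `exp(-log(2) * delta_t_min / half_life_min)`. Applied to the injected
#' dose it gives the dose still present at scan start, which is the
#' denominator of the SUV formula when decay-correcting to the point of
#' injection.
#'
#' @param half_life_min isotope half-life in minutes (> 0).
#' @param delta_t_min elapsed minutes (>= 0).
#' @return unitless scalar in (0, 1].
#' @examples
#' decay_factor(67.71, 67.71)   # one half-life -> 0.5
#' @export
decay_factor <- function(half_life_min, delta_t_min) {
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("half_life_min must be > 0")
  if (any(!is.finite(delta_t_min)) || any(delta_t_min < 0))
    stop("negative decay interval: scan precedes injection")
  exp(-log(2) * delta_t_min / half_life_min)
}

#' Convert an activity image to standardised uptake values
#'
#' Voxel-wise SUV = activity concentration (Bq/mL) x body weight (g) /
#' (injected dose (Bq) x decay factor), where the decay factor
#' `exp(-log(2) * dt / half_life)` decays the injected dose to the scan
#' start -- equivalently, decay-corrects the image activity back to the
#' time of injection. Under the 1 g/mL body-density assumption SUV is
#' unitless.
#'
#' The exponent convention is exposed: `decay_to = "injection"` (default)
#' divides by the decayed dose as above; `decay_to = "none"`
#' (scanner-precorrected input) sets the decay factor to 1, avoiding a
#' silent double correction when the scanner already decay-corrected the
#' series; `decay_to = "inverse"` applies the opposite sign for
#' sensitivity checks.
#'
#' @param activity a [voxel_grid()] in Bq/mL.
#' @param acq an [acquisition_record()].
#' @param decay_to one of `"injection"`, `"none"`, `"inverse"`.
#' @return a [voxel_grid()] with `units = "SUV"` and identical geometry.
#' @export
activity_to_suv <- function(activity, acq,
                            decay_to = c("injection", "none", "inverse")) {
  stopifnot(is_voxel_grid(activity))
  if (!inherits(acq, "acquisition_record"))
    stop("`acq` must be an acquisition_record")
  if (identical(activity$units, "SUV"))
    stop("input grid is already in SUV units; refusing double conversion")
  decay_to <- match.arg(decay_to)
  dt <- uptake_interval_min(acq)
  df <- switch(decay_to,
               injection = decay_factor(acq$half_life_min, dt),
               none = 1,
               inverse = 1 / decay_factor(acq$half_life_min, dt))
  scale <- acq$body_weight_g / (acq$injected_dose_Bq * df)
  voxel_grid(activity$values * scale, spacing = activity$spacing,
             origin = activity$origin, orientation = activity$orientation,
             units = "SUV")
}

#' Invert SUV values back to activity concentration
#'
#' Used by the phantom generator to emit scenes in activity units such that
#' [activity_to_suv()] with the matching sidecar recovers the intended SUV
#' scene exactly.
#'
#' @param suv a [voxel_grid()] in SUV units.
#' @inheritParams activity_to_suv
#' @return a [voxel_grid()] in Bq/mL.
#' @export
suv_to_activity <- function(suv, acq,
                            decay_to = c("injection", "none", "inverse")) {
  stopifnot(is_voxel_grid(suv))
  decay_to <- match.arg(decay_to)
  dt <- uptake_interval_min(acq)
  df <- switch(decay_to,
               injection = decay_factor(acq$half_life_min, dt),
               none = 1,
               inverse = 1 / decay_factor(acq$half_life_min, dt))
  voxel_grid(suv$values * acq$injected_dose_Bq * df / acq$body_weight_g,
             spacing = suv$spacing, origin = suv$origin,
             orientation = suv$orientation, units = "Bq/mL")
}
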