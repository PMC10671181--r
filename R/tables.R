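#' Packaged per-patient cohort tables
#'
#' Loads the transcribed per-patient summary tables of the ten-patient
#' dual-tracer cohort shipped with the package: scan dates and intervals
#' (table 1), PSMA-ligand BTV metrics (table 2), amino-acid-tracer BTV
#' metrics (table 3), contralateral control-VOI statistics (table 4),
#' tumour-to-salivary-gland ratios (table 5), and the nine per-patient
#' voxel-wise Pearson correlation coefficients. Patient 1 lacks FET SUV
#' fields (tables 3 and 4): the conversion metadata for that series was
#' never provided, and those entries are `NA`.
#'
#' @return a named list of data frames: `scan_intervals`, `psma_btv`,
#'   `fet_btv`, `control_voi`, `tsg`, `pearson_r`.
#' @export
study_tables <- function() {
  rd <- function(file) {
    path <- system.file("extdata", file, package = "petbtv", mustWork = TRUE)
    utils::read.csv(path, comment.char = "#")
  }
  out <- list(scan_intervals = rd("cohort_table1_scan_intervals.csv"),
              psma_btv = rd("cohort_table2_psma_btv.csv"),
              fet_btv = rd("cohort_table3_fet_btv.csv"),
              control_voi = rd("cohort_table4_control_voi.csv"),
              tsg = rd("cohort_table5_tsg.csv"),
              pearson_r = rd("cohort_pearson_r.csv"))
  validate_study_tables(out)
  out
}

validate_study_tables <- function(tabs) {
  for (nm in c("scan_intervals", "psma_btv", "fet_btv", "control_voi", "tsg"))
    if (nrow(tabs[[nm]]) != 10L || !identical(tabs[[nm]]$patient, 1:10))
      stop("fixture table '", nm, "' must list patients 1..10")
  if (!all(is.na(tabs$fet_btv[1, c("suv_mean", "suv_max")])))
    stop("fixture schema violation: patient 1 FET BTV SUV fields must be NA")
  if (!all(is.na(tabs$control_voi[1, c("fet_suv_mean", "fet_suv_max")])))
    stop("fixture schema violation: patient 1 FET control fields must be NA")
  if (nrow(tabs$pearson_r) != 9L)
    stop("fixture schema violation: nine per-patient correlations expected")
  if (anyNA(tabs$psma_btv) || anyNA(tabs$tsg))
    stop("fixture schema violation: unexpected missing values")
  invisible(tabs)
}
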