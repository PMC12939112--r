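#' Canonical cohort-table columns
#'
#' Column names and units of the per-patient cohort table: invasive
#' hemodynamics (mPAP in mmHg, PVR in Wood units, PAWP in mmHg, CI in
#' L/min/m^2, SvO2 in %, RAP in mmHg), demographics (age in years, BSA in
#' m^2), radiologist-measured diameters (DMPA and DAo in mm), CT lung volume
#' in litres, the artery/vein labeling accuracy (fraction in 0-1), and the
#' per-scan morphometry readouts.
#'
#' @return Character vector of known numeric column names.
#' @export
cohort_columns <- function() {
  c("mPAP", "PVR", "PAWP", "CI", "SvO2", "RAP", "age", "BSA",
    "DMPA", "DAo", "lung_volume_L", "av_accuracy",
    morphometry_columns())
}

#' Morphometry readout column names
#' @return Character vector of readout column names produced by
#'   [compute_report()].
#' @export
morphometry_columns <- function() {
  bins <- c("2_4", "4_6", "6_10", "all")
  c("n_segments_total", "vessel_volume_mm3", "density_total",
    "normalized_vessel_volume",
    paste0("count_artery_", bins), paste0("count_vein_", bins),
    paste0("density_artery_", bins), paste0("density_vein_", bins),
    "soam_median_artery", "soam_median_vein", "soam_median_all",
    paste0("density_diff_av_", bins[1:3]), paste0("ratio_av_", bins[1:3]))
}

#' Pulmonary-hypertension status from mPAP
#'
#' PH is defined hemodynamically as a resting mean pulmonary arterial
#' pressure strictly above 20 mmHg; the boundary value 20 is *not* PH.
#'
#' @param mpap Numeric vector of mPAP values (mmHg); NA propagates.
#' @return Logical vector.
#' @export
ph_status <- function(mpap) mpap > 20

#' Read a per-patient cohort table from CSV
#'
#' Columns are matched against [cohort_columns()]; unknown columns are kept
#' with a warning, non-numeric entries in numeric columns raise a parse error
#' naming the row. `ph_status` is derived from mPAP on the fly and never
#' stored in the file. Missing values are explicit `NA`s.
#'
#' @param path Path to a CSV with a header row.
#' @return A tibble with one row per patient, including derived `ph_status`.
#' @export
read_cohort_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) {
    tab$ph_status <- logical(0)
    return(tibble::as_tibble(tab))
  }
  known <- cohort_columns()
  unknown <- setdiff(names(tab), c("patient_id", known, "ph_status"))
  if (length(unknown) > 0)
    warning("unknown cohort columns kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  for (col in intersect(names(tab), known)) {
    raw <- tab[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(num))
    if (length(bad) > 0)
      stop("parse error: non-numeric value '", raw[bad[1]], "' in column '",
           col, "' at row ", bad[1], call. = FALSE)
    tab[[col]] <- num
  }
  tab$ph_status <- if ("mPAP" %in% names(tab)) ph_status(tab$mPAP) else NA
  tibble::as_tibble(tab)
}

#' Write a cohort table to CSV
#'
#' The derived `ph_status` column is dropped before writing; it is always
#' recomputed from mPAP on read.
#'
#' @param tab Cohort tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  tab <- tab[setdiff(names(tab), "ph_status")]
  readr::write_csv(tab, path, na = "NA")
  invisible(path)
}
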