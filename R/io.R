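# CSV input/output for ABG record tables, with unit conversion at the
# boundary only (everything inside the package is kPa).

#' Read a table of ABG records from CSV
#'
#' Expected columns: `patient_id`, `timestamp` (ISO-8601), `fio2` (fraction),
#' `pao2`, `paco2` (in `units`), `ph`, `ventilated`, and optionally `hb`
#' (g/l) and `temperature` (degrees C). Tensions are converted to kPa on
#' input when `units = "mmHg"`.
#'
#' @param path CSV file path.
#' @param units Unit of the tension columns in the file.
#' @return A tibble of ABG records with tensions in kPa.
#' @export
read_abg <- function(path, units = c("kPa", "mmHg")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (units == "mmHg")
    df <- df %>% mutate(across(any_of(c("pao2", "paco2")), mmhg_to_kpa))
  as_tibble(df)
}

#' Write a table of ABG records (or assessments) to CSV
#'
#' Tension-valued columns (`pao2`, `paco2`, `pf_ratio`, `aa_difference`) are
#' converted from the internal kPa on output when `units = "mmHg"`.
#'
#' @param records A tibble.
#' @param path Output CSV path.
#' @param units Unit for tension columns in the file.
#' @return `records`, invisibly.
#' @export
write_abg <- function(records, path, units = c("kPa", "mmHg")) {
  units <- match.arg(units)
  out <- as_tibble(records)
  if (units == "mmHg")
    out <- out %>%
      mutate(across(any_of(c("pao2", "paco2", "pf_ratio", "aa_difference")),
                    kpa_to_mmhg))
  readr::write_csv(out, path)
  invisible(records)
}

#' Validate ABG records against the physiological invariants
#'
#' Checks FiO2 within [0.21, 1], positive tensions, pH within (6.5, 8.0) and
#' PaO2 not exceeding the inspired tension (small tolerance for noise).
#' Invalid rows are flagged, not dropped.
#'
#' @param records A tibble of ABG records.
#' @param assumptions A [phys_assumptions()] object.
#' @param tol Tolerance on the supra-inspired PaO2 check, kPa.
#' @return `records` with a logical `valid` column and a `validation_note`
#'   describing the first failed check per row.
#' @export
validate_abg <- function(records, assumptions = phys_assumptions(), tol = 0.5) {
  a <- as_assumptions(assumptions)
  records <- as_tibble(records)
  pio2 <- records$fio2 * (a$pb - a$ph2o)
  note <- rep(NA_character_, nrow(records))
  note[records$pao2 > pio2 + tol] <- "pao2 exceeds inspired tension"
  note[records$ph <= 6.5 | records$ph >= 8.0] <- "ph outside (6.5, 8.0)"
  note[records$pao2 <= 0 | records$paco2 <= 0] <- "non-positive tension"
  note[records$fio2 < 0.21 | records$fio2 > 1] <- "fio2 outside [0.21, 1]"
  records %>% mutate(valid = is.na(note), validation_note = note)
}
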