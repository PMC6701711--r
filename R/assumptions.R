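# Unit conversions and gas-phase constants. All tensions are kPa internally;
# conversion to mmHg happens only at the I/O boundary.
MMHG_PER_KPA <- 7.50062

# Alveolar ventilation constant: PaCO2 [kPa] = C_VENT * VCO2 [l/min STPD] / VA
# [l/min BTPS]. This is the familiar 0.863 mmHg constant re-expressed in kPa
# with VCO2 in litres.
C_VENT <- 863 / MMHG_PER_KPA

# Gas-side oxygen transfer: uptake [ml/min STPD] = VA [l/min BTPS] *
# (PIO2 - PAO2) [kPa] * K_GAS. Consistent with C_VENT so that the ideal
# compartment reproduces the alveolar gas equation exactly.
K_GAS <- MMHG_PER_KPA / 0.863

#' Convert between kPa and mmHg
#'
#' Tensions are handled in kPa throughout the package; these helpers convert
#' at the input/output boundary (1 kPa = 7.50062 mmHg).
#'
#' @param x Numeric vector of pressures.
#' @return Numeric vector in the other unit.
#' @export
kpa_to_mmhg <- function(x) x * MMHG_PER_KPA

#' @rdname kpa_to_mmhg
#' @export
mmhg_to_kpa <- function(x) x / MMHG_PER_KPA

#' Physiological assumptions for content calculations
#'
#' The assumed constants every oxygen-content calculation depends on:
#' respiratory exchange ratio, cardiac output, oxygen consumption, barometric
#' and water-vapour pressure, the haemoglobin fallback, the Hüfner binding
#' capacity and plasma solubility. The defaults are mid-physiological values;
#' every field can be overridden directly or from a YAML file via
#' [read_assumptions()].
#'
#' @param rer Respiratory exchange ratio (dimensionless, 0.7--1.2).
#' @param q_total Cardiac output, l/min.
#' @param vo2 Oxygen consumption, l(STPD)/min.
#' @param pb Barometric pressure, kPa.
#' @param ph2o Saturated water vapour pressure at body temperature, kPa.
#' @param hb_default Haemoglobin fallback when a record omits it, g/l.
#' @param o2_capacity Oxygen binding capacity of haemoglobin, ml O2 per g Hb.
#' @param o2_solubility Plasma oxygen solubility, ml O2/dl/kPa.
#' @param temperature Default body temperature, degrees C.
#' @param dpg 2,3-diphosphoglycerate concentration, mol/l (standard value;
#'   not measured clinically).
#' @param hco3 Bicarbonate used for the base-excess-zero pH/PaCO2 relation in
#'   the simulator, mmol/l.
#' @param check If `TRUE` (default) enforce the feasibility invariants,
#'   including that VO2/Q (in ml/dl) is below the arterial O2 content at the
#'   fallback haemoglobin (otherwise mixed-venous content would be negative).
#' @return A list of class `phys_assumptions`.
#' @examples
#' a <- phys_assumptions()
#' a$q_total
#' @export
phys_assumptions <- function(rer = 0.8, q_total = 6.5, vo2 = 0.25,
                             pb = 101.325, ph2o = 6.27, hb_default = 110,
                             o2_capacity = 1.34, o2_solubility = 0.0225,
                             temperature = 37, dpg = 0.00465, hco3 = 24,
                             check = TRUE) {
  a <- structure(
    list(rer = rer, q_total = q_total, vo2 = vo2, pb = pb, ph2o = ph2o,
         hb_default = hb_default, o2_capacity = o2_capacity,
         o2_solubility = o2_solubility, temperature = temperature,
         dpg = dpg, hco3 = hco3),
    class = "phys_assumptions")
  if (check) validate_assumptions(a)
  a
}

validate_assumptions <- function(a) {
  stopifnot(is.numeric(a$rer), is.numeric(a$q_total), is.numeric(a$vo2))
  if (a$rer < 0.7 || a$rer > 1.2)
    abort(sprintf("rer = %.3g outside [0.7, 1.2]", a$rer),
          class = "effshunt_invalid_input")
  if (a$q_total <= 0) abort("q_total must be > 0", class = "effshunt_invalid_input")
  if (a$vo2 <= 0) abort("vo2 must be > 0", class = "effshunt_invalid_input")
  if (!(a$pb > a$ph2o && a$ph2o > 0))
    abort("need pb > ph2o > 0", class = "effshunt_invalid_input")
  if (a$hb_default <= 0) abort("hb_default must be > 0",
                               class = "effshunt_invalid_input")
  if (a$o2_capacity <= 0 || a$o2_solubility <= 0)
    abort("o2_capacity and o2_solubility must be > 0",
          class = "effshunt_invalid_input")
  # Fick feasibility at the fallback Hb: a-v content difference must be
  # smaller than a (near-saturated) arterial content.
  ca_max <- a$o2_capacity * a$hb_default / 10 + a$o2_solubility * 13.3
  if (vo2_q_mldl(a) >= ca_max)
    abort(sprintf(
      "VO2/Q = %.2f ml/dl is not attainable at the fallback Hb (%.0f g/l): mixed-venous content would be negative",
      vo2_q_mldl(a), a$hb_default), class = "effshunt_infeasible")
  invisible(a)
}

# VO2/Q expressed in content units: l/min over l/min, scaled to ml O2 per dl
# of blood (0.25 / 6.5 -> 3.85 ml/dl).
vo2_q_mldl <- function(a) 100 * a$vo2 / a$q_total

#' @export
print.phys_assumptions <- function(x, ...) {
  cat("Physiological assumptions\n")
  cat(sprintf("  RER %.2f | Q %.1f l/min | VO2 %.2f l/min (VO2/Q = %.2f ml/dl)\n",
              x$rer, x$q_total, x$vo2, vo2_q_mldl(x)))
  cat(sprintf("  Pb %.2f kPa | PH2O %.2f kPa | Hb fallback %.0f g/l\n",
              x$pb, x$ph2o, x$hb_default))
  cat(sprintf("  O2 capacity %.2f ml/g | solubility %.4f ml/dl/kPa | T %.1f C\n",
              x$o2_capacity, x$o2_solubility, x$temperature))
  invisible(x)
}

#' Read assumption overrides from a YAML file
#'
#' Any subset of the [phys_assumptions()] fields may appear in the file;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a YAML key-value file.
#' @param ... Further overrides applied after the file.
#' @return A `phys_assumptions` object.
#' @export
read_assumptions <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phys_assumptions))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(sprintf("unknown assumption field(s): %s", paste(bad, collapse = ", ")),
          class = "effshunt_invalid_input")
  do.call(phys_assumptions, utils::modifyList(vals, list(...)))
}

as_assumptions <- function(a) {
  if (inherits(a, "phys_assumptions")) return(a)
  abort("`assumptions` must be created with phys_assumptions()",
        class = "effshunt_invalid_input")
}
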