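# Oxyhaemoglobin dissociation: a Hill-type closed form with PO2-dependent
# cooperativity and a P50 shifted multiplicatively by pH, PCO2, temperature
# and 2,3-DPG. The standard state is pH 7.4, PCO2 40 mmHg (5.33 kPa), 37 C,
# DPG 4.65 mmol/l, where P50 is 26.8 mmHg (3.5731 kPa).

P50_STD_MMHG <- 26.8
DPG_STD <- 0.00465

#' Oxygen tension at half haemoglobin saturation
#'
#' The P50 of the dissociation model, shifted by the Bohr effect (pH and
#' PCO2), temperature and 2,3-DPG. Acidosis and hypercapnia raise P50
#' (right shift); alkalosis and hypocapnia lower it.
#'
#' @param ph Plasma pH (accepted range 6.5--8.0).
#' @param paco2 Arterial CO2 tension, kPa (accepted range 1--20).
#' @param temperature Body temperature, degrees C.
#' @param dpg 2,3-DPG concentration, mol/l.
#' @return P50 in kPa. At standard conditions this is 26.8 mmHg = 3.5731 kPa.
#' @examples
#' p50(7.4, 5.33)           # standard P50
#' p50(7.2, 6.5) > p50(7.4, 5.33)  # Bohr right shift
#' @export
p50 <- function(ph, paco2, temperature = 37, dpg = DPG_STD) {
  if (any(ph <= 6.5 | ph >= 8.0))
    abort("pH outside the supported range (6.5, 8.0)",
          class = "effshunt_invalid_input")
  if (any(paco2 < 1 | paco2 > 20))
    abort("PaCO2 outside the supported range [1, 20] kPa",
          class = "effshunt_invalid_input")
  pco2_mmhg <- paco2 * MMHG_PER_KPA
  dph <- ph - 7.4
  dco2 <- pco2_mmhg - 40
  ddpg <- dpg - DPG_STD
  dt <- temperature - 37
  f_ph  <- P50_STD_MMHG - 25.535 * dph + 10.646 * dph^2 - 1.764 * dph^3
  f_co2 <- P50_STD_MMHG + 0.1273 * dco2 + 1.083e-4 * dco2^2
  f_dpg <- P50_STD_MMHG + 795.63 * ddpg - 19660.89 * ddpg^2
  f_t   <- P50_STD_MMHG + 1.435 * dt + 4.163e-2 * dt^2 + 6.86e-4 * dt^3
  p50_mmhg <- P50_STD_MMHG * (f_ph / P50_STD_MMHG) * (f_co2 / P50_STD_MMHG) *
    (f_dpg / P50_STD_MMHG) * (f_t / P50_STD_MMHG)
  p50_mmhg / MMHG_PER_KPA
}

# Hill saturation at a given (vector) P50, with an empirical PO2-dependent
# cooperativity coefficient. S(P50) = 0.5 exactly for any nH.
sat_hill <- function(po2, p50_kpa) {
  x <- po2 / p50_kpa
  nh <- 2.82 - 1.20 * 10^(-(po2 * MMHG_PER_KPA) / 29.25)
  xn <- x^nh
  xn / (1 + xn)
}

#' Haemoglobin oxygen saturation
#'
#' Fractional saturation as a function of oxygen tension, with the P50
#' shifted by pH, PCO2 and temperature (Bohr effect). Strictly increasing in
#' PO2; equals 0.5 exactly at `po2 = p50(ph, paco2, temperature)`.
#'
#' @param po2 Oxygen tension, kPa (> 0).
#' @inheritParams p50
#' @return Saturation as a fraction in (0, 1).
#' @export
hb_saturation <- function(po2, ph, paco2, temperature = 37, dpg = DPG_STD) {
  if (any(po2 <= 0))
    abort("po2 must be > 0", class = "effshunt_invalid_input")
  sat_hill(po2, p50(ph, paco2, temperature, dpg))
}

#' Blood oxygen content
#'
#' Total content = haemoglobin-bound + dissolved:
#' `o2_capacity * (hb/10) * SO2 + o2_solubility * po2`, in ml O2 per dl.
#'
#' @inheritParams hb_saturation
#' @param hb Haemoglobin concentration, g/l.
#' @param assumptions A [phys_assumptions()] object (binding capacity,
#'   solubility).
#' @return Oxygen content, ml O2/dl.
#' @examples
#' oxygen_content(13.3, 7.4, 5.3, hb = 150)
#' @export
oxygen_content <- function(po2, ph, paco2, hb,
                           assumptions = phys_assumptions(),
                           temperature = assumptions$temperature) {
  a <- as_assumptions(assumptions)
  if (any(po2 <= 0)) abort("po2 must be > 0", class = "effshunt_invalid_input")
  if (any(hb < 0)) abort("hb must be >= 0", class = "effshunt_invalid_input")
  a$o2_capacity * (hb / 10) * sat_hill(po2, p50(ph, paco2, temperature, a$dpg)) +
    a$o2_solubility * po2
}

# Vectorised bisection for the monotone content -> tension inversion, on a
# precomputed P50 vector. Used by both the public inverter and the simulator.
invert_content_p50 <- function(target, p50_kpa, hb, a,
                               lower = 0.05, upper = 300, tol = 1e-8) {
  n <- length(target)
  cap <- a$o2_capacity * hb / 10
  f <- function(p) cap * sat_hill(p, p50_kpa) + a$o2_solubility * p - target
  lo <- rep(lower, length.out = n)
  hi <- rep(upper, length.out = n)
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Oxygen tension from content
#'
#' Procedural inversion of the content-tension relationship: bracketed
#' root-finding on the strictly monotone [oxygen_content()] over
#' `[lower, upper]` kPa (absolute tolerance `tol`). The round trip
#' `po2_from_content(oxygen_content(x), ...)` recovers `x` to better than
#' 1e-6 kPa across the physiological range.
#'
#' @param content Target oxygen content, ml O2/dl.
#' @inheritParams oxygen_content
#' @param lower,upper Bracket for the root, kPa.
#' @param tol Absolute tolerance on the tension, kPa.
#' @return Oxygen tension, kPa.
#' @export
po2_from_content <- function(content, ph, paco2, hb,
                             assumptions = phys_assumptions(),
                             temperature = assumptions$temperature,
                             lower = 0.05, upper = 300, tol = 1e-8) {
  a <- as_assumptions(assumptions)
  p50v <- p50(ph, paco2, temperature, a$dpg)
  n <- max(length(content), length(p50v), length(hb))
  content <- rep(content, length.out = n)
  p50v <- rep(p50v, length.out = n)
  hb <- rep(hb, length.out = n)
  cmin <- a$o2_capacity * hb / 10 * sat_hill(lower, p50v) + a$o2_solubility * lower
  cmax <- a$o2_capacity * hb / 10 * sat_hill(upper, p50v) + a$o2_solubility * upper
  if (any(content <= cmin)) {
    i <- which(content <= cmin)[1]
    abort(sprintf(
      "content %.4g ml/dl is at or below the attainable minimum %.4g ml/dl (PO2 = %.3g kPa lower bound)",
      content[i], cmin[i], lower), class = "effshunt_out_of_range")
  }
  if (any(content >= cmax)) {
    i <- which(content >= cmax)[1]
    abort(sprintf(
      "content %.4g ml/dl is at or above the attainable maximum %.4g ml/dl at Hb %.3g g/l (PO2 = %.3g kPa upper bound)",
      content[i], cmax[i], hb[i], upper), class = "effshunt_out_of_range")
  }
  invert_content_p50(content, p50v, hb, a, lower, upper, tol)
}

#' Alveolar oxygen tension
#'
#' The alveolar gas equation. By default the simplified form
#' `PAO2 = FiO2 * (Pb - PH2O) - PaCO2 / RER`; with `full = TRUE` the
#' inspired-gas correction term is included:
#' `PAO2 = FiO2 * (Pb - PH2O) - PaCO2 * (FiO2 + (1 - FiO2) / RER)`.
#' The correction is below 0.3 kPa at RER 0.8 and vanishes as RER approaches 1.
#'
#' @param fio2 Inspired oxygen fraction, 0.21--1.0.
#' @param paco2 Arterial CO2 tension, kPa.
#' @param assumptions A [phys_assumptions()] object (RER, Pb, PH2O).
#' @param full Use the full alveolar gas equation.
#' @return Alveolar PO2, kPa. A non-positive result (pathological PaCO2/RER
#'   combination) is an error, never silently clamped.
#' @examples
#' alveolar_po2(0.21, 5.3)   # 13.34 kPa at the defaults
#' @export
alveolar_po2 <- function(fio2, paco2, assumptions = phys_assumptions(),
                         full = FALSE) {
  a <- as_assumptions(assumptions)
  if (any(fio2 < 0.21 - 1e-9 | fio2 > 1 + 1e-9))
    abort("fio2 must be within [0.21, 1.0]", class = "effshunt_invalid_input")
  if (any(paco2 < 0))
    abort("paco2 must be >= 0", class = "effshunt_invalid_input")
  pio2 <- fio2 * (a$pb - a$ph2o)
  pao2_a <- if (full) pio2 - paco2 * (fio2 + (1 - fio2) / a$rer)
            else pio2 - paco2 / a$rer
  if (any(pao2_a <= 0)) {
    i <- which(pao2_a <= 0)[1]
    abort(sprintf(
      "alveolar PO2 is non-positive (%.3g kPa) at FiO2 %.2f, PaCO2 %.3g kPa, RER %.2f",
      pao2_a[i], fio2[min(i, length(fio2))], paco2[min(i, length(paco2))], a$rer),
      class = "effshunt_invalid_input")
  }
  pao2_a
}
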