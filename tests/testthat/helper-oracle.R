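# Independent step-by-step oracle for the content model and shunt algebra,
# written against the published closed forms before the package implementation
# and kept separate from it.

OR_MMHG <- 7.50062
OR_PB <- 101.325
OR_PH2O <- 6.27

oracle_p50 <- function(ph, pco2_kpa, temp = 37, dpg = 0.00465) {
  pco2 <- pco2_kpa * OR_MMHG
  dph <- ph - 7.4; dco2 <- pco2 - 40; ddpg <- dpg - 0.00465; dt <- temp - 37
  f_ph  <- 26.8 - 25.535 * dph + 10.646 * dph^2 - 1.764 * dph^3
  f_co2 <- 26.8 + 0.1273 * dco2 + 1.083e-4 * dco2^2
  f_dpg <- 26.8 + 795.63 * ddpg - 19660.89 * ddpg^2
  f_t   <- 26.8 + 1.435 * dt + 4.163e-2 * dt^2 + 6.86e-4 * dt^3
  26.8 * (f_ph / 26.8) * (f_co2 / 26.8) * (f_dpg / 26.8) * (f_t / 26.8) / OR_MMHG
}

oracle_sat <- function(po2, p50v) {
  x <- po2 / p50v
  n <- 2.82 - 1.20 * 10^(-(po2 * OR_MMHG) / 29.25)
  x^n / (1 + x^n)
}

oracle_content <- function(po2, ph, pco2, hb)
  1.34 * (hb / 10) * oracle_sat(po2, oracle_p50(ph, pco2)) + 0.0225 * po2

oracle_alv <- function(fio2, pco2, rer = 0.8)
  fio2 * (OR_PB - OR_PH2O) - pco2 / rer

oracle_es <- function(fio2, pao2, pco2, ph, hb, vo2 = 0.25, q = 6.5) {
  cc <- oracle_content(oracle_alv(fio2, pco2), ph, pco2, hb)
  ca <- oracle_content(pao2, ph, pco2, hb)
  d <- max(0, cc - ca)
  d / (d + 100 * vo2 / q)
}

oracle_invert <- function(target, ph, pco2, hb)
  stats::uniroot(function(p) oracle_content(p, ph, pco2, hb) - target,
                 c(0.05, 300), tol = 1e-12)$root

# Hand-enumerated pair-selection fixture: one patient, six records.
# Qualifying pairs (1,2) (1,3) (2,4) (3,4) (2,5) (3,5); exclusions cover an
# FiO2 increase (2,3), a 181-min interval (1,4), |dPaCO2| = 0.3 exactly
# (4,5), and an unventilated record (6).
pair_fixture <- function() {
  t0 <- as.POSIXct("2026-03-01 12:00:00", tz = "UTC")
  tibble::tibble(
    patient_id = "P1",
    timestamp = t0 + c(0, 60, 90, 181, 240, 270) * 60,
    fio2  = c(0.8, 0.6, 0.7, 0.5, 0.4, 0.3),
    pao2  = c(13, 11, 12, 10.5, 10, 9.5),
    paco2 = c(5.30, 5.40, 5.35, 5.30, 5.60, 5.55),
    ph = 7.40, hb = 110,
    ventilated = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
}

expected_fixture_pairs <- function() {
  list(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(2, 5), c(3, 5))
}

# Small heterogeneous cohort shared by several tests.
small_cohort <- function(n = 40, seed = 99, ...) {
  suppressMessages(generate_cohort(cohort_spec(n_patients = n, seed = seed, ...)))
}
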