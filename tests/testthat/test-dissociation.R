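test_that("P50 matches the model's standard constant and shifts with the Bohr effect", {
  # standard conditions (pH 7.4, PCO2 40 mmHg, 37 C): 26.8 mmHg exactly
  expect_equal(p50(7.4, 40 / 7.50062), 26.8 / 7.50062, tolerance = 1e-12)
  # regression constant at the usual kPa rounding of the standard PCO2
  expect_equal(p50(7.4, 5.33), 3.572670, tolerance = 1e-6)
  # frozen oracle values at shifted conditions
  expect_equal(p50(7.2, 6.5), 4.493230, tolerance = 1e-6)
  expect_equal(p50(7.6, 4.0), 2.808293, tolerance = 1e-6)
  # Bohr directions
  expect_gt(p50(7.2, 6.5), p50(7.4, 5.33))
  expect_lt(p50(7.6, 4.0), p50(7.4, 5.33))
  # acidosis and hypercapnia shift independently
  expect_gt(p50(7.2, 5.33), p50(7.4, 5.33))
  expect_gt(p50(7.4, 9.0), p50(7.4, 5.33))
  # fever right-shifts
  expect_gt(p50(7.4, 5.33, temperature = 40), p50(7.4, 5.33))
  expect_error(p50(6.2, 5.33), class = "effshunt_invalid_input")
  expect_error(p50(7.4, 25), class = "effshunt_invalid_input")
})

test_that("saturation is half at P50, bounded, and saturates at high tension", {
  for (ph in c(7.1, 7.4, 7.6)) {
    for (pco2 in c(3, 5.3, 9)) {
      expect_equal(hb_saturation(p50(ph, pco2), ph, pco2), 0.5,
                   tolerance = 1e-12)
    }
  }
  expect_gt(hb_saturation(90, 7.4, 5.3), 0.99)
  s <- hb_saturation(seq(0.5, 40, length.out = 200), 7.4, 5.3)
  expect_true(all(s > 0 & s < 1))
  expect_error(hb_saturation(-1, 7.4, 5.3), class = "effshunt_invalid_input")
})

test_that("saturation is strictly monotone in PO2 across an acid-base grid", {
  grid <- seq(0.2, 60, length.out = 400)
  for (ph in c(7.1, 7.4, 7.6)) {
    for (pco2 in c(3, 5.3, 9)) {
      s <- hb_saturation(grid, ph, pco2)
      expect_true(all(diff(s) > 0),
                  info = sprintf("pH %.1f, PaCO2 %.1f", ph, pco2))
    }
  }
})

test_that("Bohr directions hold pointwise (finite differences)", {
  po2 <- c(2, 5, 13.3)
  # dS/dpH > 0 at fixed PO2
  expect_true(all(hb_saturation(po2, 7.45, 5.3) > hb_saturation(po2, 7.35, 5.3)))
  # dS/dPaCO2 < 0 at fixed PO2
  expect_true(all(hb_saturation(po2, 7.4, 6.0) < hb_saturation(po2, 7.4, 5.0)))
})

test_that("oxygen content decomposes into bound plus dissolved terms", {
  a <- phys_assumptions()
  po2 <- c(1, 5, 13.3, 40)
  total <- oxygen_content(po2, 7.4, 5.3, hb = 150, a)
  bound <- a$o2_capacity * 15 * hb_saturation(po2, 7.4, 5.3)
  expect_equal(total, bound + a$o2_solubility * po2, tolerance = 1e-12)
  # frozen plug-through values
  expect_equal(oxygen_content(p50(7.4, 5.33), 7.4, 5.33, 150), 10.130385,
               tolerance = 1e-5)
  expect_equal(oxygen_content(13.3, 7.4, 5.3, 150), 19.918610,
               tolerance = 1e-5)
  # zero Hb leaves the dissolved term only; doubling Hb doubles the bound term
  expect_equal(oxygen_content(13.3, 7.4, 5.3, 0), a$o2_solubility * 13.3)
  c1 <- oxygen_content(13.3, 7.4, 5.3, 75) - a$o2_solubility * 13.3
  c2 <- oxygen_content(13.3, 7.4, 5.3, 150) - a$o2_solubility * 13.3
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(diff(oxygen_content(seq(1, 30, 0.5), 7.4, 5.3, 110)) > 0))
})

test_that("content-tension inversion round-trips and rejects unattainable contents", {
  po2 <- c(0.5, 2, 5, p50(7.4, 5.3), 13.3, 40, 90)
  ct <- oxygen_content(po2, 7.4, 5.3, 150)
  expect_equal(po2_from_content(ct, 7.4, 5.3, 150), po2, tolerance = 1e-6)
  # agrees with an independent uniroot inversion of the oracle content model
  expect_equal(po2_from_content(oracle_content(13.3, 7.4, 5.3, 150),
                                7.4, 5.3, 150),
               13.3, tolerance = 1e-6)
  cap <- 1.34 * 15 + 0.0225 * 90
  expect_error(po2_from_content(cap + 5, 7.4, 5.3, 150, upper = 90),
               class = "effshunt_out_of_range")
  expect_error(po2_from_content(1e-9, 7.4, 5.3, 150),
               class = "effshunt_out_of_range")
})

test_that("alveolar gas equation matches direct evaluation and flags bad input", {
  expect_equal(alveolar_po2(0.21, 5.3), 13.336550, tolerance = 1e-6)
  expect_equal(alveolar_po2(0.5, 6.0, phys_assumptions(rer = 1.0)), 41.5275,
               tolerance = 1e-6)
  # zero-CO2 limit at FiO2 1.0 is the full dry inspired tension
  expect_equal(alveolar_po2(1.0, 0), 101.325 - 6.27)
  # full form differs by < 0.3 kPa at RER 0.8 and vanishes at RER 1
  d <- alveolar_po2(0.21, 5.3, full = TRUE) - alveolar_po2(0.21, 5.3)
  expect_lt(abs(d), 0.3)
  a1 <- phys_assumptions(rer = 1.0)
  expect_equal(alveolar_po2(0.4, 5.0, a1, full = TRUE),
               alveolar_po2(0.4, 5.0, a1))
  expect_error(alveolar_po2(0.15, 5.3), class = "effshunt_invalid_input")
  expect_error(alveolar_po2(0.21, 18), class = "effshunt_invalid_input")
})

test_that("assumptions validate their invariants and read from YAML", {
  expect_error(phys_assumptions(rer = 0.5), class = "effshunt_invalid_input")
  expect_error(phys_assumptions(q_total = -1), class = "effshunt_invalid_input")
  expect_error(phys_assumptions(ph2o = 110), class = "effshunt_invalid_input")
  # VO2/Q beyond the attainable arterial content at the fallback Hb
  expect_error(phys_assumptions(vo2 = 1, q_total = 3),
               class = "effshunt_infeasible")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("q_total: 5.0", "vo2: 0.3", "hb_default: 120"), f)
  a <- read_assumptions(f)
  expect_equal(a$q_total, 5.0)
  expect_equal(a$hb_default, 120)
  expect_equal(a$rer, 0.8)  # untouched default
  writeLines("not_a_field: 1", f)
  expect_error(read_assumptions(f), class = "effshunt_invalid_input")
})

test_that("unit conversion helpers are exact inverses", {
  x <- c(5.3, 13.3, 101.325)
  expect_equal(mmhg_to_kpa(kpa_to_mmhg(x)), x)
  expect_equal(kpa_to_mmhg(1), 7.50062)
})
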