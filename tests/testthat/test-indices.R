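test_that("P/F ratio and its predictor are exact arithmetic", {
  expect_equal(pf_ratio(13.3, 0.21), 13.3 / 0.21)
  expect_equal(pf_ratio(8.0, 1.0), 8.0)
  expect_equal(pf_ratio(10.0, 0.4), 25.0)
  expect_equal(predict_pao2_pf(25, 0.4), 10.0)
  expect_equal(predict_pao2_pf(pf_ratio(13.3, 0.21), 0.21), 13.3)
  expect_error(pf_ratio(10, 0), class = "effshunt_invalid_input")
})

test_that("A-a difference clamps noise and its predictor inverts exactly", {
  alv <- alveolar_po2(0.21, 5.3)
  expect_equal(aa_difference(alv, 0.21, 5.3), 0)
  expect_equal(aa_difference(10.0, 0.21, 5.3), alv - 10.0, tolerance = 1e-9)
  # supra-alveolar PaO2 clamps to zero rather than going negative
  expect_equal(aa_difference(alv + 0.5, 0.21, 5.3), 0)
  expect_lt(aa_difference(alv + 0.5, 0.21, 5.3, clamp = FALSE), 0)
  expect_equal(predict_pao2_aa(0, 0.21, 5.3), alv)
  expect_equal(predict_pao2_aa(alv - 10, 0.21, 5.3), 10.0, tolerance = 1e-9)
  expect_error(predict_pao2_aa(20, 0.21, 5.3), class = "effshunt_out_of_range")
  expect_true(is.na(predict_pao2_aa(20, 0.21, 5.3, strict = FALSE)))
})

test_that("effective shunt matches the step-by-step oracle and clamps correctly", {
  # frozen oracle value and live oracle agreement
  expect_equal(effective_shunt(9, 0.6, 5, 7.35, 120), 0.35861322,
               tolerance = 1e-7)
  cases <- tidyr::expand_grid(fio2 = c(0.3, 0.6, 1.0), pao2 = c(7, 11),
                              paco2 = c(4.5, 6), ph = c(7.25, 7.45),
                              hb = c(80, 140))
  es_pkg <- with(cases, effective_shunt(pao2, fio2, paco2, ph, hb))
  es_ora <- purrr::pmap_dbl(cases, function(fio2, pao2, paco2, ph, hb)
    oracle_es(fio2, pao2, paco2, ph, hb))
  expect_equal(es_pkg, es_ora, tolerance = 1e-10)
  # zero numerator at PaO2 = PAO2; clamp above
  alv <- alveolar_po2(0.6, 5)
  expect_equal(effective_shunt(alv, 0.6, 5, 7.35, 120), 0)
  expect_equal(effective_shunt(alv + 1, 0.6, 5, 7.35, 120), 0)
  # deeper hypoxaemia implies larger effective shunt
  expect_gt(effective_shunt(7, 0.6, 5, 7.35, 120),
            effective_shunt(11, 0.6, 5, 7.35, 120))
  expect_true(all(es_pkg >= 0 & es_pkg < 1))
})

test_that("missing haemoglobin falls back to the default with a warning", {
  expect_warning(es <- effective_shunt(9, 0.6, 5, 7.35, NA_real_),
                 class = "effshunt_hb_fallback")
  expect_equal(es, effective_shunt(9, 0.6, 5, 7.35, 110))
})

test_that("ES prediction round-trips, matches the oracle trajectory, and handles limits", {
  # self-consistency: predicting at unchanged settings recovers measured PaO2
  es <- effective_shunt(9, 0.6, 5, 7.35, 120)
  expect_equal(predict_pao2_es(es, 0.6, 5, 7.35, 120), 9, tolerance = 1e-6)
  # frozen oracle trajectory for es = 0.2 at fixed pH/PaCO2/Hb
  expect_equal(predict_pao2_es(0.2, c(0.6, 0.5, 0.4), 5.3, 7.4, 110),
               c(16.26632385, 13.26678818, 11.36302478), tolerance = 1e-6)
  # zero-shunt limit returns the alveolar tension
  expect_equal(predict_pao2_es(0, 0.5, 5.3, 7.4, 110),
               alveolar_po2(0.5, 5.3), tolerance = 1e-6)
  # the two printed algebraic forms of the content prediction agree
  a <- phys_assumptions()
  es2 <- 0.35; q_dl <- a$q_total * 10; vo2_ml <- a$vo2 * 1000
  cc <- oxygen_content(alveolar_po2(0.5, 5.3), 7.4, 5.3, 110)
  ca_form1 <- cc - es2 / (1 - es2) * 100 * a$vo2 / a$q_total
  ca_form2 <- cc - (es2 * q_dl) * vo2_ml / (q_dl * (q_dl - es2 * q_dl))
  expect_equal(ca_form1, ca_form2, tolerance = 1e-10)
  expect_equal(predict_pao2_es(es2, 0.5, 5.3, 7.4, 110),
               po2_from_content(ca_form2, 7.4, 5.3, 110), tolerance = 1e-8)
  # extreme shunt at low FiO2: content below the attainable range
  expect_error(predict_pao2_es(0.9, 0.21, 5.3, 7.4, 110),
               class = "effshunt_out_of_range")
  expect_true(is.na(predict_pao2_es(0.9, 0.21, 5.3, 7.4, 110, strict = FALSE)))
  expect_error(predict_pao2_es(1.0, 0.5, 5.3, 7.4, 110),
               class = "effshunt_invalid_input")
})

test_that("assess_oxygenation appends all measures and tags degenerate rows", {
  recs <- tibble::tibble(
    fio2 = c(0.6, 0.21), pao2 = c(9, 14.5), paco2 = c(5, 5.3),
    ph = c(7.35, 7.4), hb = c(120, NA))
  out <- suppressMessages(assess_oxygenation(recs))
  expect_s3_class(out, "tbl_df")
  expect_equal(out$pf_ratio, c(9 / 0.6, 14.5 / 0.21))
  expect_equal(out$effective_shunt[1], 0.35861322, tolerance = 1e-7)
  # record 2 has PaO2 above the alveolar tension: clamped and tagged
  expect_true(out$supra_alveolar[2])
  expect_equal(out$aa_difference[2], 0)
  expect_equal(out$effective_shunt[2], 0)
  expect_equal(out$hb_imputed, c(FALSE, TRUE))
  expect_error(assess_oxygenation(recs[, -1]), class = "effshunt_invalid_input")
})

test_that("sensitivity sweep covers the full assumed ranges and flags infeasible combos", {
  recs <- tibble::tibble(fio2 = c(0.3, 0.5, 0.7), pao2 = c(9, 11, 13),
                         paco2 = 5.3, ph = 7.4, hb = 110)
  sw <- es_sensitivity(recs)
  expect_equal(nrow(sw), 3 * 4 * 5 * 5)   # records x RER x Q x VO2
  expect_true(all(is.finite(sw$es)))
  expect_true(all(sw$es >= 0 & sw$es < 1))
  # combos implying negative venous content are flagged, not dropped
  expect_true(any(!sw$feasible))
  expect_true(all(sw$feasible[sw$vo2 == 0.15 & sw$q_total >= 6]))
  # at fixed record, ES falls as the assumed VO2/Q rises (larger a-v difference
  # explains more of the gradient without shunt)
  one <- dplyr::filter(sw, record == 2, rer == 0.8, q_total == 6)
  expect_true(all(diff(one$es[order(one$vo2)]) < 0))
})
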