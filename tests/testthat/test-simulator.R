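test_that("mixed-venous update follows the Fick principle", {
  a <- phys_assumptions()  # VO2/Q = 3.846 ml/dl
  expect_equal(mixed_venous_update(20, a), 20 - 100 * 0.25 / 6.5)
  expect_error(mixed_venous_update(100 * 0.25 / 6.5, a),
               class = "effshunt_infeasible")
  # doubling Q halves the a-v difference exactly
  a2 <- phys_assumptions(q_total = 13)
  expect_equal(20 - mixed_venous_update(20, a2),
               (20 - mixed_venous_update(20, a)) / 2)
})

test_that("alveolar ventilation, PaCO2 and pH relations are mutually consistent", {
  a <- phys_assumptions()
  va <- va_for_paco2(5.3, a)
  r <- steady_state(shunt = 0, vq_sigma = 0, fio2 = 0.21,
                    alveolar_ventilation = va)
  expect_equal(r$out_paco2, 5.3, tolerance = 1e-10)
  # base-excess-zero HH gives a near-normal pH at normocapnia
  expect_equal(r$out_ph, ph_from_paco2(5.3), tolerance = 1e-12)
  expect_gt(r$out_ph, 7.35); expect_lt(r$out_ph, 7.45)
  # halving ventilation doubles PaCO2 (linearised carriage)
  r2 <- steady_state(shunt = 0, vq_sigma = 0, fio2 = 0.21,
                     alveolar_ventilation = va / 2)
  expect_equal(r2$out_paco2, 10.6, tolerance = 1e-10)
})

test_that("ideal lung reproduces the alveolar gas equation", {
  va <- va_for_paco2(5.3)
  r <- steady_state(shunt = 0, vq_sigma = 0, fio2 = 0.4,
                    alveolar_ventilation = va)
  expect_equal(r$out_pao2, alveolar_po2(0.4, 5.3), tolerance = 1e-6)
})

test_that("steady state is monotone in shunt, V/Q spread and FiO2", {
  va <- va_for_paco2(5.3)
  sweep <- tidyr::expand_grid(shunt = c(0, 0.15, 0.3, 0.45),
                              vq_sigma = c(0, 0.5, 1, 1.5),
                              fio2 = c(0.3, 0.5, 0.8)) |>
    dplyr::mutate(q_total = 6.5, hb = 110, alveolar_ventilation = va)
  out <- steady_state_batch(sweep, n_compartments = 30)
  expect_true(all(out$converged))
  # PaO2 never reaches the inspired tension
  expect_true(all(out$out_pao2 < out$fio2 * (101.325 - 6.27)))
  by_shunt <- out |> dplyr::arrange(vq_sigma, fio2, shunt) |>
    dplyr::group_by(vq_sigma, fio2) |>
    dplyr::summarise(mono = all(diff(out_pao2) < 0), .groups = "drop")
  expect_true(all(by_shunt$mono))
  by_vq <- out |> dplyr::arrange(shunt, fio2, vq_sigma) |>
    dplyr::group_by(shunt, fio2) |>
    dplyr::summarise(mono = all(diff(out_pao2) < 0), .groups = "drop")
  expect_true(all(by_vq$mono))
  by_fio2 <- out |> dplyr::arrange(shunt, vq_sigma, fio2) |>
    dplyr::group_by(shunt, vq_sigma) |>
    dplyr::summarise(mono = all(diff(out_pao2) > 0), .groups = "drop")
  expect_true(all(by_fio2$mono))
})

test_that("oxygen mass is conserved at the fixed point", {
  va <- va_for_paco2(5.3)
  runs <- tidyr::expand_grid(shunt = c(0.1, 0.3), vq_sigma = c(0, 0.8),
                             q_total = c(4.5, 7.5)) |>
    dplyr::mutate(hb = 110, fio2 = 0.5, alveolar_ventilation = va)
  out <- steady_state_batch(runs)
  # Q (dl/min) x (Ca - Cv) (ml/dl) = VO2 (ml/min), to < 1e-6 l/min
  uptake_l <- out$q_total * 10 * (out$ca - out$cv) / 1000
  expect_equal(uptake_l, out$vo2, tolerance = 1e-6)
})

test_that("near-total shunt drives arterial blood towards mixed venous", {
  # high shunt is only sustainable with low VO2 and high Q: the residual
  # pulmonary flow must still deliver the whole oxygen consumption
  a <- phys_assumptions()
  va <- va_for_paco2(5.3, a, vo2 = 0.15)
  out <- steady_state_batch(
    tibble::tibble(shunt = c(0.1, 0.5, 0.9), vq_sigma = 0, q_total = 12,
                   hb = 110, fio2 = 1.0, alveolar_ventilation = va,
                   vo2 = 0.15), a)
  expect_true(all(diff(out$out_pao2) < 0))
  # at 90% shunt the arterial tension sits far below the alveolar tension and
  # arterial blood is one a-v difference above mixed venous
  expect_lt(out$out_pao2[3], alveolar_po2(1.0, out$out_paco2[3], a) / 5)
  expect_equal(out$ca[3] - out$cv[3], 100 * 0.15 / 12, tolerance = 1e-9)
  # a lower-Q, higher-VO2 version of the same shunt is infeasible
  expect_error(steady_state(shunt = 0.9, fio2 = 1.0, q_total = 6.5,
                            alveolar_ventilation = va_for_paco2(5.3)),
               class = "effshunt_infeasible")
  expect_error(steady_state(shunt = 0.99, fio2 = 0.5,
                            alveolar_ventilation = va),
               class = "effshunt_invalid_input")
})

test_that("the multi-compartment path is continuous with the ideal-lung closed form", {
  va <- va_for_paco2(5.3)
  r0 <- steady_state(0.15, 0, 6.5, 110, 0.4, va)
  r1 <- steady_state(0.15, 1e-9, 6.5, 110, 0.4, va)
  expect_equal(r1$out_pao2, r0$out_pao2, tolerance = 1e-4)
  expect_equal(r0$iterations, 0L)  # closed form, no iteration
  expect_gt(r1$iterations, 0L)
})

test_that("infeasible oxygen transport errors in strict mode and flags otherwise", {
  va <- va_for_paco2(5.3)
  # VO2 far above what Q and Hb can deliver
  bad <- tibble::tibble(shunt = 0.5, vq_sigma = 0, q_total = 3, hb = 60,
                        fio2 = 0.21, alveolar_ventilation = va, vo2 = 0.6)
  expect_error(steady_state_batch(bad), class = "effshunt_infeasible")
  out <- steady_state_batch(bad, strict = FALSE)
  expect_false(out$converged)
  expect_true(is.na(out$out_pao2))
  expect_error(steady_state_batch(dplyr::mutate(bad, shunt = -0.1)),
               class = "effshunt_invalid_input")
})

test_that("pure-shunt simulated gases return the latent shunt through the ES formula", {
  a <- phys_assumptions()
  runs <- tidyr::expand_grid(shunt = c(0.05, 0.2, 0.35, 0.5),
                             fio2 = c(0.3, 0.6)) |>
    dplyr::mutate(vq_sigma = 0, q_total = a$q_total, hb = a$hb_default,
                  alveolar_ventilation = va_for_paco2(5.3, a))
  sim <- steady_state_batch(runs, a)
  es <- effective_shunt(sim$out_pao2, sim$fio2, sim$out_paco2, sim$out_ph,
                        sim$hb, a)
  expect_equal(es, sim$shunt, tolerance = 1e-6)
})

test_that("V/Q heterogeneity inflates effective shunt above the pure shunt", {
  a <- phys_assumptions()
  sim <- steady_state_batch(
    tibble::tibble(shunt = 0.1, vq_sigma = c(0.5, 1, 1.5), q_total = 6.5,
                   hb = 110, fio2 = 0.4,
                   alveolar_ventilation = va_for_paco2(5.3, a)), a)
  es <- effective_shunt(sim$out_pao2, sim$fio2, sim$out_paco2, sim$out_ph,
                        sim$hb, a)
  expect_true(all(es > 0.1))
  expect_true(all(diff(es) > 0))  # more heterogeneity, more equivalent shunt
})
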