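# Steady-state gas exchange: a shunt compartment receiving mixed-venous blood
# plus N equal-perfusion compartments whose V/Q ratios are log-normally spaced
# (spread vq_sigma; vq_sigma = 0 collapses to a single ideal compartment).
# CO2 carriage is linearised: arterial PCO2 follows from total alveolar
# ventilation and CO2 production via the alveolar ventilation equation, and pH
# from PaCO2 by a base-excess-zero Henderson-Hasselbalch relation. Oxygen uses
# the full content model with per-compartment alveolar mass balance.

#' Alveolar ventilation required for a target PaCO2
#'
#' Inverts the linearised CO2 carriage relation
#' `PaCO2 = C * VO2 * RER / VA` for the alveolar ventilation `VA`. Because the
#' relation is closed-form monotone, the root is analytic.
#'
#' @param paco2 Target arterial CO2 tension, kPa.
#' @param assumptions A [phys_assumptions()] object.
#' @param vo2 Oxygen consumption, l/min (defaults to the assumed value).
#' @return Alveolar ventilation, l/min (BTPS).
#' @export
va_for_paco2 <- function(paco2, assumptions = phys_assumptions(),
                         vo2 = assumptions$vo2) {
  if (any(paco2 <= 0)) abort("paco2 must be > 0", class = "effshunt_invalid_input")
  C_VENT * vo2 * assumptions$rer / paco2
}

#' pH from PaCO2 at zero base excess
#'
#' Henderson-Hasselbalch with a fixed bicarbonate (default 24 mmol/l):
#' `pH = 6.1 + log10(HCO3 / (0.03 * PaCO2_mmHg))`.
#'
#' @param paco2 Arterial CO2 tension, kPa.
#' @param hco3 Bicarbonate, mmol/l.
#' @return Arterial pH.
#' @export
ph_from_paco2 <- function(paco2, hco3 = 24) {
  6.1 + log10(hco3 / (0.03 * paco2 * MMHG_PER_KPA))
}

#' Mixed-venous content from the Fick principle
#'
#' `CvO2 = CaO2 - VO2/Q` with VO2/Q in ml/dl.
#'
#' @param ca Arterial oxygen content, ml/dl.
#' @param assumptions A [phys_assumptions()] object.
#' @return Mixed-venous oxygen content, ml/dl.
#' @export
mixed_venous_update <- function(ca, assumptions = phys_assumptions()) {
  a <- as_assumptions(assumptions)
  cv <- ca - vo2_q_mldl(a)
  if (any(cv <= 0))
    abort(sprintf(
      "mixed-venous content would be %.3g ml/dl: VO2 %.2f l/min is not sustainable at Q %.1f l/min with Ca %.3g ml/dl",
      min(cv), a$vo2, a$q_total, ca[which(cv <= 0)[1]]),
      class = "effshunt_infeasible")
  cv
}

#' Steady-state blood gases for a batch of model runs
#'
#' Solves the integrated gas-exchange model for every row of `runs`. Each run
#' needs `shunt`, `vq_sigma`, `q_total` (l/min), `hb` (g/l), `fio2` and
#' `alveolar_ventilation` (l/min BTPS); `vo2` is taken from the assumptions
#' when absent. The O2 fixed point iterates (1) the perfusion split across the
#' compartments, (2) per-compartment alveolar PO2 from ventilation-perfusion
#' mass balance with the content model, (3) mixed arterial content as the
#' perfusion-weighted mixture including the shunt, and (4) the Fick
#' mixed-venous update, until successive arterial contents agree to `tol`
#' ml/dl (with Aitken acceleration). Runs with `vq_sigma = 0` are solved in
#' closed form: the Fick constraint fixes the single compartment's uptake, so
#' its PO2 follows directly from the mass balance.
#'
#' @param runs Data frame of model-run inputs (one run per row).
#' @param assumptions A [phys_assumptions()] object.
#' @param n_compartments Number of non-shunt V/Q compartments.
#' @param tol Convergence tolerance on arterial content, ml/dl.
#' @param max_iter Fixed-point iteration cap.
#' @param strict If `TRUE`, infeasible runs (negative mixed-venous content) or
#'   non-convergence abort with diagnostics; if `FALSE` such runs return `NA`
#'   outputs with `converged = FALSE`.
#' @return `runs` as a tibble with `out_pao2`, `out_paco2`, `out_ph`, `ca`,
#'   `cv` (ml/dl), `converged` and `iterations` appended.
#' @export
steady_state_batch <- function(runs, assumptions = phys_assumptions(),
                               n_compartments = 50, tol = 1e-6,
                               max_iter = 200, strict = TRUE) {
  a <- as_assumptions(assumptions)
  runs <- as_tibble(runs)
  req <- c("shunt", "vq_sigma", "q_total", "hb", "fio2", "alveolar_ventilation")
  miss <- setdiff(req, names(runs))
  if (length(miss) > 0)
    abort(sprintf("runs lack required column(s): %s", paste(miss, collapse = ", ")),
          class = "effshunt_invalid_input")
  if (!("vo2" %in% names(runs))) runs$vo2 <- a$vo2
  if (any(runs$shunt < 0 | runs$shunt > 0.95))
    abort("shunt must be within [0, 0.95]", class = "effshunt_invalid_input")
  if (any(runs$vq_sigma < 0))
    abort("vq_sigma must be >= 0", class = "effshunt_invalid_input")
  if (any(runs$q_total <= 0 | runs$alveolar_ventilation <= 0 |
          runs$hb <= 0 | runs$vo2 <= 0))
    abort("q_total, alveolar_ventilation, hb and vo2 must be > 0",
          class = "effshunt_invalid_input")
  if (any(runs$fio2 < 0.21 - 1e-9 | runs$fio2 > 1 + 1e-9))
    abort("fio2 must be within [0.21, 1.0]", class = "effshunt_invalid_input")

  n <- nrow(runs)
  paco2 <- C_VENT * runs$vo2 * a$rer / runs$alveolar_ventilation
  if (any(paco2 < 1 | paco2 > 20))
    abort(sprintf(
      "alveolar ventilation implies PaCO2 %.3g kPa, outside the supported range [1, 20]",
      paco2[which(paco2 < 1 | paco2 > 20)[1]]),
      class = "effshunt_invalid_input")
  ph <- ph_from_paco2(paco2, a$hco3)
  pio2 <- runs$fio2 * (a$pb - a$ph2o)
  p50r <- p50(ph, paco2, a$temperature, a$dpg)
  capr <- a$o2_capacity * runs$hb / 10
  sol <- a$o2_solubility
  k_fick <- 100 * runs$vo2 / runs$q_total                      # a-v difference
  k_ns <- k_fick / (1 - runs$shunt)                            # per non-shunt dl
  content_run <- function(po2, i) capr[i] * sat_hill(po2, p50r[i]) + sol * po2

  # Ideal-compartment tension: total uptake through the gas side is pinned at
  # VO2 by the Fick constraint, giving the closed form used both as the
  # sigma = 0 solution and as the sigma > 0 initial guess.
  pa_ideal <- pio2 - 1000 * runs$vo2 / (K_GAS * runs$alveolar_ventilation)

  ca <- rep(NA_real_, n); cv <- rep(NA_real_, n)
  converged <- rep(FALSE, n); iters <- rep(0L, n)
  failed_msg <- NULL

  is0 <- runs$vq_sigma < 1e-12
  if (any(is0)) {
    i0 <- which(is0)
    ok <- pa_ideal[i0] > 0.05
    cc0 <- rep(NA_real_, length(i0))
    cc0[ok] <- content_run(pa_ideal[i0][ok], i0[ok])
    ca0 <- cc0 - runs$shunt[i0] / (1 - runs$shunt[i0]) * k_fick[i0]
    cv0 <- ca0 - k_fick[i0]
    good <- ok & !is.na(cv0) & cv0 > 0.05 & ca0 > 0.05
    ca[i0[good]] <- ca0[good]; cv[i0[good]] <- cv0[good]
    converged[i0[good]] <- TRUE
    if (any(!good)) failed_msg <- "infeasible ideal-compartment run (mixed-venous content <= 0 or non-positive alveolar PO2)"
  }

  ipos <- which(!is0)
  if (length(ipos) > 0) {
    N <- n_compartments
    z <- qnorm((seq_len(N) - 0.5) / N)
    w <- exp(outer(runs$vq_sigma[ipos], z))
    r0 <- runs$alveolar_ventilation[ipos] /
      ((1 - runs$shunt[ipos]) * runs$q_total[ipos])
    r <- (r0 * w) / rowMeans(w)                        # V/Q per compartment
    kgr <- K_GAS * r
    np <- length(ipos)
    cap_p <- capr[ipos]; p50_p <- p50r[ipos]; pio2_p <- pio2[ipos]
    kns_p <- k_ns[ipos]; kf_p <- k_fick[ipos]
    cmax_p <- cap_p * sat_hill(pio2_p, p50_p) + sol * pio2_p
    cv_p <- pmin(pmax(content_run(pmax(pa_ideal[ipos], 0.5), ipos) - kns_p, 0.3),
                 cmax_p - 0.3)
    act <- rep(TRUE, np)
    fail <- rep(FALSE, np)
    it_p <- rep(0L, np)
    hist1 <- rep(NA_real_, np); hist2 <- rep(NA_real_, np)
    nbis <- 36L

    for (k in seq_len(max_iter)) {
      ai <- which(act)
      if (length(ai) == 0) break
      rs <- r[ai, , drop = FALSE]
      kgrs <- kgr[ai, , drop = FALSE]
      lo <- matrix(0.02, nrow = length(ai), ncol = N)
      hi <- matrix(pio2_p[ai], nrow = length(ai), ncol = N)
      cvv <- cv_p[ai]; capv <- cap_p[ai]; p50v <- p50_p[ai]; piov <- pio2_p[ai]
      for (b in seq_len(nbis)) {
        mid <- (lo + hi) / 2
        g <- (piov - mid) * kgrs -
          10 * (capv * sat_hill(mid, p50v) + sol * mid - cvv)
        pos <- g > 0
        lo[pos] <- mid[pos]
        hi[!pos] <- mid[!pos]
      }
      pa <- (lo + hi) / 2
      mcc <- rowMeans(capv * sat_hill(pa, p50v) + sol * pa)
      cv_new <- mcc - kns_p[ai]
      bad <- cv_new <= 0.05
      if (any(bad)) {
        fail[ai[bad]] <- TRUE
        act[ai[bad]] <- FALSE
      }
      okr <- !bad
      delta <- abs(cv_new - cvv)
      done <- okr & delta < tol
      cv_p[ai] <- ifelse(okr, cv_new, cv_p[ai])
      it_p[ai] <- it_p[ai] + 1L
      act[ai[done]] <- FALSE
      # Aitken extrapolation every third step on the still-active runs
      if (k %% 3 == 0) {
        aj <- which(act)
        d1 <- hist2[aj] - hist1[aj]
        d2 <- cv_p[aj] - hist2[aj]
        den <- d2 - d1
        use <- is.finite(d1) & is.finite(d2) & abs(den) > 1e-14
        acc <- hist1[aj] - d1^2 / den
        use <- use & is.finite(acc) & acc > 0.05 & acc < cmax_p[aj] - 0.05
        cv_p[aj[use]] <- acc[use]
        hist1[aj] <- NA_real_; hist2[aj] <- NA_real_
      } else {
        hist1[act] <- hist2[act]
        hist2[act] <- cv_p[act]
      }
    }
    not_conv <- act  # still active after max_iter
    conv_p <- !fail & !not_conv
    ca_p <- cv_p + kf_p
    ca[ipos[conv_p]] <- ca_p[conv_p]
    cv[ipos[conv_p]] <- cv_p[conv_p]
    converged[ipos] <- conv_p
    iters[ipos] <- it_p
    if (any(fail))
      failed_msg <- "infeasible run(s): mixed-venous content fell below 0.05 ml/dl (VO2 not sustainable at the given Q/Hb/FiO2)"
    if (any(not_conv))
      failed_msg <- sprintf("fixed point did not converge within %d iterations for %d run(s)",
                            max_iter, sum(not_conv))
  }

  if (!all(converged) && strict) {
    i <- which(!converged)[1]
    abort(sprintf(
      "%s [first offending run %d: shunt %.2f, vq_sigma %.2f, Q %.1f, FiO2 %.2f, Hb %.0f]",
      failed_msg %||% "steady state failed", i, runs$shunt[i], runs$vq_sigma[i],
      runs$q_total[i], runs$fio2[i], runs$hb[i]),
      class = "effshunt_infeasible")
  }

  out_pao2 <- rep(NA_real_, n)
  okc <- converged & !is.na(ca)
  if (any(okc))
    out_pao2[okc] <- invert_content_p50(ca[okc], p50r[okc], runs$hb[okc], a)
  runs %>%
    mutate(out_pao2 = out_pao2, out_paco2 = paco2, out_ph = ph,
           ca = ca, cv = cv, converged = converged, iterations = iters)
}

#' Steady-state blood gases for one set of inputs
#'
#' Scalar convenience wrapper around [steady_state_batch()].
#'
#' @param shunt Pure shunt fraction, 0--0.95.
#' @param vq_sigma V/Q heterogeneity index (log-scale spread, >= 0).
#' @param q_total Cardiac output, l/min.
#' @param hb Haemoglobin, g/l.
#' @param fio2 Inspired oxygen fraction.
#' @param alveolar_ventilation Alveolar ventilation, l/min (BTPS).
#' @param vo2 Oxygen consumption, l/min.
#' @param assumptions A [phys_assumptions()] object.
#' @param ... Passed to [steady_state_batch()].
#' @return One-row tibble with the inputs and `out_pao2`, `out_paco2`,
#'   `out_ph` and diagnostics.
#' @examples
#' steady_state(shunt = 0.2, vq_sigma = 0, q_total = 6.5, hb = 110,
#'              fio2 = 0.4, alveolar_ventilation = va_for_paco2(5.3))
#' @export
steady_state <- function(shunt, vq_sigma = 0, q_total = 6.5, hb = 110, fio2,
                         alveolar_ventilation,
                         vo2 = assumptions$vo2,
                         assumptions = phys_assumptions(), ...) {
  steady_state_batch(
    tibble(shunt = shunt, vq_sigma = vq_sigma, q_total = q_total, hb = hb,
           fio2 = fio2, alveolar_ventilation = alveolar_ventilation, vo2 = vo2),
    assumptions = assumptions, ...)
}
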