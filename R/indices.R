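# The four oxygenation measures and their forward predictions of PaO2 at a
# new FiO2, each under the assumption that the measure itself is invariant.

#' PaO2/FiO2 ratio
#'
#' @param pao2 Arterial oxygen tension, kPa.
#' @param fio2 Inspired oxygen fraction.
#' @return P/F ratio in kPa.
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(fio2 <= 0)) abort("fio2 must be > 0", class = "effshunt_invalid_input")
  pao2 / fio2
}

#' Alveolar-arterial oxygen difference
#'
#' `max(0, PAO2 - PaO2)`: negative values (measurement noise or FiO2
#' transcription error placing the arterial tension above the alveolar one)
#' are clamped to zero by default.
#'
#' @inheritParams pf_ratio
#' @param paco2 Arterial CO2 tension, kPa.
#' @param assumptions A [phys_assumptions()] object.
#' @param clamp Clamp negative differences to 0 (default `TRUE`).
#' @return A-a difference, kPa.
#' @export
aa_difference <- function(pao2, fio2, paco2, assumptions = phys_assumptions(),
                          clamp = TRUE) {
  d <- alveolar_po2(fio2, paco2, assumptions) - pao2
  if (clamp) pmax(0, d) else d
}

#' Effective shunt fraction from a single arterial blood gas
#'
#' The pure right-to-left shunt fraction that would, in a three-compartment
#' lung, produce the observed oxygenation impairment:
#' \deqn{ES = \frac{C_{c'}O_2 - C_aO_2}{C_{c'}O_2 - C_aO_2 + VO_2/Q}}
#' with end-capillary content evaluated at the alveolar PO2 from the alveolar
#' gas equation, arterial content at the measured PaO2 (both at the measured
#' pH and PaCO2), and VO2/Q in ml/dl. The denominator's `+ VO2/Q` follows from
#' substituting the Fick rearrangement `CvO2 = CaO2 - VO2/Q` into the shunt
#' equation; it alone keeps ES in [0, 1) and makes the prediction round trip
#' exact. When the arterial content reaches or exceeds the end-capillary
#' content the result is clamped to 0.
#'
#' @inheritParams aa_difference
#' @param ph Arterial pH.
#' @param hb Haemoglobin, g/l; `NA`/`NULL` falls back to
#'   `assumptions$hb_default` with a warning.
#' @param temperature Body temperature, degrees C.
#' @return Effective shunt as a fraction in [0, 1).
#' @examples
#' effective_shunt(pao2 = 9, fio2 = 0.6, paco2 = 5, ph = 7.35, hb = 120)
#' @export
effective_shunt <- function(pao2, fio2, paco2, ph, hb = NULL,
                            assumptions = phys_assumptions(),
                            temperature = assumptions$temperature) {
  a <- as_assumptions(assumptions)
  hb <- resolve_hb(hb, length(pao2), a)
  pao2_alv <- alveolar_po2(fio2, paco2, a)
  cc <- oxygen_content(pao2_alv, ph, paco2, hb, a, temperature)
  ca <- oxygen_content(pao2, ph, paco2, hb, a, temperature)
  d <- pmax(0, cc - ca)
  d / (d + vo2_q_mldl(a))
}

resolve_hb <- function(hb, n, a) {
  if (is.null(hb)) hb <- rep(NA_real_, n)
  if (anyNA(hb)) {
    warn(sprintf("missing haemoglobin: falling back to %.0f g/l for %d record(s)",
                 a$hb_default, sum(is.na(hb))),
         class = "effshunt_hb_fallback")
    hb[is.na(hb)] <- a$hb_default
  }
  hb
}

#' Predict PaO2 at a new FiO2 from an effective shunt
#'
#' Inverts the effective-shunt relationship at new settings: the predicted
#' arterial content is
#' `CaO2 = Cc'O2(new PAO2) - es/(1-es) * VO2/Q`
#' (equivalently `Cc'O2 - Qs*VO2 / (QT*(QT - Qs))` -- the two algebraic forms
#' are identical), then converted back to a tension with
#' [po2_from_content()].
#'
#' @param es Effective shunt fraction in [0, 1).
#' @param new_fio2 Inspired oxygen fraction after the change.
#' @param new_paco2 Arterial CO2 tension after the change, kPa.
#' @inheritParams effective_shunt
#' @param strict If `TRUE` an infeasible prediction (content at or below the
#'   attainable range: extreme shunt at low FiO2) is an error; if `FALSE` it
#'   becomes `NA` so cohort pipelines can count failures.
#' @return Predicted PaO2, kPa.
#' @export
predict_pao2_es <- function(es, new_fio2, new_paco2, ph, hb = NULL,
                            assumptions = phys_assumptions(),
                            temperature = assumptions$temperature,
                            strict = TRUE) {
  a <- as_assumptions(assumptions)
  if (any(es < 0 | es >= 1))
    abort("es must be within [0, 1)", class = "effshunt_invalid_input")
  hb <- resolve_hb(hb, length(es), a)
  pao2_alv <- alveolar_po2(new_fio2, new_paco2, a)
  cc <- oxygen_content(pao2_alv, ph, new_paco2, hb, a, temperature)
  ca <- cc - es / (1 - es) * vo2_q_mldl(a)
  p50v <- p50(ph, new_paco2, temperature, a$dpg)
  n <- max(length(ca), length(p50v), length(hb))
  ca <- rep(ca, length.out = n); p50v <- rep(p50v, length.out = n)
  hb <- rep(hb, length.out = n)
  cmin <- a$o2_capacity * hb / 10 * sat_hill(0.05, p50v) + a$o2_solubility * 0.05
  bad <- ca <= cmin
  if (any(bad) && strict)
    abort(sprintf(
      "predicted content %.3g ml/dl is below the attainable range (extreme shunt %.2f at FiO2 %.2f)",
      ca[which(bad)[1]], es[min(which(bad)[1], length(es))],
      new_fio2[min(which(bad)[1], length(new_fio2))]),
      class = "effshunt_out_of_range")
  out <- rep(NA_real_, n)
  if (any(!bad))
    out[!bad] <- invert_content_p50(ca[!bad], p50v[!bad], hb[!bad], a)
  out
}

#' Predict PaO2 at a new FiO2 from a P/F ratio
#'
#' @param pf P/F ratio, kPa.
#' @param new_fio2 Inspired oxygen fraction after the change.
#' @return Predicted PaO2 = `pf * new_fio2`, kPa.
#' @export
predict_pao2_pf <- function(pf, new_fio2) {
  if (any(pf <= 0)) abort("pf must be > 0", class = "effshunt_invalid_input")
  pf * new_fio2
}

#' Predict PaO2 at a new FiO2 from an A-a difference
#'
#' @param aa A-a difference, kPa (>= 0).
#' @inheritParams predict_pao2_es
#' @return Predicted PaO2 = `PAO2(new settings) - aa`, kPa. A non-positive
#'   prediction is an error (`strict = TRUE`) or `NA` (recorded as a failed
#'   prediction for that pair).
#' @export
predict_pao2_aa <- function(aa, new_fio2, new_paco2,
                            assumptions = phys_assumptions(), strict = TRUE) {
  if (any(aa < 0)) abort("aa must be >= 0", class = "effshunt_invalid_input")
  pred <- alveolar_po2(new_fio2, new_paco2, assumptions) - aa
  bad <- pred <= 0
  if (any(bad)) {
    if (strict)
      abort(sprintf("A-a prediction is non-positive (%.3g kPa) at FiO2 %.2f",
                    pred[which(bad)[1]],
                    new_fio2[min(which(bad)[1], length(new_fio2))]),
            class = "effshunt_out_of_range")
    pred[bad] <- NA_real_
  }
  pred
}

#' Compute all oxygenation measures for a table of blood gases
#'
#' Adds the P/F ratio, A-a difference and effective shunt (and optionally a
#' database-inferred shunt summary) to a table of ABG records. Records with a
#' supra-alveolar PaO2 are not dropped: the A-a difference and effective shunt
#' are clamped to zero and the row is tagged in `supra_alveolar`. Missing
#' haemoglobin falls back to the assumed default and is tagged in
#' `hb_imputed`.
#'
#' @param records Data frame of ABG records with columns `fio2`, `pao2`,
#'   `paco2`, `ph` and optionally `hb` and `temperature`.
#' @param assumptions A [phys_assumptions()] object.
#' @param db Optional model-run database from [build_db()]; when supplied a
#'   `db_shunt` column (mean pure-shunt fraction of the matching runs) is
#'   added.
#' @param tolerances Matching windows for the database, see [db_tolerances()].
#' @return The input as a tibble with columns `pf_ratio`, `aa_difference`,
#'   `effective_shunt`, `supra_alveolar`, `hb_imputed` (and `db_shunt`)
#'   appended.
#' @export
assess_oxygenation <- function(records, assumptions = phys_assumptions(),
                               db = NULL, tolerances = db_tolerances()) {
  a <- as_assumptions(assumptions)
  records <- as_tibble(records)
  req <- c("fio2", "pao2", "paco2", "ph")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    abort(sprintf("records lack required column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "effshunt_invalid_input")
  hb_in <- if ("hb" %in% names(records)) records$hb else rep(NA_real_, nrow(records))
  temp <- if ("temperature" %in% names(records))
    coalesce(records$temperature, a$temperature) else a$temperature
  hb_imputed <- is.na(hb_in)
  hb_use <- suppressWarnings(resolve_hb(hb_in, nrow(records), a))
  pao2_alv <- alveolar_po2(records$fio2, records$paco2, a)
  out <- records %>%
    mutate(
      pf_ratio = pf_ratio(.data$pao2, .data$fio2),
      aa_difference = pmax(0, pao2_alv - .data$pao2),
      effective_shunt = effective_shunt(.data$pao2, .data$fio2, .data$paco2,
                                        .data$ph, !!hb_use, a, !!temp),
      supra_alveolar = .data$pao2 > pao2_alv,
      hb_imputed = !!hb_imputed)
  if (any(hb_imputed))
    inform(sprintf("haemoglobin imputed at %.0f g/l for %d record(s)",
                   a$hb_default, sum(hb_imputed)))
  if (!is.null(db)) {
    out$db_shunt <- map_dbl(seq_len(nrow(out)), function(i) {
      m <- match_abg(db, out[i, ], tolerances)
      if (nrow(m) == 0) NA_real_ else mean(m$shunt)
    })
  }
  out
}

#' Sensitivity of effective shunt to the assumed parameters
#'
#' Recomputes the effective shunt for every record over a grid of assumed RER,
#' cardiac output and oxygen consumption values. Combinations whose VO2/Q is
#' not attainable at the record's haemoglobin (implied negative mixed-venous
#' content) are still evaluated -- the effective-shunt formula needs no venous
#' content -- but flagged `feasible = FALSE`.
#'
#' @inheritParams assess_oxygenation
#' @param rer_values,q_values,vo2_values Parameter values to sweep.
#' @return A tibble with one row per record x parameter combination:
#'   `record`, `rer`, `q_total`, `vo2`, `es`, `feasible`.
#' @export
es_sensitivity <- function(records, rer_values = c(0.8, 0.9, 1.0, 1.1),
                           q_values = c(3, 6, 9, 12, 15),
                           vo2_values = c(0.15, 0.25, 0.5, 0.75, 1.0),
                           assumptions = phys_assumptions()) {
  a <- as_assumptions(assumptions)
  records <- as_tibble(records)
  hb <- if ("hb" %in% names(records))
    suppressWarnings(resolve_hb(records$hb, nrow(records), a))
  else rep(a$hb_default, nrow(records))
  grid <- expand_grid(rer = rer_values, q_total = q_values, vo2 = vo2_values)
  res <- pmap(grid, function(rer, q_total, vo2) {
    ai <- phys_assumptions(rer = rer, q_total = q_total, vo2 = vo2,
                           pb = a$pb, ph2o = a$ph2o, hb_default = a$hb_default,
                           o2_capacity = a$o2_capacity,
                           o2_solubility = a$o2_solubility,
                           temperature = a$temperature, dpg = a$dpg,
                           hco3 = a$hco3, check = FALSE)
    ca <- oxygen_content(records$pao2, records$ph, records$paco2, hb, ai)
    tibble(record = seq_len(nrow(records)),
           rer = rer, q_total = q_total, vo2 = vo2,
           es = effective_shunt(records$pao2, records$fio2, records$paco2,
                                records$ph, hb, ai),
           feasible = vo2_q_mldl(ai) < ca)
  })
  bind_rows(res)
}
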