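# The DB oxygenation measure: a precomputed database of steady-state model
# runs, queried by matching a measured ABG, extrapolated to new settings, and
# used to bound the physiological states consistent with one or two ABGs.

#' Default model-run grid for the database
#'
#' Pure shunt 0--0.5 (step 0.025), V/Q spread 0--2 (step 0.25), cardiac output
#' 3--9 l/min (step 1.5), haemoglobin \{80, 110, 140\} g/l and the common
#' clinical FiO2 settings. All axes are configurable.
#'
#' @param shunt,vq_sigma,q_total,hb,fio2 Grid axes.
#' @return A named list of axes for [build_db()].
#' @export
default_db_grid <- function(shunt = seq(0, 0.5, by = 0.025),
                            vq_sigma = seq(0, 2, by = 0.25),
                            q_total = seq(3, 9, by = 1.5),
                            hb = c(80, 110, 140),
                            fio2 = c(0.21, seq(0.25, 1, by = 0.05))) {
  list(shunt = shunt, vq_sigma = vq_sigma, q_total = q_total, hb = hb,
       fio2 = fio2)
}

#' Build the model-run database
#'
#' Runs the steady-state simulator over the full grid, with alveolar
#' ventilation tuned so every run sits at the reference PaCO2
#' (normocapnia by default).
#'
#' @param grid Named list of axes (see [default_db_grid()]) or a data frame of
#'   input combinations.
#' @param assumptions A [phys_assumptions()] object.
#' @param paco2_ref Reference PaCO2 the database is conditioned on, kPa.
#' @param n_compartments Compartment count passed to [steady_state_batch()].
#' @return A tibble of class `abg_db`, one converged model run per row.
#' @export
build_db <- function(grid = default_db_grid(),
                     assumptions = phys_assumptions(), paco2_ref = 5.3,
                     n_compartments = 50) {
  a <- as_assumptions(assumptions)
  runs <- if (is.data.frame(grid)) as_tibble(grid) else do.call(expand_grid, grid)
  runs$alveolar_ventilation <- va_for_paco2(paco2_ref, a)
  runs$vo2 <- a$vo2
  db <- steady_state_batch(runs, a, n_compartments = n_compartments,
                           strict = FALSE)
  n_bad <- sum(!db$converged)
  if (n_bad > 0)
    inform(sprintf("dropping %d infeasible/unconverged grid point(s)", n_bad))
  db <- db %>% filter(.data$converged)
  structure(db, class = c("abg_db", class(db)),
            assumptions = a, paco2_ref = paco2_ref,
            n_compartments = n_compartments)
}

#' Matching tolerances for database queries
#'
#' Defaults mirror the pipeline's stability window: PaO2 within 0.5 kPa,
#' PaCO2 within 0.3 kPa, FiO2 exact to the grid, haemoglobin matched to the
#' nearest grid value.
#'
#' @param pao2,paco2 Absolute match windows, kPa.
#' @param fio2 Absolute window on FiO2 (exact-to-grid by default).
#' @param hb Either `"nearest"` (match the grid value closest to the query) or
#'   an absolute window in g/l.
#' @return A named list of tolerances.
#' @export
db_tolerances <- function(pao2 = 0.5, paco2 = 0.3, fio2 = 1e-6,
                          hb = "nearest") {
  list(pao2 = pao2, paco2 = paco2, fio2 = fio2, hb = hb)
}

#' Match an ABG against the model-run database
#'
#' Returns every run whose steady-state outputs lie within the tolerances of
#' the measured blood gas. An empty match set is reported, not an error.
#'
#' @param db An `abg_db` from [build_db()].
#' @param record A one-row data frame (or named list) with `fio2`, `pao2`,
#'   `paco2` and optionally `hb` (falls back to the assumed default).
#' @param tolerances See [db_tolerances()].
#' @return The matching rows of `db` as a tibble.
#' @export
match_abg <- function(db, record, tolerances = db_tolerances()) {
  if (nrow(db) == 0) abort("database is empty", class = "effshunt_invalid_input")
  a <- attr(db, "assumptions")
  hb_q <- record$hb %||% NA_real_
  if (is.na(hb_q)) hb_q <- a$hb_default
  keep <- abs(db$out_pao2 - record$pao2) <= tolerances$pao2 &
    abs(db$out_paco2 - record$paco2) <= tolerances$paco2 &
    abs(db$fio2 - record$fio2) <= tolerances$fio2
  if (identical(tolerances$hb, "nearest")) {
    hb_grid <- sort(unique(db$hb))
    hb_near <- hb_grid[which.min(abs(hb_grid - hb_q))]
    keep <- keep & db$hb == hb_near
  } else {
    keep <- keep & abs(db$hb - hb_q) <= tolerances$hb
  }
  as_tibble(db)[keep, , drop = FALSE]
}

#' Extrapolate matched runs to new settings
#'
#' Re-runs the simulator for every matched run at the new FiO2, with alveolar
#' ventilation retuned so the modelled PaCO2 equals the new PaCO2, and returns
#' the arithmetic mean of the predicted PaO2 values. An empty match set gives
#' the no-prediction sentinel `NA` (with attribute `n = 0`).
#'
#' @param matches Matched runs from [match_abg()].
#' @param new_fio2,new_paco2 Settings of the second ABG.
#' @param assumptions A [phys_assumptions()] object.
#' @param n_compartments Compartment count for the re-runs.
#' @return Mean predicted PaO2 (kPa) with attribute `n`, the number of runs
#'   contributing.
#' @export
db_predict <- function(matches, new_fio2, new_paco2,
                       assumptions = phys_assumptions(),
                       n_compartments = 50) {
  if (nrow(matches) == 0)
    return(structure(NA_real_, n = 0L))
  a <- as_assumptions(assumptions)
  runs <- as_tibble(matches) %>%
    select("shunt", "vq_sigma", "q_total", "hb", "vo2") %>%
    mutate(fio2 = new_fio2,
           alveolar_ventilation = va_for_paco2(new_paco2, a, vo2 = .data$vo2))
  out <- steady_state_batch(runs, a, n_compartments = n_compartments,
                            strict = FALSE)
  ok <- out$converged
  structure(mean(out$out_pao2[ok]), n = sum(ok))
}

#' Physiological states consistent with one or two ABGs
#'
#' Matches each record against the database and intersects the matched
#' parameter combinations (shunt, V/Q spread, cardiac output, haemoglobin).
#' With a single ABG a wide envelope of states remains; a second ABG at a
#' different FiO2 can only shrink it (set intersection), usually strictly.
#'
#' @param db An `abg_db` from [build_db()].
#' @param records A data frame of one or two ABG records from the same
#'   patient (different FiO2 if two).
#' @param tolerances See [db_tolerances()].
#' @return An object of class `es_envelope`: a list with `cells` (the matched
#'   parameter combinations), `summary` (per-parameter min/max) and
#'   `n_records`. An empty intersection yields zero cells, reported.
#' @export
constrain_state <- function(db, records, tolerances = db_tolerances()) {
  records <- as_tibble(records)
  if (!nrow(records) %in% 1:2)
    abort("constrain_state takes one or two records",
          class = "effshunt_invalid_input")
  if (nrow(records) == 2 && "patient_id" %in% names(records) &&
      length(unique(records$patient_id)) != 1)
    abort("records must come from the same patient",
          class = "effshunt_invalid_input")
  params <- c("shunt", "vq_sigma", "q_total", "hb")
  cells <- NULL
  for (i in seq_len(nrow(records))) {
    m <- match_abg(db, records[i, ], tolerances) %>% distinct(across(all_of(params)))
    cells <- if (is.null(cells)) m else inner_join(cells, m, by = params)
  }
  summ <- if (nrow(cells) == 0) {
    tibble(parameter = params, min = NA_real_, max = NA_real_)
  } else {
    cells %>%
      pivot_longer(everything(), names_to = "parameter", values_to = "value") %>%
      group_by(.data$parameter) %>%
      summarise(min = min(.data$value), max = max(.data$value), .groups = "drop")
  }
  structure(list(cells = cells, summary = summ, n_records = nrow(records)),
            class = "es_envelope")
}

#' @export
print.es_envelope <- function(x, ...) {
  cat(sprintf("State envelope from %d ABG(s): %d grid cell(s)\n",
              x$n_records, nrow(x$cells)))
  print(x$summary)
  invisible(x)
}

#' @describeIn constrain_state Tile plot of the matched (shunt, V/Q spread)
#'   cells.
#' @param object An `es_envelope`.
#' @param ... Ignored.
#' @method autoplot es_envelope
#' @export
autoplot.es_envelope <- function(object, ...) {
  counts <- object$cells %>% count(.data$shunt, .data$vq_sigma)
  ggplot(counts, aes(x = .data$shunt, y = .data$vq_sigma, fill = .data$n)) +
    geom_tile() +
    labs(x = "pure shunt fraction", y = "V/Q heterogeneity index",
         fill = "matching\nruns",
         title = sprintf("States consistent with %d ABG(s)", object$n_records)) +
    theme_minimal()
}

#' Oxygen-response band for an envelope of states
#'
#' Extrapolates every parameter combination in an envelope across a range of
#' FiO2 settings and plots the band of attainable PaO2 -- the uncertainty in a
#' patient's oxygen responsiveness given the matched states.
#'
#' @param db An `abg_db` (supplies assumptions and the reference PaCO2).
#' @param envelope An `es_envelope` from [constrain_state()].
#' @param fio2 FiO2 settings to extrapolate to.
#' @param paco2 PaCO2 the extrapolation is conditioned on, kPa.
#' @param max_cells Cap on envelope cells extrapolated (sampled
#'   deterministically by taking every k-th cell) to bound cost.
#' @return A ggplot with the PaO2 band over FiO2.
#' @export
plot_oxygen_response <- function(db, envelope,
                                 fio2 = c(0.21, seq(0.25, 1, by = 0.05)),
                                 paco2 = attr(db, "paco2_ref"),
                                 max_cells = 200) {
  cells <- envelope$cells
  if (nrow(cells) == 0)
    abort("envelope has no cells to extrapolate", class = "effshunt_invalid_input")
  if (nrow(cells) > max_cells)
    cells <- cells[seq(1, nrow(cells), length.out = max_cells), ]
  a <- attr(db, "assumptions")
  runs <- expand_grid(cells, fio2 = fio2) %>%
    mutate(vo2 = a$vo2, alveolar_ventilation = va_for_paco2(paco2, a))
  out <- steady_state_batch(runs, a,
                            n_compartments = attr(db, "n_compartments"),
                            strict = FALSE) %>%
    filter(.data$converged) %>%
    group_by(.data$fio2) %>%
    summarise(lo = min(.data$out_pao2), hi = max(.data$out_pao2),
              mid = mean(.data$out_pao2), .groups = "drop")
  ggplot(out, aes(x = .data$fio2)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.3) +
    geom_line(aes(y = .data$mid)) +
    labs(x = "FiO2", y = "possible PaO2 (kPa)",
         title = sprintf("Oxygen response band (%d ABG%s)",
                         envelope$n_records,
                         if (envelope$n_records > 1) "s" else "")) +
    theme_minimal()
}
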