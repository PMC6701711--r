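# Seeded generator of synthetic ICU weaning cohorts: per-patient latent
# shunt, V/Q heterogeneity, cardiac output and haemoglobin; monotone
# non-increasing FiO2 trajectories on the common clinical settings; blood
# gases from the steady-state simulator plus additive measurement noise.

FIO2_SETTINGS <- c(0.21, seq(0.25, 1, by = 0.05))

#' Specification of a synthetic ABG cohort
#'
#' Defaults emulate a general-ICU weaning population: latent pure shunt
#' Beta(2, 5) scaled to [0, 0.5] (population mean about 0.14), V/Q spread
#' Gamma(2, scale 0.3) truncated at 2, cardiac output normal around
#' 6.5 l/min, haemoglobin normal around 105 g/l, ventilation to a normocapnic
#' PaCO2 target, FiO2 weaned downwards over the common clinical settings, and
#' additive Gaussian measurement noise on the tensions (0.5 kPa on PaO2,
#' 0.15 kPa on PaCO2), truncated at physiological bounds.
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Inclusive range of ABG counts per patient.
#' @param shunt_shape Beta shape parameters of the latent shunt.
#' @param shunt_max Upper end of the scaled shunt support.
#' @param vq_shape,vq_scale,vq_max Gamma parameters (and truncation) of the
#'   latent V/Q spread.
#' @param q_mean,q_sd,q_range Cardiac output distribution, l/min.
#' @param hb_mean,hb_sd,hb_range Haemoglobin distribution, g/l.
#' @param fio2_start_range Range of starting FiO2 (snapped to clinical
#'   settings).
#' @param step_probs Probabilities of (stay, one step down, two steps down)
#'   at each successive sample.
#' @param paco2_target Ventilation target PaCO2, kPa.
#' @param pao2_noise_sd,paco2_noise_sd Measurement noise, kPa.
#' @param interval_meanlog,interval_sdlog Log-normal sampling-interval
#'   parameters (minutes).
#' @param prop_unventilated Fraction of patients flagged not ventilated.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200, samples_per_patient = c(3, 6),
                        shunt_shape = c(2, 5), shunt_max = 0.5,
                        vq_shape = 2, vq_scale = 0.3, vq_max = 2,
                        q_mean = 6.5, q_sd = 1.2, q_range = c(3, 12),
                        hb_mean = 105, hb_sd = 18, hb_range = c(60, 170),
                        fio2_start_range = c(0.4, 0.8),
                        step_probs = c(stay = 0.3, down1 = 0.45, down2 = 0.25),
                        paco2_target = 5.3,
                        pao2_noise_sd = 0.5, paco2_noise_sd = 0.15,
                        interval_meanlog = log(60), interval_sdlog = 0.4,
                        prop_unventilated = 0.05, seed = 1L) {
  stopifnot(n_patients >= 0, pao2_noise_sd >= 0, paco2_noise_sd >= 0,
            all(step_probs >= 0), length(samples_per_patient) == 2)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic ABG cohort
#'
#' Draws per-patient latent physiology, builds a non-increasing FiO2
#' trajectory with timestamps, produces each blood gas with
#' [steady_state_batch()] and adds measurement noise. Infeasible latent draws
#' are redrawn with bounded retries. Deterministic under the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @param assumptions A [phys_assumptions()] object (supplies VO2, RER and the
#'   content-model constants).
#' @param n_compartments Simulator compartment count.
#' @param max_retries Redraw attempts for infeasible latent combinations.
#' @return A tibble of ABG records (`patient_id`, `timestamp`, `fio2`,
#'   `pao2`, `paco2`, `ph`, `hb`, `temperature`, `ventilated`) with the latent
#'   truth alongside in `true_*` columns.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            assumptions = phys_assumptions(),
                            n_compartments = 50, max_retries = 5) {
  stopifnot(inherits(spec, "cohort_spec"))
  a <- as_assumptions(assumptions)
  if (spec$n_patients == 0) return(empty_cohort())
  with_seed(as.integer(spec$seed), {
    latents <- draw_latents(spec)
    for (attempt in seq_len(max_retries)) {
      records <- build_trajectories(latents, spec, a)
      sim <- steady_state_batch(records, a, n_compartments = n_compartments,
                                strict = FALSE)
      bad_patients <- unique(sim$patient[!sim$converged])
      if (length(bad_patients) == 0) break
      if (attempt == max_retries)
        abort(sprintf("latent redraw failed for %d patient(s) after %d attempts",
                      length(bad_patients), max_retries),
              class = "effshunt_infeasible")
      inform(sprintf("redrawing %d infeasible patient(s)", length(bad_patients)))
      latents[bad_patients, -1] <- draw_latents(spec,
                                                n = length(bad_patients))[, -1]
    }
    noise_and_assemble(sim, spec, a)
  })
}

empty_cohort <- function() {
  tibble(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
         fio2 = numeric(), pao2 = numeric(), paco2 = numeric(), ph = numeric(),
         hb = numeric(), temperature = numeric(), ventilated = logical(),
         true_shunt = numeric(), true_vq_sigma = numeric(), true_q = numeric(),
         true_pao2 = numeric(), true_paco2 = numeric())
}

draw_latents <- function(spec, n = spec$n_patients) {
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  tibble(
    patient = seq_len(n),
    shunt = rbeta(n, spec$shunt_shape[1], spec$shunt_shape[2]) * spec$shunt_max,
    vq_sigma = pmin(rgamma(n, shape = spec$vq_shape, scale = spec$vq_scale),
                    spec$vq_max),
    q_total = clamp(rnorm(n, spec$q_mean, spec$q_sd), spec$q_range),
    hb = clamp(rnorm(n, spec$hb_mean, spec$hb_sd), spec$hb_range),
    ventilated = runif(n) >= spec$prop_unventilated,
    n_samples = resample(seq(spec$samples_per_patient[1],
                             spec$samples_per_patient[2]), n))
}

# sample() that never treats a length-1 x as 1:x
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

build_trajectories <- function(latents, spec, a) {
  starts <- FIO2_SETTINGS[FIO2_SETTINGS >= spec$fio2_start_range[1] &
                            FIO2_SETTINGS <= spec$fio2_start_range[2]]
  va <- va_for_paco2(spec$paco2_target, a)
  p <- spec$step_probs / sum(spec$step_probs)
  rows <- map(seq_len(nrow(latents)), function(i) {
    k <- latents$n_samples[i]
    idx0 <- which(FIO2_SETTINGS == sample(starts, 1))
    steps <- sample(c(0L, -1L, -2L), k - 1, replace = TRUE, prob = p)
    idx <- pmax(cumsum(c(idx0, steps)), 1L)
    mins <- cumsum(c(0, pmax(1, round(rlnorm(k - 1, spec$interval_meanlog,
                                             spec$interval_sdlog)))))
    tibble(patient = latents$patient[i], sample = seq_len(k),
           minutes = mins, fio2 = FIO2_SETTINGS[idx])
  })
  bind_rows(rows) %>%
    left_join(latents, by = "patient") %>%
    mutate(alveolar_ventilation = va, vo2 = a$vo2)
}

noise_and_assemble <- function(sim, spec, a) {
  n <- nrow(sim)
  pio2 <- sim$fio2 * (a$pb - a$ph2o)
  pao2 <- pmin(pmax(sim$out_pao2 + rnorm(n, 0, spec$pao2_noise_sd), 0.5),
               pio2 - 0.05)
  paco2 <- pmin(pmax(sim$out_paco2 + rnorm(n, 0, spec$paco2_noise_sd), 1.5), 15)
  origin <- as.POSIXct("2026-01-01 08:00:00", tz = "UTC")
  tibble(
    patient_id = sprintf("P%04d", sim$patient),
    timestamp = origin + (sim$patient * 7 * 86400) + sim$minutes * 60,
    fio2 = sim$fio2,
    pao2 = pao2,
    paco2 = paco2,
    ph = ph_from_paco2(paco2, a$hco3),
    hb = sim$hb,
    temperature = a$temperature,
    ventilated = sim$ventilated,
    true_shunt = sim$shunt,
    true_vq_sigma = sim$vq_sigma,
    true_q = sim$q_total,
    true_pao2 = sim$out_pao2,
    true_paco2 = sim$out_paco2)
}

#' Inject FiO2 transcription errors
#'
#' Clinician-entered FiO2 is a known error source; this corrupts a stated
#' fraction of records by moving FiO2 to an adjacent common setting for
#' robustness testing. The original value is kept in `true_fio2` and corrupted
#' rows are flagged in `fio2_corrupted`.
#'
#' @param records A cohort tibble.
#' @param rate Fraction of records to corrupt, in [0, 1].
#' @param seed Integer seed.
#' @return `records` with `fio2` possibly replaced and the truth columns
#'   appended.
#' @export
inject_fio2_transcription_errors <- function(records, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  records <- as_tibble(records)
  with_seed(as.integer(seed), {
    n <- nrow(records)
    hit <- runif(n) < rate
    idx <- match_nearest(records$fio2, FIO2_SETTINGS)
    shift <- sample(c(-1L, 1L), n, replace = TRUE)
    new_idx <- pmin(pmax(idx + shift, 1L), length(FIO2_SETTINGS))
    # at the range ends move inward so every hit really changes the value
    new_idx[new_idx == idx] <- idx[new_idx == idx] +
      ifelse(idx[new_idx == idx] == 1L, 1L, -1L)
    records %>%
      mutate(true_fio2 = .data$fio2,
             fio2_corrupted = hit,
             fio2 = ifelse(hit, FIO2_SETTINGS[new_idx], .data$fio2))
  })
}

match_nearest <- function(x, grid) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}
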