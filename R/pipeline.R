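# Cohort-level predictive validity: pair selection, per-measure PaO2
# prediction, median-absolute-error scoring, the unchanged-FiO2 noise floor,
# and nonparametric comparison of the error distributions.

REQUIRED_ABG_COLS <- c("patient_id", "timestamp", "fio2", "pao2", "paco2",
                       "ph", "ventilated")

#' Select qualifying ABG pairs
#'
#' Pairs every record with every later record of the same patient that
#' satisfies the inclusion criteria: taken within the time window (default 3 h,
#' interval strictly positive), both records from a mechanically ventilated
#' patient, FiO2 reduced between the samples (strict), and stable alveolar
#' ventilation (|change in PaCO2| < 0.3 kPa, strict). Records with missing
#' required fields are skipped with a logged count. Output ordering is
#' deterministic (patient, first timestamp, second timestamp).
#'
#' @param records Data frame of ABG records with columns `patient_id`,
#'   `timestamp` (POSIXct or ISO-8601 string), `fio2`, `pao2`, `paco2`, `ph`,
#'   `ventilated`, and optionally `hb`.
#' @param window Maximum interval between the two samples, minutes.
#' @param paco2_stability Strict bound on |change in PaCO2|, kPa.
#' @param fio2_rule `"decrease"` (predictive-validity pairs) or `"unchanged"`
#'   (baseline noise pairs).
#' @param consecutive_only Restrict to pairs of consecutive samples.
#' @return A tibble of pairs, first-record columns suffixed `_1`, second
#'   `_2`, with `interval` in minutes.
#' @export
filter_pairs <- function(records, window = 180, paco2_stability = 0.3,
                         fio2_rule = c("decrease", "unchanged"),
                         consecutive_only = FALSE) {
  fio2_rule <- match.arg(fio2_rule)
  records <- as_tibble(records)
  miss <- setdiff(REQUIRED_ABG_COLS, names(records))
  if (length(miss) > 0)
    abort(sprintf("records lack required column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "effshunt_invalid_input")
  if (is.character(records$timestamp))
    records$timestamp <- as.POSIXct(records$timestamp, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                   "%Y-%m-%d %H:%M:%S"))
  complete <- stats::complete.cases(
    records[, intersect(REQUIRED_ABG_COLS, names(records))])
  if (any(!complete))
    inform(sprintf("skipping %d record(s) with missing required fields",
                   sum(!complete)))
  recs <- records[complete, ] %>%
    arrange(.data$patient_id, .data$timestamp) %>%
    group_by(.data$patient_id) %>%
    mutate(.order = row_number()) %>%
    ungroup()
  pairs <- inner_join(recs, recs, by = "patient_id", suffix = c("_1", "_2"),
                      relationship = "many-to-many") %>%
    mutate(interval = as.numeric(difftime(.data$timestamp_2,
                                          .data$timestamp_1, units = "mins"))) %>%
    filter(.data$interval > 0, .data$interval <= window,
           .data$ventilated_1, .data$ventilated_2,
           # round to the analyser's resolution so the strict 0.3 kPa boundary
           # is not blurred by binary floating point (5.6 - 5.3 != 0.3)
           round(abs(.data$paco2_2 - .data$paco2_1), 9) < paco2_stability)
  pairs <- switch(fio2_rule,
    decrease = filter(pairs, .data$fio2_2 < .data$fio2_1),
    unchanged = filter(pairs, .data$fio2_2 == .data$fio2_1))
  if (consecutive_only)
    pairs <- filter(pairs, .data$.order_2 == .data$.order_1 + 1L)
  pairs %>%
    select(-".order_1", -".order_2") %>%
    arrange(.data$patient_id, .data$timestamp_1, .data$timestamp_2)
}

#' Baseline noise floor from unchanged-FiO2 pairs
#'
#' Pairs meeting every selection criterion except that FiO2 is unchanged
#' rather than reduced carry no oxygenation signal: the distribution of their
#' |change in PaO2| is the noise floor no predictive measure can beat.
#'
#' @inheritParams filter_pairs
#' @return A list of class `es_baseline` with `deltas` (|change in PaO2| per
#'   pair, kPa), `median` and `n`. Empty input yields `n = 0` and `NA` median.
#' @export
baseline_error <- function(records, window = 180, paco2_stability = 0.3,
                           consecutive_only = FALSE) {
  pairs <- filter_pairs(records, window, paco2_stability,
                        fio2_rule = "unchanged",
                        consecutive_only = consecutive_only)
  deltas <- abs(pairs$pao2_2 - pairs$pao2_1)
  if (length(deltas) == 0) inform("no unchanged-FiO2 pairs found")
  structure(list(deltas = deltas,
                 median = if (length(deltas)) median(deltas) else NA_real_,
                 n = length(deltas)),
            class = "es_baseline")
}

#' @export
print.es_baseline <- function(x, ...) {
  cat(sprintf("Baseline |dPaO2| over %d unchanged-FiO2 pairs: median %.3f kPa\n",
              x$n, x$median))
  invisible(x)
}

#' Predictive validity of the oxygenation measures
#'
#' For every pair, each measure is computed on the first ABG, PaO2 is
#' predicted at the second ABG's FiO2 and PaCO2 assuming the measure is
#' unchanged, and the absolute prediction error against the measured second
#' PaO2 is recorded. The median absolute error (MAE) per measure is the
#' predictive validity. Prediction failures (infeasible A-a or ES
#' predictions, empty database match sets) are counted and excluded from the
#' medians; with `failure_policy = "drop_pair"` a failed pair is dropped for
#' all measures so the medians stay comparable.
#'
#' @param pairs Pair table from [filter_pairs()].
#' @param measures Subset of `c("aa", "pf", "es", "db")`.
#' @param db An `abg_db`, required when `"db"` is among the measures.
#' @param assumptions A [phys_assumptions()] object.
#' @param tolerances Database matching tolerances, see [db_tolerances()].
#' @param failure_policy `"pairwise"` (default) or `"drop_pair"`.
#' @return An object of class `es_validity` with elements `errors` (long
#'   tibble: pair, measure, predicted, observed, abs_error), `summary`
#'   (per-measure MAE and counts), `tests` (from [compare_errors()]) and
#'   `n_pairs`.
#' @export
evaluate_validity <- function(pairs, measures = c("aa", "pf", "es"),
                              db = NULL, assumptions = phys_assumptions(),
                              tolerances = db_tolerances(),
                              failure_policy = c("pairwise", "drop_pair")) {
  failure_policy <- match.arg(failure_policy)
  measures <- match.arg(measures, c("aa", "pf", "es", "db"),
                        several.ok = TRUE)
  if ("db" %in% measures && is.null(db))
    abort("measure 'db' requires a database from build_db()",
          class = "effshunt_invalid_input")
  a <- as_assumptions(assumptions)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0)
    abort("no pairs to evaluate", class = "effshunt_invalid_input")
  hb1 <- if ("hb_1" %in% names(pairs)) pairs$hb_1 else rep(NA_real_, nrow(pairs))
  hb2 <- if ("hb_2" %in% names(pairs)) pairs$hb_2 else rep(NA_real_, nrow(pairs))
  hb1 <- suppressWarnings(resolve_hb(hb1, nrow(pairs), a))
  hb2 <- suppressWarnings(resolve_hb(hb2, nrow(pairs), a))

  preds <- list()
  if ("aa" %in% measures) {
    aa1 <- aa_difference(pairs$pao2_1, pairs$fio2_1, pairs$paco2_1, a)
    preds$aa <- predict_pao2_aa(aa1, pairs$fio2_2, pairs$paco2_2, a,
                                strict = FALSE)
  }
  if ("pf" %in% measures) {
    preds$pf <- predict_pao2_pf(pf_ratio(pairs$pao2_1, pairs$fio2_1),
                                pairs$fio2_2)
  }
  if ("es" %in% measures) {
    es1 <- effective_shunt(pairs$pao2_1, pairs$fio2_1, pairs$paco2_1,
                           pairs$ph_1, hb1, a)
    preds$es <- predict_pao2_es(es1, pairs$fio2_2, pairs$paco2_2,
                                pairs$ph_2, hb2, a, strict = FALSE)
  }
  if ("db" %in% measures) {
    preds$db <- db_predict_pairs(pairs, db, tolerances, hb1)
  }

  errors <- imap(preds, function(p, m) {
    tibble(pair = seq_len(nrow(pairs)), measure = m,
           predicted = p, observed = pairs$pao2_2,
           abs_error = abs(p - pairs$pao2_2))
  }) %>% bind_rows()
  if (failure_policy == "drop_pair") {
    bad_pairs <- errors %>% filter(is.na(.data$abs_error)) %>% pull(.data$pair)
    errors <- errors %>%
      mutate(abs_error = ifelse(.data$pair %in% bad_pairs, NA_real_,
                                .data$abs_error))
  }
  summary <- errors %>%
    group_by(.data$measure) %>%
    summarise(mae = median(.data$abs_error, na.rm = TRUE),
              n_scored = sum(!is.na(.data$abs_error)),
              n_failed = sum(is.na(.data$abs_error)), .groups = "drop") %>%
    arrange(match(.data$measure, c("aa", "pf", "db", "es")))
  tests <- if (length(measures) >= 2)
    tryCatch(compare_errors(errors),
             effshunt_invalid_input = function(e) NULL)
  else NULL
  structure(list(errors = errors, summary = summary, tests = tests,
                 n_pairs = nrow(pairs), measures = measures,
                 failure_policy = failure_policy),
            class = "es_validity")
}

# Batched DB prediction over a pair table: gather every matched run for every
# pair, extrapolate them all in one simulator call, then average per pair.
db_predict_pairs <- function(pairs, db, tolerances, hb1) {
  a <- attr(db, "assumptions")
  matched <- map(seq_len(nrow(pairs)), function(i) {
    rec <- list(fio2 = pairs$fio2_1[i], pao2 = pairs$pao2_1[i],
                paco2 = pairs$paco2_1[i], hb = hb1[i])
    m <- match_abg(db, rec, tolerances)
    if (nrow(m) == 0) return(NULL)
    m %>%
      select("shunt", "vq_sigma", "q_total", "hb", "vo2") %>%
      mutate(.pair = i, fio2 = pairs$fio2_2[i],
             alveolar_ventilation = va_for_paco2(pairs$paco2_2[i], a,
                                                 vo2 = .data$vo2))
  })
  matched <- bind_rows(matched)
  out <- rep(NA_real_, nrow(pairs))
  if (nrow(matched) == 0) return(out)
  sim <- steady_state_batch(matched, a,
                            n_compartments = attr(db, "n_compartments"),
                            strict = FALSE) %>%
    filter(.data$converged) %>%
    group_by(.data$.pair) %>%
    summarise(pred = mean(.data$out_pao2), .groups = "drop")
  out[sim$.pair] <- sim$pred
  out
}

#' Nonparametric comparison of prediction-error distributions
#'
#' Kruskal-Wallis omnibus test across measures, then all pairwise two-sided
#' Mann-Whitney U tests with Bonferroni correction (multiplication by the
#' number of pairwise comparisons, capped at 1). Exact U distributions are
#' enumerated for small untied samples (both n <= 20); otherwise the normal
#' approximation with tie correction is used. Degenerate all-tied input
#' reports p = 1 rather than erroring.
#'
#' @param errors Long data frame with columns `measure` and `abs_error`
#'   (`NA`s dropped), e.g. the `errors` element of [evaluate_validity()].
#' @return A list of class `es_error_tests`: `kruskal` (statistic, df,
#'   p.value) and `pairwise` (tibble of U statistics, raw and adjusted p).
#' @export
compare_errors <- function(errors) {
  errors <- as_tibble(errors) %>% filter(!is.na(.data$abs_error))
  groups <- split(errors$abs_error, errors$measure)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2)
    abort("need >= 2 measures with >= 2 errors each",
          class = "effshunt_invalid_input")
  all_tied <- length(unique(unlist(groups))) == 1
  kw <- if (all_tied) {
    list(statistic = 0, parameter = length(groups) - 1, p.value = 1)
  } else {
    k <- kruskal.test(groups)
    list(statistic = unname(k$statistic), parameter = unname(k$parameter),
         p.value = k$p.value)
  }
  combos <- utils::combn(names(groups), 2, simplify = FALSE)
  n_comp <- length(combos)
  pairwise <- map(combos, function(cp) {
    x <- groups[[cp[1]]]; y <- groups[[cp[2]]]
    ties <- anyDuplicated(c(x, y)) > 0
    if (length(unique(c(x, y))) == 1) {
      u <- length(x) * length(y) / 2; p <- 1
    } else {
      exact <- !ties && length(x) <= 20 && length(y) <= 20
      wt <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE))
      u <- unname(wt$statistic); p <- wt$p.value
    }
    tibble(measure_1 = cp[1], measure_2 = cp[2], u = u,
           p_value = p, p_adjusted = pmin(1, p * n_comp))
  }) %>% bind_rows()
  structure(list(kruskal = kw, pairwise = pairwise,
                 n_comparisons = n_comp),
            class = "es_error_tests")
}

#' @export
print.es_error_tests <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f (df %d), p = %.3g\n",
              x$kruskal$statistic, x$kruskal$parameter, x$kruskal$p.value))
  print(x$pairwise)
  invisible(x)
}

#' @export
print.es_validity <- function(x, ...) {
  cat(sprintf("Predictive validity over %d ABG pairs (failure policy: %s)\n",
              x$n_pairs, x$failure_policy))
  print(x$summary)
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' @describeIn evaluate_validity Per-measure summary: MAE, counts, and the
#'   Bonferroni-adjusted p-value of each pairwise comparison is available via
#'   `$tests`.
#' @param x An `es_validity` object.
#' @param ... Ignored.
#' @method tidy es_validity
#' @export
tidy.es_validity <- function(x, ...) x$summary

#' @describeIn evaluate_validity One-row overview with the omnibus test.
#' @method glance es_validity
#' @export
glance.es_validity <- function(x, ...) {
  tibble(n_pairs = x$n_pairs,
         n_measures = length(x$measures),
         kruskal_h = if (is.null(x$tests)) NA_real_ else x$tests$kruskal$statistic,
         kruskal_p = if (is.null(x$tests)) NA_real_ else x$tests$kruskal$p.value)
}

#' @describeIn evaluate_validity Boxplot of absolute prediction errors by
#'   measure.
#' @param object An `es_validity` object.
#' @method autoplot es_validity
#' @export
autoplot.es_validity <- function(object, ...) {
  ggplot(filter(object$errors, !is.na(.data$abs_error)),
         aes(x = .data$measure, y = .data$abs_error)) +
    geom_boxplot(outlier.alpha = 0.25) +
    labs(x = NULL, y = "|predicted - measured PaO2| (kPa)",
         title = "Predictive validity of oxygenation measures") +
    theme_minimal()
}
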