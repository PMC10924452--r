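# External validation: clinical outcomes (biologic use, surgery, remission)
# are extracted from simulated trajectories on a semiannual grid (2 cycles
# per interval, 9 intervals over the 4.5-year follow-up) under a permissive
# or restrictive definition, summarised as cumulative incidences, and
# compared with an empirical series through a Beta-posterior acceptance
# statistic: starting from a prior with mean 50%, the posterior probability
# that a decision maker accepts the model is (k+1)/(n+2) after k of n
# replicates fall within a proximity band of the empirical value.

#' Clinical outcome definitions
#'
#' The permissive definition counts any 6-month period of biologic use, all
#' surgery types, and remission (CDAI <= 150) lasting any 6 months preceded
#' by active disease; the restrictive definition requires at least 12
#' months of biologic use, only elective and emergency surgeries, and
#' remission lasting at least 12 months.
#'
#' @param name `"permissive"` or `"restrictive"`.
#' @return A named list with `name`, `biologic_min_months`,
#'   `surgery_types_included`, `remission_min_months`.
#' @export
outcome_definition <- function(name = c("permissive", "restrictive")) {
  name <- match.arg(name)
  if (name == "permissive") {
    list(name = name, biologic_min_months = 6L,
         surgery_types_included = c("elective", "emergency", "other"),
         remission_min_months = 6L)
  } else {
    list(name = name, biologic_min_months = 12L,
         surgery_types_included = c("elective", "emergency"),
         remission_min_months = 12L)
  }
}

# runs of TRUE in a logical vector: tibble(start, length)
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], length = r$lengths[r$values])
}

#' Extract clinical outcomes from a simulated trajectory
#'
#' Maps per-cycle records onto the semiannual grid and applies an outcome
#' definition. A remission interval requires every cycle in the window to
#' have CDAI <= 150 and the preceding interval (or the baseline record for
#' the first interval) to contain active disease (CDAI > 150). A biologic
#' period is a maximal run of intervals fully covered by biologic therapy
#' of at least the definition's minimum length. Surgeries are filtered by
#' type.
#'
#' @param trajectory Trajectory tibble from [simulate_arm()].
#' @param events Event tibble from [simulate_arm()] (surgery rows carry
#'   `surgery_type`).
#' @param cohort Baseline cohort (for the baseline CDAI preceding interval 1).
#' @param definition An [outcome_definition()].
#' @param n_intervals Number of semiannual intervals in follow-up
#'   (default 9, i.e. 4.5 years; requires 2 cycles per interval).
#' @return One row per patient: `first_biologic_interval`,
#'   `first_surgery_interval`, `first_remission_interval` (NA when the
#'   outcome never occurs), `total_biologic_periods`, `total_surgeries`,
#'   `total_remission_months`.
#' @export
extract_outcomes <- function(trajectory, events, cohort,
                             definition = outcome_definition("permissive"),
                             n_intervals = 9L) {
  need_cycles <- 2L * n_intervals
  max_cycle <- if (nrow(trajectory)) max(trajectory$cycle) else 0L
  if (max_cycle < need_cycles) {
    abort(sprintf("trajectory covers %d cycles but the follow-up needs %d",
                  max_cycle, need_cycles))
  }
  w_rem <- definition$remission_min_months %/% 6L
  w_bio <- definition$biologic_min_months %/% 6L

  traj <- trajectory %>%
    filter(.data$cycle <= need_cycles) %>%
    mutate(interval = ceiling(.data$cycle / 2)) %>%
    group_by(.data$patient_id, .data$interval) %>%
    summarise(
      quiet = all(.data$cdai <= 150),
      active = any(.data$cdai > 150),
      bio = all(.data$on_biologic),
      .groups = "drop"
    )

  base <- tibble(patient_id = cohort$patient_id,
                 baseline_active = cohort$baseline_cdai > 150)

  surg <- events %>%
    filter(.data$kind == "surgery",
           .data$surgery_type %in% definition$surgery_types_included,
           .data$cycle <= need_cycles) %>%
    mutate(interval = as.integer(ceiling(.data$cycle / 2)))
  surg <- if (nrow(surg) == 0) {
    tibble(patient_id = character(0),
           first_surgery_interval = integer(0), total_surgeries = integer(0))
  } else {
    surg %>%
      group_by(.data$patient_id) %>%
      summarise(first_surgery_interval = min(.data$interval),
                total_surgeries = dplyr::n(), .groups = "drop")
  }

  per_patient <- traj %>%
    arrange(.data$patient_id, .data$interval) %>%
    group_by(.data$patient_id) %>%
    summarise(
      res = list(list(quiet = .data$quiet, active = .data$active,
                      bio = .data$bio)),
      .groups = "drop"
    ) %>%
    left_join(base, by = "patient_id")

  out <- purrr::map2_dfr(per_patient$res, per_patient$baseline_active,
    function(v, base_active) {
      quiet <- v$quiet; active <- v$active; bio <- v$bio
      k <- length(quiet)
      # remission: maximal quiet runs preceded by an active period
      runs <- true_runs(quiet)
      preceded <- vapply(runs$start, function(s) {
        if (s == 1L) isTRUE(base_active) else active[s - 1L]
      }, logical(1))
      qualifying <- runs[preceded & runs$length >= w_rem, ]
      first_rem <- if (nrow(qualifying)) min(qualifying$start) else NA_integer_
      total_rem_months <- 6L * sum(qualifying$length)
      # biologic periods: maximal covered runs of sufficient length
      bruns <- true_runs(bio)
      bq <- bruns[bruns$length >= w_bio, ]
      first_bio <- if (nrow(bq)) min(bq$start) else NA_integer_
      tibble(first_biologic_interval = first_bio,
             first_remission_interval = as.integer(first_rem),
             total_biologic_periods = nrow(bq),
             total_remission_months = total_rem_months)
    })
  out <- dplyr::bind_cols(per_patient["patient_id"], out) %>%
    left_join(surg, by = "patient_id") %>%
    mutate(
      total_surgeries = dplyr::coalesce(.data$total_surgeries, 0L),
      definition = definition$name
    ) %>%
    select("patient_id", "first_biologic_interval", "first_surgery_interval",
           "first_remission_interval", "total_biologic_periods",
           "total_surgeries", "total_remission_months", "definition")
  out
}

#' Cumulative incidence on the semiannual grid
#'
#' @param first_intervals Integer vector of first-event interval indices
#'   (NA when the event never occurred).
#' @param n_intervals Number of intervals in the series.
#' @return A tibble `interval`, `incidence`, where `incidence[t]` is the
#'   fraction of patients with a first event at or before interval `t`
#'   (non-decreasing, in \[0,1\]).
#' @export
cumulative_incidence <- function(first_intervals, n_intervals = 9L) {
  n <- length(first_intervals)
  inc <- vapply(seq_len(n_intervals), function(t) {
    if (n == 0) 0 else mean(!is.na(first_intervals) & first_intervals <= t)
  }, numeric(1))
  tibble(interval = seq_len(n_intervals), incidence = inc)
}

#' Count validation replicates within a proximity band
#'
#' @param replicate_totals Numeric vector of per-replicate model totals.
#' @param empirical The empirical (real-world) total.
#' @param proximity Relative proximity band (e.g. 0.10 for 10%); a
#'   replicate succeeds when `|total - empirical| <= proximity *
#'   |empirical|`, boundary inclusive.
#' @param absolute_tolerance Absolute fallback band applied when
#'   `empirical` is zero.
#' @param empirical_interval Optional length-2 numeric: the empirical
#'   uncertainty interval used for the "true value" row (`proximity = 0`);
#'   a replicate succeeds when it falls inside the interval (inclusive).
#' @return Integer count of successful replicates.
#' @export
count_successes <- function(replicate_totals, empirical, proximity,
                            absolute_tolerance = 0,
                            empirical_interval = NULL) {
  if (length(replicate_totals) == 0) abort("replicate_totals must be non-empty")
  if (proximity == 0 && !is.null(empirical_interval)) {
    return(sum(replicate_totals >= empirical_interval[1] &
               replicate_totals <= empirical_interval[2]))
  }
  band <- if (empirical == 0) absolute_tolerance else proximity * abs(empirical)
  sum(abs(replicate_totals - empirical) <= band)
}

#' Beta-posterior model acceptance
#'
#' Starting from a prior on the acceptance probability with mean 50%
#' (uniform, Beta(1,1)), updating on k successes in n validation replicates
#' gives posterior mean (k+1)/(n+2) and an equal-tailed 95% credible
#' interval from the Beta(k+1, n-k+1) quantiles.
#'
#' @param k Number of successful replicates.
#' @param n Number of replicates (default 100).
#' @param prior Prior Beta parameters as `list(a, b)`; the default uniform
#'   prior has mean 0.5. A target acceptance rate of 80% corresponds to
#'   `list(a = 1.6, b = 0.4)`.
#' @return An object of class `cd_acceptance`: a one-row tibble with `k`,
#'   `n`, `posterior_mean`, `ci95_lower`, `ci95_upper` (probabilities).
#' @examples
#' bayesian_acceptance(81, 100)  # posterior mean 0.804
#' @export
bayesian_acceptance <- function(k, n = 100L, prior = list(a = 1, b = 1)) {
  if (any(k < 0) || any(k > n) || n < 1) {
    abort("need 0 <= k <= n and n >= 1")
  }
  a <- prior$a + k
  b <- prior$b + n - k
  out <- tibble(
    k = as.integer(k), n = as.integer(n),
    posterior_mean = a / (a + b),
    ci95_lower = qbeta(0.025, a, b),
    ci95_upper = qbeta(0.975, a, b)
  )
  class(out) <- c("cd_acceptance", class(out))
  out
}

#' Format an acceptance result the way the validation table prints it
#'
#' @param x A `cd_acceptance` row.
#' @return Character, e.g. `"80.4% (72.2%-87.5%)"`.
#' @export
format_acceptance <- function(x) {
  sprintf("%.1f%% (%.1f%%-%.1f%%)",
          round(100 * x$posterior_mean, 1),
          round(100 * x$ci95_lower, 1),
          round(100 * x$ci95_upper, 1))
}

#' Acceptance analysis across proximity bands
#'
#' Computes the Beta-posterior acceptance statistic for one outcome at the
#' true-value row (empirical uncertainty interval) and each relative
#' proximity band.
#'
#' @param replicate_totals Per-replicate model totals.
#' @param empirical Empirical total.
#' @param empirical_interval Length-2 empirical uncertainty interval for
#'   the true-value row.
#' @param proximities Relative proximity bands.
#' @param prior Prior Beta parameters.
#' @return A tibble with one row per proximity (`"true_value"`, `"1%"`,
#'   ...), the success count, posterior mean and 95% credible interval.
#' @export
acceptance_analysis <- function(replicate_totals, empirical,
                                empirical_interval = NULL,
                                proximities = c(0.01, 0.05, 0.10, 0.20),
                                prior = list(a = 1, b = 1)) {
  n <- length(replicate_totals)
  rows <- list()
  if (!is.null(empirical_interval)) {
    k <- count_successes(replicate_totals, empirical, 0,
                         empirical_interval = empirical_interval)
    rows[[1]] <- bayesian_acceptance(k, n, prior) %>%
      mutate(proximity = "true_value", .before = 1)
  }
  for (p in proximities) {
    k <- count_successes(replicate_totals, empirical, p)
    rows[[length(rows) + 1L]] <- bayesian_acceptance(k, n, prior) %>%
      mutate(proximity = sprintf("%g%%", 100 * p), .before = 1)
  }
  dplyr::bind_rows(rows)
}

#' Analytic acceptance table over all success counts
#'
#' The full grid of the Beta-posterior acceptance statistic for k = 0..n,
#' in reporting units (percent, one decimal).
#'
#' @param n Number of replicates.
#' @param prior Prior Beta parameters.
#' @return Tibble with `k`, `posterior_mean_pct`, `ci95_lower_pct`,
#'   `ci95_upper_pct`.
#' @export
acceptance_grid <- function(n = 100L, prior = list(a = 1, b = 1)) {
  acc <- bayesian_acceptance(0:n, n, prior)
  tibble(
    k = 0:n,
    posterior_mean_pct = round(100 * acc$posterior_mean, 1),
    ci95_lower_pct = round(100 * acc$ci95_lower, 1),
    ci95_upper_pct = round(100 * acc$ci95_upper, 1)
  )
}

#' @describeIn cumulative_incidence Step plot of one or more cumulative
#'   incidence series.
#' @param series Named list of tibbles from [cumulative_incidence()] (for
#'   example model vs empirical).
#' @export
plot_cumulative_incidence <- function(series) {
  df <- dplyr::bind_rows(series, .id = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$incidence,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Semiannual interval", y = "Cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
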