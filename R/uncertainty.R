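# Sensitivity analyses: a multivariate bootstrap over simulated patients'
# per-patient annual cost differences, and a one-way +/-20% tornado over
# cost-catalogue items. Because event streams are fixed by the seeds,
# re-pricing the same events under a scaled catalogue is identical to
# re-running the model with that amount changed, and the cost response is
# exactly linear in each unit cost.

#' Bootstrap sensitivity analysis of per-patient savings
#'
#' Resamples simulated patients' per-patient annual cost differences into
#' `n_populations` with-replacement populations of `population_size`
#' patients each; each population is summarised by its mean difference, and
#' the median, interquartile range and central 95% interval are taken over
#' the population means. The fraction of individual patients with savings
#' (difference below zero) is reported alongside.
#'
#' @param per_patient_differences Numeric vector of per-patient annual cost
#'   differences in euros (VCE minus SOC; negative = saving). Any
#'   eligibility filter (such as requiring at least one completed capsule
#'   study) is applied by the caller before this function.
#' @param n_populations Number of bootstrap populations (default 1000).
#' @param population_size Patients per population (default 500).
#' @param seed RNG seed for the resampling.
#' @return An object of class `cd_bootstrap` with the population means and
#'   their summary quantiles (linear interpolation between order
#'   statistics).
#' @export
bootstrap_analysis <- function(per_patient_differences,
                               n_populations = 1000L,
                               population_size = 500L,
                               seed = 1L) {
  x <- per_patient_differences
  if (length(x) == 0) abort("per_patient_differences must be non-empty")
  stream <- rng_stream(seed)
  means <- with_stream(stream, {
    vapply(seq_len(n_populations), function(i) {
      mean(x[sample.int(length(x), population_size, replace = TRUE)])
    }, numeric(1))
  })
  q <- quantile(means, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                type = 7)
  structure(
    list(
      population_means = means,
      n_populations = as.integer(n_populations),
      population_size = as.integer(population_size),
      median = q[3],
      iqr = c(lower = q[2], upper = q[4]),
      ci95 = c(lower = q[1], upper = q[5]),
      fraction_of_patients_with_savings = mean(x < 0)
    ),
    class = "cd_bootstrap"
  )
}

#' @export
print.cd_bootstrap <- function(x, ...) {
  cat(sprintf("<cd_bootstrap> %d populations of %d patients\n",
              x$n_populations, x$population_size))
  cat(sprintf("  median difference: EUR %.2f (IQR %.2f to %.2f; 95%% %.2f to %.2f)\n",
              x$median, x$iqr[1], x$iqr[2], x$ci95[1], x$ci95[2]))
  cat(sprintf("  patients with savings: %.1f%%\n",
              100 * x$fraction_of_patients_with_savings))
  invisible(x)
}

#' @describeIn bootstrap_analysis One row per bootstrap population.
#' @param x A `cd_bootstrap`.
#' @param ... Unused.
#' @method tidy cd_bootstrap
#' @export
tidy.cd_bootstrap <- function(x, ...) {
  tibble(population = seq_len(x$n_populations),
         mean_difference = x$population_means)
}

#' @describeIn bootstrap_analysis One-row summary of the bootstrap
#'   distribution.
#' @method glance cd_bootstrap
#' @export
glance.cd_bootstrap <- function(x, ...) {
  tibble(
    n_populations = x$n_populations,
    population_size = x$population_size,
    median = x$median,
    iqr_lower = x$iqr[["lower"]], iqr_upper = x$iqr[["upper"]],
    ci95_lower = x$ci95[["lower"]], ci95_upper = x$ci95[["upper"]],
    fraction_of_patients_with_savings = x$fraction_of_patients_with_savings
  )
}

#' @describeIn bootstrap_analysis Histogram of bootstrap population means.
#' @param object A `cd_bootstrap`.
#' @method autoplot cd_bootstrap
#' @export
autoplot.cd_bootstrap <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mean_difference)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$median, linetype = "dashed") +
    ggplot2::labs(x = "Mean cost difference per patient per year (EUR)",
                  y = "Bootstrap populations",
                  title = "Bootstrap distribution of the budget impact") +
    ggplot2::theme_minimal()
}

#' One-way cost sensitivity (tornado) analysis
#'
#' For each catalogue item, scales its unit amount by (1 - delta) and
#' (1 + delta) while holding the simulated event streams fixed, re-prices
#' both arms, and records the resulting total cost difference per patient
#' per year at each endpoint. Entries are ordered by descending width
#' (ties broken alphabetically).
#'
#' @param trial A `cd_trial` from [simulate_trial()].
#' @param config The `model_config` used for the trial.
#' @param items Character vector of catalogue item names (default: all).
#' @param delta Relative perturbation (default 0.20).
#' @param years Reporting years.
#' @return An object of class `cd_tornado`; its `table` element has one row
#'   per item with `low`, `high` (euro total difference per patient per
#'   year) and `width = |high - low|`.
#' @export
one_way_tornado <- function(trial, config, items = NULL, delta = 0.20,
                            years = 5) {
  catalogue <- config$costs
  if (is.null(items)) items <- names(catalogue$items)
  unknown <- setdiff(items, names(catalogue$items))
  if (length(unknown) > 0) {
    abort(sprintf("unknown cost item(s): %s", paste(unknown, collapse = ", ")))
  }
  n <- trial$soc$n_patients
  run_with <- function(costs) {
    bi <- budget_impact(accrue_costs(trial$soc$events, costs),
                        accrue_costs(trial$vce$events, costs),
                        n_patients = n, years = years)
    sum(bi$yearly$difference[bi$yearly$bucket == "total"]) / (n * years)
  }
  rows <- purrr::map_dfr(items, function(it) {
    scale_item <- function(f) {
      costs <- catalogue
      costs$items[[it]]$amount <- costs$items[[it]]$amount * f
      costs
    }
    lo <- run_with(scale_item(1 - delta))
    hi <- run_with(scale_item(1 + delta))
    tibble(item = it, low = lo, high = hi, width = abs(hi - lo))
  })
  rows <- rows %>% arrange(desc(.data$width), .data$item)
  structure(list(table = rows, delta = delta), class = "cd_tornado")
}

#' @export
print.cd_tornado <- function(x, ...) {
  cat(sprintf("<cd_tornado> +/-%.0f%% one-way cost sensitivity\n",
              100 * x$delta))
  print(x$table, n = 10)
  invisible(x)
}

#' @describeIn one_way_tornado The tornado table, widest item first.
#' @param x A `cd_tornado`.
#' @param ... Unused.
#' @method tidy cd_tornado
#' @export
tidy.cd_tornado <- function(x, ...) {
  x$table
}

#' @describeIn one_way_tornado Horizontal bar chart of cost-difference
#'   ranges, widest item on top.
#' @param object A `cd_tornado`.
#' @param top Number of items to display.
#' @method autoplot cd_tornado
#' @export
autoplot.cd_tornado <- function(object, top = 10, ...) {
  tab <- head(object$table, top) %>%
    mutate(item = factor(.data$item, levels = rev(.data$item)))
  ggplot2::ggplot(tab, ggplot2::aes(y = .data$item)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       yend = .data$item), linewidth = 4) +
    ggplot2::labs(x = "Total cost difference per patient per year (EUR)",
                  y = NULL,
                  title = sprintf("One-way sensitivity (+/-%.0f%% unit cost)",
                                  100 * object$delta)) +
    ggplot2::theme_minimal()
}
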