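# Costing and budget impact. Events are priced from the catalogue into four
# buckets (monitoring, interventions, adverse events, surgery); arithmetic
# is carried in integer cents internally so bucket additivity is exact to
# the cent, and amounts are reported in euros.

cost_buckets <- function() {
  c("monitoring", "interventions", "adverse_events", "surgery")
}

#' Price an event stream into a per-patient, per-cycle cost ledger
#'
#' @param events Event tibble from [simulate_arm()] (columns `patient_id`,
#'   `cycle`, `kind`, `item`).
#' @param costs The `costs` element of a `model_config`.
#' @return A ledger tibble: `patient_id`, `cycle`, one euro column per
#'   bucket, and `total` (the exact sum of the buckets).
#' @export
accrue_costs <- function(events, costs = default_config()$costs) {
  items <- costs$items
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$item), names(items))
    if (length(unknown) > 0) {
      abort(sprintf("no cost catalogue entry for event kind(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  amount_cents <- vapply(items, function(it) as.integer(round(it$amount * 100)),
                         integer(1))
  bucket <- vapply(items, function(it) it$bucket, character(1))

  if (nrow(events) == 0) {
    out <- tibble(patient_id = character(0), cycle = integer(0))
    for (b in cost_buckets()) out[[b]] <- numeric(0)
    out$total <- numeric(0)
    return(out)
  }

  priced <- events %>%
    mutate(
      cents = amount_cents[.data$item],
      bucket = bucket[.data$item]
    ) %>%
    group_by(.data$patient_id, .data$cycle, .data$bucket) %>%
    summarise(cents = sum(.data$cents), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "bucket", values_from = "cents",
                       values_fill = 0L)
  for (b in cost_buckets()) {
    if (!b %in% names(priced)) priced[[b]] <- 0L
  }
  priced$total_cents <- priced$monitoring + priced$interventions +
    priced$adverse_events + priced$surgery
  out <- priced %>%
    mutate(across(dplyr::all_of(c(cost_buckets(), "total_cents")), ~ .x / 100)) %>%
    rename(total = "total_cents") %>%
    select(dplyr::all_of(c("patient_id", "cycle", cost_buckets(), "total"))) %>%
    arrange(.data$patient_id, .data$cycle)
  out
}

# per-patient totals over a cycle range, euros
ledger_patient_totals <- function(ledger, max_cycle = Inf) {
  ledger %>%
    filter(.data$cycle <= max_cycle) %>%
    group_by(.data$patient_id) %>%
    summarise(total = sum(.data$total), .groups = "drop")
}

#' Budget impact of the capsule arm versus standard of care
#'
#' Aggregates the two arms' ledgers into per-year mean costs per patient,
#' per-year differences by bucket, the cumulative difference series, and
#' the mean saving per patient per year. A model year is 4 cycles; year y
#' covers cycles 4(y-1)+1 .. 4y.
#'
#' @param soc_ledger,vce_ledger Ledgers from [accrue_costs()]; both arms
#'   must cover the same number of patients.
#' @param n_patients Number of patients per arm.
#' @param years Number of reporting years (default 5; requires
#'   `years * 4 <= horizon_cycles`).
#' @return An object of class `cd_budget_impact` with elements `yearly`
#'   (tibble: year, bucket, soc, vce, difference in euros, mean per
#'   patient), `cumulative` (running total difference per patient by year),
#'   and `mean_saving_per_patient_year` (euros; positive when the capsule
#'   arm is cheaper).
#' @export
budget_impact <- function(soc_ledger, vce_ledger, n_patients, years = 5) {
  n_soc <- length(unique(soc_ledger$patient_id))
  n_vce <- length(unique(vce_ledger$patient_id))
  if (!missing(n_patients)) {
    n_soc <- n_vce <- n_patients
  } else if (n_soc != n_vce) {
    abort(sprintf("arm cohort sizes differ: %d (SOC) vs %d (VCE)", n_soc, n_vce))
  }
  n <- n_soc

  year_sums <- function(ledger) {
    ledger %>%
      mutate(year = ceiling(.data$cycle / 4)) %>%
      filter(.data$year <= years) %>%
      group_by(.data$year) %>%
      summarise(across(dplyr::all_of(c(cost_buckets(), "total")), sum),
                .groups = "drop") %>%
      tidyr::pivot_longer(-"year", names_to = "bucket", values_to = "euros")
  }
  grid <- tidyr::expand_grid(year = seq_len(years),
                             bucket = c(cost_buckets(), "total"))
  soc <- grid %>% left_join(year_sums(soc_ledger), by = c("year", "bucket")) %>%
    mutate(euros = dplyr::coalesce(.data$euros, 0))
  vce <- grid %>% left_join(year_sums(vce_ledger), by = c("year", "bucket")) %>%
    mutate(euros = dplyr::coalesce(.data$euros, 0))

  yearly <- soc %>%
    rename(soc = "euros") %>%
    mutate(vce = vce$euros,
           difference = .data$vce - .data$soc,
           soc_per_patient = .data$soc / n,
           vce_per_patient = .data$vce / n,
           difference_per_patient = .data$difference / n)

  cum <- yearly %>%
    filter(.data$bucket == "total") %>%
    mutate(cumulative_difference_per_patient = cumsum(.data$difference_per_patient)) %>%
    select("year", "difference_per_patient", "cumulative_difference_per_patient")

  total_diff <- sum(yearly$difference[yearly$bucket == "total"])
  structure(
    list(
      yearly = yearly,
      cumulative = cum,
      n_patients = n,
      years = years,
      mean_saving_per_patient_year = -total_diff / (n * years)
    ),
    class = "cd_budget_impact"
  )
}

#' @export
print.cd_budget_impact <- function(x, ...) {
  cat(sprintf("<cd_budget_impact> %d patients/arm over %d years\n",
              x$n_patients, x$years))
  cat(sprintf("  mean saving per patient per year (VCE vs SOC): EUR %.2f\n",
              x$mean_saving_per_patient_year))
  cat(sprintf("  cumulative difference per patient by year %d: EUR %.2f\n",
              x$years,
              x$cumulative$cumulative_difference_per_patient[x$years]))
  invisible(x)
}

#' @describeIn budget_impact Tidy per-year, per-bucket differences.
#' @param x A `cd_budget_impact`.
#' @param ... Unused.
#' @method tidy cd_budget_impact
#' @export
tidy.cd_budget_impact <- function(x, ...) {
  x$yearly
}

#' @describeIn budget_impact One-row summary.
#' @method glance cd_budget_impact
#' @export
glance.cd_budget_impact <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    years = x$years,
    mean_saving_per_patient_year = x$mean_saving_per_patient_year,
    cumulative_difference_per_patient =
      x$cumulative$cumulative_difference_per_patient[x$years]
  )
}

#' @describeIn budget_impact Yearly per-bucket cost differences with the
#'   cumulative total overlaid.
#' @param object A `cd_budget_impact`.
#' @method autoplot cd_budget_impact
#' @export
autoplot.cd_budget_impact <- function(object, ...) {
  yearly <- object$yearly %>% filter(.data$bucket != "total")
  ggplot2::ggplot(yearly,
                  ggplot2::aes(x = .data$year, y = .data$difference_per_patient,
                               fill = .data$bucket)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(
      data = object$cumulative,
      mapping = ggplot2::aes(x = .data$year,
                             y = .data$cumulative_difference_per_patient),
      inherit.aes = FALSE
    ) +
    ggplot2::geom_point(
      data = object$cumulative,
      mapping = ggplot2::aes(x = .data$year,
                             y = .data$cumulative_difference_per_patient),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "Year", y = "Cost difference per patient (EUR, VCE - SOC)",
      fill = "Bucket",
      title = "Budget impact of capsule surveillance vs standard of care"
    ) +
    ggplot2::theme_minimal()
}
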