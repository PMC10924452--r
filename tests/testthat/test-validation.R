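test_that("outcome definitions carry the documented triples", {
  p <- outcome_definition("permissive")
  expect_equal(p$biologic_min_months, 6L)
  expect_equal(p$remission_min_months, 6L)
  expect_true("other" %in% p$surgery_types_included)
  r <- outcome_definition("restrictive")
  expect_equal(r$biologic_min_months, 12L)
  expect_equal(r$remission_min_months, 12L)
  expect_setequal(r$surgery_types_included, c("elective", "emergency"))
  expect_error(outcome_definition("lenient"))
})

test_that("remission requires a preceding active period and the definition's duration", {
  cohort_quiet <- tibble::tibble(patient_id = "q", baseline_cdai = 100)
  always_quiet <- interval_trajectory("q", rep(100, 9))
  for (def in list(outcome_definition("permissive"),
                   outcome_definition("restrictive"))) {
    oc <- extract_outcomes(always_quiet, empty_events(), cohort_quiet, def)
    expect_true(is.na(oc$first_remission_interval))
    expect_equal(oc$total_remission_months, 0L)
  }

  # active interval, 6 quiet months, relapse: permissive counts it,
  # restrictive (12-month minimum) does not
  cohort_act <- tibble::tibble(patient_id = "a", baseline_cdai = 100)
  relapse <- interval_trajectory("a", c(300, 100, 300, 300, 300, 300, 300, 300, 300))
  oc_p <- extract_outcomes(relapse, empty_events(), cohort_act,
                           outcome_definition("permissive"))
  expect_equal(oc_p$first_remission_interval, 2L)
  expect_equal(oc_p$total_remission_months, 6L)
  oc_r <- extract_outcomes(relapse, empty_events(), cohort_act,
                           outcome_definition("restrictive"))
  expect_true(is.na(oc_r$first_remission_interval))

  # a 12-month quiet period qualifies under both
  long_rem <- interval_trajectory("a", c(300, 100, 100, 300, 300, 300, 300, 300, 300))
  oc_r2 <- extract_outcomes(long_rem, empty_events(), cohort_act,
                            outcome_definition("restrictive"))
  expect_equal(oc_r2$first_remission_interval, 2L)
  expect_equal(oc_r2$total_remission_months, 12L)

  # the baseline record is the preceding period for interval 1
  cohort_base_active <- tibble::tibble(patient_id = "b", baseline_cdai = 200)
  from_start <- interval_trajectory("b", c(100, 300, 300, 300, 300, 300, 300, 300, 300))
  oc_b <- extract_outcomes(from_start, empty_events(), cohort_base_active,
                           outcome_definition("permissive"))
  expect_equal(oc_b$first_remission_interval, 1L)

  # a short trajectory is an input error
  expect_error(
    extract_outcomes(interval_trajectory("a", rep(100, 5)), empty_events(),
                     cohort_act, outcome_definition("permissive")),
    "cycles")
})

test_that("surgery filtering and biologic periods follow the definition", {
  cohort <- tibble::tibble(patient_id = "s", baseline_cdai = 300)
  traj <- interval_trajectory("s", rep(300, 9),
                              bio_by_interval = c(FALSE, FALSE, TRUE, TRUE,
                                                  FALSE, TRUE, FALSE, FALSE, FALSE))
  ev <- surgery_event("s", cycle = 5, type = "other", item = "surgery_other")
  oc_p <- extract_outcomes(traj, ev, cohort, outcome_definition("permissive"))
  expect_equal(oc_p$total_surgeries, 1L)
  expect_equal(oc_p$first_surgery_interval, 3)
  # permissive: the 2-interval run and the single interval both count
  expect_equal(oc_p$total_biologic_periods, 2L)
  expect_equal(oc_p$first_biologic_interval, 3L)

  oc_r <- extract_outcomes(traj, ev, cohort, outcome_definition("restrictive"))
  expect_equal(oc_r$total_surgeries, 0L)  # "other" surgeries excluded
  expect_true(is.na(oc_r$first_surgery_interval))
  expect_equal(oc_r$total_biologic_periods, 1L)  # only the >= 12-month run
  expect_equal(oc_r$first_biologic_interval, 3L)
})

test_that("cumulative incidence is a hand-countable, monotone, order-invariant series", {
  firsts <- c(2L, 2L, 2L, rep(NA_integer_, 7))
  ci <- cumulative_incidence(firsts, n_intervals = 5)
  expect_equal(ci$incidence, c(0, 0.3, 0.3, 0.3, 0.3))

  expect_equal(cumulative_incidence(rep(NA_integer_, 4), 3)$incidence,
               c(0, 0, 0))
  expect_equal(cumulative_incidence(rep(1L, 6), 3)$incidence, c(1, 1, 1))

  set.seed(12)
  random_firsts <- sample(c(1:9, NA), 50, replace = TRUE)
  ci1 <- cumulative_incidence(random_firsts)
  expect_true(all(diff(ci1$incidence) >= 0))
  expect_true(all(ci1$incidence >= 0 & ci1$incidence <= 1))
  ci2 <- cumulative_incidence(sample(random_firsts))
  expect_equal(ci1$incidence, ci2$incidence)
})

test_that("proximity counting is boundary-inclusive with an interval-based true-value row", {
  expect_equal(count_successes(rep(42, 7), 42, 0.01), 7L)
  expect_equal(count_successes(c(95, 105, 121), 100, 0.10), 2L)
  expect_equal(count_successes(120, 100, 0.20), 1L)  # exactly on the boundary
  expect_equal(count_successes(c(79.9, 120.1), 100, 0.20), 0L)
  expect_equal(count_successes(c(1, 2, 3), 0, 0.10, absolute_tolerance = 1.5), 1L)
  expect_equal(
    count_successes(c(90, 100, 130), 100, 0, empirical_interval = c(85, 110)),
    2L)
  expect_error(count_successes(numeric(0), 1, 0.1), "non-empty")
})

test_that("the Beta-posterior acceptance statistic matches its closed form and oracle", {
  # boundary cases pin the construction
  a0 <- bayesian_acceptance(0, 100)
  expect_equal(format_acceptance(a0), "1.0% (0.0%-3.6%)")
  a100 <- bayesian_acceptance(100, 100)
  expect_equal(format_acceptance(a100), "99.0% (96.4%-100.0%)")

  expect_equal(bayesian_acceptance(50, 100)$posterior_mean, 51 / 102)
  expect_equal(bayesian_acceptance(81, 100)$posterior_mean, 82 / 102)

  # posterior mean is (k+1)/(n+2) and strictly increasing in k
  grid <- bayesian_acceptance(0:100, 100)
  expect_equal(grid$posterior_mean, (0:100 + 1) / 102)
  expect_true(all(diff(grid$posterior_mean) > 0))
  expect_true(all(grid$ci95_lower <= grid$posterior_mean + 1e-12))
  expect_true(all(grid$posterior_mean <= grid$ci95_upper + 1e-12))

  # credible bounds agree with a numeric-integration oracle of the density
  beta_quantile_oracle <- function(p, a, b) {
    dens <- function(t) t^(a - 1) * (1 - t)^(b - 1) / beta(a, b)
    cdf <- function(x) integrate(dens, 0, x, rel.tol = 1e-10)$value
    uniroot(function(x) cdf(x) - p, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  for (k in c(5, 43, 81)) {
    acc <- bayesian_acceptance(k, 100)
    expect_equal(acc$ci95_lower, beta_quantile_oracle(0.025, k + 1, 101 - k),
                 tolerance = 1e-6)
    expect_equal(acc$ci95_upper, beta_quantile_oracle(0.975, k + 1, 101 - k),
                 tolerance = 1e-6)
  }

  expect_error(bayesian_acceptance(101, 100), "k <= n")
  expect_error(bayesian_acceptance(-1, 100), "k <= n")

  # the 80%-target prior variant shifts the posterior mean up
  shifted <- bayesian_acceptance(50, 100, prior = list(a = 1.6, b = 0.4))
  expect_gt(shifted$posterior_mean, bayesian_acceptance(50, 100)$posterior_mean)
})

test_that("acceptance analysis assembles one row per proximity band", {
  totals <- c(95, 99, 100, 101, 105, 111, 120, 130, 140, 80)
  tab <- acceptance_analysis(totals, empirical = 100,
                             empirical_interval = c(98, 102))
  expect_equal(tab$proximity, c("true_value", "1%", "5%", "10%", "20%"))
  expect_equal(tab$k, c(3L, 3L, 5L, 5L, 8L))
  # more permissive proximity never lowers acceptance
  expect_true(all(diff(tab$posterior_mean[-1]) >= 0))
})

test_that("simulated replicates validate against an independently seeded run of the same engine", {
  cohort <- generate_cohort(cohort_params(n_patients = 40, rng_seed = 21))
  cfg <- default_config(arm = "SOC")
  cfg$horizon_cycles <- 18L
  n_rep <- 25L

  rep_cohort <- replicate_cohort(cohort, n_rep)
  sim <- simulate_arm(rep_cohort, cfg, master_seed = 101)
  oc <- extract_outcomes(sim$trajectory, sim$events, rep_cohort,
                         outcome_definition("permissive"))
  oc$replicate <- sub("^.*:", "", oc$patient_id)
  totals <- tapply(oc$total_biologic_periods, oc$replicate, sum)
  expect_length(totals, n_rep)

  # synthetic "empirical" outcome: the same engine, a different seed
  emp_sim <- simulate_arm(cohort, cfg, master_seed = 999)
  emp_oc <- extract_outcomes(emp_sim$trajectory, emp_sim$events, cohort,
                             outcome_definition("permissive"))
  empirical <- sum(emp_oc$total_biologic_periods)

  k <- count_successes(as.numeric(totals), empirical, 0.20)
  acc <- bayesian_acceptance(k, n_rep)
  # self-consistency: at 20% proximity the model should usually accept itself
  expect_gt(acc$posterior_mean, 0.5)
})
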