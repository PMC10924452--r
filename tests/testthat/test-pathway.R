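test_that("apply_test honours perfect operating characteristics and segment rules", {
  perfect <- test_spec("x", sensitivity = 1, specificity = 1)
  set.seed(1)
  expect_true(apply_test(perfect, TRUE, "colon")$positive)
  expect_false(apply_test(perfect, FALSE, "colon")$positive)

  blind <- test_spec("y", sensitivity = 0, specificity = 1)
  expect_false(apply_test(blind, TRUE, "colon")$positive)

  ile <- default_config()$tests$ileocolonoscopy
  expect_error(apply_test(ile, TRUE, "small_bowel"), "small bowel")

  # incomplete procedures are never positive
  never <- test_spec("z", sensitivity = 1, specificity = 1, completion_rate = 0)
  res <- apply_test(never, rep(TRUE, 50), "colon")
  expect_false(any(res$complete))
  expect_false(any(res$positive))
})

test_that("no visit means no tests; a negative marker blocks unscheduled endoscopy", {
  cfg <- default_config()
  state <- init_patient_state(baseline_record(baseline_cdai = 80), cfg)
  state$cycle_index <- 1L  # not a scheduled cycle, no flare
  set.seed(2)
  res <- run_cycle_pathway(state, cfg)
  expect_equal(res$cycle_record$visit_type, "none")
  expect_null(res$cycle_record$tests)
  expect_false(any(res$events$kind == "test"))

  # flare signal, but truth negative and a perfectly specific marker:
  # the work-up stops at the marker
  cfg2 <- default_config()
  cfg2$tests$fcal$specificity <- 1
  state2 <- init_patient_state(baseline_record(baseline_cdai = 80), cfg2)
  state2$cycle_index <- 1L
  state2$flare_this_cycle <- TRUE  # flare resolved within the cycle
  set.seed(3)
  res2 <- run_cycle_pathway(state2, cfg2)
  expect_equal(res2$cycle_record$visit_type, "flare_triggered")
  expect_equal(res2$cycle_record$tests$modality, "fcal")
  expect_false(any(res2$events$item %in% c("vce", "ileocolonoscopy", "mre")))
  expect_equal(res2$cycle_record$diagnosis, "no_active_disease")
})

test_that("a diagnosed complication routes to surgery and resection resets the state", {
  cfg <- perfect_tests_config(default_config(arm = "SOC"))
  state <- init_patient_state(
    baseline_record(baseline_cdai = 300, stricturing = TRUE), cfg)
  state$cycle_index <- cfg$scheduled_visit_interval_cycles
  set.seed(4)
  res <- run_cycle_pathway(state, cfg)
  expect_equal(res$cycle_record$visit_type, "scheduled")
  expect_equal(res$cycle_record$diagnosis, "complication")
  expect_equal(res$cycle_record$treatment_action, "surgery")
  expect_true(res$cycle_record$surgery_type %in% c("elective", "emergency"))
  expect_true(any(res$events$kind == "surgery"))
  expect_equal(res$state$severity, "remission")
  expect_length(res$state$active_complications, 0)
})

test_that("with perfect tests the diagnosis equals the latent ground truth", {
  set.seed(5)
  for (arm in c("SOC", "VCE")) {
    cfg <- perfect_tests_config(default_config(arm = arm))
    for (i in 1:60) {
      cdai <- runif(1, 0, 600)
      state <- init_patient_state(
        baseline_record(baseline_cdai = cdai,
                        colonic = runif(1) < 0.6,
                        stricturing = runif(1) < 0.3,
                        abscess = runif(1) < 0.2), cfg)
      state$cycle_index <- cfg$scheduled_visit_interval_cycles
      truth <- if (length(state$active_complications) > 0) {
        "complication"
      } else if (classify_cdai(cdai) != "remission") {
        "active_disease"
      } else {
        "no_active_disease"
      }
      res <- run_cycle_pathway(state, cfg)
      expect_equal(res$cycle_record$diagnosis, truth)
    }
  }
})

test_that("each arm bills only its own endoscopy bundle", {
  cohort <- generate_cohort(cohort_params(n_patients = 15, rng_seed = 3))
  trial <- simulate_trial(cohort, default_config(), master_seed = 11)
  expect_false(any(trial$soc$events$item == "vce"))
  expect_true(any(trial$soc$events$item == "ileocolonoscopy"))
  expect_false(any(trial$vce$events$item == "ileocolonoscopy"))
  expect_true(any(trial$vce$events$item == "vce"))
})

test_that("treatment escalation follows the bottom-up and top-down strategies", {
  cfg <- default_config()
  # persistent moderate disease, top-down, not on a biologic
  state <- init_patient_state(
    baseline_record(baseline_cdai = 300, strategy = "top_down"), cfg)
  set.seed(6)
  dec <- decide_treatment(state, "active_disease", cfg)
  expect_equal(dec$action, "escalate")
  expect_equal(dec$state$treatment_line, "biologic")
  expect_true(dec$state$on_biologic)

  # bottom-up advances one line at a time
  state2 <- init_patient_state(baseline_record(baseline_cdai = 300), cfg)
  dec2 <- decide_treatment(state2, "active_disease", cfg)
  expect_equal(dec2$state$treatment_line, "immunomodulator")
  expect_false(dec2$state$on_biologic)
  dec3 <- decide_treatment(dec2$state, "active_disease", cfg)
  expect_equal(dec3$state$treatment_line, "biologic")
  expect_true(dec3$state$on_biologic)

  # improvement since the last assessment: no escalation
  state4 <- init_patient_state(baseline_record(baseline_cdai = 300), cfg)
  state4$severity <- "mild"; state4$cdai <- 160
  dec4 <- decide_treatment(state4, "active_disease", cfg)
  expect_equal(dec4$action, "none")

  # no active disease: nothing happens
  dec5 <- decide_treatment(state2, "no_active_disease", cfg)
  expect_equal(dec5$action, "none")
  expect_equal(dec5$state$treatment_line, "conventional")
})

test_that("capsule retention and ileocolonoscopy adverse events are billed when drawn", {
  cfg <- default_config(arm = "SOC")
  cfg$tests$ileocolonoscopy$p_infection <- 1
  state <- init_patient_state(baseline_record(baseline_cdai = 300), cfg)
  state$cycle_index <- cfg$scheduled_visit_interval_cycles
  set.seed(7)
  res <- run_cycle_pathway(state, cfg)
  expect_true(any(res$events$item == "ae_infection"))

  cfgv <- default_config(arm = "VCE")
  cfgv$tests$vce$p_retention <- 1
  statev <- init_patient_state(baseline_record(baseline_cdai = 300), cfgv)
  statev$cycle_index <- cfgv$scheduled_visit_interval_cycles
  set.seed(8)
  resv <- run_cycle_pathway(statev, cfgv)
  expect_true(any(resv$events$item == "ae_retention"))
})
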