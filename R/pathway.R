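# Per-cycle care pathway. Patients reach monitoring either on the semiannual
# schedule or through a flare signal; in both cases a fecal-calprotectin
# marker test gates the work-up. Scheduled patients proceed to endoscopy
# regardless of the marker; unscheduled (flare-triggered) patients proceed
# only on a positive marker. Endoscopy is arm-specific: standard of care is
# ileocolonoscopy for the colon plus MR enteroscopy for the small bowel when
# involved; the capsule arm covers both segments with a single capsule study.
# Diagnosed complications route to surgery; persistent active disease
# escalates treatment bottom-up or top-down.

#' Apply a diagnostic test
#'
#' Draws completion, the test result conditional on the latent truth, and
#' per-procedure adverse events. Small-bowel applications use the
#' segment-specific operating characteristics; a modality without them
#' cannot be applied to the small bowel.
#'
#' @param spec A [test_spec()].
#' @param truth_positive Logical vector: latent disease activity per draw
#'   (a single value performs one test; a vector performs one per element).
#' @param segment `"colon"`, `"small_bowel"`, or `"both"`.
#' @return A tibble with one row per draw: `modality`, `performed`,
#'   `complete`, `positive`, `segment`, and one logical column per
#'   adverse-event type.
#' @export
apply_test <- function(spec, truth_positive, segment = "colon") {
  n <- length(truth_positive)
  if (segment == "small_bowel" &&
      (is.null(spec$sb_sensitivity) || is.null(spec$sb_specificity))) {
    abort(sprintf("modality '%s' is not applied to the small bowel", spec$name))
  }
  sens <- if (segment == "small_bowel") spec$sb_sensitivity else spec$sensitivity
  spcf <- if (segment == "small_bowel") spec$sb_specificity else spec$specificity

  complete <- runif(n) < spec$completion_rate
  p_pos <- ifelse(truth_positive, sens, 1 - spcf)
  positive <- complete & (runif(n) < p_pos)
  tibble(
    modality = spec$name,
    performed = TRUE,
    complete = complete,
    positive = positive,
    segment = segment,
    hospitalization = runif(n) < spec$p_hospitalization,
    obstruction = runif(n) < spec$p_obstruction,
    bleeding = runif(n) < spec$p_bleeding,
    infection = runif(n) < spec$p_infection,
    retention = runif(n) < spec$p_retention
  )
}

# segment(s) a patient's disease can occupy
patient_segments <- function(baseline) {
  segs <- character(0)
  if (isTRUE(baseline$small_bowel_involvement)) segs <- c(segs, "small_bowel")
  if (isTRUE(baseline$colonic_involvement)) segs <- c(segs, "colon")
  segs
}

# complications sit in the small bowel when it is involved, else the colon
complication_segment <- function(baseline) {
  if (isTRUE(baseline$small_bowel_involvement)) "small_bowel" else "colon"
}

ae_types <- c("hospitalization", "obstruction", "bleeding", "infection",
              "retention")

#' Run the per-cycle diagnostic and treatment pathway
#'
#' Implements the monitoring workflow for one cycle on an already-advanced
#' state: visit eligibility, marker gating, arm-specific endoscopy with an
#' MR-enteroscopy follow-on after an incomplete capsule study or
#' ileocolonoscopy, diagnosis under test error, and treatment routing.
#'
#' @param state Patient state advanced for this cycle.
#' @param config A `model_config` (its `arm` selects the endoscopy bundle).
#' @return List with `state` (after any treatment action), `events` (tibble
#'   of billable events: `cycle`, `kind`, `item`), and `cycle_record` (visit
#'   type, diagnosis, treatment action, surgery type, tests performed).
#' @export
run_cycle_pathway <- function(state, config) {
  cyc <- state$cycle_index
  events <- list()
  add_event <- function(kind, item, complete = NA) {
    events[[length(events) + 1L]] <<-
      list(cycle = cyc, kind = kind, item = item, complete = complete)
  }

  visit_type <- "none"
  if (cyc == state$next_scheduled_visit_cycle) {
    visit_type <- "scheduled"
    state$next_scheduled_visit_cycle <-
      state$next_scheduled_visit_cycle + config$scheduled_visit_interval_cycles
  } else if (has_flare_signal(state)) {
    visit_type <- "flare_triggered"
  }

  tests <- list()
  diagnosis <- NA_character_
  truth_active <- severity_rank(state$severity) >= 2L ||
    length(state$active_complications) > 0L

  bill_test <- function(result) {
    tests[[length(tests) + 1L]] <<- result
    add_event("test", result$modality[1], complete = result$complete[1])
    for (ae in ae_types) {
      if (isTRUE(result[[ae]][1])) add_event("adverse_event", paste0("ae_", ae))
    }
  }

  detected_segments <- character(0)
  any_positive <- FALSE

  if (visit_type != "none") {
    fcal <- apply_test(config$tests$fcal, truth_active, "colon")
    bill_test(fcal)
    do_endoscopy <- visit_type == "scheduled" || isTRUE(fcal$positive[1])

    if (do_endoscopy) {
      segs <- patient_segments(state$baseline)
      run_endoscopy <- function(spec, segment) {
        res <- apply_test(spec, truth_active, segment)
        bill_test(res)
        if (!isTRUE(res$complete[1])) {
          # incomplete study: one radiological follow-on, billed
          res2 <- apply_test(config$tests$mre, truth_active, segment)
          bill_test(res2)
          res <- res2
        }
        if (isTRUE(res$complete[1]) && isTRUE(res$positive[1])) {
          detected_segments <<- union(detected_segments, segment)
          any_positive <<- TRUE
        }
      }
      if (config$arm == "VCE") {
        # one capsule study covers both segments; billed once
        vspec <- config$tests$vce
        comp <- runif(1) < vspec$completion_rate
        add_event("test", "vce", complete = comp)
        for (seg in segs) {
          sens <- if (seg == "small_bowel") vspec$sb_sensitivity else vspec$sensitivity
          spcf <- if (seg == "small_bowel") vspec$sb_specificity else vspec$specificity
          pos <- comp && (runif(1) < (if (truth_active) sens else 1 - spcf))
          tests[[length(tests) + 1L]] <- tibble(
            modality = "vce", performed = TRUE, complete = comp,
            positive = pos, segment = seg,
            hospitalization = FALSE, obstruction = FALSE, bleeding = FALSE,
            infection = FALSE, retention = FALSE
          )
          if (comp && pos) {
            detected_segments <- union(detected_segments, seg)
            any_positive <- TRUE
          }
        }
        if (runif(1) < vspec$p_retention) add_event("adverse_event", "ae_retention")
        if (!comp) {
          seg2 <- if ("small_bowel" %in% segs) "small_bowel" else "colon"
          res2 <- apply_test(config$tests$mre, truth_active, seg2)
          bill_test(res2)
          if (isTRUE(res2$complete[1]) && isTRUE(res2$positive[1])) {
            detected_segments <- union(detected_segments, res2$segment[1])
            any_positive <- TRUE
          }
        }
      } else {
        # SOC: ileocolonoscopy always; MR enteroscopy added for the small
        # bowel when involved
        run_endoscopy(config$tests$ileocolonoscopy, "colon")
        if ("small_bowel" %in% segs) run_endoscopy(config$tests$mre, "small_bowel")
      }

      comp_seg <- complication_segment(state$baseline)
      complication_detected <- length(state$active_complications) > 0L &&
        comp_seg %in% detected_segments
      diagnosis <- if (complication_detected) {
        "complication"
      } else if (any_positive) {
        "active_disease"
      } else {
        "no_active_disease"
      }
      # a completed work-up updates the reference severity for persistence
      assessed <- state$severity
    } else {
      diagnosis <- "no_active_disease"
      assessed <- NULL
    }
  } else {
    assessed <- NULL
  }

  action <- "none"
  surgery_type <- "none"
  if (!is.na(diagnosis)) {
    dec <- decide_treatment(state, diagnosis, config)
    state <- dec$state
    action <- dec$action
    surgery_type <- dec$surgery_type
    if (action == "surgery") {
      add_event("surgery", dec$surgery_item)
    }
    if (!is.null(assessed)) state$last_assessed_severity <- assessed
  }

  # maintenance medication accrues every cycle for the current line
  add_event("medication", paste0("medication_", state$treatment_line))

  list(
    state = state,
    events = dplyr::bind_rows(lapply(events, as_tibble)),
    cycle_record = list(
      visit_type = visit_type,
      tests = if (length(tests)) dplyr::bind_rows(tests) else NULL,
      diagnosis = diagnosis,
      treatment_action = action,
      surgery_type = surgery_type
    )
  )
}

#' Decide the treatment action following a diagnosis
#'
#' A diagnosed complication routes to surgery (stricture: elective with
#' probability 0.7, else emergency; abscess and fistula: emergency). Active
#' disease that persists -- the current band is the same or worse than at
#' the previous completed assessment -- escalates treatment: bottom-up
#' advances one line, top-down starts a biologic immediately. Surgery
#' resets severity to the remission band and clears the active
#' complications (resection semantics).
#'
#' @param state Patient state.
#' @param diagnosis One of `"no_active_disease"`, `"active_disease"`,
#'   `"complication"`.
#' @param config A `model_config`.
#' @return List with `action`, `surgery_type`, `surgery_item`, and the
#'   mutated `state`.
#' @export
decide_treatment <- function(state, diagnosis, config) {
  action <- "none"
  surgery_type <- "none"
  surgery_item <- NA_character_

  if (diagnosis == "complication") {
    action <- "surgery"
    comps <- state$active_complications
    if ("stricture" %in% comps) {
      elective <- runif(1) < config$surgery$p_elective_given_stricture
      surgery_type <- if (elective) "elective" else "emergency"
      surgery_item <- paste0("surgery_", surgery_type)
    } else if ("abscess" %in% comps || "fistula" %in% comps) {
      surgery_type <- "emergency"
      surgery_item <- if ("fistula" %in% comps && !("abscess" %in% comps)) {
        "fistula_repair"
      } else {
        "surgery_emergency"
      }
    }
    # resection: complications cleared, severity resets to remission band
    state$active_complications <- character(0)
    bb <- cdai_band_bounds("remission", config$thresholds)
    state$cdai <- runif(1, bb[1], bb[2])
    state$severity <- "remission"
    state$months_in_state <- 0L
  } else if (diagnosis == "active_disease") {
    persistent <- severity_rank(state$severity) >=
      severity_rank(state$last_assessed_severity)
    if (persistent) {
      action <- "escalate"
      if (identical(state$baseline$strategy, "top_down")) {
        state$treatment_line <- "biologic"
      } else {
        lines <- treatment_lines()
        idx <- match(state$treatment_line, lines)
        state$treatment_line <- lines[min(idx + 1L, length(lines))]
      }
      if (identical(state$treatment_line, "biologic") && !state$on_biologic) {
        state$on_biologic <- TRUE
        state$biologic_start_cycle <- state$cycle_index
      }
    }
  }

  list(state = state, action = action, surgery_type = surgery_type,
       surgery_item = surgery_item)
}
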