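# Latent disease engine: a semi-Markov severity process with monthly
# transitions nested inside 3-month model cycles. Severity moves over the
# four CDAI bands via a per-treatment-line row-stochastic monthly matrix;
# complications (stricture, abscess, fistula) onset independently each month
# with a severity-dependent probability. The CDAI score is resampled
# uniformly within the new band whenever the band changes, since the model
# semantics live at band level.

complication_types <- function() c("stricture", "abscess", "fistula")

#' Initialise a patient state from a baseline record
#'
#' @param baseline One-row tibble (or named list) of baseline fields.
#' @param config A `model_config`.
#' @return A named list representing the evolving patient state.
#' @export
init_patient_state <- function(baseline, config) {
  baseline <- as.list(baseline)
  sev <- classify_cdai(baseline$baseline_cdai, config$thresholds)
  comps <- character(0)
  if (isTRUE(baseline$stricturing)) comps <- c(comps, "stricture")
  if (isTRUE(baseline$abscess)) comps <- c(comps, "abscess")
  list(
    baseline = baseline,
    current_age = baseline$age,
    cycle_index = 0L,
    severity = sev,
    cdai = baseline$baseline_cdai,
    months_in_state = 0L,
    active_complications = comps,
    complication_diagnosed = setNames(rep(FALSE, 3), complication_types()),
    on_biologic = identical(baseline$treatment_line, "biologic"),
    biologic_start_cycle = if (identical(baseline$treatment_line, "biologic")) 0L else NA_integer_,
    treatment_line = baseline$treatment_line,
    # severity band at the previous completed endoscopic assessment;
    # the baseline work-up is the first assessment
    last_assessed_severity = sev,
    next_scheduled_visit_cycle = config$scheduled_visit_interval_cycles,
    flare_this_cycle = FALSE,
    alive_in_model = TRUE
  )
}

#' One monthly semi-Markov transition
#'
#' Draws the next severity band from the monthly matrix row of the current
#' (band, treatment line), then draws complication onsets independently per
#' type with the configured base monthly probability scaled by the
#' severity multiplier. On a band change the CDAI is resampled uniformly in
#' the new band and time-in-state resets.
#'
#' @param state Patient state list (must be alive in model).
#' @param transitions The `transitions` element of a `model_config`.
#' @param thresholds CDAI thresholds.
#' @return List with `state` (updated) and `step` (month record with
#'   `severity_before`, `severity_after`, `complication_onsets`).
#' @export
monthly_transition <- function(state, transitions,
                               thresholds = severity_thresholds()) {
  if (!isTRUE(state$alive_in_model)) abort("patient is not in the model")
  mat <- transitions$monthly_matrix[[state$treatment_line]]
  if (is.null(mat)) {
    abort(sprintf("no monthly transition matrix for treatment line '%s'",
                  state$treatment_line))
  }
  before <- state$severity
  row <- mat[severity_rank(before), ]
  after <- severity_levels()[sample.int(4L, 1L, prob = row)]

  mult <- transitions$severity_multiplier[[after]]
  onsets <- character(0)
  for (ct in complication_types()) {
    if (ct %in% state$active_complications) next
    p <- transitions$p_complication_per_month[[ct]] * mult
    if (p > 0 && runif(1) < p) onsets <- c(onsets, ct)
  }

  if (!identical(after, before)) {
    bb <- cdai_band_bounds(after, thresholds)
    state$cdai <- runif(1, bb[1], bb[2])
    state$severity <- after
    state$months_in_state <- 0L
  } else {
    state$months_in_state <- state$months_in_state + 1L
  }
  state$active_complications <- union(state$active_complications, onsets)

  list(
    state = state,
    step = list(severity_before = before, severity_after = after,
                complication_onsets = onsets)
  )
}

#' Advance a patient one model cycle
#'
#' Applies `cycle_months` monthly transitions in order. The cycle counts as a
#' flare when any month's severity strictly escalates, even if it resolves
#' within the same cycle; the flare signal can therefore fire while the
#' end-of-cycle band equals (or improves on) the starting band. Age advances
#' one year every 4 cycles.
#'
#' @param state Patient state list.
#' @param config A `model_config`.
#' @return Updated state, with `cycle_index` incremented and
#'   `flare_this_cycle` set.
#' @export
advance_cycle <- function(state, config) {
  flare <- FALSE
  for (m in seq_len(config$cycle_months)) {
    res <- monthly_transition(state, config$transitions, config$thresholds)
    state <- res$state
    if (severity_rank(res$step$severity_after) >
        severity_rank(res$step$severity_before)) {
      flare <- TRUE
    }
  }
  state$flare_this_cycle <- flare
  state$cycle_index <- state$cycle_index + 1L
  if (state$cycle_index %% 4L == 0L) {
    state$current_age <- state$current_age + 1
  }
  state
}

#' Does the patient signal a flare this cycle?
#'
#' Pure read of the flare flag set by [advance_cycle()]: true when any
#' within-cycle month escalated severity, regardless of the end-of-cycle
#' band.
#'
#' @param state Patient state list.
#' @return Logical flag.
#' @export
has_flare_signal <- function(state) {
  isTRUE(state$flare_this_cycle)
}
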