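# Shared fixtures, all built in code.

# deterministic 4x4 transition matrix: each state moves to `to[state]` surely
det_matrix <- function(to) {
  states <- severity_levels()
  mat <- matrix(0, 4, 4, dimnames = list(states, states))
  for (s in states) mat[s, to[[s]]] <- 1
  mat
}

identity_matrix <- function() {
  diag(4) |> (\(m) {
    dimnames(m) <- list(severity_levels(), severity_levels())
    m
  })()
}

# config whose every treatment line uses the same matrix
config_with_matrix <- function(mat, ..., p_comp = 0) {
  cfg <- default_config(...)
  for (line in names(cfg$transitions$monthly_matrix)) {
    cfg$transitions$monthly_matrix[[line]] <- mat
  }
  for (ct in names(cfg$transitions$p_complication_per_month)) {
    cfg$transitions$p_complication_per_month[[ct]] <- p_comp
  }
  cfg
}

# all sensitivities/specificities/completions 1, adverse events 0
perfect_tests_config <- function(cfg = default_config()) {
  for (tn in names(cfg$tests)) {
    spec <- cfg$tests[[tn]]
    spec$sensitivity <- 1; spec$specificity <- 1
    if (!is.null(spec$sb_sensitivity)) spec$sb_sensitivity <- 1
    if (!is.null(spec$sb_specificity)) spec$sb_specificity <- 1
    spec$completion_rate <- 1
    spec$p_hospitalization <- 0; spec$p_obstruction <- 0
    spec$p_bleeding <- 0; spec$p_infection <- 0; spec$p_retention <- 0
    cfg$tests[[tn]] <- spec
  }
  cfg
}

baseline_record <- function(patient_id = "p001:0", baseline_cdai = 180,
                            treatment_line = "conventional",
                            strategy = "bottom_up",
                            small_bowel = TRUE, colonic = TRUE,
                            stricturing = FALSE, abscess = FALSE) {
  list(
    patient_id = patient_id, age = 40, sex = "F",
    years_since_diagnosis = 5, baseline_cdai = baseline_cdai,
    small_bowel_involvement = small_bowel, colonic_involvement = colonic,
    stricturing = stricturing, abscess = abscess,
    treatment_line = treatment_line, strategy = strategy
  )
}

# hand-built one-patient trajectory on the semiannual grid:
# cdai_by_interval / bio_by_interval give one value per 6-month interval,
# expanded to the 2 cycles inside it
interval_trajectory <- function(patient_id, cdai_by_interval,
                                bio_by_interval = rep(FALSE, length(cdai_by_interval))) {
  k <- length(cdai_by_interval)
  tibble::tibble(
    patient_id = patient_id,
    cycle = seq_len(2L * k),
    cdai = rep(cdai_by_interval, each = 2),
    on_biologic = rep(bio_by_interval, each = 2),
    severity = classify_cdai(rep(cdai_by_interval, each = 2))
  )
}

empty_events <- function() {
  tibble::tibble(patient_id = character(0), cycle = integer(0),
                 kind = character(0), item = character(0),
                 complete = logical(0), surgery_type = character(0))
}

surgery_event <- function(patient_id, cycle, type,
                          item = paste0("surgery_", type)) {
  tibble::tibble(patient_id = patient_id, cycle = as.integer(cycle),
                 kind = "surgery", item = item, complete = NA,
                 surgery_type = type)
}
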