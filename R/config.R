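# Model configuration: diagnostic test characteristics, monthly transition
# matrices, cost catalogue, scheduling rules and horizon. Defaults for the
# diagnostic modalities are the published efficacy/safety/cost inputs; the
# transition matrices and the non-procedure cost items are documented
# synthetic defaults (the source supplementary schedules are not public).

#' Diagnostic test specification
#'
#' Sensitivity/specificity (overall and, where the modality reads the small
#' bowel, segment-specific), completion rate, per-procedure adverse-event
#' probabilities, and unit cost in euros.
#'
#' @param name Modality identifier.
#' @param sensitivity,specificity Overall operating characteristics in \[0,1\].
#' @param sb_sensitivity,sb_specificity Small-bowel characteristics, or `NULL`
#'   when the modality is never applied to the small bowel.
#' @param completion_rate Probability the procedure completes.
#' @param p_hospitalization,p_obstruction,p_bleeding,p_infection,p_retention
#'   Per-procedure adverse-event probabilities.
#' @param unit_cost Euro cost per procedure.
#' @return A named list of class `test_spec`.
#' @export
test_spec <- function(name, sensitivity, specificity,
                      sb_sensitivity = NULL, sb_specificity = NULL,
                      completion_rate = 1,
                      p_hospitalization = 0, p_obstruction = 0,
                      p_bleeding = 0, p_infection = 0, p_retention = 0,
                      unit_cost = 0) {
  structure(
    list(
      name = name,
      sensitivity = sensitivity, specificity = specificity,
      sb_sensitivity = sb_sensitivity, sb_specificity = sb_specificity,
      completion_rate = completion_rate,
      p_hospitalization = p_hospitalization, p_obstruction = p_obstruction,
      p_bleeding = p_bleeding, p_infection = p_infection,
      p_retention = p_retention,
      unit_cost = unit_cost
    ),
    class = "test_spec"
  )
}

default_tests <- function() {
  list(
    fcal = test_spec("fcal", sensitivity = 0.788, specificity = 0.972,
                     completion_rate = 1, unit_cost = 12.05),
    vce = test_spec("vce", sensitivity = 0.83, specificity = 0.88,
                    sb_sensitivity = 0.97, sb_specificity = 0.87,
                    completion_rate = 0.887, p_retention = 0,
                    unit_cost = 850.00),
    ileocolonoscopy = test_spec("ileocolonoscopy", sensitivity = 0.91,
                                specificity = 0.89, completion_rate = 0.869,
                                p_hospitalization = 0.0163,
                                p_obstruction = 0.0008,
                                p_bleeding = 0.0042, p_infection = 0.04,
                                unit_cost = 74.00),
    # MR enteroscopy reads the small bowel with its single published
    # operating point, so the segment-specific fields equal the overall ones
    mre = test_spec("mre", sensitivity = 0.71, specificity = 0.66,
                    sb_sensitivity = 0.71, sb_specificity = 0.66,
                    completion_rate = 1, unit_cost = 160.10)
  )
}

# Synthetic monthly transition matrices per treatment line over
# (remission, mild, moderate, severe). Improvement probabilities increase
# with treatment line; flare probabilities are small and monthly.
default_transitions <- function() {
  states <- severity_levels()
  m <- function(...) {
    mat <- matrix(c(...), nrow = 4, byrow = TRUE,
                  dimnames = list(states, states))
    mat
  }
  list(
    states = states,
    monthly_matrix = list(
      conventional = m(
        0.920, 0.060, 0.015, 0.005,
        0.120, 0.740, 0.120, 0.020,
        0.020, 0.120, 0.760, 0.100,
        0.005, 0.030, 0.170, 0.795
      ),
      immunomodulator = m(
        0.950, 0.040, 0.008, 0.002,
        0.180, 0.720, 0.085, 0.015,
        0.030, 0.170, 0.730, 0.070,
        0.010, 0.050, 0.210, 0.730
      ),
      biologic = m(
        0.970, 0.025, 0.004, 0.001,
        0.250, 0.680, 0.060, 0.010,
        0.050, 0.220, 0.680, 0.050,
        0.020, 0.080, 0.250, 0.650
      )
    ),
    p_complication_per_month = list(
      stricture = 0.004, abscess = 0.002, fistula = 0.002
    ),
    # onset multiplier by severity band: complications track activity
    severity_multiplier = c(remission = 0, mild = 1, moderate = 2, severe = 4)
  )
}

# Euro cost catalogue. Procedure costs are the published tariff values;
# surgery, medication and adverse-event amounts are synthetic defaults
# (the full DRG schedule is not public). Every item carries exactly one of
# the four reporting buckets.
default_costs <- function() {
  item <- function(amount, bucket) list(amount = amount, bucket = bucket)
  list(items = list(
    fcal = item(12.05, "monitoring"),
    vce = item(850.00, "monitoring"),
    ileocolonoscopy = item(74.00, "monitoring"),
    mre = item(160.10, "monitoring"),
    ct = item(150.00, "monitoring"),
    patency_capsule = item(0.00, "monitoring"),
    medication_conventional = item(150.00, "interventions"),
    medication_immunomodulator = item(450.00, "interventions"),
    medication_biologic = item(3000.00, "interventions"),
    ae_hospitalization = item(1500.00, "adverse_events"),
    ae_obstruction = item(3000.00, "adverse_events"),
    ae_bleeding = item(2500.00, "adverse_events"),
    ae_infection = item(1000.00, "adverse_events"),
    ae_retention = item(2000.00, "adverse_events"),
    surgery_elective = item(8000.00, "surgery"),
    surgery_emergency = item(12000.00, "surgery"),
    surgery_other = item(6000.00, "surgery"),
    fistula_repair = item(5000.00, "surgery")
  ))
}

#' Default model configuration
#'
#' Assembles the full simulation configuration: severity thresholds, the four
#' diagnostic modalities, per-treatment-line monthly transition matrices,
#' the cost catalogue, scheduling rules and horizon.
#'
#' @param arm Surveillance arm, `"SOC"` or `"VCE"`.
#' @param rng_seed Master seed for the simulation.
#' @return A named list of class `model_config`, valid under
#'   [validate_config()].
#' @details Cycles are 3 months; the default horizon of 20 cycles gives 5
#'   years of budget reporting, while follow-up outcome comparisons use the
#'   first 18 cycles (4.5 years) on a semiannual grid. Scheduled surveillance
#'   visits recur every 2 cycles (semiannually).
#' @export
default_config <- function(arm = "SOC", rng_seed = 1L) {
  structure(
    list(
      arm = arm,
      cycle_months = 3L,
      horizon_cycles = 20L,
      scheduled_visit_interval_cycles = 2L,
      rng_seed = as.integer(rng_seed),
      discount_rate = 0,
      thresholds = severity_thresholds(),
      tests = default_tests(),
      transitions = default_transitions(),
      costs = default_costs(),
      surgery = list(
        p_elective_given_stricture = 0.7,
        post_op_relapse_multiplier = 1.0
      ),
      validation = list(
        n_replicates = 100L,
        prior = list(a = 1, b = 1)
      )
    ),
    class = "model_config"
  )
}

prob_fields <- c("sensitivity", "specificity", "sb_sensitivity",
                 "sb_specificity", "completion_rate", "p_hospitalization",
                 "p_obstruction", "p_bleeding", "p_infection", "p_retention")

#' Validate a model configuration
#'
#' Checks every structural invariant: probabilities in \[0,1\], non-negative
#' costs, row-stochastic transition matrices (rows sum to 1 within 1e-9),
#' ordered severity thresholds, recognised arm label, positive horizon.
#'
#' @param config A `model_config` list.
#' @return A character vector of violations, each naming the offending key;
#'   empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  add <- function(msg) bad[[length(bad) + 1L]] <<- msg

  thr <- config$thresholds
  if (!(isTRUE(thr$remission_upper > 0) &&
        isTRUE(thr$mild_upper > thr$remission_upper) &&
        isTRUE(thr$moderate_upper > thr$mild_upper))) {
    add("thresholds: must satisfy 0 < remission_upper < mild_upper < moderate_upper")
  }
  if (!isTRUE(config$arm %in% c("SOC", "VCE"))) {
    add(sprintf("arm: '%s' is not one of SOC, VCE", config$arm))
  }
  if (!isTRUE(config$cycle_months >= 1)) add("cycle_months: must be >= 1")
  if (!isTRUE(config$horizon_cycles >= 1)) add("horizon_cycles: must be >= 1")
  if (!isTRUE(config$scheduled_visit_interval_cycles >= 1)) {
    add("scheduled_visit_interval_cycles: must be >= 1")
  }

  for (tn in names(config$tests)) {
    spec <- config$tests[[tn]]
    for (f in prob_fields) {
      v <- spec[[f]]
      if (!is.null(v) && !(isTRUE(v >= 0) && isTRUE(v <= 1))) {
        add(sprintf("tests.%s.%s: %s not in [0,1]", tn, f, format(v)))
      }
    }
    if (!isTRUE(spec$unit_cost >= 0)) {
      add(sprintf("tests.%s.unit_cost: must be >= 0", tn))
    }
  }

  tr <- config$transitions
  for (line in names(tr$monthly_matrix)) {
    mat <- tr$monthly_matrix[[line]]
    if (!is.matrix(mat) || any(dim(mat) != c(4L, 4L))) {
      add(sprintf("transitions.monthly_matrix.%s: must be a 4x4 matrix", line))
      next
    }
    if (any(mat < 0 | mat > 1)) {
      add(sprintf("transitions.monthly_matrix.%s: entries outside [0,1]", line))
    }
    rs <- rowSums(mat)
    off <- which(abs(rs - 1) > 1e-9)
    for (i in off) {
      add(sprintf("transitions.monthly_matrix.%s row %s: sums to %.6f, not 1",
                  line, severity_levels()[i], rs[i]))
    }
  }
  for (ct in names(tr$p_complication_per_month)) {
    p <- tr$p_complication_per_month[[ct]]
    if (!(isTRUE(p >= 0) && isTRUE(p <= 1))) {
      add(sprintf("transitions.p_complication_per_month.%s: not in [0,1]", ct))
    }
  }

  buckets <- c("monitoring", "interventions", "adverse_events", "surgery")
  for (nm in names(config$costs$items)) {
    it <- config$costs$items[[nm]]
    if (!isTRUE(it$amount >= 0)) {
      add(sprintf("costs.items.%s.amount: must be >= 0", nm))
    }
    if (!isTRUE(it$bucket %in% buckets)) {
      add(sprintf("costs.items.%s.bucket: '%s' is not a recognised bucket",
                  nm, it$bucket))
    }
  }
  bad
}

# deep-merge user values over defaults, preserving matrix structure
merge_config <- function(base, override) {
  for (nm in names(override)) {
    bv <- base[[nm]]
    ov <- override[[nm]]
    if (is.list(bv) && is.list(ov) && !is.null(names(bv))) {
      base[[nm]] <- merge_config(bv, ov)
    } else if (is.matrix(bv) && !is.matrix(ov)) {
      mat <- do.call(rbind, lapply(ov, as.numeric))
      dimnames(mat) <- dimnames(bv)
      base[[nm]] <- mat
    } else if (is.atomic(bv) && length(bv) > 1L && is.list(ov)) {
      v <- unlist(ov)
      if (is.null(names(v)) && !is.null(names(bv))) names(v) <- names(bv)
      base[[nm]] <- v
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

config_to_plain <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) unname(x[i, ]))
  } else if (is.list(x)) {
    lapply(unclass(x), config_to_plain)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

#' Save a model configuration to JSON or YAML
#'
#' @param config A `model_config`.
#' @param path Output path; the extension (`.json`, `.yaml`/`.yml`) selects
#'   the dialect.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  plain <- config_to_plain(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Load a model configuration from JSON or YAML
#'
#' Fields not present in the file are filled with the documented defaults;
#' the merged configuration is validated before being returned.
#'
#' @param path Path to a JSON or YAML configuration file.
#' @return A validated `model_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path))
  }
  raw <- tryCatch(
    {
      if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        yaml::read_yaml(path)
      } else {
        jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
      }
    },
    error = function(e) abort(sprintf("config parse failure in %s: %s",
                                      path, conditionMessage(e)))
  )
  if (!is.list(raw)) abort(sprintf("config file %s does not contain a mapping", path))
  cfg <- merge_config(default_config(), raw)
  # restore test_spec classes dropped by serialization
  cfg$tests <- lapply(cfg$tests, function(x) structure(x, class = "test_spec"))
  class(cfg) <- "model_config"
  bad <- validate_config(cfg)
  if (length(bad) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", bad, collapse = "\n")))
  }
  cfg
}
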