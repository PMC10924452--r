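# Synthetic baseline cohort. The study population is patients with Crohn's
# disease and small-bowel involvement followed at a single centre; the real
# records are not deposited, so the generator emulates a clinic cohort with
# configurable marginals. Every downstream analysis is distribution-robust:
# nothing asserts the particular euro outcomes of this synthetic population.

cohort_columns <- c(
  "patient_id", "age", "sex", "years_since_diagnosis", "baseline_cdai",
  "small_bowel_involvement", "colonic_involvement", "stricturing", "abscess",
  "treatment_line", "strategy"
)

treatment_lines <- function() c("conventional", "immunomodulator", "biologic")

#' Parameters of the synthetic baseline cohort
#'
#' Marginal distributions for a clinic population of Crohn's disease patients
#' with small-bowel involvement. Ages follow a truncated normal; baseline
#' CDAI is a mixture over the four severity bands with uniform scores within
#' each band.
#'
#' @param n_patients Number of baseline records (default 276, the retained
#'   study population size).
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age distribution.
#' @param severity_shares Mixture shares over
#'   remission/mild/moderate/severe baseline bands; must sum to 1.
#' @param p_small_bowel,p_colonic,p_stricturing,p_abscess Flag prevalences.
#' @param p_female Share of female patients.
#' @param p_top_down Share on a top-down treatment strategy.
#' @param line_shares Shares over conventional/immunomodulator/biologic
#'   current treatment line.
#' @param diagnosis_years_mean Mean years since diagnosis (exponential).
#' @param rng_seed Generator seed.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 276L,
                          age_mean = 40, age_sd = 13,
                          age_min = 16, age_max = 80,
                          severity_shares = c(remission = 0.25, mild = 0.35,
                                              moderate = 0.30, severe = 0.10),
                          p_small_bowel = 1.0, p_colonic = 0.6,
                          p_stricturing = 0.15, p_abscess = 0.05,
                          p_female = 0.5, p_top_down = 0.2,
                          line_shares = c(conventional = 0.40,
                                          immunomodulator = 0.35,
                                          biologic = 0.25),
                          diagnosis_years_mean = 8,
                          rng_seed = 1L) {
  params <- list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    severity_shares = severity_shares,
    p_small_bowel = p_small_bowel, p_colonic = p_colonic,
    p_stricturing = p_stricturing, p_abscess = p_abscess,
    p_female = p_female, p_top_down = p_top_down,
    line_shares = line_shares,
    diagnosis_years_mean = diagnosis_years_mean,
    rng_seed = as.integer(rng_seed)
  )
  if (params$n_patients < 1L) abort("n_patients must be >= 1")
  probs <- c(p_small_bowel, p_colonic, p_stricturing, p_abscess,
             p_female, p_top_down)
  if (any(probs < 0 | probs > 1)) abort("all prevalences must lie in [0,1]")
  if (abs(sum(severity_shares) - 1) > 1e-9) {
    abort("severity_shares must sum to 1")
  }
  if (abs(sum(line_shares) - 1) > 1e-9) abort("line_shares must sum to 1")
  structure(params, class = "cohort_params")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic baseline cohort
#'
#' @param params A [cohort_params()] object.
#' @param thresholds CDAI band thresholds used for the baseline severity
#'   mixture.
#' @return A tibble with one row per patient and the documented baseline
#'   columns; identical output for identical seed. At least one disease
#'   location flag is set for every patient.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 10))
#' @export
generate_cohort <- function(params = cohort_params(),
                            thresholds = severity_thresholds()) {
  if (!inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, params)
  }
  n <- params$n_patients
  stream <- rng_stream(params$rng_seed)
  with_stream(stream, {
    bands <- sample(severity_levels(), n, replace = TRUE,
                    prob = params$severity_shares)
    cdai <- vapply(bands, function(b) {
      bb <- cdai_band_bounds(b, thresholds)
      runif(1, bb[1], bb[2])
    }, numeric(1))
    sb <- runif(n) < params$p_small_bowel
    col <- runif(n) < params$p_colonic
    # a retained record must have a diagnosed disease location
    col[!sb & !col] <- TRUE
    tibble(
      patient_id = sprintf("p%03d:0", seq_len(n)),
      age = round(rtrunc_norm(n, params$age_mean, params$age_sd,
                              params$age_min, params$age_max), 1),
      sex = ifelse(runif(n) < params$p_female, "F", "M"),
      years_since_diagnosis = round(stats::rexp(n, 1 / params$diagnosis_years_mean), 1),
      baseline_cdai = round(cdai, 1),
      small_bowel_involvement = sb,
      colonic_involvement = col,
      stricturing = runif(n) < params$p_stricturing,
      abscess = runif(n) < params$p_abscess,
      treatment_line = sample(treatment_lines(), n, replace = TRUE,
                              prob = params$line_shares),
      strategy = ifelse(runif(n) < params$p_top_down, "top_down", "bottom_up")
    )
  })
}

#' Replicate a baseline cohort
#'
#' Copies every baseline record `factor` times, as done to enlarge the
#' simulation set (276 x 10 = 2760) and the validation set
#' (276 x 100 = 27 600). Replicate `j` of patient `i` gets patient id
#' `"<base>:j"` so replicates of the same record can be grouped later.
#'
#' @param cohort A baseline cohort tibble.
#' @param factor Replication factor (>= 1).
#' @return A tibble with `nrow(cohort) * factor` rows; baseline fields are
#'   copied unchanged.
#' @export
replicate_cohort <- function(cohort, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    abort("replication factor must be a single count >= 1")
  }
  factor <- as.integer(factor)
  base_id <- sub(":[0-9]+$", "", cohort$patient_id)
  out <- cohort[rep(seq_len(nrow(cohort)), times = factor), ]
  rep_idx <- rep(seq_len(factor) - 1L, each = nrow(cohort))
  out$patient_id <- sprintf("%s:%d", rep(base_id, times = factor), rep_idx)
  as_tibble(out)
}

#' Validate a baseline cohort table
#'
#' @param cohort A cohort tibble (for example from [read_cohort()]).
#' @return Character vector of row-level violations (empty when valid), each
#'   naming the row and column.
#' @export
validate_cohort <- function(cohort) {
  bad <- character(0)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    return(sprintf("missing column: %s", missing_cols))
  }
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    if (is.na(row$age) || row$age < 16 || row$age > 90) {
      bad <- c(bad, sprintf("row %d, age: %s outside [16, 90]", i, row$age))
    }
    if (is.na(row$baseline_cdai) || row$baseline_cdai < 0) {
      bad <- c(bad, sprintf("row %d, baseline_cdai: must be >= 0", i))
    }
    if (!isTRUE(row$small_bowel_involvement) && !isTRUE(row$colonic_involvement)) {
      bad <- c(bad, sprintf(
        "row %d, small_bowel_involvement/colonic_involvement: no diagnosed disease location", i))
    }
    if (is.na(row$years_since_diagnosis) || row$years_since_diagnosis < 0) {
      bad <- c(bad, sprintf("row %d, years_since_diagnosis: must be >= 0", i))
    }
    if (!row$treatment_line %in% treatment_lines()) {
      bad <- c(bad, sprintf("row %d, treatment_line: '%s' unknown", i,
                            row$treatment_line))
    }
    if (!row$strategy %in% c("bottom_up", "top_down")) {
      bad <- c(bad, sprintf("row %d, strategy: '%s' unknown", i, row$strategy))
    }
    if (!row$sex %in% c("F", "M")) {
      bad <- c(bad, sprintf("row %d, sex: '%s' unknown", i, row$sex))
    }
  }
  bad
}

#' Write a cohort to CSV
#'
#' UTF-8, "." decimal separator, one row per patient.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, cohort_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path CSV path with the documented header.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) abort(sprintf("cannot parse cohort CSV %s: %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(df) == 0) abort(sprintf("cohort file %s contains no records", path))
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort file %s missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  cohort <- as_tibble(df[, cohort_columns])
  bad <- validate_cohort(cohort)
  if (length(bad) > 0) {
    abort(paste0("invalid cohort:\n", paste("-", bad, collapse = "\n")))
  }
  cohort
}
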