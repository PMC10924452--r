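#' Disease severity bands
#'
#' The four CDAI-derived severity bands used throughout the simulation, in
#' increasing order of disease activity.
#'
#' @return Character vector `c("remission", "mild", "moderate", "severe")`.
#' @export
severity_levels <- function() {
  c("remission", "mild", "moderate", "severe")
}

#' Default CDAI severity thresholds
#'
#' Band boundaries on the Crohn's Disease Activity Index: remission below 150,
#' mild in \[150, 220), moderate in \[220, 450), severe at 450 and above.
#'
#' @param remission_upper Exclusive upper CDAI bound of remission.
#' @param mild_upper Exclusive upper CDAI bound of mild disease.
#' @param moderate_upper Exclusive upper CDAI bound of moderate disease.
#' @return A named list with the three thresholds.
#' @export
severity_thresholds <- function(remission_upper = 150, mild_upper = 220,
                                moderate_upper = 450) {
  thr <- list(
    remission_upper = remission_upper,
    mild_upper = mild_upper,
    moderate_upper = moderate_upper
  )
  if (!(remission_upper > 0 && mild_upper > remission_upper &&
        moderate_upper > mild_upper)) {
    abort("severity thresholds must satisfy 0 < remission_upper < mild_upper < moderate_upper")
  }
  thr
}

#' Classify a CDAI score into a severity band
#'
#' Bands are lower-inclusive and upper-exclusive: a score of exactly 150 is
#' mild, 220 moderate, 450 severe.
#'
#' @param score Numeric vector of CDAI scores (non-negative).
#' @param thresholds Output of [severity_thresholds()].
#' @return Character vector of band labels, one per score.
#' @examples
#' classify_cdai(c(0, 100, 150, 219, 220, 449, 450))
#' @export
classify_cdai <- function(score, thresholds = severity_thresholds()) {
  if (any(is.na(score)) || any(score < 0)) {
    abort("CDAI scores must be non-negative and non-missing")
  }
  cuts <- c(thresholds$remission_upper, thresholds$mild_upper,
            thresholds$moderate_upper)
  severity_levels()[findInterval(score, cuts) + 1L]
}

# integer rank 1..4 for ordinal comparisons
severity_rank <- function(severity) {
  match(severity, severity_levels())
}

# uniform CDAI draw within a band (severe capped at 600)
cdai_band_bounds <- function(severity, thresholds) {
  switch(severity,
    remission = c(0, thresholds$remission_upper),
    mild = c(thresholds$remission_upper, thresholds$mild_upper),
    moderate = c(thresholds$mild_upper, thresholds$moderate_upper),
    severe = c(thresholds$moderate_upper, 600)
  )
}
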