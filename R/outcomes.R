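# Deterministic outcome classifiers: the composite 14-day clinical
# response and KDIGO acute-kidney-injury staging from serum creatinine.

#' SOFA improvement criterion
#'
#' A baseline SOFA score of at least 3 counts as improved when the day-14
#' score is lower by at least 30% (inclusive at exactly 30%); for a
#' baseline below 3 the score must be unchanged or lower.
#'
#' @param baseline,day14 Non-negative integer SOFA scores (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' sofa_improved(10, 7)   # TRUE: exactly 30%
#' sofa_improved(10, 8)   # FALSE: 20%
sofa_improved <- function(baseline, day14) {
  if (any(baseline < 0) || any(day14 < 0))
    stop("SOFA scores must be >= 0", call. = FALSE)
  ifelse(baseline >= 3,
         (baseline - day14) / baseline >= 0.30,
         day14 <= baseline)
}

#' Composite 14-day clinical response
#'
#' A patient responds at day 14 when alive, the SOFA criterion holds
#' ([sofa_improved()]), and every applicable syndrome-specific criterion
#' holds: with baseline shock, hemodynamic stability (mean arterial
#' pressure > 65 mmHg without vasopressors); with pneumonia, an improved
#' or stable PaO2/FiO2 ratio; with bacteremia, no day-14 growth of the
#' index isolate.  Criteria for absent syndromes are vacuously true.  All
#' applicable criteria are combined with AND (the strict reading); set
#' `any_applicable = TRUE` for a labelled OR sensitivity variant that is
#' not the protocol definition.
#'
#' @param course A `data.frame` (one row per patient) or list with fields
#'   `alive_day14`, `sofa_baseline`, `sofa_day14`, `shock_at_baseline`,
#'   `map_day14`, `on_vasopressor_day14`, `has_pneumonia`, `pf_baseline`,
#'   `pf_day14`, `has_bacteremia`, `blood_culture_day14_positive`.
#'   Fields required by an applicable criterion must be non-missing for
#'   patients alive at day 14.
#' @param pf_tolerance Tolerated decline in the P/F ratio still counted as
#'   "stable" (mmHg); the protocol reading is 0.
#' @param any_applicable Combine applicable syndrome criteria with OR
#'   instead of AND (sensitivity variant only).
#' @return Logical vector of responder flags.
#' @export
classify_response <- function(course, pf_tolerance = 0,
                              any_applicable = FALSE) {
  course <- as.data.frame(course)
  need <- c("alive_day14", "sofa_baseline", "sofa_day14",
            "shock_at_baseline", "has_pneumonia", "has_bacteremia")
  miss <- setdiff(need, names(course))
  if (length(miss))
    stop("course is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  alive <- course$alive_day14
  get_field <- function(nm) if (nm %in% names(course)) course[[nm]] else
    rep(NA, nrow(course))
  check_required <- function(applicable, fields) {
    for (nm in fields) {
      bad <- alive & applicable & is.na(get_field(nm))
      if (any(bad))
        stop("field `", nm, "` is required for patients with an applicable ",
             "criterion", call. = FALSE)
    }
  }
  check_required(rep(TRUE, nrow(course)), c("sofa_baseline", "sofa_day14"))
  check_required(course$shock_at_baseline,
                 c("map_day14", "on_vasopressor_day14"))
  check_required(course$has_pneumonia, c("pf_baseline", "pf_day14"))
  check_required(course$has_bacteremia, "blood_culture_day14_positive")

  sofa_ok <- ifelse(alive,
                    sofa_improved(course$sofa_baseline, course$sofa_day14),
                    FALSE)
  hemo_ok <- !course$shock_at_baseline |
    (get_field("map_day14") > 65 & !get_field("on_vasopressor_day14"))
  pf_ok <- !course$has_pneumonia |
    (get_field("pf_day14") >= get_field("pf_baseline") - pf_tolerance)
  micro_ok <- !course$has_bacteremia |
    !get_field("blood_culture_day14_positive")
  applicable_ok <- if (any_applicable) {
    none <- !course$shock_at_baseline & !course$has_pneumonia &
      !course$has_bacteremia
    none |
      (course$shock_at_baseline & hemo_ok) |
      (course$has_pneumonia & pf_ok) |
      (course$has_bacteremia & micro_ok)
  } else hemo_ok & pf_ok & micro_ok
  out <- alive & sofa_ok & applicable_ok
  out[!alive] <- FALSE
  as.logical(out)
}

#' KDIGO acute-kidney-injury stage from a creatinine series
#'
#' Stages AKI from serum creatinine (micromol/L) and renal replacement
#' therapy, using the creatinine criteria only (no urine output): stage 1
#' for a peak/baseline ratio of 1.5-1.9 or an absolute rise of at least
#' 26.5 micromol/L (0.3 mg/dL) within 48 h; stage 2 for a ratio of
#' 2.0-2.9; stage 3 for a ratio of at least 3.0, a peak of at least 353.6
#' micromol/L (4.0 mg/dL), or renal replacement therapy.  Stage 0 means no
#' AKI.
#'
#' @param scr_series `data.frame` with columns `day` (days from baseline,
#'   first row must be day 0) and `scr` (micromol/L, > 0).
#' @param on_rrt Logical: renal replacement therapy during the episode.
#' @return Integer stage 0-3.
#' @export
#' @examples
#' s <- data.frame(day = c(0, 2, 5), scr = c(80, 100, 128))
#' kdigo_stage(s)          # ratio 1.6 -> stage 1
kdigo_stage <- function(scr_series, on_rrt = FALSE) {
  if (!is.data.frame(scr_series) || nrow(scr_series) == 0L)
    stop("scr_series must be a non-empty data.frame", call. = FALSE)
  stopifnot(all(c("day", "scr") %in% names(scr_series)))
  scr_series <- scr_series[order(scr_series$day), , drop = FALSE]
  if (scr_series$day[1] != 0)
    stop("scr_series must contain a baseline value at day 0", call. = FALSE)
  baseline <- scr_series$scr[1]
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline creatinine must be > 0", call. = FALSE)
  peak <- max(scr_series$scr)
  # largest rise between any two measurements at most 48 h apart
  rise48 <- 0
  n <- nrow(scr_series)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- which(scr_series$day > scr_series$day[i] &
                   scr_series$day <= scr_series$day[i] + 2)
      if (length(j))
        rise48 <- max(rise48, max(scr_series$scr[j]) - scr_series$scr[i])
    }
  }
  .kdigo_from_summary(baseline, peak, rise48, on_rrt)
}

# Vectorized staging from per-patient summaries (used by the cohort
# simulator, which constructs the series itself).
.kdigo_from_summary <- function(baseline, peak, rise48, on_rrt) {
  ratio <- peak / baseline
  stage <- integer(length(ratio))
  stage[ratio >= 1.5 | rise48 >= 26.5] <- 1L
  stage[ratio >= 2.0] <- 2L
  stage[ratio >= 3.0 | peak >= 353.6 | on_rrt] <- 3L
  stage
}
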