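# Limited-sampling estimation of the steady-state 24-h AUC of polymyxin B
# from a trough (C0h) / 2-h (C2h) concentration pair, plus the 50-100
# mg.h/L therapeutic-window classifier and exposure-unit helpers.

#' Limited-sampling strategy coefficients
#'
#' Published regression constants mapping a steady-state trough/2-h pair
#' to the 24-h AUC:
#' `AUC0-24 = 2 * (-0.673 + 6.084 * C0h + 6.230 * C2h)`.
#' The defaults are those constants; override only deliberately.
#'
#' @param intercept Regression intercept (mg·h/L per half day).
#' @param weight_c0 Coefficient on the trough concentration (h).
#' @param weight_c2 Coefficient on the 2-h concentration (h).
#' @param half_day_multiplier Multiplier from the 12-h interval AUC to the
#'   24-h AUC (2 under q12h dosing).
#' @return An object of class `lss_coefficients`.
#' @export
lss_coefficients <- function(intercept = -0.673, weight_c0 = 6.084,
                             weight_c2 = 6.230, half_day_multiplier = 2) {
  structure(list(intercept = intercept, weight_c0 = weight_c0,
                 weight_c2 = weight_c2,
                 half_day_multiplier = half_day_multiplier),
            class = "lss_coefficients")
}

#' Estimate the steady-state 24-h AUC from a trough/2-h pair
#'
#' Applies the limited-sampling regression to one or more concentration
#' pairs and classifies each estimate against the therapeutic window.
#' Because of the negative intercept the estimate can be non-positive at
#' very low concentrations; such estimates are flagged `valid = FALSE`
#' (never an error) and downstream titration treats them as below target.
#'
#' @param c0h Trough concentration(s), mg/L, >= 0.
#' @param c2h Concentration(s) 2 h after the start of the infusion, mg/L,
#'   >= 0.
#' @param occasion Optional dose index/label of the sampling occasion.
#' @param coefficients An [lss_coefficients()] object.
#' @param window Therapeutic window bounds (mg·h/L), default `c(50, 100)`.
#'
#' @return A `data.frame` with columns `value` (mg·h/L), `category`
#'   (below/within/above), `valid` and `occasion`.
#' @export
#' @examples
#' estimate_auc(2.0, 4.0)          # 72.83, within the window
#' estimate_auc(0, 0)              # -1.346, flagged invalid
estimate_auc <- function(c0h, c2h, occasion = NA,
                         coefficients = lss_coefficients(),
                         window = c(50, 100)) {
  if (length(c2h) != length(c0h))
    stop("c0h and c2h must have equal length", call. = FALSE)
  if (any(!is.finite(c0h)) || any(!is.finite(c2h)) ||
      any(c0h < 0) || any(c2h < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  stopifnot(inherits(coefficients, "lss_coefficients"))
  value <- coefficients$half_day_multiplier *
    (coefficients$intercept + coefficients$weight_c0 * c0h +
       coefficients$weight_c2 * c2h)
  data.frame(value = value,
             category = classify_auc(value, window),
             valid = value > 0,
             occasion = rep_len(occasion, length(value)))
}

#' Classify an AUC against the therapeutic window
#'
#' Both bounds are inclusive: the protocol maintains the dose once the
#' ssAUC0-24 "reaches" 50-100 mg·h/L, so 50 and 100 themselves count as
#' within.  The three categories partition the real line.
#'
#' @param value AUC value(s), mg·h/L (finite).
#' @param window Lower/upper window bounds, default `c(50, 100)`.
#' @return A factor with levels `below`, `within`, `above`.
#' @export
classify_auc <- function(value, window = c(50, 100)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (any(!is.finite(value))) stop("AUC values must be finite", call. = FALSE)
  factor(ifelse(value < window[1], "below",
                ifelse(value > window[2], "above", "within")),
         levels = c("below", "within", "above"))
}

#' Average steady-state concentration implied by a 24-h AUC
#'
#' `Css,avg = AUC0-24 / 24`; the 50-100 mg·h/L window corresponds to
#' roughly 2-4 mg/L.
#'
#' @param value AUC value(s), mg·h/L, >= 0.
#' @return Css,avg in mg/L.
#' @export
auc_to_css_avg <- function(value) {
  if (any(value < 0)) stop("AUC must be >= 0", call. = FALSE)
  value / 24
}

#' Unbound AUC to MIC ratio (fAUC/MIC)
#'
#' The efficacy-driving PK/PD index for polymyxins; around 20 is
#' associated with 2-log bacterial killing in murine thigh-infection
#' models.  No default unbound fraction is provided: it must be supplied.
#'
#' @param auc Total-drug AUC0-24 (mg·h/L), >= 0.
#' @param unbound_fraction Fraction of unbound drug in plasma, in `[0, 1]`.
#' @param mic Minimal inhibitory concentration (mg/L), > 0.
#' @return The dimensionless fAUC/MIC ratio.
#' @export
#' @examples
#' compute_fauc_mic(40, unbound_fraction = 1, mic = 2)  # 20
compute_fauc_mic <- function(auc, unbound_fraction, mic) {
  if (any(mic <= 0)) stop("mic must be > 0", call. = FALSE)
  if (any(unbound_fraction < 0) || any(unbound_fraction > 1))
    stop("unbound_fraction must be in [0, 1]", call. = FALSE)
  if (any(auc < 0)) stop("auc must be >= 0", call. = FALSE)
  auc * unbound_fraction / mic
}
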