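# Analytic two-compartment intravenous-infusion pharmacokinetics.
#
# Linear kinetics throughout: every dose contributes independently
# (superposition), so concentrations and AUCs are sums of per-dose
# closed-form terms.  With zero intercompartmental clearance the model
# collapses exactly to the one-compartment infusion solution.

#' Pharmacokinetic parameters for a two-compartment infusion model
#'
#' Structural parameters of a linear two-compartment model with zero-order
#' (constant-rate) infusion input.  Defaults are illustrative,
#' literature-typical values for intravenous polymyxin B in critically ill
#' adults (clearance around 2 L/h, steady-state volume around 30 L); they
#' are configuration, not fitted constants.
#'
#' @param clearance Elimination clearance CL (L/h), > 0.
#' @param central_volume Central compartment volume V1 (L), > 0.
#' @param intercompartmental_clearance Distribution clearance Q (L/h),
#'   >= 0.  With `Q = 0` the model reduces exactly to a one-compartment
#'   model.
#' @param peripheral_volume Peripheral volume V2 (L), > 0.
#' @param crrt_clearance_multiplier Multiplicative clearance increase
#'   (dimensionless, >= 1) applied to patients on continuous renal
#'   replacement therapy; convective filtration removes polymyxin B.
#' @param scr_exponent Covariate exponent (dimensionless, >= 0) linking
#'   serum creatinine to clearance: individual clearance is scaled by
#'   `(scr / scr_reference)^(-scr_exponent)`, so higher creatinine means
#'   lower clearance and higher exposure.
#'
#' @return An object of class `pk_parameters`.
#' @seealso [concentration_at()], [true_auc_window()],
#'   [assign_individual_pk()]
#' @export
#' @examples
#' p <- pk_parameters(clearance = 2, central_volume = 12,
#'                    intercompartmental_clearance = 8, peripheral_volume = 18)
#' concentration_at(p, regimen_doses(initial_regimen("HD"), 14), t = 72)
pk_parameters <- function(clearance = 2.0,
                          central_volume = 12,
                          intercompartmental_clearance = 8,
                          peripheral_volume = 18,
                          crrt_clearance_multiplier = 1.4,
                          scr_exponent = 0.35) {
  stopifnot(is.numeric(clearance), length(clearance) == 1L,
            is.numeric(central_volume), length(central_volume) == 1L,
            is.numeric(intercompartmental_clearance),
            is.numeric(peripheral_volume), length(peripheral_volume) == 1L)
  if (!(clearance > 0) || !(central_volume > 0) || !(peripheral_volume > 0))
    stop("clearance and volumes must be strictly positive", call. = FALSE)
  if (intercompartmental_clearance < 0)
    stop("intercompartmental_clearance must be >= 0", call. = FALSE)
  if (crrt_clearance_multiplier < 1)
    stop("crrt_clearance_multiplier must be >= 1", call. = FALSE)
  if (scr_exponent < 0)
    stop("scr_exponent must be >= 0", call. = FALSE)
  structure(list(clearance = clearance,
                 central_volume = central_volume,
                 intercompartmental_clearance = intercompartmental_clearance,
                 peripheral_volume = peripheral_volume,
                 crrt_clearance_multiplier = crrt_clearance_multiplier,
                 scr_exponent = scr_exponent),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment infusion PK parameters\n")
  cat(sprintf("  CL = %.3g L/h, V1 = %.3g L, Q = %.3g L/h, V2 = %.3g L\n",
              x$clearance, x$central_volume,
              x$intercompartmental_clearance, x$peripheral_volume))
  cat(sprintf("  CRRT clearance multiplier = %.3g, Scr exponent = %.3g\n",
              x$crrt_clearance_multiplier, x$scr_exponent))
  invisible(x)
}

# Hybrid (macro) constants: disposition exponents alpha >= beta > 0 and the
# bolus unit-dose coefficients, so that a bolus gives
#   C(t) = (D/V1) * (ca * exp(-alpha t) + cb * exp(-beta t)),  ca + cb = 1.
# One-compartment limit (Q = 0) is special-cased to avoid the beta -> 0
# singularity and to reproduce the one-compartment closed form exactly.
.pk_macro <- function(params) {
  k10 <- params$clearance / params$central_volume
  if (params$intercompartmental_clearance == 0) {
    return(list(lambda = k10, coef = 1))
  }
  k12 <- params$intercompartmental_clearance / params$central_volume
  k21 <- params$intercompartmental_clearance / params$peripheral_volume
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(lambda = c(alpha, beta),
       coef = c((alpha - k21) / (alpha - beta), (k21 - beta) / (alpha - beta)))
}

#' Dosing history constructors
#'
#' `dose_events()` assembles a validated dosing history (one row per
#' infusion).  `regimen()` describes the protocol's loading + q12h
#' maintenance pattern and `regimen_doses()` expands it into a dosing
#' history of `n_doses` administrations (dose 1 is the loading dose at
#' time 0).
#'
#' @param start_time Hours from the first dose, >= 0.
#' @param amount Dose amount (mg), > 0.
#' @param infusion_duration Infusion duration (h), > 0.  The protocol never
#'   states one; 1 h is the package default.
#'
#' @return A `data.frame` of class `dose_events` with columns `start_time`,
#'   `amount`, `infusion_duration`, sorted by `start_time`.
#' @export
#' @examples
#' dose_events(c(0, 12), c(150, 75), 1)
dose_events <- function(start_time, amount, infusion_duration = 1) {
  n <- length(start_time)
  amount <- rep_len(amount, n)
  infusion_duration <- rep_len(infusion_duration, n)
  if (n > 0 && (any(!is.finite(start_time)) || any(start_time < 0)))
    stop("dose start times must be finite and >= 0", call. = FALSE)
  if (any(amount <= 0) || any(infusion_duration <= 0))
    stop("dose amounts and infusion durations must be > 0", call. = FALSE)
  o <- order(start_time)
  d <- data.frame(start_time = start_time[o], amount = amount[o],
                  infusion_duration = infusion_duration[o])
  if (n > 1 &&
      any(d$start_time[-1] < (d$start_time + d$infusion_duration)[-n]))
    stop("infusions overlap: a dose starts before the previous one ends",
         call. = FALSE)
  class(d) <- c("dose_events", "data.frame")
  d
}

#' @param loading_dose Loading dose (mg), > 0.
#' @param maintenance_dose Maintenance dose (mg) given every
#'   `dosing_interval` hours.
#' @param dosing_interval Dosing interval (h); the protocol fixes 12.
#' @rdname dose_events
#' @export
regimen <- function(loading_dose, maintenance_dose, dosing_interval = 12,
                    infusion_duration = 1) {
  stopifnot(loading_dose > 0, maintenance_dose > 0, dosing_interval > 0,
            infusion_duration > 0, infusion_duration < dosing_interval)
  structure(list(loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose,
                 dosing_interval = dosing_interval,
                 infusion_duration = infusion_duration),
            class = "regimen")
}

#' @param x A `regimen`.
#' @param n_doses Number of administrations to expand to (>= 1).
#' @rdname dose_events
#' @export
regimen_doses <- function(x, n_doses) {
  stopifnot(inherits(x, "regimen"), n_doses >= 1)
  dose_events(start_time = x$dosing_interval * (seq_len(n_doses) - 1),
              amount = c(x$loading_dose,
                         rep(x$maintenance_dose, n_doses - 1)),
              infusion_duration = x$infusion_duration)
}

.check_doses <- function(doses) {
  if (!inherits(doses, "dose_events")) {
    if (is.data.frame(doses) &&
        all(c("start_time", "amount", "infusion_duration") %in% names(doses)))
      doses <- dose_events(doses$start_time, doses$amount,
                           doses$infusion_duration)
    else stop("`doses` must be a dose_events object", call. = FALSE)
  }
  doses
}

#' Plasma concentration under a dosing history
#'
#' Evaluates the analytic two-compartment infusion solution, summed over
#' all doses (superposition).  During an infusion of rate `R0 = amount /
#' infusion_duration` each disposition exponent `lambda` contributes
#' `R0 * c_lambda / (V1 * lambda) * (1 - exp(-lambda * tau))`; after the
#' infusion the accumulated term washes out mono-exponentially.
#'
#' @param params A [pk_parameters()] object.
#' @param doses A [dose_events()] history (possibly empty).
#' @param t Time(s) in hours since the first dose, >= 0 (vectorized).
#'
#' @return Plasma concentration (mg/L), same length as `t`; non-negative
#'   and continuous in `t`.
#' @export
concentration_at <- function(params, doses, t) {
  stopifnot(inherits(params, "pk_parameters"))
  doses <- .check_doses(doses)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  out <- numeric(length(t))
  if (nrow(doses) == 0L) return(out)
  m <- .pk_macro(params)
  v1 <- params$central_volume
  for (i in seq_len(nrow(doses))) {
    tau <- t - doses$start_time[i]
    act <- tau > 0
    if (!any(act)) next
    tinf <- doses$infusion_duration[i]
    r0 <- doses$amount[i] / tinf
    ta <- tau[act]
    contrib <- numeric(length(ta))
    for (j in seq_along(m$lambda)) {
      lam <- m$lambda[j]
      k <- r0 * m$coef[j] / (v1 * lam)
      during <- ta <= tinf
      val <- numeric(length(ta))
      val[during] <- k * (1 - exp(-lam * ta[during]))
      val[!during] <- k * (1 - exp(-lam * tinf)) *
        exp(-lam * (ta[!during] - tinf))
      contrib <- contrib + val
    }
    out[act] <- out[act] + contrib
  }
  out
}

# Integral over [0, x] (x >= 0, relative to dose start) of one exponential
# term of the infusion solution.
.term_auc <- function(k, lam, tinf, x) {
  if (x <= 0) return(0)
  if (x <= tinf) {
    k * (x - (1 - exp(-lam * x)) / lam)
  } else {
    k * (tinf - (1 - exp(-lam * tinf)) / lam) +
      k * (1 - exp(-lam * tinf)) * (1 - exp(-lam * (x - tinf))) / lam
  }
}

#' Analytic AUC of the concentration curve over a time window
#'
#' Term-by-term exponential integration of [concentration_at()] over
#' `[t0, t1]`; exactly additive over adjacent windows.
#'
#' @inheritParams concentration_at
#' @param t0,t1 Window bounds in hours, `t1 > t0 >= 0`.
#'
#' @return AUC over the window (mg·h/L).
#' @export
#' @examples
#' p <- pk_parameters()
#' d <- regimen_doses(regimen(150, 75), 14)
#' true_auc_window(p, d, 72, 96)   # steady-state-ish daily AUC ~ 150 / CL
true_auc_window <- function(params, doses, t0, t1) {
  stopifnot(inherits(params, "pk_parameters"))
  doses <- .check_doses(doses)
  if (!is.finite(t0) || !is.finite(t1) || t0 < 0 || t1 <= t0)
    stop("window must satisfy t1 > t0 >= 0", call. = FALSE)
  if (nrow(doses) == 0L) return(0)
  m <- .pk_macro(params)
  v1 <- params$central_volume
  total <- 0
  for (i in seq_len(nrow(doses))) {
    x0 <- max(0, t0 - doses$start_time[i])
    x1 <- max(0, t1 - doses$start_time[i])
    if (x1 <= 0) next
    tinf <- doses$infusion_duration[i]
    r0 <- doses$amount[i] / tinf
    for (j in seq_along(m$lambda)) {
      lam <- m$lambda[j]
      k <- r0 * m$coef[j] / (v1 * lam)
      total <- total + .term_auc(k, lam, tinf, x1) - .term_auc(k, lam, tinf, x0)
    }
  }
  total
}

#' Simulate a trough/2-h concentration pair at a sampling occasion
#'
#' Returns the model concentrations immediately before the start of the
#' indexed dose (`C0h`, the trough) and 2 h after the start of its
#' infusion (`C2h`), each perturbed by an independent lognormal residual
#' error with median 1 and coefficient of variation `residual_cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = 0`).  The titration protocol
#' samples at the 2nd and 7th administrations.
#'
#' @inheritParams concentration_at
#' @param occasion_dose_index Index (1-based) of an existing dose in
#'   `doses`.
#' @param residual_cv Residual (assay + model) coefficient of variation,
#'   >= 0; 0 returns exact model predictions.
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#'
#' @return Named numeric vector `c(c0h = ..., c2h = ...)` (mg/L).
#' @export
sample_concentrations <- function(params, doses, occasion_dose_index,
                                  residual_cv = 0, seed = NULL) {
  doses <- .check_doses(doses)
  if (length(occasion_dose_index) != 1L ||
      !occasion_dose_index %in% seq_len(nrow(doses)))
    stop("occasion_dose_index does not identify an existing dose",
         call. = FALSE)
  if (residual_cv < 0) stop("residual_cv must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_start <- doses$start_time[occasion_dose_index]
  conc <- concentration_at(params, doses, c(t_start, t_start + 2))
  if (residual_cv > 0) {
    sdlog <- sqrt(log(1 + residual_cv^2))
    conc <- conc * stats::rlnorm(2, meanlog = 0, sdlog = sdlog)
  }
  c(c0h = conc[1], c2h = conc[2])
}
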