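# Dose-titration protocol: arm-specific initial regimens, sampling at the
# 2nd and 7th administrations, +/-25 mg maintenance-dose steps toward the
# 50-100 mg.h/L window, rechecks four doses after each adjustment, and the
# 50-200 mg/day dose-bound stopping rule.

#' Initial regimen by randomization arm
#'
#' HD (high initial dose): 150 mg loading, 75 mg q12h maintenance.
#' LD (low initial dose): 100 mg loading, 50 mg q12h maintenance.
#'
#' @param arm `"HD"` or `"LD"`.
#' @param infusion_duration Infusion duration (h); the protocol does not
#'   state one, default 1 h.
#' @return A [regimen()].
#' @export
initial_regimen <- function(arm, infusion_duration = 1) {
  arm <- match.arg(arm, c("HD", "LD"))
  if (arm == "HD") regimen(150, 75, 12, infusion_duration)
  else regimen(100, 50, 12, infusion_duration)
}

#' Titration protocol settings
#'
#' @param max_adjustments Cap on dose adjustments per course (default 2:
#'   in practice a minority of patients underwent a second adjustment).
#' @param residual_cv Residual coefficient of variation of measured
#'   concentrations (default 0.15).
#' @param dropout_hazard Daily hazard of leaving the study (death,
#'   discharge, transfer) before titration completes; default 0.05/day.
#' @param recheck_prob Probability that a scheduled recheck is actually
#'   performed (default 0.32, the fraction observed in practice).
#' @param adjust_at_second_dose If `TRUE` the second-dose sample may also
#'   trigger adjustment; the protocol decides on the 7th-dose
#'   (steady-state) result only, so the default is `FALSE`.
#' @param daily_dose_bounds Permissible daily-dose range (mg), closed
#'   interval; adjustments that would leave it are not applied.
#' @param window Therapeutic window (mg·h/L).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(max_adjustments = 2,
                            residual_cv = 0.15,
                            dropout_hazard = 0.05,
                            recheck_prob = 0.32,
                            adjust_at_second_dose = FALSE,
                            daily_dose_bounds = c(50, 200),
                            window = c(50, 100)) {
  stopifnot(max_adjustments >= 0, residual_cv >= 0, dropout_hazard >= 0,
            recheck_prob >= 0, recheck_prob <= 1,
            length(daily_dose_bounds) == 2L,
            daily_dose_bounds[1] < daily_dose_bounds[2])
  structure(list(max_adjustments = max_adjustments,
                 residual_cv = residual_cv,
                 dropout_hazard = dropout_hazard,
                 recheck_prob = recheck_prob,
                 adjust_at_second_dose = adjust_at_second_dose,
                 daily_dose_bounds = daily_dose_bounds,
                 window = window),
            class = "protocol_config")
}

#' Titration state
#'
#' Mutable protocol state for one patient: current maintenance dose,
#' status (`titrating`, `on_target`, `stopped_dose_bounds`, `off_study`)
#' and an append-only adjustment history.
#'
#' @param arm `"HD"` or `"LD"`.
#' @param config A [protocol_config()].
#' @return An object of class `titration_state`.
#' @export
titration_state <- function(arm, config = protocol_config()) {
  arm <- match.arg(arm, c("HD", "LD"))
  reg <- initial_regimen(arm)
  structure(list(arm = arm,
                 current_maintenance = reg$maintenance_dose,
                 next_sampling_occasion = 7L,
                 adjustments_made = 0L,
                 status = "titrating",
                 config = config,
                 history = list()),
            class = "titration_state")
}

#' @export
print.titration_state <- function(x, ...) {
  cat(sprintf("Titration state [%s]: %s, maintenance %g mg q12h (%d adjustment%s)\n",
              x$arm, x$status, x$current_maintenance, x$adjustments_made,
              if (x$adjustments_made == 1L) "" else "s"))
  invisible(x)
}

#' Apply one titration decision
#'
#' Given the latest ssAUC estimate: within the window leaves the dose
#' unchanged and sets status `on_target`; below adds 25 mg to the
#' maintenance dose; above subtracts 25 mg.  If the adjusted daily dose
#' (2 x maintenance) would leave the closed 50-200 mg interval the
#' adjustment is not applied and status becomes `stopped_dose_bounds`;
#' otherwise a recheck is scheduled four administrations after the
#' adjustment.  Invalid (non-positive) estimates count as below target.
#'
#' @param state A [titration_state()] with status `titrating`.
#' @param estimate One row of [estimate_auc()] output (or a list with
#'   elements `value`, `category`, `valid`).
#' @param step Dose step size (mg), default 25.
#' @return The updated `titration_state`.
#' @export
adjust_dose <- function(state, estimate, step = 25) {
  stopifnot(inherits(state, "titration_state"))
  if (state$status != "titrating")
    stop("adjust_dose() called on terminal state: ", state$status,
         call. = FALSE)
  category <- as.character(estimate$category)
  if (!isTRUE(estimate$valid) && category != "above") category <- "below"
  occ <- if (!is.null(estimate$occasion)) estimate$occasion else NA
  bounds <- state$config$daily_dose_bounds
  if (category == "within") {
    state$status <- "on_target"
    action <- "none"
    state$next_sampling_occasion <- NA_integer_
  } else {
    delta <- if (category == "below") step else -step
    proposed <- state$current_maintenance + delta
    if (2 * proposed < bounds[1] || 2 * proposed > bounds[2]) {
      state$status <- "stopped_dose_bounds"
      action <- "stop"
      state$next_sampling_occasion <- NA_integer_
    } else {
      state$current_maintenance <- proposed
      state$adjustments_made <- state$adjustments_made + 1L
      action <- if (delta > 0) "+25" else "-25"
    }
  }
  state$history <- c(state$history,
                     list(list(occasion = occ, value = estimate$value,
                               category = category, action = action,
                               maintenance = state$current_maintenance,
                               status = state$status)))
  state
}

#' Simulate a complete TDM-guided course for one patient
#'
#' Runs the dosing/sampling/adjustment cycle: loading dose at time 0,
#' maintenance q12h; informational sample at the 2nd dose; decision sample
#' at the 7th dose (steady state, day 4); then [adjust_dose()]/recheck
#' cycles (recheck four administrations after each adjustment) until the
#' state is terminal, the adjustment cap is reached, a scheduled recheck
#' is skipped, or the patient leaves the study (exponential dropout).
#' The whole trajectory is reproducible given `seed`.
#'
#' @param pk A [pk_parameters()] object (the patient's individual
#'   parameters).
#' @param arm `"HD"` or `"LD"`.
#' @param config A [protocol_config()].
#' @param seed Optional integer seed.
#' @param n_doses_horizon Number of administrations simulated (default 24,
#'   i.e. 12 days, ample for two adjustment/recheck cycles).
#'
#' @return A list with elements
#'   \describe{
#'     \item{state}{final [titration_state()]}
#'     \item{log}{`data.frame`: one row per sampling occasion with
#'       `occasion`, `c0h`, `c2h`, `auc_estimate`, `category`, `action`,
#'       `resulting_maintenance_mg`, `status`}
#'     \item{doses}{the administered dosing history ([dose_events()])}
#'     \item{true_ssauc7}{true model AUC over the 24 h following the 7th
#'       dose start under the regimen in effect at that dose (`NA` if the
#'       patient left before day 4)}
#'     \item{final_estimate}{last available ssAUC estimate, carried
#'       forward (`NA` if never sampled at steady state)}
#'     \item{final_category}{window category of `final_estimate`}
#'   }
#' @export
run_tdm_course <- function(pk, arm, config = protocol_config(), seed = NULL,
                           n_doses_horizon = 24) {
  if (!is.null(seed)) set.seed(seed)
  arm <- match.arg(arm, c("HD", "LD"))
  stopifnot(inherits(config, "protocol_config"))
  reg <- initial_regimen(arm)
  interval <- reg$dosing_interval
  tinf <- reg$infusion_duration
  # administered maintenance for doses 2..horizon; updated as titration acts
  maint <- rep(reg$maintenance_dose, n_doses_horizon)
  amounts <- c(reg$loading_dose, maint[-1])
  starts <- interval * (seq_len(n_doses_horizon) - 1)
  t_off <- if (config$dropout_hazard > 0)
    stats::rexp(1, config$dropout_hazard) * 24 else Inf

  state <- titration_state(arm, config)
  log_rows <- list()
  true_ssauc7 <- NA_real_
  final_estimate <- NA_real_

  sample_occ <- function(idx) {
    d <- dose_events(starts[seq_len(idx)], amounts[seq_len(idx)], tinf)
    sample_concentrations(pk, d, idx, config$residual_cv)
  }
  add_log <- function(occ, cc, est, action) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      occasion = occ, c0h = cc[["c0h"]], c2h = cc[["c2h"]],
      auc_estimate = est$value, category = as.character(est$category),
      action = action, resulting_maintenance_mg = state$current_maintenance,
      status = state$status)
  }

  # --- informational sample at dose 2 (t = 12 h)
  if (t_off > starts[2]) {
    cc <- sample_occ(2L)
    est <- estimate_auc(cc[["c0h"]], cc[["c2h"]], occasion = 2L,
                        window = config$window)
    if (config$adjust_at_second_dose && est$category != "within") {
      state <- adjust_dose(state, est)
      if (state$status == "titrating" || state$status == "on_target") {
        i <- 3:n_doses_horizon
        amounts[i] <- state$current_maintenance
      }
      add_log(2L, cc, est, state$history[[length(state$history)]]$action)
    } else add_log(2L, cc, est, "none")
  } else {
    state$status <- "off_study"
  }

  # --- decision sample at dose 7 and subsequent recheck cycles
  occ <- 7L
  while (state$status == "titrating") {
    if (occ > n_doses_horizon || t_off <= starts[occ]) {
      state$status <- "off_study"
      break
    }
    cc <- sample_occ(occ)
    est <- estimate_auc(cc[["c0h"]], cc[["c2h"]], occasion = occ,
                        window = config$window)
    if (occ == 7L) {
      d7 <- dose_events(starts, ifelse(seq_along(amounts) <= 7,
                                       amounts, amounts[7]), tinf)
      true_ssauc7 <- true_auc_window(pk, d7, starts[7], starts[7] + 24)
    }
    final_estimate <- est$value
    if (state$adjustments_made >= config$max_adjustments &&
        est$category != "within") {
      add_log(occ, cc, est, "none")
      state$status <- "stopped_max_adjustments"
      break
    }
    before <- state$adjustments_made
    state <- adjust_dose(state, est)
    add_log(occ, cc, est, state$history[[length(state$history)]]$action)
    if (state$adjustments_made > before) {
      # new maintenance takes effect at the next scheduled dose
      if (occ < n_doses_horizon) {
        i <- (occ + 1L):n_doses_horizon
        amounts[i] <- state$current_maintenance
      }
      if (stats::runif(1) > config$recheck_prob) {
        state$status <- "not_rechecked"
        break
      }
      occ <- occ + 4L  # recheck after four administrations
    }
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(occasion = integer(), c0h = numeric(), c2h = numeric(),
               auc_estimate = numeric(), category = character(),
               action = character(), resulting_maintenance_mg = numeric(),
               status = character())
  n_admin <- if (is.finite(t_off))
    max(1L, min(n_doses_horizon, sum(starts < t_off))) else n_doses_horizon
  list(state = state,
       log = log,
       doses = dose_events(starts[seq_len(n_admin)],
                           amounts[seq_len(n_admin)], tinf),
       true_ssauc7 = true_ssauc7,
       final_estimate = final_estimate,
       final_category = if (is.na(final_estimate)) NA_character_ else
         as.character(classify_auc(final_estimate, config$window)))
}
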