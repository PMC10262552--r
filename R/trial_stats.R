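# Randomized-trial statistics: 2x2 effect estimates with the interval
# methods used for the printed tables (log-Wald for relative risk, Wald
# and Newcombe hybrid Wilson-score for risk differences), Pearson
# chi-square without continuity correction, exact tests, Kaplan-Meier /
# log-rank / Cox machinery, and two-proportion sample size and power.

#' A 2x2 events table
#'
#' @param events_a,n_a Events and sample size in arm A.
#' @param events_b,n_b Events and sample size in arm B.
#' @return An object of class `two_by_two`.
#' @export
#' @examples
#' two_by_two(95, 152, 95, 159)
two_by_two <- function(events_a, n_a, events_b, n_b) {
  v <- c(events_a, n_a, events_b, n_b)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_a <= 0 || n_b <= 0 || events_a > n_a || events_b > n_b)
    stop("events must satisfy 0 <= events <= n with n > 0", call. = FALSE)
  structure(list(events_a = events_a, n_a = n_a,
                 events_b = events_b, n_b = n_b),
            class = "two_by_two")
}

.effect <- function(measure, point, ci_low, ci_high, method, alpha) {
  structure(list(measure = measure, point = point, ci_low = ci_low,
                 ci_high = ci_high, method = method, alpha = alpha),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s %.3f (%g%% CI %.3f, %.3f) [%s]\n", x$measure, x$point,
              100 * (1 - x$alpha), x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Relative risk with a log-Wald interval
#'
#' Point estimate `(a/n_a) / (b/n_b)` with the asymptotic interval
#' `exp(log RR +/- z * sqrt(1/a - 1/n_a + 1/b - 1/n_b))`.  A zero cell
#' leaves the interval `NA` (flagged, not an error); a zero denominator
#' proportion is an error.
#'
#' @param t A [two_by_two()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return An `effect_estimate`.
#' @export
#' @examples
#' relative_risk(two_by_two(95, 152, 95, 159))   # 1.046 (0.876, 1.249)
relative_risk <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$events_b == 0)
    stop("relative risk undefined: no events in the reference arm",
         call. = FALSE)
  point <- (t$events_a / t$n_a) / (t$events_b / t$n_b)
  if (t$events_a == 0) {
    lo <- hi <- NA_real_
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    se <- sqrt(1 / t$events_a - 1 / t$n_a + 1 / t$events_b - 1 / t$n_b)
    lo <- exp(log(point) - z * se)
    hi <- exp(log(point) + z * se)
  }
  .effect("RR", point, lo, hi, "wald_log", alpha)
}

#' Risk difference with a Wald interval
#'
#' `p_a - p_b` with the plain asymptotic interval
#' `d +/- z * sqrt(p_a q_a / n_a + p_b q_b / n_b)` (proportions scale;
#' multiply by 100 for percentage points).
#'
#' @inheritParams relative_risk
#' @return An `effect_estimate`.
#' @export
risk_difference_wald <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  pa <- t$events_a / t$n_a
  pb <- t$events_b / t$n_b
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(pa * (1 - pa) / t$n_a + pb * (1 - pb) / t$n_b)
  .effect("RD", pa - pb, pa - pb - z * se, pa - pb + z * se, "wald", alpha)
}

# Wilson score limits for one proportion.
.wilson <- function(x, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c((centre - half) / den, (centre + half) / den)
}

#' Risk difference with the Newcombe hybrid Wilson-score interval
#'
#' `d = p_a - p_b` with bounds built from the per-arm Wilson score limits
#' `(l, u)`:
#' `lower = d - sqrt((p_a - l_a)^2 + (u_b - p_b)^2)`,
#' `upper = d + sqrt((u_a - p_a)^2 + (p_b - l_b)^2)`.
#' Bounds are always within `[-1, 1]`.
#'
#' @inheritParams relative_risk
#' @return An `effect_estimate`.
#' @export
#' @examples
#' risk_difference_newcombe(two_by_two(81, 127, 51, 131))
risk_difference_newcombe <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  pa <- t$events_a / t$n_a
  pb <- t$events_b / t$n_b
  wa <- .wilson(t$events_a, t$n_a, alpha)
  wb <- .wilson(t$events_b, t$n_b, alpha)
  d <- pa - pb
  .effect("RD", d,
          d - sqrt((pa - wa[1])^2 + (wb[2] - pb)^2),
          d + sqrt((wa[2] - pa)^2 + (pb - wb[1])^2),
          "newcombe_hybrid", alpha)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction:
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to the
#' 1-df chi-square distribution.
#'
#' @inheritParams relative_risk
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_test <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$events_a; b <- t$n_a - t$events_a
  c_ <- t$events_b; d <- t$n_b - t$events_b
  n <- t$n_a + t$n_b
  m1 <- a + c_; m0 <- b + d
  if (m1 == 0 || m0 == 0)
    stop("degenerate table: an event margin is zero", call. = FALSE)
  stat <- n * (a * d - b * c_)^2 / (t$n_a * t$n_b * m1 * m0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @inheritParams relative_risk
#' @return The two-sided exact hypergeometric p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$events_a, t$n_a - t$events_a,
                t$events_b, t$n_b - t$events_b), 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

.check_survival <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time", "event", "arm") %in% names(data)))
  if (nrow(data) == 0L) stop("empty survival data", call. = FALSE)
  if (any(data$time <= 0)) stop("times must be positive", call. = FALSE)
  data
}

#' Kaplan-Meier survival estimate per arm
#'
#' Product-limit estimator (right-continuous, starting at 1) computed per
#' arm via \pkg{survival}.
#'
#' @param data `data.frame` with columns `time` (> 0), `event` (logical
#'   or 0/1; FALSE = censored) and `arm`.
#' @return A `data.frame` with columns `arm`, `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
km_estimate <- function(data) {
  data <- .check_survival(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = data)
  if (is.null(fit$strata)) {
    arm <- rep(as.character(data$arm[1]), length(fit$time))
  } else {
    arm <- rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  }
  data.frame(arm = arm, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}

#' Log-rank test and Cox hazard ratio between two arms
#'
#' `logrank_test()` is the standard 1-df log-rank chi-square;
#' `cox_hr()` estimates the hazard ratio of the second arm level relative
#' to the first (reference) level from the Cox partial likelihood with
#' Efron tie handling.
#'
#' @inheritParams km_estimate
#' @param alpha Two-sided level for the Cox interval.
#' @return `logrank_test()`: list with `statistic` and `p_value`.
#'   `cox_hr()`: an `effect_estimate` with `measure = "HR"`.
#' @export
logrank_test <- function(data) {
  data <- .check_survival(data)
  if (length(unique(data$arm)) != 2L)
    stop("log-rank test requires exactly two arms", call. = FALSE)
  if (sum(data$event) < 1) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = data)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' @rdname logrank_test
#' @export
cox_hr <- function(data, alpha = 0.05) {
  data <- .check_survival(data)
  if (length(unique(data$arm)) != 2L)
    stop("Cox hazard ratio requires exactly two arms", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = data,
                         ties = "efron")
  z <- stats::qnorm(1 - alpha / 2)
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  .effect("HR", exp(beta), exp(beta - z * se), exp(beta + z * se),
          "cox", alpha)
}

#' Sample size for two proportions (normal approximation)
#'
#' Closed-form per-arm size for detecting treatment rate
#' `control_rate * rr` against `control_rate` with a two-sided
#' alpha-level test:
#' `n_b = (z_{a/2} sqrt((1 + 1/r) pbar qbar) +
#'         z_beta sqrt(p1 q1 / r + p2 q2))^2 / (p1 - p2)^2`
#' with `r = allocation_ratio = n_a / n_b` and `pbar` the
#' allocation-weighted mean rate; per-arm sizes are rounded up.
#'
#' @param control_rate Event rate in the control arm, in (0, 1).
#' @param rr Relative risk to detect (> 0); `control_rate * rr` must stay
#'   below 1.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param allocation_ratio Treatment-to-control allocation `n_a / n_b`.
#' @return List with `n_a`, `n_b`, `total`.
#' @export
#' @examples
#' sample_size_two_proportions(0.58, 1.26)$total   # ~310
sample_size_two_proportions <- function(control_rate, rr, alpha = 0.05,
                                        power = 0.80,
                                        allocation_ratio = 1) {
  p2 <- control_rate
  p1 <- control_rate * rr
  if (p2 <= 0 || p2 >= 1) stop("control_rate must be in (0,1)", call. = FALSE)
  if (p1 >= 1) stop("treatment rate control_rate * rr must be < 1",
                    call. = FALSE)
  r <- allocation_ratio
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (r * p1 + p2) / (r + 1)
  qbar <- 1 - pbar
  n_b <- (za * sqrt((1 + 1 / r) * pbar * qbar) +
            zb * sqrt(p1 * (1 - p1) / r + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_b <- ceiling(n_b)
  n_a <- ceiling(r * n_b)
  list(n_a = n_a, n_b = n_b, total = n_a + n_b)
}

#' Power of the two-proportion chi-square test
#'
#' `empirical_power()` estimates power by Monte Carlo: the fraction of
#' simulated trials in which [chi_square_test()] rejects at `alpha`
#' (seed-deterministic).  `exact_power_two_proportions()` computes the
#' same rejection probability exactly by enumerating the joint binomial
#' distribution of the two arms; it serves as the deterministic oracle
#' for the Monte Carlo estimate.
#'
#' @param n_a,n_b Arm sizes.
#' @param rate_a,rate_b True event rates.
#' @param alpha Two-sided significance level.
#' @param replications Number of simulated trials (>= 1000).
#' @param seed Optional integer seed.
#' @return Proportion of rejections.
#' @export
empirical_power <- function(n_a, n_b, rate_a, rate_b, alpha = 0.05,
                            replications = 10000, seed = NULL) {
  if (replications < 1000)
    stop("use at least 1000 replications", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rbinom(replications, n_a, rate_a)
  b <- stats::rbinom(replications, n_b, rate_b)
  mean(.chisq_p_vec(a, n_a, b, n_b) < alpha)
}

# vectorized Pearson chi-square p over many 2x2 tables; degenerate
# margins count as p = 1 (never reject)
.chisq_p_vec <- function(a, n_a, b, n_b) {
  n <- n_a + n_b
  m1 <- a + b
  m0 <- n - m1
  stat <- ifelse(m1 == 0 | m0 == 0, 0,
                 n * (a * (n_b - b) - (n_a - a) * b)^2 /
                   (n_a * n_b * m1 * m0))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @rdname empirical_power
#' @export
exact_power_two_proportions <- function(n_a, n_b, rate_a, rate_b,
                                        alpha = 0.05) {
  a <- matrix(0:n_a, n_a + 1, n_b + 1)
  b <- matrix(0:n_b, n_a + 1, n_b + 1, byrow = TRUE)
  p <- .chisq_p_vec(a, n_a, b, n_b)
  w <- outer(stats::dbinom(0:n_a, n_a, rate_a),
             stats::dbinom(0:n_b, n_b, rate_b))
  sum(w[p < alpha])
}
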