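# Effect estimates, interval methods, tests, survival machinery and
# power, against printed values and hand-computed oracles.

test_that("two_by_two validates its counts", {
  expect_error(two_by_two(-1, 10, 2, 10), "non-negative")
  expect_error(two_by_two(11, 10, 2, 10), "0 <= events")
  expect_error(two_by_two(1, 0, 2, 10), "0 <= events")
})

test_that("relative risk reproduces printed points and intervals", {
  rr <- relative_risk(two_by_two(95, 152, 95, 159))
  expect_equal(round(rr$point, 3), 1.046)
  expect_equal(round(rr$ci_low, 3), 0.876)
  expect_equal(round(rr$ci_high, 3), 1.249)
  rr2 <- relative_risk(two_by_two(15, 127, 4, 131))
  expect_equal(round(rr2$point, 3), 3.868)
  expect_equal(round(rr2$ci_low, 3), 1.319)
  expect_equal(rr2$ci_high, 11.340, tolerance = 2e-4)
  # equal proportions
  expect_equal(relative_risk(two_by_two(30, 100, 30, 100))$point, 1)
  expect_error(relative_risk(two_by_two(5, 10, 0, 10)), "undefined")
})

test_that("RR antisymmetry is exact", {
  set.seed(1)
  for (i in 1:20) {
    na <- sample(20:200, 1); nb <- sample(20:200, 1)
    a <- sample(seq_len(na - 1), 1); b <- sample(seq_len(nb - 1), 1)
    f <- relative_risk(two_by_two(a, na, b, nb))
    r <- relative_risk(two_by_two(b, nb, a, na))
    expect_equal(f$point * r$point, 1)
    # CI bounds swap and invert
    expect_equal(f$ci_low, 1 / r$ci_high)
  }
})

test_that("Wald risk difference reproduces the primary-outcome row", {
  rd <- risk_difference_wald(two_by_two(95, 152, 95, 159))
  expect_equal(round(100 * rd$point, 2), 2.75)
  expect_equal(round(100 * rd$ci_low, 2), -8.08)
  expect_equal(round(100 * rd$ci_high, 2), 13.58)
  same <- risk_difference_wald(two_by_two(40, 100, 40, 100))
  expect_equal(same$point, 0)
  expect_equal(same$ci_low, -same$ci_high)
})

test_that("Newcombe hybrid interval reproduces the attainment row", {
  rd <- risk_difference_newcombe(two_by_two(81, 127, 51, 131))
  expect_equal(round(100 * rd$point, 2), 24.85)
  expect_equal(round(100 * rd$ci_high, 2), 35.99)
  # printed 12.68; the recomputation is accepted within 0.02 points
  expect_equal(100 * rd$ci_low, 12.68, tolerance = 0.02 / 12.68)
  # degenerate all-events arms stay inside [-1, 1]
  deg <- risk_difference_newcombe(two_by_two(10, 10, 0, 10))
  expect_true(deg$ci_low >= -1 && deg$ci_high <= 1)
  # antisymmetry: bounds swap and negate
  f <- risk_difference_newcombe(two_by_two(30, 80, 50, 90))
  r <- risk_difference_newcombe(two_by_two(50, 90, 30, 80))
  expect_equal(f$point, -r$point)
  expect_equal(f$ci_low, -r$ci_high)
  expect_equal(f$ci_high, -r$ci_low)
})

test_that("chi-square matches the hand formula and printed p", {
  t <- two_by_two(82, 127, 62, 131)
  # n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) by hand
  a <- 82; b <- 45; c_ <- 62; d <- 69; n <- 258
  hand <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  res <- chi_square_test(t)
  expect_equal(res$statistic, hand)
  expect_equal(round(res$p_value, 3), 0.005)
  # balanced table
  bal <- chi_square_test(two_by_two(25, 50, 25, 50))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  # invariance to swapping arms and event labels
  expect_equal(chi_square_test(two_by_two(62, 131, 82, 127))$statistic,
               res$statistic)
  expect_equal(chi_square_test(two_by_two(45, 127, 69, 131))$statistic,
               res$statistic)
  expect_error(chi_square_test(two_by_two(0, 10, 0, 12)), "degenerate")
})

test_that("Fisher exact agrees with brute-force enumeration", {
  expect_equal(fisher_exact(two_by_two(10, 20, 10, 20)), 1)
  # enumerate all tables with both margins fixed at 10
  t <- two_by_two(0, 10, 10, 10)
  p0 <- dhyper(0, 10, 10, 10)
  brute <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                          p0 * (1 + 1e-7)])
  expect_equal(fisher_exact(t), brute, tolerance = 1e-10)
  # asymptotic agreement with chi-square on a large balanced table
  big <- two_by_two(5100, 10000, 4900, 10000)
  expect_equal(fisher_exact(big), chi_square_test(big)$p_value,
               tolerance = 0.1)
})

test_that("Kaplan-Meier matches hand computation", {
  # no censoring: 1 - ecdf
  d <- data.frame(time = c(2, 4, 6, 8), event = TRUE, arm = "A")
  km <- km_estimate(d)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # single subject
  km1 <- km_estimate(data.frame(time = 5, event = TRUE, arm = "A"))
  expect_equal(km1$survival, 0)
  # interleaved censoring, product-limit by hand:
  # events at 1, 3, 5, 6; censored at 2, 4
  d2 <- data.frame(time = 1:6,
                   event = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
                   arm = "A")
  km2 <- km_estimate(d2)
  s <- km2$survival[km2$n_event == 1]
  expect_equal(s, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0))
  expect_error(km_estimate(data.frame(time = 0, event = TRUE, arm = "A")),
               "positive")
})

test_that("log-rank matches an 8-subject hand computation", {
  dup <- data.frame(time = rep(c(3, 5, 8), 2), event = TRUE,
                    arm = rep(c("A", "B"), each = 3))
  expect_equal(logrank_test(dup)$statistic, 0, tolerance = 1e-12)
  # alternating distinct event times; O - E and V accumulated by hand:
  # E_A = 1/2 + 3/7 + 1/2 + 2/5 + 1/2 + 1/3 + 1/2 + 0, O_A = 4,
  # V   = 1/4 + 12/49 + 1/4 + 6/25 + 1/4 + 2/9 + 1/4 + 0
  d <- data.frame(time = 1:8, event = TRUE,
                  arm = rep(c("A", "B"), 4))
  hand <- (4 - (2 + 3 / 7 + 2 / 5 + 1 / 3))^2 /
    (1 + 12 / 49 + 6 / 25 + 2 / 9)
  expect_equal(logrank_test(d)$statistic, hand, tolerance = 1e-8)
  expect_error(logrank_test(data.frame(time = 1:3, event = TRUE,
                                       arm = "A")), "two arms")
})

test_that("Cox recovers a simulated rate ratio at n = 500", {
  set.seed(1)
  n <- 250
  d <- data.frame(time = c(rexp(n, 0.02), rexp(n, 0.04)),
                  event = TRUE,
                  arm = rep(c("HD", "LD"), each = n))
  d$event <- d$time < 180
  d$time <- pmin(d$time, 180)
  hr <- cox_hr(d)   # LD vs HD: true hazard ratio 2
  expect_true(hr$ci_low < 2 && 2 < hr$ci_high)
  expect_equal(hr$point, 2, tolerance = 0.25)
  expect_equal(hr$method, "cox")
})

test_that("closed-form sample size lands in the published band", {
  ss <- sample_size_two_proportions(0.58, 1.26, 0.05, 0.80)
  expect_true(ss$total >= 309 && ss$total <= 312)
  # monotone in power
  expect_gt(sample_size_two_proportions(0.58, 1.26, 0.05, 0.999)$total,
            ss$total)
  # the returned n really delivers the target power (exact enumeration)
  expect_gte(exact_power_two_proportions(ss$n_a, ss$n_b,
                                         0.58 * 1.26, 0.58), 0.80)
  expect_error(sample_size_two_proportions(0.9, 1.3), "< 1")
})

test_that("empirical power is calibrated and matches analytic power", {
  # type-I error under the null
  null_rate <- empirical_power(152, 159, 0.58, 0.58, replications = 10000,
                               seed = 1)
  expect_equal(null_rate, 0.05, tolerance = 0.015 / 0.05)
  # against the closed-form normal-approximation power
  p1 <- 0.7308; p2 <- 0.58
  se <- sqrt(p1 * (1 - p1) / 152 + p2 * (1 - p2) / 159)
  analytic <- pnorm((p1 - p2) / se - qnorm(0.975))
  mc <- empirical_power(152, 159, p1, p2, replications = 10000, seed = 1)
  expect_equal(mc, analytic, tolerance = 0.02 / analytic)
  # seed determinism
  expect_identical(mc, empirical_power(152, 159, p1, p2,
                                       replications = 10000, seed = 1))
})
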