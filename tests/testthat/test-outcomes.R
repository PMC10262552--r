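# Composite 14-day response and KDIGO staging classifiers.

course_row <- function(alive = TRUE, shock = FALSE, map = NA,
                       pressor = NA, pneumonia = FALSE, pf0 = NA,
                       pf14 = NA, bacteremia = FALSE, culture_pos = NA,
                       sofa0 = 8, sofa14 = 5) {
  data.frame(alive_day14 = alive, shock_at_baseline = shock,
             map_day14 = map, on_vasopressor_day14 = pressor,
             has_pneumonia = pneumonia, pf_baseline = pf0,
             pf_day14 = pf14, has_bacteremia = bacteremia,
             blood_culture_day14_positive = culture_pos,
             sofa_baseline = sofa0, sofa_day14 = sofa14)
}

test_that("sofa_improved applies the 30% rule inclusively", {
  expect_true(sofa_improved(10, 7))     # exactly 30%
  expect_false(sofa_improved(10, 8))    # 20%
  expect_true(sofa_improved(2, 2))      # baseline < 3, unchanged
  expect_false(sofa_improved(2, 3))     # baseline < 3, worsened
  expect_true(sofa_improved(3, 2))      # 33%
  expect_error(sofa_improved(-1, 0), ">= 0")
})

test_that("classify_response combines applicable criteria with AND", {
  expect_false(classify_response(course_row(alive = FALSE)))
  # only the SOFA criterion applies: 8 -> 5 is 37.5%
  expect_true(classify_response(course_row()))
  # pneumonia with worsened P/F fails despite improved SOFA
  expect_false(classify_response(
    course_row(pneumonia = TRUE, pf0 = 220, pf14 = 180)))
  expect_true(classify_response(
    course_row(pneumonia = TRUE, pf0 = 220, pf14 = 220)))
  # shock: MAP > 65 without vasopressors required
  expect_true(classify_response(
    course_row(shock = TRUE, map = 70, pressor = FALSE)))
  expect_false(classify_response(
    course_row(shock = TRUE, map = 60, pressor = FALSE)))
  expect_false(classify_response(
    course_row(shock = TRUE, map = 70, pressor = TRUE)))
  # bacteremia: day-14 culture must be negative
  expect_false(classify_response(
    course_row(bacteremia = TRUE, culture_pos = TRUE)))
  expect_true(classify_response(
    course_row(bacteremia = TRUE, culture_pos = FALSE)))
  # missing field for an applicable criterion is an error...
  expect_error(classify_response(course_row(shock = TRUE)), "map_day14")
  # ...but not for a dead patient (response is FALSE regardless)
  expect_false(classify_response(course_row(alive = FALSE, shock = TRUE)))
})

test_that("improving any single component never flips TRUE to FALSE", {
  set.seed(1)
  for (i in 1:50) {
    base <- course_row(alive = runif(1) < 0.8,
                       shock = runif(1) < 0.3,
                       map = sample(c(60, 70), 1),
                       pressor = runif(1) < 0.3,
                       pneumonia = runif(1) < 0.6,
                       pf0 = runif(1, 100, 300), pf14 = runif(1, 80, 400),
                       bacteremia = runif(1) < 0.3,
                       culture_pos = runif(1) < 0.3,
                       sofa0 = sample(0:12, 1), sofa14 = sample(0:12, 1))
    r0 <- classify_response(base)
    improved <- list(
      within(base, alive_day14 <- TRUE),
      within(base, map_day14 <- 80),
      within(base, on_vasopressor_day14 <- FALSE),
      within(base, pf_day14 <- pf_baseline + 50),
      within(base, blood_culture_day14_positive <- FALSE),
      within(base, sofa_day14 <- 0))
    for (b in improved) expect_true(classify_response(b) >= r0)
  }
})

test_that("kdigo_stage implements the creatinine criteria", {
  s <- function(days, scr) data.frame(day = days, scr = scr)
  expect_equal(kdigo_stage(s(c(0, 2, 5), c(80, 100, 128))), 1L)  # ratio 1.6
  expect_equal(kdigo_stage(s(c(0, 5), c(80, 200))), 2L)          # ratio 2.5
  expect_equal(kdigo_stage(s(c(0, 5), c(80, 250))), 3L)          # ratio 3.1
  expect_equal(kdigo_stage(s(c(0, 3), c(80, 90)), on_rrt = TRUE), 3L)
  expect_equal(kdigo_stage(s(c(0, 2), c(100, 130))), 1L)  # rise 30 in 48 h
  # the same absolute rise spread over > 48 h does not qualify
  expect_equal(kdigo_stage(s(c(0, 5), c(100, 130))), 0L)
  expect_equal(kdigo_stage(s(c(0, 4), c(300, 400))), 3L)  # peak >= 353.6
  expect_equal(kdigo_stage(s(0, 80)), 0L)
  expect_error(kdigo_stage(data.frame(day = numeric(), scr = numeric())),
               "non-empty")
  expect_error(kdigo_stage(s(c(1, 3), c(80, 90))), "day 0")
})

test_that("stage is non-decreasing in peak creatinine", {
  peaks <- seq(60, 400, by = 10)
  stages <- vapply(peaks, function(p)
    kdigo_stage(data.frame(day = c(0, 5), scr = c(80, p))), integer(1))
  expect_true(all(diff(stages) >= 0))
})
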