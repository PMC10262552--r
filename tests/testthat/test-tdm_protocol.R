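# Titration state machine: arm regimens, +/-25 mg steps, dose bounds,
# recheck scheduling and whole-course behaviour.

noise_free <- function(...) {
  protocol_config(residual_cv = 0, dropout_hazard = 0, recheck_prob = 1, ...)
}

test_that("initial regimens match the protocol arms", {
  hd <- initial_regimen("HD")
  expect_equal(c(hd$loading_dose, hd$maintenance_dose, hd$dosing_interval),
               c(150, 75, 12))
  ld <- initial_regimen("LD")
  expect_equal(c(ld$loading_dose, ld$maintenance_dose, ld$dosing_interval),
               c(100, 50, 12))
  expect_error(initial_regimen("X"))
})

test_that("adjust_dose applies the +/-25 rule with inclusive dose bounds", {
  est <- function(v) estimate_auc(0, (v / 2 + 0.673 - 6.084 * 0) / 6.230,
                                  occasion = 7)
  # within: unchanged, on target
  s <- adjust_dose(titration_state("HD"), est(80))
  expect_equal(s$status, "on_target")
  expect_equal(s$current_maintenance, 75)
  # below: +25 with a recheck scheduled
  s <- adjust_dose(titration_state("LD"), est(42))
  expect_equal(s$current_maintenance, 75)
  expect_equal(s$status, "titrating")
  expect_equal(s$adjustments_made, 1L)
  # LD titrated down to 25 q12h (daily 50, legal), then blocked at the
  # lower bound
  s <- adjust_dose(titration_state("LD"), est(120))
  expect_equal(s$current_maintenance, 25)
  s <- adjust_dose(s, est(120))
  expect_equal(s$status, "stopped_dose_bounds")
  expect_equal(s$current_maintenance, 25)   # adjustment not applied
  # upper bound: 100 q12h (daily 200) is legal, 125 is not
  s <- adjust_dose(titration_state("HD"), est(40))
  expect_equal(s$current_maintenance, 100)
  s <- adjust_dose(s, est(40))
  expect_equal(s$status, "stopped_dose_bounds")
  expect_equal(s$current_maintenance, 100)
  # invalid (non-positive) estimates count as below target
  s <- adjust_dose(titration_state("HD"), estimate_auc(0, 0))
  expect_equal(s$current_maintenance, 100)
  # terminal states refuse further adjustment
  s <- adjust_dose(titration_state("HD"), est(80))
  expect_error(adjust_dose(s, est(80)), "terminal")
})

test_that("an in-window patient stays at the initial dose", {
  pk <- test_pk(clearance = 2)   # true HD ssAUC ~ 150/2 = 75
  course <- run_tdm_course(pk, "HD", noise_free(), seed = 1)
  expect_equal(course$state$status, "on_target")
  expect_equal(course$state$adjustments_made, 0L)
  expect_equal(course$state$current_maintenance, 75)
  expect_equal(course$true_ssauc7, 75, tolerance = 0.01)
  expect_equal(course$final_category, "within")
})

test_that("a high-exposure HD patient is titrated down in one step", {
  pk <- test_pk(clearance = 150 / 110)   # true HD ssAUC ~ 110
  course <- run_tdm_course(pk, "HD", noise_free(), seed = 1)
  expect_equal(course$state$adjustments_made, 1L)
  expect_equal(course$state$current_maintenance, 50)
  expect_equal(course$state$status, "on_target")
  # linear PK: new ssAUC ~ 110 * 100/150 at the recheck
  recheck <- course$log[course$log$occasion == 11, ]
  expect_equal(recheck$auc_estimate, 110 * 100 / 150, tolerance = 0.1)
  expect_equal(recheck$category, "within")
})

test_that("dropout truncates the course", {
  pk <- test_pk()
  course <- run_tdm_course(pk, "HD",
                           protocol_config(residual_cv = 0,
                                           dropout_hazard = 50),
                           seed = 2)
  expect_equal(course$state$status, "off_study")
  expect_lt(nrow(course$log), 2)
})

test_that("courses respect dose bounds, terminate, and correct towards the window", {
  set.seed(1)
  statuses <- character(400)
  for (i in 1:400) {
    pk <- random_pk()
    arm <- sample(c("HD", "LD"), 1)
    course <- run_tdm_course(pk, arm,
                             protocol_config(recheck_prob = 1,
                                             dropout_hazard = 0.05))
    maint <- course$doses$amount[-1]
    if (length(maint))
      expect_true(all(2 * maint >= 50 & 2 * maint <= 200))
    statuses[i] <- course$state$status
  }
  expect_true(all(statuses != "titrating"))

  # monotone correction under noise-free linear PK: the final true ssAUC
  # is never farther from the window than the 7th-dose true ssAUC
  dist <- function(x) pmax(0, 50 - x, x - 100)
  for (cl in c(0.9, 1.2, 1.6, 2.4, 3.5, 5)) {
    for (arm in c("HD", "LD")) {
      pk <- test_pk(clearance = cl)
      course <- run_tdm_course(pk, arm, noise_free(), seed = 1)
      daily0 <- 2 * initial_regimen(arm)$maintenance_dose
      true_final <- course$true_ssauc7 *
        2 * course$state$current_maintenance / daily0
      expect_lte(dist(true_final), dist(course$true_ssauc7) + 1e-9)
      # and each accepted step moved strictly toward the window
      if (course$state$adjustments_made > 0 &&
          dist(course$true_ssauc7) > 0)
        expect_lt(dist(true_final), dist(course$true_ssauc7))
    }
  }
})

test_that("trial-scale attainment separates the arms by >= 15 points", {
  set.seed(42)
  co <- generate_cohort(311)
  arm <- rep(c("HD", "LD"), length.out = 311)
  within7 <- rep(NA, 311)
  for (i in 1:311) {
    pk <- pk_parameters(co$clearance[i], co$central_volume[i],
                        co$intercompartmental_clearance[i],
                        co$peripheral_volume[i],
                        crrt_clearance_multiplier = 1, scr_exponent = 0)
    course <- run_tdm_course(pk, arm[i], protocol_config())
    occ7 <- course$log[course$log$occasion == 7, ]
    if (nrow(occ7)) within7[i] <- occ7$category == "within"
  }
  p_hd <- mean(within7[arm == "HD"], na.rm = TRUE)
  p_ld <- mean(within7[arm == "LD"], na.rm = TRUE)
  expect_gt(p_hd, p_ld + 0.15)
})
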