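# The dosing equations, branch rule, floors, decay and effective dose.

cfg17 <- dose_config(target_count_rate_kcps = 1.7)

test_that("reference count rate reproduces hand-evaluated exponents", {
  p <- patient("a", "female", 61, 168.5, 73.5)
  expect_equal(reference_count_rate(p, eq1_coefficients()),
               exp(1.3499625), tolerance = 1e-12)
  expect_equal(reference_count_rate(p, eq1_coefficients()), 3.857281,
               tolerance = 1e-6)
  p2 <- patient("b", "female", 61, 165, 60)
  expect_equal(reference_count_rate(p2, eq2_coefficients()),
               exp(1.619), tolerance = 1e-12)
  # degenerate coefficient set: only a zero intercept -> exp(0) = 1 kcps
  zero <- equation_coefficients(0, 0, 0, 0, 0, 0)
  expect_equal(reference_count_rate(p, zero), 1.0)
})

test_that("raw equation doses match the independent oracle examples", {
  p <- patient("a", "female", 61, 168.5, 73.5)
  expect_equal(dose_eq1(p, cfg17), 264.6454, tolerance = 1e-6)
  expect_equal(dose_eq1(p, cfg17), oracle_dose1(73.5, 168.5, 0, 61, 1.7),
               tolerance = 1e-12)
  p2 <- patient("b", "female", 61, 165, 60)
  expect_equal(dose_eq2(p2, cfg17), 185.2204, tolerance = 1e-5)
  # target equal to the patient's own reference rate -> exactly the
  # reference activity in both equations
  crt1 <- reference_count_rate(p, eq1_coefficients())
  expect_equal(dose_eq1(p, cfg17, target_kcps = crt1), 550)
  crt2 <- reference_count_rate(p2, eq2_coefficients())
  expect_equal(dose_eq2(p2, cfg17, target_kcps = crt2), 550)
  # light patients at high targets: the offset equation goes negative
  light <- patient("c", "female", 25, 160, 45)
  expect_lt(dose_eq1(light, cfg17, target_kcps = 2.7), 0)
  # proportionality of the eq2 dose in the target rate
  expect_equal(dose_eq2(p2, cfg17, target_kcps = 3.4),
               2 * dose_eq2(p2, cfg17, target_kcps = 1.7))
})

test_that("plan_dose selects the branch by weight, inclusively at the threshold", {
  p <- patient("a", "female", 61, 168.5, 73.5)
  plan <- plan_dose(p, cfg17)
  expect_equal(plan$equation_used, "eq1")
  expect_equal(plan$planned_dose_MBq, 264.6454, tolerance = 1e-6)
  expect_false(plan$floor_applied)
  expect_false(plan$cap_applied)

  at <- plan_dose(patient("t", "male", 50, 175, 73.0), cfg17)
  expect_equal(at$equation_used, "eq1")
  below <- plan_dose(patient("u", "male", 50, 175, 72.999), cfg17)
  expect_equal(below$equation_used, "eq2")
})

test_that("minimum-dose floors raise low suggestions and are logged", {
  cfg10 <- dose_config(target_count_rate_kcps = 1.0)
  light <- patient("f", "female", 30, 160, 50)
  expect_equal(dose_eq2(light, cfg10), 87.2623, tolerance = 1e-5)
  expect_message(plan <- plan_dose(light, cfg10), "event=floor patient=f")
  expect_equal(plan$planned_dose_MBq, 100)
  expect_true(plan$floor_applied)
  # floored eq2 dose exceeds the raw one, so the predicted rate exceeds the
  # target -- the sign of the over-prediction
  expect_gt(plan$predicted_count_rate_kcps, 1.0)
  # the 150 MBq floor applies at 1.5 kcps and above
  expect_equal(floor_for_target(1.5, cfg10$floor_policy), 150)
  expect_equal(floor_for_target(1.49, cfg10$floor_policy), 100)
  # a policy that does not cover the target is a configuration error
  bad <- dose_config(target_count_rate_kcps = 1.7,
                     floor_policy = data.frame(crt_min = 2, floor_MBq = 150))
  expect_error(plan_dose(patient("x", "male", 40, 180, 90), bad),
               "no entry covering")
})

test_that("optional cap fires above the configured maximum and is logged", {
  cfgcap <- dose_config(target_count_rate_kcps = 2.7, max_dose_cap_MBq = 550,
                        weight_threshold_kg = 0)
  heavy <- patient("h", "male", 40, 170, 160)
  expect_gt(dose_eq1(heavy, cfgcap, 2.7), 550)
  expect_message(plan <- plan_dose(heavy, cfgcap), "event=cap patient=h")
  expect_equal(plan$planned_dose_MBq, 550)
  expect_true(plan$cap_applied)
  # without a cap the same patient exceeds the reference activity, logged
  cfgno <- dose_config(target_count_rate_kcps = 2.7, weight_threshold_kg = 0)
  expect_message(plan2 <- plan_dose(heavy, cfgno), "event=above_reference")
  expect_gt(plan2$planned_dose_MBq, 550)
})

test_that("missing anthropometrics fall back to the standard protocol", {
  wl <- data.frame(id = c("s1", "s2"), sex = c("male", "female"),
                   age_years = c(60, 55), height_cm = c(NA, 170),
                   weight_kg = c(80, 72))
  plans <- plan_dose(as_patients(wl, allow_missing = TRUE), cfg17)
  expect_equal(plans$equation_used, c("standard", "eq2"))
  expect_equal(plans$planned_dose_MBq[1], 550)
  expect_false(plans$floor_applied[1])
  # with no anthropometrics at all, no count rate can be predicted
  expect_true(is.na(plans$reference_count_rate_kcps[1]))
})

test_that("count-rate prediction inverts the planning algebra", {
  p <- patient("a", "female", 61, 168.5, 73.5)
  # at the reference activity both branches return the reference rate
  expect_equal(predicted_count_rate_at_dose(p, 550, "eq1", cfg17),
               3.857281, tolerance = 1e-6)
  p2 <- patient("b", "female", 61, 165, 60)
  expect_equal(predicted_count_rate_at_dose(p2, 550, "eq2", cfg17),
               reference_count_rate(p2, eq2_coefficients()))
  expect_error(predicted_count_rate_at_dose(p, -10, "eq1", cfg17),
               "strictly positive")
  # round trip over a randomized cohort: whenever no floor/cap fired the
  # planned activity maps back to the target exactly
  pats <- random_patients(400, seed = 11)
  plans <- suppressMessages(plan_dose(pats, cfg17))
  free <- !plans$floor_applied & !plans$cap_applied
  back <- predicted_count_rate_at_dose(pats[free, ],
                                       plans$planned_dose_MBq[free],
                                       plans$equation_used[free], cfg17)
  expect_equal(back, rep(1.7, sum(free)), tolerance = 1e-12)
  expect_equal(plans$predicted_count_rate_kcps[free], rep(1.7, sum(free)),
               tolerance = 1e-12)
})

test_that("decay adjustment follows Tc-99m physics with 5-min rounding", {
  expect_equal(decay_adjusted_dose(200, 0, cfg17), 200)
  # one half-life late, rounded from 360.4 to 360 min
  expect_equal(decay_adjusted_dose(200, 360.4, cfg17),
               200 * 2^(-360 / 360.4), tolerance = 1e-12)
  expect_equal(decay_adjusted_dose(200, 360.4, cfg17) / 200, 0.500385,
               tolerance = 1e-6)
  # half-away-from-zero ties, sign preserved
  expect_equal(decay_adjusted_dose(100, 2.5, cfg17),
               100 * 2^(-5 / 360.4))
  expect_equal(decay_adjusted_dose(100, -2.5, cfg17),
               100 * 2^(5 / 360.4))
  expect_equal(decay_adjusted_dose(100, 7.4, cfg17),
               100 * 2^(-5 / 360.4))
  # monotone decreasing in delay
  delays <- seq(-60, 60, by = 5)
  doses <- decay_adjusted_dose(300, delays, cfg17)
  expect_true(all(diff(doses) < 0))
  # with rounding disabled the adjustment composes additively
  cfg0 <- dose_config(target_count_rate_kcps = 1.7, time_rounding_min = 0)
  set.seed(3)
  t1 <- runif(50, -100, 100); t2 <- runif(50, -100, 100)
  expect_equal(
    decay_adjusted_dose(decay_adjusted_dose(250, t1, cfg0), t2, cfg0),
    decay_adjusted_dose(250, t1 + t2, cfg0), tolerance = 1e-12)
})

test_that("effective dose is a linear conversion with a guarded coefficient", {
  expect_equal(effective_dose(0, cfg17), 0)
  expect_equal(effective_dose(258, cfg17), 1.5996, tolerance = 1e-12)
  expect_equal(effective_dose(550, cfg17), 3.41, tolerance = 1e-12)
  expect_error(effective_dose(-5, cfg17), "non-negative")
  bad <- cfg17
  bad$effective_dose_coef_mSv_per_MBq <- -1
  expect_error(effective_dose(100, bad), "non-negative")
})

test_that("patient validation rejects rather than clamps", {
  expect_error(patient("x", "male", 60, 170, 0), "bounds|positive")
  expect_error(patient("x", "male", 60, 170, 300), "plausibility bounds")
  expect_error(patient("x", "male", 5, 170, 80), "plausibility bounds")
  expect_error(patient("x", "dog", 60, 170, 80), "unrecognised sex")
  expect_error(as_patients(data.frame(id = "x", sex = "m", age_years = 50,
                                      height_cm = NA, weight_kg = 80)),
               "missing height_cm")
  # bounds are configurable
  wide <- patient_bounds(age_years = c(0, 120), height_cm = c(40, 230),
                         weight_kg = c(2, 300))
  expect_silent(as_patients(data.frame(id = "baby", sex = "f", age_years = 1,
                                       height_cm = 70, weight_kg = 8), wide))
})

test_that("doses are monotone in target rate and weight; sex shifts by exp(0.06)", {
  pats <- random_patients(60, seed = 5)
  for (crt in c(1.0, 1.7)) {
    d1a <- dose_eq1(pats, cfg17, crt); d1b <- dose_eq1(pats, cfg17, crt + 0.2)
    d2a <- dose_eq2(pats, cfg17, crt); d2b <- dose_eq2(pats, cfg17, crt + 0.2)
    expect_true(all(d1b > d1a))
    expect_true(all(d2b > d2a))
    # eq1 is linear in the target with slope 1/0.00756 MBq per kcps
    expect_equal(d1b - d1a, rep(0.2 / 0.00756, nrow(pats)), tolerance = 1e-9)
  }
  # weight: heavier -> larger dose, all else fixed, across the bounds range
  w <- seq(30, 250, by = 5)
  grid <- as_patients(data.frame(id = paste0("w", w), sex = "female",
                                 age_years = 60, height_cm = 170,
                                 weight_kg = w))
  expect_true(all(diff(dose_eq1(grid, cfg17)) > 0))
  expect_true(all(diff(dose_eq2(grid, cfg17)) > 0))
  # switching coded sex multiplies the reference rate by exp(0.06)
  m <- patient("m", "male", 60, 175, 80)
  f <- patient("f", "female", 60, 175, 80)
  for (coefs in list(eq1_coefficients(), eq2_coefficients()))
    expect_equal(reference_count_rate(m, coefs) / reference_count_rate(f, coefs),
                 exp(0.06), tolerance = 1e-12)
})

test_that("all dose computations match the single-expression oracle to 1e-9", {
  pats <- random_patients(10000, seed = 42)
  g <- sex_code01(pats$sex)
  for (crt in c(1.0, 1.7, 2.7)) {
    rel1 <- abs(dose_eq1(pats, cfg17, crt) -
                  oracle_dose1(pats$weight_kg, pats$height_cm, g,
                               pats$age_years, crt)) /
      pmax(1, abs(oracle_dose1(pats$weight_kg, pats$height_cm, g,
                               pats$age_years, crt)))
    rel2 <- abs(dose_eq2(pats, cfg17, crt) -
                  oracle_dose2(pats$weight_kg, pats$height_cm, g,
                               pats$age_years, crt)) /
      oracle_dose2(pats$weight_kg, pats$height_cm, g, pats$age_years, crt)
    expect_lt(max(rel1), 1e-9)
    expect_lt(max(rel2), 1e-9)
  }
})
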