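# Estimation chain: the six parameter equations, the weight-status
# classifier, and the chained per-subject estimator.

test_that("bmi matches direct arithmetic and is scale invariant", {
  expect_equal(bmi(30, 1.25), 19.2)
  expect_equal(bmi(100, 2.0), 25.0)
  expect_error(bmi(30, 0), class = "pedibca_domain_error")
  ws <- withr::with_seed(2, runif(20, 10, 80))
  hs <- withr::with_seed(3, runif(20, 0.9, 1.8))
  expect_equal(bmi(4 * ws, 2 * hs), bmi(ws, hs), tolerance = 1e-12)
})

test_that("body-fat equation is evaluated exactly as published", {
  expect_equal(bf_percent(20, 10, 0), 17.4)
  expect_equal(bf_percent(20, 10, 1), 13.8)
  expect_equal(bf_percent(0, 0, 0), 1.4)
  # sex term is an exact -3.6 offset
  bmis <- withr::with_seed(4, runif(15, 12, 30))
  expect_equal(bf_percent(bmis, 9, 1), bf_percent(bmis, 9, 0) - 3.6,
               tolerance = 1e-12)
  expect_error(bf_percent(20, 10, 2), class = "pedibca_domain_error")
})

test_that("fat-free mass follows the impedance index and is monotone in Z", {
  expect_equal(ffm(100, 742, 10), 13.123)
  expect_equal(ffm(0, 742, 0), 1.613)
  expect_error(ffm(100, 0, 10), class = "pedibca_domain_error")
  zs <- seq(300, 900, by = 50)
  expect_true(all(diff(ffm(130, zs, 35)) < 0))
})

test_that("muscle mass follows its resistance relation and decreases with age", {
  expect_equal(mm(100, 401, 0, 0), 18.927)
  expect_equal(mm(100, 401, 1, 10), 19.217)
  expect_error(mm(100, 0, 0, 10), class = "pedibca_domain_error")
  ages <- 5:14
  expect_true(all(diff(mm(120, 500, 1, ages)) < 0))
})

test_that("total body water handles the optical-current log term", {
  expect_equal(tbw(10, 100, 30, 1.0), 48.26)
  expect_equal(tbw(10, 100, 30, 0.1), 50.898)
  expect_error(tbw(10, 100, 30, 0), class = "pedibca_domain_error")
  # strictly decreasing in the optical current
  ocs <- c(0.005, 0.01, 0.021, 0.05, 0.1)
  expect_true(all(diff(tbw(8, 125, 30, ocs)) < 0))
  # natural-log variant changes the value by the expected factor
  expect_equal(
    tbw(10, 100, 30, 0.1, log_base = "ln") - tbw(10, 100, 30, 1.0),
    2.638 * log(10),
    tolerance = 1e-12
  )
})

test_that("bone mass matches its closed form and warns when negative", {
  expect_equal(bm(50, 150, 20), 17.717)
  w <- 41.2; h <- 128.4
  expect_equal(bm(w, h, 0.328 * w + 0.339 * h - 29.533), 0)
  expect_warning(out <- bm(0, 0, 0), class = "pedibca_soft_warning")
  expect_equal(out, -29.533)
})

test_that("weight-status classification uses the CDC percentile cut points", {
  expect_identical(classify_weight_status(50), "healthy")
  expect_identical(classify_weight_status(96), "obese")
  expect_identical(classify_weight_status(4.9), "underweight")
  # upper class wins at the exact cut points
  expect_identical(
    classify_weight_status(c(0, 5, 84.999, 85, 94.999, 95, 100)),
    c("underweight", "healthy", "healthy", "overweight", "overweight",
      "obese", "obese")
  )
  expect_error(classify_weight_status(101), class = "pedibca_domain_error")
  expect_error(classify_weight_status(-1), class = "pedibca_domain_error")
})

test_that("estimate_all equals the composition of the individual equations", {
  calib <- ref_calibration()
  cases <- withr::with_seed(5, data.frame(
    age = runif(10, 6, 12), sex = sample(0:1, 10, replace = TRUE),
    h = runif(10, 110, 150), adc = runif(10, 2e5, 5e5),
    z = runif(10, 400, 800), res = runif(10, 400, 800),
    v = runif(10, 0.01, 0.4)
  ))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    prof <- subject_profile("X", cs$age, cs$sex, cs$h)
    frame <- list(adc_counts = cs$adc, z_ohm = cs$z,
                  resistance_ohm = cs$res, v_volts = cs$v)
    got <- suppressWarnings(estimate_all(prof, frame, calib))
    w <- adc_to_weight(cs$adc, calib)
    expect_equal(got$weight_kg, w)
    expect_equal(got$bmi, bmi(w, cs$h / 100))
    expect_equal(got$bf_pct, bf_percent(bmi(w, cs$h / 100), cs$age, cs$sex))
    expect_equal(got$ffm_kg, ffm(cs$h, cs$z, w))
    expect_equal(got$mm_kg, mm(cs$h, cs$res, cs$sex, cs$age))
    expect_equal(got$tbw_kg, tbw(cs$age, cs$h, w, optical_current(cs$v)))
    expect_equal(got$bm_kg, suppressWarnings(bm(w, cs$h, got$mm_kg)))
  }
})

test_that("estimate_all reports the failing stage and rejects bad profiles", {
  calib <- ref_calibration()
  prof <- obese_profile()
  err <- tryCatch(
    estimate_all(prof, list(weight_kg = 40, v_volts = 0.05), calib),
    error = identity
  )
  expect_s3_class(err, "pedibca_stage_error")
  expect_identical(err$stage, "ffm")
  expect_match(conditionMessage(err), "z_ohm")

  expect_error(subject_profile("X", 8, 2, 120),
               class = "pedibca_domain_error")
})

test_that("the chain round-trips a sensor frame built by inversion", {
  calib <- ref_calibration()
  prof <- obese_profile()
  x <- consistent_composition(prof)
  frame <- invert_to_sensors(x, prof, calib)
  y <- suppressWarnings(estimate_all(prof, frame, calib))
  expect_equal(unclass(y), unclass(x), tolerance = 1e-12)
})

test_that("estimate_table collects per-subject errors and keeps going", {
  calib <- ref_calibration()
  cohort <- small_cohort(n = 3, seed = 21)
  frames <- invert_cohort(cohort, calib)
  subjects <- cohort[, c("subject_id", "age_years", "sex_code",
                         "height_cm", "group_label")]
  # break one subject's impedance
  frames$z_ohm[2] <- NA
  res <- estimate_table(subjects, frames, calib)
  expect_equal(nrow(res$composition), nrow(subjects) - 1L)
  expect_equal(nrow(res$errors), 1L)
  expect_identical(res$errors$stage, "ffm")
  expect_identical(res$errors$subject_id, subjects$subject_id[2])

  expect_error(
    estimate_table(subjects[0, ], frames, calib),
    class = "pedibca_schema_error"
  )
})

test_that("body_composition flags out-of-range body fat without rejecting", {
  expect_warning(
    body_composition(40, 22, 105, 25, 18, 22, 1),
    class = "pedibca_soft_warning"
  )
  expect_error(
    body_composition(-1, 22, 30, 25, 18, 22, 1),
    class = "pedibca_domain_error"
  )
  expect_error(
    body_composition(40, Inf, 30, 25, 18, 22, 1),
    class = "pedibca_domain_error"
  )
})
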