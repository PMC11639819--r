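# Agreement statistics: accuracy metrics, percent differences,
# Bland-Altman, ICC, SEM and the group summary.

test_that("accuracy reproduces the published weight cells and is scale free", {
  expect_equal(round(accuracy(43.501, 42.746), 2), 98.23)
  expect_equal(round(accuracy(29.511, 30.473), 2), 96.84)
  expect_equal(accuracy(12.3, 12.3), 100)
  # invariant under common positive rescaling
  ps <- withr::with_seed(6, runif(20, 5, 50))
  ts <- withr::with_seed(7, runif(20, 5, 50))
  expect_equal(accuracy(3.7 * ps, 3.7 * ts), accuracy(ps, ts),
               tolerance = 1e-12)
  expect_error(accuracy(10, 0), class = "pedibca_domain_error")
})

make_pairs <- function(params, a_ob, b_ob, a_no, b_no) {
  data.frame(
    parameter = rep(params, 2),
    group = rep(c("obese", "normal"), each = length(params)),
    device_a = c(a_ob, a_no),
    device_b = c(b_ob, b_no),
    stringsAsFactors = FALSE
  )
}

test_that("mean accuracy and mean average error follow their definitions", {
  # identical devices
  same <- make_pairs(c("p1", "p2"), c(10, 20), c(10, 20), c(5, 8), c(5, 8))
  expect_equal(mean_accuracy(same), 100)
  expect_equal(mean_avg_error(same), 0)
  # single parameter with 10% difference in each group
  one <- make_pairs("p", 90, 100, 45, 50)
  expect_equal(mean_accuracy(one), 90)
  # single parameter with |diff| 1.0 in each group
  unit <- make_pairs("p", 9, 10, 21, 20)
  expect_equal(mean_avg_error(unit), 1.0)
})

test_that("mean accuracy collapses to 100 minus the mean row difference", {
  tbl <- withr::with_seed(9, make_pairs(
    paste0("p", 1:5),
    runif(5, 10, 40), runif(5, 10, 40),
    runif(5, 10, 40), runif(5, 10, 40)
  ))
  diff_pct <- 100 - accuracy(tbl$device_a, tbl$device_b)
  expect_equal(mean_accuracy(tbl), 100 - mean(diff_pct), tolerance = 1e-9)
})

test_that("paired tables must cover both groups consistently", {
  bad <- data.frame(
    parameter = c("p1", "p2", "p1"),
    group = c("obese", "obese", "normal"),
    device_a = 1:3, device_b = 4:6
  )
  expect_error(mean_accuracy(bad), class = "pedibca_contract_error")
  single_group <- data.frame(parameter = "p1", group = "obese",
                             device_a = 1, device_b = 2)
  expect_error(mean_avg_error(single_group),
               class = "pedibca_contract_error")
})

test_that("percent difference is symmetric and matches the published rows", {
  expect_equal(percent_difference(43.501, 29.511), 38.322, tolerance = 1e-4)
  expect_equal(percent_difference(27.473, 22.431), 20.206, tolerance = 1e-4)
  expect_equal(percent_difference(5, 5), 0)
  xs <- withr::with_seed(10, runif(20, 1, 50))
  ys <- withr::with_seed(11, runif(20, 1, 50))
  expect_equal(percent_difference(xs, ys), percent_difference(ys, xs))
  expect_error(percent_difference(1, -1), class = "pedibca_domain_error")
})

test_that("Bland-Altman bias and limits follow the 1.96-SD convention", {
  # constant offset: zero-width limits
  ba_const <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba_const$bias, 3)
  expect_equal(ba_const$loa_low, 3)
  expect_equal(ba_const$loa_high, 3)
  # identical devices
  ba_id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba_id$bias, 0)
  expect_equal(c(ba_id$loa_low, ba_id$loa_high), c(0, 0))
  # differences (1, 2, 3): SD is exactly 1
  ba <- bland_altman(c(1, 2, 3), c(0, 0, 0))
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_error(bland_altman(1, 1), class = "pedibca_insufficient_data")
})

test_that("ICC is exact on duplicated raters and near zero under the null", {
  dup <- cbind(c(1, 5, 9, 2, 7), c(1, 5, 9, 2, 7))
  expect_equal(icc(dup)$icc, 1)
  z <- withr::with_seed(1, cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(icc(z)$icc), 0.1)
  expect_error(icc(cbind(c(1, NA), c(2, 3))),
               class = "pedibca_contract_error")
  expect_error(icc(matrix(1:2, ncol = 1)),
               class = "pedibca_contract_error")
})

test_that("ICC mean squares agree with a two-way ANOVA oracle", {
  m <- withr::with_seed(7, {
    base <- rnorm(12, 10, 2)
    cbind(base, base + rnorm(12, 0.5, 0.8))
  })
  got <- icc(m)
  # independent oracle: stats::aov two-way decomposition
  df <- data.frame(
    y = c(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- anova(stats::aov(y ~ subj + rater, data = df))[["Mean Sq"]]
  n <- nrow(m); k <- ncol(m)
  oracle <- (ms[1] - ms[3]) /
    (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
  expect_equal(got$icc, oracle, tolerance = 1e-10)
  expect_equal(got$mean_squares$msr, ms[1], tolerance = 1e-10)
  expect_equal(got$mean_squares$msc, ms[2], tolerance = 1e-10)
  expect_equal(got$mean_squares$mse, ms[3], tolerance = 1e-10)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
})

test_that("absolute-agreement ICC is sensitive to a systematic rater shift", {
  m <- withr::with_seed(12, {
    base <- rnorm(200, 20, 3)
    cbind(base + rnorm(200, 0, 0.5), base + rnorm(200, 0, 0.5))
  })
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc(shifted)$icc, icc(m)$icc)
  # with equal rater means the agreement and consistency forms coincide
  # up to the small (k/n) column term
  centred <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(icc(centred, type = "agreement")$icc,
               icc(centred, type = "consistency")$icc,
               tolerance = 0.02)
})

test_that("SEM follows sd * sqrt(1 - ICC)", {
  expect_equal(sem_from_icc(3.7, 1.0), 0)
  expect_equal(sem_from_icc(1.0, 0.75), 0.5)
  expect_equal(sem_from_icc(2.0, 0.96), 0.4)
  expect_error(sem_from_icc(1, 1.2), class = "pedibca_domain_error")
})

test_that("group summaries reproduce published differences on exact means", {
  gs <- published_group_summary()
  two_of <- function(mean, sd = 0) c(mean, mean)  # both subjects at the mean
  records <- do.call(rbind, lapply(c("obese", "normal"), function(g) {
    data.frame(
      group_label = g,
      weight_kg = two_of(gs[gs$parameter == "weight_kg",
                            paste0(g, "_mean")]),
      bmi = two_of(gs[gs$parameter == "bmi", paste0(g, "_mean")]),
      ffm_kg = two_of(gs[gs$parameter == "ffm_kg", paste0(g, "_mean")])
    )
  }))
  out <- suppressWarnings(  # constant columns: correlations undefined
    summarize_groups(records, parameters = c("weight_kg", "bmi", "ffm_kg"))
  )
  sm <- out$summary
  expect_equal(sm$pct_diff[sm$parameter == "weight_kg"], 38.322,
               tolerance = 1e-4)
  expect_equal(sm$pct_diff[sm$parameter == "bmi"], 41.736,
               tolerance = 1e-4)
  # correlation matrices are symmetric with unit diagonal
  ch <- small_cohort(n = 15, seed = 31)
  out2 <- summarize_groups(ch, parameters = c("weight_kg", "ffm_kg",
                                              "tbw_kg", "mm_kg"))
  for (cm in out2$correlations) {
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  }
  one_group <- records[records$group_label == "obese", ]
  expect_error(summarize_groups(one_group), class = "pedibca_contract_error")
})

test_that("the agreement report bundles the validation statistics", {
  ch <- small_cohort(n = 20, seed = 41)
  dp <- simulate_device_pair(ch, device_pair_spec(0.3, 0.3, seed = 5))
  rep <- agreement_report(group_mean_pairs(dp), subject_pairs = dp)
  expect_s3_class(rep, "agreement_report")
  expect_true(all(rep$rows$accuracy <= 100))
  expect_length(rep$per_parameter, 7)
  for (pp in rep$per_parameter) {
    ba <- pp$bland_altman
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
    expect_true(pp$paired_p >= 0 && pp$paired_p <= 1)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(rep, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$mean_accuracy, rep$mean_accuracy)
  expect_equal(nrow(doc$rows), 14)
})
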