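# Validation pipeline: exclusions, model application, agreement statistics.

test_that("filter drops sutureless and length-free cases with messages", {
  cohort <- tiny_validation_cohort()
  expect_message(out <- filter_validation_cases(cohort), "sutureless")
  expect_equal(nrow(out), 4)
  expect_setequal(out$case_id, c("v1", "v2", "v3", "v4"))

  clean <- cohort[1:4, ]
  expect_identical(filter_validation_cases(clean), clean)

  all_sl <- cohort
  all_sl$sutureless_flag <- TRUE
  expect_error(suppressMessages(filter_validation_cases(all_sl)),
               "no usable cases")
})

test_that("apply_model fills scaling-law velocities and is linear in k", {
  cohort <- suppressMessages(filter_validation_cases(tiny_validation_cohort()))
  filled <- apply_model(cohort)
  expect_equal(round_printed(filled$calculated_velocity_m_s[1]), 1.547)
  doubled <- apply_model(cohort, k = 2 * default_k())
  expect_equal(doubled$calculated_velocity_m_s,
               2 * filled$calculated_velocity_m_s)

  bad <- cohort
  bad$circumference_mm[2] <- -1
  expect_error(apply_model(bad), "case v2")
})

test_that("agreement_stats matches the t.test oracle on random cohorts", {
  set.seed(123)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    calc <- runif(n, 1, 2)
    meas <- calc + rnorm(n, 0.05, 0.2)
    rep <- agreement_stats(calc, meas)
    tt <- t.test(calc, meas, paired = TRUE)
    expect_equal(rep$mean_diff, unname(tt$estimate), tolerance = 1e-12)
    expect_equal(rep$t_statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(rep$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(c(rep$ci_low, rep$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-12)
    expect_equal(rep$mae, mean(abs(calc - meas)), tolerance = 1e-12)
    expect_equal(rep$sd_diff, sd(calc - meas), tolerance = 1e-12)
    # structural invariants
    expect_gte(rep$mae, abs(rep$mean_diff))
    expect_equal(rep$loa_low, rep$mean_diff - 1.96 * rep$sd_diff)
    expect_equal(rep$loa_high, rep$mean_diff + 1.96 * rep$sd_diff)
    expect_lt(rep$ci_low, rep$ci_high)
    # CI excludes zero iff p < 0.05
    expect_equal(rep$p_value < 0.05, rep$ci_low > 0 || rep$ci_high < 0)
  }
})

test_that("degenerate difference vectors are flagged, not divided by zero", {
  x <- c(1.2, 1.5, 1.8)
  rep0 <- agreement_stats(x, x)
  expect_true(rep0$degenerate)
  expect_equal(rep0$mae, 0)
  expect_true(is.na(rep0$t_statistic) && is.na(rep0$p_value))

  shifted <- agreement_stats(x + 0.3, x)
  expect_true(shifted$degenerate)
  expect_equal(shifted$mean_diff, 0.3)
  expect_equal(shifted$mae, 0.3)
  expect_equal(shifted$sd_diff, 0)
})

test_that("two-sided t p-values match symmetry, closed form and quadrature", {
  expect_equal(student_t_two_sided_p(0, 5), 1)
  # df = 1 is Cauchy: P(|T| > 1) = 2 * (1/2 - atan(1)/pi) = 1/2
  expect_equal(student_t_two_sided_p(1, 1), 0.5, tolerance = 1e-12)
  # quadrature oracle on the t density, df = 21
  tdens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_quad <- 2 * integrate(tdens, 1.5993, Inf, df = 21)$value
  expect_equal(student_t_two_sided_p(1.5993, 21), p_quad, tolerance = 1e-6)
  expect_error(student_t_two_sided_p(1, 0), "df")
})

test_that("injected shift and noise are recovered on a large seeded cohort", {
  spec <- synthetic_cohort_spec(n_cases = 1e4, seed = 202)
  cohort <- generate_validation_cohort(spec, shift = -0.08,
                                       measurement_sigma = 0.2)
  rep <- agreement_stats(cohort$calculated_velocity_m_s,
                         cohort$echo_velocity_m_s)
  se <- 0.2 / sqrt(1e4)
  expect_lt(abs(rep$mean_diff - (-0.08)), 3 * se)
  expect_lt(abs(rep$sd_diff - 0.2), 3 * se)
})

test_that("full pipeline on the packaged cohort matches published summaries", {
  res <- run_validation_pipeline(load_validation_fixture())
  expect_equal(res$report$n, 22)
  # unrounded recomputed velocities land within ~1e-3 of the published
  # statistics (which derive from the printed, rounded column)
  expect_lt(abs(res$report$mae - 0.1742), 0.0015)
  expect_lt(abs(res$report$mean_diff - 0.0767), 0.0015)
  expect_lt(abs(res$report$sd_diff - 0.2250), 0.0015)
})
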