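# Reduced-order pulsatile orifice-flow surrogate and synthetic cohorts.

test_that("inflow waveform conserves prescribed cardiac output per cycle", {
  cfg <- pulsatile_sim_config()
  wf <- weight_to_flow_waveform(3.27, cfg)
  n_cyc <- length(wf$time_s) / cfg$n_cycles
  target <- 200 * 3.27 * 1000 / 60  # mL/kg/min -> mm^3/s
  expect_equal(target, 10900)
  for (c_i in seq_len(cfg$n_cycles)) {
    idx <- ((c_i - 1) * n_cyc + 1):(c_i * n_cyc)
    expect_lt(abs(mean(wf$flow_mm3_s[idx]) / target - 1), 1e-9)
  }
})

test_that("inflow is pointwise linear in weight", {
  wf1 <- weight_to_flow_waveform(2.0)
  wf2 <- weight_to_flow_waveform(4.0)
  expect_equal(wf2$flow_mm3_s, 2 * wf1$flow_mm3_s)
  expect_error(weight_to_flow_waveform(0), "weight_kg")
})

test_that("outlet pressure waveform spans its bounds periodically", {
  cfg <- pulsatile_sim_config()
  period <- 60 / cfg$heart_rate_bpm
  t <- seq(0, period, length.out = 2001)
  p <- la_pressure_waveform(t, cfg)
  expect_equal(min(p), 4)
  expect_equal(max(p), 12, tolerance = 1e-6)
  expect_equal(la_pressure_waveform(0.123, cfg),
               la_pressure_waveform(0.123 + period, cfg))
  expect_error(pulsatile_sim_config(la_pressure_min_mmHg = 12,
                                    la_pressure_max_mmHg = 12), "below")
})

test_that("calibrated surrogate reproduces the scaling law across the study range", {
  cfg <- calibrate_alpha(pulsatile_sim_config())
  grid <- expand.grid(m = c(1.95, 3.35, 4.06), l = c(4.89, 11.33, 18.33),
                      cc = c(14.9, 21.8, 30.83))
  for (i in seq_len(nrow(grid))) {
    v_sim <- simulate_peak_velocity(grid$m[i], grid$l[i], grid$cc[i], cfg)
    v_law <- predict_velocity(grid$m[i], grid$l[i], grid$cc[i])
    expect_lt(abs(v_sim - v_law) / v_law, 0.01)
  }
  # the sweep-table reference point: the surrogate equals the law's 2.048
  # there, and the full flow simulation's printed 2.021 sits within the
  # law's own 2% fit residual
  expect_equal(simulate_peak_velocity(4.06, 11.33, 28.6, cfg),
               predict_velocity(4.06, 11.33, 28.6), tolerance = 1e-6)
  expect_equal(simulate_peak_velocity(4.06, 11.33, 28.6, cfg), 2.021,
               tolerance = 0.02)
})

test_that("peak velocity halves when incision length doubles", {
  cfg <- calibrate_alpha(pulsatile_sim_config())
  expect_equal(simulate_peak_velocity(3.5, 20, 22, cfg),
               simulate_peak_velocity(3.5, 10, 22, cfg) / 2,
               tolerance = 1e-12)
})

test_that("sweeps preserve order and fall monotonically with length", {
  cfg <- calibrate_alpha(pulsatile_sim_config())
  lengths <- c(11.33, 12.53, 13.53, 15.36, 16.56, 17.60)
  sweep <- generate_sweep(4.06, 28.6, lengths, cfg, case_id = "Case A")
  expect_equal(nrow(sweep), 6)
  expect_equal(sweep$length_mm, lengths)
  expect_true(all(diff(sweep$velocity_m_s) < 0))
  expect_error(generate_sweep(4.06, 28.6, numeric(0), cfg), "non-empty")
  expect_warning(generate_sweep(4.06, 28.6, c(10, 10), cfg), "duplicate")
})

test_that("degenerate orifice area is rejected", {
  cfg <- calibrate_alpha(pulsatile_sim_config())
  cfg$area_coefficient_alpha <- 1e-12
  expect_error(simulate_peak_velocity(3.5, 0.001, 0.001, cfg), "degenerate")
})

test_that("synthetic cohorts are seed-deterministic", {
  spec <- synthetic_cohort_spec(n_cases = 25, seed = 5)
  expect_identical(generate_synthetic_cohort(spec),
                   generate_synthetic_cohort(spec))
  other <- generate_synthetic_cohort(synthetic_cohort_spec(n_cases = 25,
                                                           seed = 6))
  expect_false(identical(generate_synthetic_cohort(spec), other))
})

test_that("cohort generation does not disturb the session RNG stream", {
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  invisible(generate_synthetic_cohort(synthetic_cohort_spec(10, seed = 3)))
  expect_identical(runif(1), a)
})

test_that("calibration recovers the generating constant from noisy cohorts", {
  # noiseless: exact recovery
  fit0 <- fit_scaling_model(generate_synthetic_cohort(
    synthetic_cohort_spec(n_cases = 200, noise_sigma = 0, seed = 31)))
  expect_lt(abs(fit0$slope / default_k() - 1), 1e-9)
  # sigma = 0.05, n = 200: within 2% over several seeds
  for (seed in c(1, 12, 123)) {
    fit <- fit_scaling_model(generate_synthetic_cohort(
      synthetic_cohort_spec(n_cases = 200, noise_sigma = 0.05, seed = seed)))
    expect_lt(abs(fit$slope / default_k() - 1), 0.02)
  }
})

test_that("synthetic validation cohorts carry the injected offset", {
  spec <- synthetic_cohort_spec(n_cases = 50, seed = 9)
  exact <- generate_validation_cohort(spec, shift = 0, measurement_sigma = 0)
  rep <- agreement_stats(exact$calculated_velocity_m_s,
                         exact$echo_velocity_m_s)
  expect_equal(rep$mae, 0)
  expect_true(rep$degenerate)

  shifted <- generate_validation_cohort(spec, shift = 0.1,
                                        measurement_sigma = 0)
  rep_s <- agreement_stats(shifted$calculated_velocity_m_s,
                           shifted$echo_velocity_m_s)
  expect_equal(rep_s$mean_diff, 0.1, tolerance = 1e-12)
})

test_that("config validation catches inconsistent settings", {
  expect_error(pulsatile_sim_config(n_cycles = 1), "n_cycles")
  expect_error(pulsatile_sim_config(dt_s = 0), "dt_s")
  expect_error(synthetic_cohort_spec(10, weight_range_kg = c(5, 2), seed = 1),
               "weight_range_kg")
  expect_error(synthetic_cohort_spec(10, noise_sigma = -0.1, seed = 1),
               "noise_sigma")
  expect_error(synthetic_cohort_spec(10), "seed")
})
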