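# Reduced-order pulsatile orifice-flow surrogate.
#
# Stands in for a full fluid-structure-interaction solver when generating
# velocity sweeps: a weight-indexed pulsatile inflow Q(t) is pushed through
# an effective orifice A_eff = alpha * L * C (continuity equation
# V = Q / A_eff), rigid-walled. The single shape coefficient alpha is
# calibrated once against the scaling law; outlet (left-atrial) pressure is
# carried for interface completeness but does not enter the
# continuity-derived velocity.

#' Configuration for the pulsatile orifice-flow surrogate
#'
#' @param cardiac_output_per_kg Weight-indexed cardiac output in
#'   mL/kg/min (default 200, a typical neonatal requirement).
#' @param heart_rate_bpm Heart rate in beats per minute (default 140).
#' @param la_pressure_min_mmHg,la_pressure_max_mmHg Bounds of the
#'   time-varying left-atrial (outlet) pressure waveform, defaults 4 and 12
#'   mmHg (the typical infant range).
#' @param rim_height_mm Aperture rim height in mm (default 0.5).
#' @param area_coefficient_alpha Dimensionless effective-orifice shape
#'   factor in A_eff = alpha * L * C. `NULL` (default) means "calibrate
#'   against the scaling law on first use"; see [calibrate_alpha()].
#' @param n_cycles Cardiac cycles simulated (default 3); the first cycle is
#'   discarded before taking the peak.
#' @param dt_s Time step in seconds (default 1e-3).
#' @return A validated list of class `"pulsatile_sim_config"`.
#' @export
pulsatile_sim_config <- function(cardiac_output_per_kg = 200,
                                 heart_rate_bpm = 140,
                                 la_pressure_min_mmHg = 4,
                                 la_pressure_max_mmHg = 12,
                                 rim_height_mm = 0.5,
                                 area_coefficient_alpha = NULL,
                                 n_cycles = 3,
                                 dt_s = 1e-3) {
  check_positive(cardiac_output_per_kg, "cardiac_output_per_kg")
  check_positive(heart_rate_bpm, "heart_rate_bpm")
  check_positive(rim_height_mm, "rim_height_mm")
  check_positive(dt_s, "dt_s")
  if (!is.numeric(n_cycles) || n_cycles < 2) {
    stop("`n_cycles` must be >= 2 (first cycle is discarded)", call. = FALSE)
  }
  if (la_pressure_min_mmHg >= la_pressure_max_mmHg) {
    stop("`la_pressure_min_mmHg` must be below `la_pressure_max_mmHg`",
         call. = FALSE)
  }
  if (!is.null(area_coefficient_alpha)) {
    check_positive(area_coefficient_alpha, "area_coefficient_alpha")
  }
  structure(list(cardiac_output_per_kg = cardiac_output_per_kg,
                 heart_rate_bpm = heart_rate_bpm,
                 la_pressure_min_mmHg = la_pressure_min_mmHg,
                 la_pressure_max_mmHg = la_pressure_max_mmHg,
                 rim_height_mm = rim_height_mm,
                 area_coefficient_alpha = area_coefficient_alpha,
                 n_cycles = n_cycles,
                 dt_s = dt_s),
            class = "pulsatile_sim_config")
}

# Uniform time grid with an integer number of samples per cycle, so that
# per-cycle means are exact sums over complete cycles.
sim_time_grid <- function(config) {
  period <- 60 / config$heart_rate_bpm
  n_per_cycle <- max(16L, as.integer(round(period / config$dt_s)))
  list(period = period, n_per_cycle = n_per_cycle,
       t = (seq_len(config$n_cycles * n_per_cycle) - 1L) *
         (period / n_per_cycle))
}

#' Weight-indexed pulsatile inflow waveform
#'
#' Builds the volumetric inflow Q(t) for a patient: a rectified-sinusoid
#' pulse (flow during systolic ejection, zero otherwise; peak-to-mean ratio
#' ~ pi) normalised on the discrete grid so that the mean over each cardiac
#' cycle equals the prescribed cardiac output
#' `cardiac_output_per_kg * weight_kg` exactly.
#'
#' @param weight_kg Body weight in kg.
#' @param config A [pulsatile_sim_config()].
#' @return A data.frame with columns `time_s` and `flow_mm3_s` covering
#'   `n_cycles` cardiac cycles.
#' @export
weight_to_flow_waveform <- function(weight_kg, config = pulsatile_sim_config()) {
  check_positive(weight_kg, "weight_kg")
  stopifnot(inherits(config, "pulsatile_sim_config"))
  grid <- sim_time_grid(config)
  # target cycle-mean flow: mL/min -> mm^3/s
  q_mean <- config$cardiac_output_per_kg * weight_kg * 1000 / 60
  shape <- pmax(0, sin(2 * pi * grid$t / grid$period))
  shape_mean <- mean(shape[seq_len(grid$n_per_cycle)])
  data.frame(time_s = grid$t, flow_mm3_s = shape * (q_mean / shape_mean))
}

#' Left-atrial outlet pressure waveform
#'
#' Raised-cosine oscillation between the configured minimum and maximum
#' outlet pressures, period 60/heart_rate. In this rigid-walled surrogate
#' the outlet pressure does not alter the continuity-derived velocity; the
#' waveform exists for interface completeness.
#'
#' @param t Time points in seconds.
#' @param config A [pulsatile_sim_config()].
#' @return Pressures in mmHg at `t`.
#' @export
la_pressure_waveform <- function(t, config = pulsatile_sim_config()) {
  stopifnot(inherits(config, "pulsatile_sim_config"), is.numeric(t))
  period <- 60 / config$heart_rate_bpm
  mid <- (config$la_pressure_min_mmHg + config$la_pressure_max_mmHg) / 2
  amp <- (config$la_pressure_max_mmHg - config$la_pressure_min_mmHg) / 2
  mid - amp * cos(2 * pi * t / period)
}

#' Calibrate the effective-orifice coefficient against the scaling law
#'
#' Runs the surrogate once at a reference patient with alpha = 1 and scales
#' alpha so the surrogate's peak velocity matches the scaling-law prediction
#' k * M / (L * C). Because peak inflow is linear in weight and the
#' effective area linear in L * C, one calibration point aligns the
#' surrogate with the law over the whole parameter range.
#'
#' @param config A [pulsatile_sim_config()].
#' @param k Calibration constant (default [default_k()]).
#' @param reference Named list giving the reference patient
#'   (`weight_kg`, `length_mm`, `circumference_mm`).
#' @return The config with `area_coefficient_alpha` set.
#' @export
calibrate_alpha <- function(config = pulsatile_sim_config(),
                            k = default_k(),
                            reference = list(weight_kg = 3.5,
                                             length_mm = 15,
                                             circumference_mm = 22)) {
  stopifnot(inherits(config, "pulsatile_sim_config"))
  k <- resolve_k(k)
  check_positive(k, "k")
  cfg1 <- config
  cfg1$area_coefficient_alpha <- 1
  v1 <- simulate_peak_velocity(reference$weight_kg, reference$length_mm,
                               reference$circumference_mm, cfg1)
  target <- predict_velocity(reference$weight_kg, reference$length_mm,
                             reference$circumference_mm, k = k)
  config$area_coefficient_alpha <- v1 / target
  config
}

# minimum admissible effective orifice area (mm^2)
.MIN_AREA_MM2 <- 1e-6

#' Simulate peak anastomotic velocity with the reduced-order surrogate
#'
#' Continuity-equation velocity V(t) = Q(t) / A_eff with
#' A_eff = alpha * L * C; the reported peak is the maximum after discarding
#' the first cardiac cycle (transient-settling convention). With alpha
#' calibrated against the scaling law ([calibrate_alpha()]), the surrogate
#' reproduces k * M / (L * C).
#'
#' @inheritParams predict_velocity
#' @param config A [pulsatile_sim_config()]. If its alpha is `NULL` it is
#'   calibrated on the fly against the published constant.
#' @return Peak velocity in m/s (scalar; scalar inputs expected).
#' @export
#' @examples
#' cfg <- calibrate_alpha(pulsatile_sim_config())
#' simulate_peak_velocity(4.06, 11.33, 28.6, cfg)
#' predict_velocity(4.06, 11.33, 28.6)   # near-identical by construction
simulate_peak_velocity <- function(weight_kg, length_mm, circumference_mm,
                                   config = pulsatile_sim_config()) {
  stopifnot(inherits(config, "pulsatile_sim_config"))
  check_positive(weight_kg, "weight_kg")
  check_dimension(length_mm, "length_mm")
  check_dimension(circumference_mm, "circumference_mm")
  if (is.null(config$area_coefficient_alpha)) {
    config <- calibrate_alpha(config)
  }
  a_eff <- config$area_coefficient_alpha * length_mm * circumference_mm
  if (a_eff < .MIN_AREA_MM2) {
    stop("effective orifice area below ", .MIN_AREA_MM2,
         " mm^2: degenerate geometry", call. = FALSE)
  }
  wf <- weight_to_flow_waveform(weight_kg, config)
  grid <- sim_time_grid(config)
  settled <- wf$flow_mm3_s[-seq_len(grid$n_per_cycle)]
  max(settled / a_eff) / 1000  # mm/s -> m/s
}

#' Generate a velocity-length sweep for one patient
#'
#' Runs the surrogate at a series of incision lengths for a fixed patient,
#' producing one simulation record per length (the shape of the packaged
#' sweep table).
#'
#' @inheritParams predict_velocity
#' @param lengths Incision lengths in mm, at least one.
#' @param config A [pulsatile_sim_config()] (alpha calibrated on the fly if
#'   unset).
#' @param case_id Label for the records.
#' @param tapvc_type `"supra-cardiac"` or `"infra-cardiac"`.
#' @return data.frame with columns `case_id`, `tapvc_type`, `weight_kg`,
#'   `circumference_mm`, `length_mm`, `velocity_m_s`, in input length order.
#' @export
generate_sweep <- function(weight_kg, circumference_mm, lengths,
                           config = pulsatile_sim_config(),
                           case_id = "case", tapvc_type = "supra-cardiac") {
  if (length(lengths) == 0) stop("`lengths` must be non-empty", call. = FALSE)
  check_dimension(lengths, "lengths")
  check_tapvc_type(tapvc_type)
  if (anyDuplicated(lengths)) {
    warning("duplicate incision lengths in sweep; kept as given")
  }
  if (is.null(config$area_coefficient_alpha)) {
    config <- calibrate_alpha(config)
  }
  v <- vapply(lengths, function(L) {
    simulate_peak_velocity(weight_kg, L, circumference_mm, config)
  }, numeric(1))
  data.frame(case_id = case_id, tapvc_type = tapvc_type,
             weight_kg = weight_kg, circumference_mm = circumference_mm,
             length_mm = lengths, velocity_m_s = v)
}

#' Specification of a synthetic calibration cohort
#'
#' Defines the sampling scheme for synthetic sweep points: weights,
#' circumferences and lengths drawn uniformly within bounds spanning the
#' study's observed ranges, velocities generated from the scaling law with
#' multiplicative lognormal noise.
#'
#' @param n_cases Number of synthetic points.
#' @param weight_range_kg,circumference_range_mm,length_range_mm Uniform
#'   sampling bounds (defaults span the packaged study tables: weights
#'   1.9-4.9 kg, circumferences 14-31 mm, lengths 5-19 mm).
#' @param k_true Generating constant (default the published 163.48).
#' @param noise_sigma Standard deviation of the lognormal multiplicative
#'   noise on velocity (default 0.05).
#' @param seed Integer seed; required so every cohort is reproducible.
#' @return A validated list of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(n_cases,
                                  weight_range_kg = c(1.9, 4.9),
                                  circumference_range_mm = c(14, 31),
                                  length_range_mm = c(5, 19),
                                  k_true = default_k(),
                                  noise_sigma = 0.05,
                                  seed) {
  stopifnot(is.numeric(n_cases), n_cases >= 1)
  for (nm in c("weight_range_kg", "circumference_range_mm",
               "length_range_mm")) {
    rng <- get(nm)
    if (length(rng) != 2 || any(rng <= 0) || rng[1] >= rng[2]) {
      stop("`", nm, "` must be positive bounds with lower < upper",
           call. = FALSE)
    }
  }
  check_positive(k_true, "k_true")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer `seed` is required", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 weight_range_kg = weight_range_kg,
                 circumference_range_mm = circumference_range_mm,
                 length_range_mm = length_range_mm,
                 k_true = k_true, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Evaluate `expr` under a private RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic calibration cohort
#'
#' Draws `n_cases` synthetic sweep points per the spec:
#' V = k_true * M / (L * C) * exp(eps), eps ~ Normal(0, noise_sigma),
#' fully determined by the spec's seed.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return data.frame shaped like a simulation sweep table (`case_id`,
#'   `tapvc_type`, `weight_kg`, `circumference_mm`, `length_mm`,
#'   `velocity_m_s`).
#' @export
#' @examples
#' spec <- synthetic_cohort_spec(n_cases = 50, seed = 1)
#' cohort <- generate_synthetic_cohort(spec)
#' fit_scaling_model(cohort)
generate_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cases
    m <- stats::runif(n, spec$weight_range_kg[1], spec$weight_range_kg[2])
    cc <- stats::runif(n, spec$circumference_range_mm[1],
                       spec$circumference_range_mm[2])
    l <- stats::runif(n, spec$length_range_mm[1], spec$length_range_mm[2])
    eps <- if (spec$noise_sigma > 0) stats::rnorm(n, 0, spec$noise_sigma)
           else numeric(n)
    data.frame(case_id = sprintf("synth-%03d", seq_len(n)),
               tapvc_type = "supra-cardiac",
               weight_kg = m, circumference_mm = cc, length_mm = l,
               velocity_m_s = spec$k_true * m / (l * cc) * exp(eps))
  })
}

#' Generate a synthetic paired validation cohort
#'
#' Builds paired calculated/measured velocities for stress-testing the
#' agreement pipeline: calculated values come from the scaling law at
#' `k_true`; measured values are `calculated - shift + noise`, so a positive
#' `shift` makes the model under-read relative to measurement and the
#' recovered mean difference (calculated - measured) estimates `shift`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param shift Systematic offset in m/s (default 0).
#' @param measurement_sigma SD of additive measurement noise in m/s
#'   (default 0).
#' @return data.frame shaped like a validation cohort (`case_id`,
#'   `weight_kg`, `incision_length_mm`, `circumference_mm`, `tapvc_type`,
#'   `calculated_velocity_m_s`, `echo_velocity_m_s`, `sutureless_flag`).
#' @export
generate_validation_cohort <- function(spec, shift = 0,
                                       measurement_sigma = 0) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!is.numeric(measurement_sigma) || measurement_sigma < 0) {
    stop("`measurement_sigma` must be >= 0", call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_cases
    m <- stats::runif(n, spec$weight_range_kg[1], spec$weight_range_kg[2])
    cc <- stats::runif(n, spec$circumference_range_mm[1],
                       spec$circumference_range_mm[2])
    l <- stats::runif(n, spec$length_range_mm[1], spec$length_range_mm[2])
    calc <- spec$k_true * m / (l * cc)
    noise <- if (measurement_sigma > 0) stats::rnorm(n, 0, measurement_sigma)
             else numeric(n)
    data.frame(case_id = sprintf("vsynth-%03d", seq_len(n)),
               weight_kg = m, incision_length_mm = l, circumference_mm = cc,
               tapvc_type = "supra-cardiac",
               calculated_velocity_m_s = calc,
               echo_velocity_m_s = calc - shift + noise,
               sutureless_flag = FALSE)
  })
}
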