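# Scaling-law predictor and its inversion for incision planning.
#
# Unit system is fixed: M in kg, L and C in mm, V in m/s, so k carries
# m*mm^2/(s*kg). Geometry below 1e-6 mm is rejected rather than producing
# astronomically large velocities from a unit mistake.

#' Published calibration constant of the velocity scaling law
#'
#' The constant k of V = k * M / (L * C), fitted by pooled linear regression
#' of simulated peak velocity on M/(L*C) over seven patient-specific
#' simulation sweeps. Units: m*mm^2/(s*kg).
#'
#' @return The scalar 163.48.
#' @export
#' @examples
#' default_k()
default_k <- function() 163.48

# smallest admissible length/circumference (mm); guards against unit errors
.MIN_DIM_MM <- 1e-6

#' Predict peak anastomotic blood-flow velocity
#'
#' Evaluates the scaling law V = k * M / (L * C): peak velocity across the
#' anastomosis rises with patient weight (which sets required cardiac
#' output) and falls as the effective orifice — proportional to incision
#' length times confluence circumference — grows.
#'
#' @param weight_kg Body weight M in kilograms.
#' @param length_mm Incision/anastomosis length L in millimeters.
#' @param circumference_mm Circumference C of the pulmonary venous
#'   confluence in millimeters.
#' @param k Calibration constant in m*mm^2/(s*kg); defaults to the published
#'   value 163.48 ([default_k()]). A [fit_scaling_model()] result may be
#'   passed instead of a number, in which case its slope is used.
#' @return Numeric vector of predicted peak velocities in m/s. Inputs are
#'   recycled as usual.
#' @seealso [plan_incision_length()] for the algebraic inverse,
#'   [compute_ratios()] for the underlying predictors.
#' @export
#' @examples
#' predict_velocity(weight_kg = 3.27, length_mm = 18, circumference_mm = 19.2)
predict_velocity <- function(weight_kg, length_mm, circumference_mm,
                             k = default_k()) {
  k <- resolve_k(k)
  check_positive(weight_kg, "weight_kg")
  check_dimension(length_mm, "length_mm")
  check_dimension(circumference_mm, "circumference_mm")
  check_positive(k, "k")
  k * weight_kg / (length_mm * circumference_mm)
}

#' Plan an incision length for a target peak velocity
#'
#' Algebraic inversion of the scaling law: L = k * M / (V * C). Given the
#' patient's weight, the CTA-measured confluence circumference and a target
#' postoperative peak velocity, returns the incision length expected to
#' produce that velocity.
#'
#' @inheritParams predict_velocity
#' @param target_velocity_m_s Desired peak velocity V in m/s.
#' @return Numeric vector of incision lengths in millimeters.
#' @export
#' @examples
#' # length that the model maps back to a 1.547 m/s peak
#' plan_incision_length(weight_kg = 3.27, target_velocity_m_s = 1.547,
#'                      circumference_mm = 19.2)
plan_incision_length <- function(weight_kg, target_velocity_m_s,
                                 circumference_mm, k = default_k()) {
  k <- resolve_k(k)
  check_positive(weight_kg, "weight_kg")
  check_positive(target_velocity_m_s, "target_velocity_m_s")
  check_dimension(circumference_mm, "circumference_mm")
  check_positive(k, "k")
  k * weight_kg / (target_velocity_m_s * circumference_mm)
}

#' Weight-to-geometry ratios used as regression predictors
#'
#' Computes the two candidate predictors of peak velocity: M/(L*C), which
#' accounts for confluence size, and M/L, which ignores it. The model
#' comparison between them is the core of the calibration analysis.
#'
#' @inheritParams predict_velocity
#' @return A data.frame with columns `m_over_lc` (kg/mm^2) and `m_over_l`
#'   (kg/mm).
#' @export
#' @examples
#' compute_ratios(weight_kg = 4.06, length_mm = 11.33, circumference_mm = 28.6)
compute_ratios <- function(weight_kg, length_mm, circumference_mm) {
  check_positive(weight_kg, "weight_kg")
  check_dimension(length_mm, "length_mm")
  check_dimension(circumference_mm, "circumference_mm")
  data.frame(m_over_lc = weight_kg / (length_mm * circumference_mm),
             m_over_l = weight_kg / length_mm)
}

#' Round to a fixed number of decimals, half to even
#'
#' Printed-table comparisons use R's round-half-even at 3 decimals; internal
#' computation always uses unrounded values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3, the precision of the printed
#'   velocity tables).
#' @return Rounded numeric vector.
#' @export
round_printed <- function(x, digits = 3) round(x, digits)

# Accept a bare constant or a scaling_fit whose slope is the constant.
resolve_k <- function(k) {
  if (inherits(k, "scaling_fit")) k$slope else k
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and non-missing", name),
         call. = FALSE)
  }
  invisible(x)
}

check_dimension <- function(x, name) {
  check_positive(x, name)
  if (any(x < .MIN_DIM_MM)) {
    stop(sprintf("`%s` below %g mm: check input units", name, .MIN_DIM_MM),
         call. = FALSE)
  }
  invisible(x)
}

check_tapvc_type <- function(type) {
  ok <- type %in% c("supra-cardiac", "infra-cardiac")
  if (!all(ok)) {
    stop("`tapvc_type` must be \"supra-cardiac\" or \"infra-cardiac\" (got ",
         paste(unique(type[!ok]), collapse = ", "), ")", call. = FALSE)
  }
  invisible(type)
}
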