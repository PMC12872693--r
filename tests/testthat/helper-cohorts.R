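# Shared fixtures built in code.

# A small hand-built validation cohort: 4 clean cases, 1 sutureless,
# 1 missing intraoperative length.
tiny_validation_cohort <- function() {
  data.frame(
    case_id = c("v1", "v2", "v3", "v4", "v5", "v6"),
    weight_kg = c(3.27, 3.50, 3.65, 4.80, 2.56, 2.58),
    incision_length_mm = c(18, 20, 20, 20, NA, 15),
    circumference_mm = c(19.2, 25.7, 21.8, 28.1, 22.9, 21.9),
    tapvc_type = c("infra-cardiac", "infra-cardiac", "supra-cardiac",
                   "supra-cardiac", "infra-cardiac", "supra-cardiac"),
    echo_velocity_m_s = c(1.66, 1.27, 1.52, 1.60, 1.32, 1.25),
    sutureless_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
}

# Closed-form simple linear regression and Pearson r via the raw
# sum formulas; independent oracle for fit_scaling_model / pearson_r.
sum_formula_ols <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r = sxy / sqrt(sxx * syy))
}
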