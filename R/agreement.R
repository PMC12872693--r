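# Clinical validation: apply the calibrated scaling law to a surgical
# cohort and quantify agreement with echo-measured peak velocities.
# Difference convention throughout: calculated - measured.

#' Filter a validation cohort to usable cases
#'
#' Drops cases repaired with a "sutureless" technique (the scaling law
#' models a direct confluence-to-atrium suture line, so no incision length
#' exists) and cases whose intraoperative incision length was not recorded.
#' Each exclusion is reported via [message()].
#'
#' @param cases A data.frame with at least `case_id` and
#'   `incision_length_mm`; an optional logical `sutureless_flag` column
#'   marks sutureless repairs (absent means none).
#' @return The retained rows, same columns.
#' @export
filter_validation_cases <- function(cases) {
  stopifnot(is.data.frame(cases), "case_id" %in% names(cases),
            "incision_length_mm" %in% names(cases))
  keep <- rep(TRUE, nrow(cases))
  if ("sutureless_flag" %in% names(cases)) {
    sl <- isTRUE_vec(cases$sutureless_flag)
    for (id in cases$case_id[sl]) {
      message("excluding case ", id, ": sutureless technique")
    }
    keep <- keep & !sl
  }
  no_len <- is.na(cases$incision_length_mm)
  for (id in cases$case_id[keep & no_len]) {
    message("excluding case ", id, ": no intraoperative anastomosis length")
  }
  keep <- keep & !no_len
  out <- cases[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no usable cases after exclusions", call. = FALSE)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Fill model-calculated velocities into a validation cohort
#'
#' Evaluates the scaling law per case, writing the result to a
#' `calculated_velocity_m_s` column. Domain errors (non-positive inputs)
#' are re-raised naming the offending case.
#'
#' @param cases Filtered validation data.frame with `case_id`, `weight_kg`,
#'   `incision_length_mm`, `circumference_mm`.
#' @param k Calibration constant or a [fit_scaling_model()] result.
#' @return `cases` with `calculated_velocity_m_s` added/overwritten.
#' @export
apply_model <- function(cases, k = default_k()) {
  stopifnot(is.data.frame(cases))
  need <- c("case_id", "weight_kg", "incision_length_mm", "circumference_mm")
  missing_cols <- setdiff(need, names(cases))
  if (length(missing_cols) > 0) {
    stop("cases lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cases$calculated_velocity_m_s <- vapply(seq_len(nrow(cases)), function(i) {
    tryCatch(
      predict_velocity(cases$weight_kg[i], cases$incision_length_mm[i],
                       cases$circumference_mm[i], k = k),
      error = function(e) stop("case ", cases$case_id[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }, numeric(1))
  cases
}

#' Agreement statistics between calculated and measured velocities
#'
#' Computes the method-agreement summary for paired model-calculated and
#' echo-measured peak velocities: mean absolute error, the mean and sample
#' standard deviation (n - 1 denominator) of the differences
#' (calculated - measured), a t-based 95% confidence interval for the mean
#' difference (df = n - 1), Bland-Altman limits of agreement
#' (mean +/- 1.96 * sd), and the two-sided paired t-test.
#'
#' @param calculated,measured Numeric vectors of equal length n >= 2, paired
#'   by case.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return An object of class `"agreement_report"`: list with `n`, `mae`,
#'   `mean_diff`, `sd_diff`, `ci_low`, `ci_high`, `loa_low`, `loa_high`,
#'   `t_statistic`, `p_value`, `degenerate` (`TRUE` when sd_diff = 0, in
#'   which case t and p are `NA` rather than a division by zero), and
#'   `conf_level`.
#' @export
#' @examples
#' calc <- c(1.55, 1.11, 1.37, 1.40)
#' echo <- c(1.66, 1.27, 1.52, 1.60)
#' agreement_stats(calc, echo)
agreement_stats <- function(calculated, measured, conf_level = 0.95) {
  stopifnot(is.numeric(calculated), is.numeric(measured))
  if (length(calculated) != length(measured)) {
    stop("calculated and measured must have equal length", call. = FALSE)
  }
  n <- length(calculated)
  if (n < 2) stop("need at least 2 paired cases", call. = FALSE)
  if (anyNA(calculated) || anyNA(measured)) {
    stop("missing values in paired velocities", call. = FALSE)
  }

  d <- calculated - measured
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  mae <- mean(abs(d))
  degenerate <- sd_diff == 0

  if (degenerate) {
    t_stat <- NA_real_
    p <- NA_real_
    ci <- c(mean_diff, mean_diff)
  } else {
    se <- sd_diff / sqrt(n)
    t_stat <- mean_diff / se
    p <- student_t_two_sided_p(t_stat, df = n - 1)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- mean_diff + c(-1, 1) * tq * se
  }

  structure(list(n = n, mae = mae, mean_diff = mean_diff, sd_diff = sd_diff,
                 ci_low = ci[1], ci_high = ci[2],
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff,
                 t_statistic = t_stat, p_value = p,
                 degenerate = degenerate, conf_level = conf_level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement of calculated vs measured velocities",
      sprintf("(n = %d, differences = calculated - measured)\n", x$n))
  cat(sprintf("  MAE        %.4f m/s\n", x$mae))
  cat(sprintf("  mean diff  %.4f m/s  (sd %.4f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  %d%% CI     [%.4f, %.4f]\n", round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  cat(sprintf("  LoA        [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  if (x$degenerate) {
    cat("  paired t   degenerate (zero-variance differences)\n")
  } else {
    cat(sprintf("  paired t   t = %.4f, p = %.4f\n", x$t_statistic,
                x$p_value))
  }
  invisible(x)
}

#' Two-sided p-value of a Student-t statistic
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom, >= 1.
#' @return 2 * P(T >= |t|) under the t distribution with `df` degrees of
#'   freedom.
#' @export
student_t_two_sided_p <- function(t, df) {
  if (!is.numeric(df) || any(df < 1)) stop("df must be >= 1", call. = FALSE)
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Run the full validation pipeline on a cohort
#'
#' Convenience wrapper: filter usable cases, fill model velocities, and
#' compute agreement statistics against the echo measurements.
#'
#' @param cases Validation data.frame (see [filter_validation_cases()] and
#'   [apply_model()]) with an `echo_velocity_m_s` column.
#' @param k Calibration constant or [fit_scaling_model()] result.
#' @return List with `cases` (filtered, velocities filled) and `report`
#'   (the [agreement_stats()] result).
#' @export
#' @examples
#' cohort <- load_validation_fixture()
#' run_validation_pipeline(cohort)$report
run_validation_pipeline <- function(cases, k = default_k()) {
  stopifnot("echo_velocity_m_s" %in% names(cases))
  cases <- filter_validation_cases(cases)
  cases <- apply_model(cases, k = k)
  list(cases = cases,
       report = agreement_stats(cases$calculated_velocity_m_s,
                                cases$echo_velocity_m_s))
}

#' Bland-Altman plot of paired velocities
#'
#' Differences (calculated - measured) against pairwise means, with the mean
#' difference and 1.96-sd limits of agreement drawn as horizontal lines.
#'
#' @inheritParams agreement_stats
#' @param ... Passed to [graphics::plot()].
#' @return The [agreement_stats()] report, invisibly.
#' @export
bland_altman_plot <- function(calculated, measured, ...) {
  rep <- agreement_stats(calculated, measured)
  m <- (calculated + measured) / 2
  d <- calculated - measured
  graphics::plot(m, d, xlab = "mean of calculated and measured (m/s)",
                 ylab = "calculated - measured (m/s)", ...)
  graphics::abline(h = rep$mean_diff, lty = 1)
  graphics::abline(h = c(rep$loa_low, rep$loa_high), lty = 2)
  invisible(rep)
}
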