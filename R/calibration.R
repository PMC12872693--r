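# Calibration of the scaling constant from simulation velocity sweeps:
# pooled simple linear regression of peak velocity on M/(L*C) or M/L.

#' Fit the velocity scaling law to simulation sweep data
#'
#' Pools all sweep points and fits peak velocity against a single
#' weight-to-geometry ratio by ordinary least squares. With the `m_lc`
#' predictor the fitted slope is the calibration constant k of
#' V = k * M / (L * C) (the intercept is expected to be negligible); the
#' `m_l` predictor, which ignores confluence circumference, serves as the
#' comparison model.
#'
#' @param records A data.frame of sweep points with columns `weight_kg`,
#'   `length_mm`, `circumference_mm`, `velocity_m_s`, and (only needed when
#'   `ratio_source = "printed"`) `m_over_lc_printed` / `m_over_l_printed`.
#'   [load_simulation_fixture()] and [generate_sweep()] produce this shape.
#' @param predictor `"m_lc"` (default) regresses V on M/(L*C); `"m_l"` on
#'   M/L.
#' @param ratio_source `"recomputed"` (default) rebuilds the ratio from each
#'   record's own weight and geometry; `"printed"` uses the ratio column as
#'   published, which in the packaged sweep table differs from its own row
#'   arithmetic in several cells (see [audit_ratio_discrepancies()]).
#' @param through_origin If `TRUE`, fit V = k * x with no intercept
#'   (slope = sum(xy)/sum(x^2)); default `FALSE` fits a free intercept and
#'   reports the slope as the constant.
#' @return An object of class `"scaling_fit"`: a list with `slope`,
#'   `intercept` (0 for through-origin fits), `pearson_r`, `r_squared`
#'   (= pearson_r^2), `p_value` (two-sided, from the t-transform of r with
#'   n - 2 df), `n_points`, `predictor`, `ratio_source`, `through_origin`,
#'   and `k_units`.
#' @seealso [pearson_r()], [predict_velocity()] which accepts the fit as its
#'   `k` argument.
#' @export
#' @examples
#' sweeps <- load_simulation_fixture()
#' fit_scaling_model(sweeps)                       # k from row arithmetic
#' fit_scaling_model(sweeps, ratio_source = "printed")
#' fit_scaling_model(sweeps, predictor = "m_l")    # circumference ignored
fit_scaling_model <- function(records,
                              predictor = c("m_lc", "m_l"),
                              ratio_source = c("recomputed", "printed"),
                              through_origin = FALSE) {
  predictor <- match.arg(predictor)
  ratio_source <- match.arg(ratio_source)
  stopifnot(is.data.frame(records))
  need <- c("weight_kg", "length_mm", "circumference_mm", "velocity_m_s")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) < 3) stop("need at least 3 sweep points", call. = FALSE)

  x <- if (ratio_source == "recomputed") {
    r <- compute_ratios(records$weight_kg, records$length_mm,
                        records$circumference_mm)
    if (predictor == "m_lc") r$m_over_lc else r$m_over_l
  } else {
    col <- if (predictor == "m_lc") "m_over_lc_printed" else "m_over_l_printed"
    if (!col %in% names(records) || anyNA(records[[col]])) {
      stop("ratio_source = \"printed\" requires a complete `", col,
           "` column", call. = FALSE)
    }
    records[[col]]
  }
  y <- records$velocity_m_s
  if (stats::var(x) == 0) stop("zero variance in predictor", call. = FALSE)

  if (through_origin) {
    fit <- stats::lm(y ~ 0 + x)
    slope <- unname(stats::coef(fit)[["x"]])
    intercept <- 0
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[["x"]])
    intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  }
  ct <- pearson_r(x, y)

  structure(list(slope = slope,
                 intercept = intercept,
                 pearson_r = ct$r,
                 r_squared = ct$r^2,
                 p_value = ct$p_value,
                 n_points = length(y),
                 predictor = predictor,
                 ratio_source = ratio_source,
                 through_origin = through_origin,
                 k_units = "m*mm^2/(s*kg)"),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  lab <- if (x$predictor == "m_lc") "M/(L*C)" else "M/L"
  cat("Scaling-law fit: V ~ ", lab,
      if (x$through_origin) " (through origin)" else "", "\n", sep = "")
  cat(sprintf("  slope (k) = %.4f %s,  intercept = %.4f\n",
              x$slope, x$k_units, x$intercept))
  cat(sprintf("  Pearson r = %.4f,  r^2 = %.4f,  p = %.3g,  n = %d\n",
              x$pearson_r, x$r_squared, x$p_value, x$n_points))
  cat(sprintf("  ratios: %s\n", x$ratio_source))
  invisible(x)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning just the correlation
#' and its two-sided significance (t-transform with n - 2 degrees of
#' freedom), with an explicit zero-variance guard.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with elements `r` and `p_value`.
#' @export
#' @examples
#' pearson_r(1:10, (1:10) * 2 + rnorm(10, sd = 0.1))
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined for a constant vector",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Shapiro-Wilk normality check
#'
#' Advisory normality assessment of a sample (e.g. paired differences before
#' a t-based analysis). Does not block any downstream fit.
#'
#' @param values Numeric vector, 3 to 5000 observations (the Shapiro-Wilk
#'   implementation's supported range).
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List with `statistic` (W), `p_value` and `pass` (`TRUE` when the
#'   normality hypothesis is not rejected at `alpha`).
#' @export
#' @examples
#' check_normality(rnorm(100))
check_normality <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  if (length(values) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("zero variance: normality test undefined for a constant vector",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value > alpha)
}
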