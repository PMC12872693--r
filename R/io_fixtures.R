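# Packaged study tables and CSV I/O with schema validation.
#
# Two fixtures ship as plain CSV under inst/extdata/:
#   table1_sweeps.csv      42 simulation sweep points (7 cases x 6 lengths)
#   table2_validation.csv  22 clinical validation cases
# Loaders verify structure and frozen column checksums so silent edits to
# the packaged data are caught; printed ratio/velocity columns are kept
# verbatim and audited against row arithmetic, never corrected.

SIM_COLS <- c("case_id", "tapvc_type", "weight_kg", "circumference_mm",
              "length_mm", "velocity_m_s")
VALIDATION_COLS <- c("case_id", "weight_kg", "incision_length_mm",
                     "circumference_mm", "tapvc_type", "echo_velocity_m_s")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "tapvcflow")
  if (path == "") stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

check_fixture_sums <- function(df, expected, file) {
  for (col in names(expected)) {
    if (abs(sum(df[[col]]) - expected[[col]]) > 1e-8) {
      stop("fixture integrity check failed for ", file, ": column `", col,
           "` does not sum to its recorded checksum", call. = FALSE)
    }
  }
}

#' Load the packaged simulation-sweep table
#'
#' The 42 simulation sweep points (7 patients, 5 supra-cardiac and 2
#' infra-cardiac, each swept over 6 incision lengths) with peak velocities
#' from patient-specific flow simulations. Both ratio predictors are
#' attached twice: as printed in the source table
#' (`m_over_lc_printed`, `m_over_l_printed`) and recomputed from each row's
#' own weight and geometry (`m_over_lc`, `m_over_l`). Several printed cells
#' disagree with their own row arithmetic; see
#' [audit_ratio_discrepancies()].
#'
#' @return data.frame of 42 records with attribute
#'   `provenance = "table1_fixture"`.
#' @export
#' @examples
#' sweeps <- load_simulation_fixture()
#' table(sweeps$case_id)
load_simulation_fixture <- function() {
  df <- utils::read.csv(fixture_path("table1_sweeps.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 42,
            length(unique(df$case_id)) == 7,
            all(table(df$case_id) == 6))
  check_tapvc_type(df$tapvc_type)
  type_by_case <- unique(df[, c("case_id", "tapvc_type")])
  stopifnot(sum(type_by_case$tapvc_type == "supra-cardiac") == 5,
            sum(type_by_case$tapvc_type == "infra-cardiac") == 2)
  check_fixture_sums(df, list(weight_kg = 142.56, circumference_mm = 1010.64,
                              length_mm = 536.04, velocity_m_s = 81.694,
                              m_over_lc_printed = 0.50892,
                              m_over_l_printed = 11.6069),
                     "table1_sweeps.csv")
  ratios <- compute_ratios(df$weight_kg, df$length_mm, df$circumference_mm)
  df$m_over_lc <- ratios$m_over_lc
  df$m_over_l <- ratios$m_over_l
  attr(df, "provenance") <- "table1_fixture"
  df
}

#' Load the packaged clinical validation table
#'
#' The 22 surgically repaired cases used for model validation: body weight,
#' intraoperative incision length, CTA-measured confluence circumference,
#' TAPVC subtype, the calculated velocity as printed in the source table
#' (`calculated_velocity_printed`) and the postoperative echo-measured peak
#' velocity. `cfd_case` flags the five cases that also underwent full flow
#' simulation. One printed calculated-velocity cell (case 06) disagrees
#' with its own row arithmetic; [audit_calculated_velocities()] reports it.
#'
#' @return data.frame of 22 records with attribute
#'   `provenance = "table2_fixture"`.
#' @export
#' @examples
#' cohort <- load_validation_fixture()
#' sum(cohort$cfd_case)
load_validation_fixture <- function() {
  df <- utils::read.csv(fixture_path("table2_validation.csv"),
                        colClasses = c(case_id = "character"),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 22, sum(df$cfd_case) == 5)
  check_tapvc_type(df$tapvc_type)
  check_fixture_sums(df, list(weight_kg = 76.58, incision_length_mm = 365,
                              circumference_mm = 521.8,
                              calculated_velocity_printed = 32.558,
                              echo_velocity_m_s = 30.87),
                     "table2_validation.csv")
  attr(df, "provenance") <- "table2_fixture"
  df
}

#' Audit printed ratio columns against row arithmetic
#'
#' Flags every sweep record whose printed M/(L*C) or M/L differs from the
#' value recomputed from that row's own weight and geometry by more than
#' `tol`. Discrepancies are reported, never corrected: both columns stay
#' available to [fit_scaling_model()] via its `ratio_source` argument.
#'
#' @param sweeps A simulation sweep table ([load_simulation_fixture()]).
#' @param tol Absolute discrepancy threshold (default 5e-5, half a unit in
#'   the printed table's last decimal place at its coarsest).
#' @return data.frame with `case_id`, `length_mm`, `ratio` ("m_over_lc" or
#'   "m_over_l"), `printed`, `recomputed`, `abs_diff`; zero rows when all
#'   cells are consistent.
#' @export
audit_ratio_discrepancies <- function(sweeps, tol = 5e-5) {
  stopifnot(all(c("m_over_lc_printed", "m_over_l_printed",
                  "m_over_lc", "m_over_l") %in% names(sweeps)))
  one <- function(ratio, printed, recomputed) {
    bad <- abs(printed - recomputed) > tol
    data.frame(case_id = sweeps$case_id[bad],
               length_mm = sweeps$length_mm[bad],
               ratio = ratio, printed = printed[bad],
               recomputed = recomputed[bad],
               abs_diff = abs(printed - recomputed)[bad])
  }
  out <- rbind(one("m_over_lc", sweeps$m_over_lc_printed, sweeps$m_over_lc),
               one("m_over_l", sweeps$m_over_l_printed, sweeps$m_over_l))
  rownames(out) <- NULL
  out
}

#' Audit printed calculated velocities against the scaling law
#'
#' Recomputes each validation case's model velocity with the published
#' constant and flags printed cells differing by more than `tol` after
#' rounding to the printed precision.
#'
#' @param cohort A validation table ([load_validation_fixture()]).
#' @param k Calibration constant (default [default_k()]).
#' @param tol Absolute threshold on the rounded difference (default 0.0015,
#'   one-and-a-half units in the printed last decimal).
#' @return data.frame with `case_id`, `printed`, `recomputed`, `abs_diff`.
#' @export
audit_calculated_velocities <- function(cohort, k = default_k(),
                                        tol = 0.0015) {
  stopifnot("calculated_velocity_printed" %in% names(cohort))
  recomputed <- round_printed(predict_velocity(
    cohort$weight_kg, cohort$incision_length_mm, cohort$circumference_mm,
    k = k))
  bad <- abs(recomputed - cohort$calculated_velocity_printed) > tol
  out <- data.frame(case_id = cohort$case_id[bad],
                    printed = cohort$calculated_velocity_printed[bad],
                    recomputed = recomputed[bad],
                    abs_diff = abs(recomputed -
                                   cohort$calculated_velocity_printed)[bad])
  rownames(out) <- NULL
  out
}

#' Read a cohort table from CSV
#'
#' Validates the schema for the requested kind (simulation sweeps or
#' validation cohort), checks that every required numeric column parses as
#' numeric, and preserves unrecognised extra columns untouched.
#'
#' @param path CSV file path (comma-separated, header row, decimal point).
#' @param kind `"simulation"` or `"validation"`.
#' @return data.frame with attribute `provenance = "user_csv"`.
#' @export
read_cohort_csv <- function(path, kind = c("simulation", "validation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- if (kind == "simulation") SIM_COLS else VALIDATION_COLS
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("weight_kg", "circumference_mm", "length_mm", "incision_length_mm",
      "velocity_m_s", "echo_velocity_m_s", "calculated_velocity_m_s",
      "calculated_velocity_printed", "m_over_lc_printed",
      "m_over_l_printed"),
    names(df))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !(df[[col]] %in% c("", "NA")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value \"%s\" in column `%s`, row %d",
                   df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  if ("sutureless_flag" %in% names(df)) {
    df$sutureless_flag <- as.logical(df$sutureless_flag)
  }
  if ("cfd_case" %in% names(df)) df$cfd_case <- as.logical(df$cfd_case)
  attr(df, "provenance") <- "user_csv"
  df
}

#' Write a cohort table to CSV
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read round-trip reproduces every double bit-exactly.
#'
#' @param table data.frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
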