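#' Load the bundled timing data for the time-comparison exercise
#'
#' Returns the 24 timing records of the method-comparison exercise exactly
#' as printed in the source assignment matrix: 4 raters x 3 days x 2
#' sessions, with the three task times in seconds and the method label for
#' each calorie count. The printed method labels are preserved verbatim;
#' several of them conflict with the exercise's alternating balanced design,
#' and correcting them is an explicit, opt-in step via
#' [resolve_method_labels()].
#'
#' @return A data.frame of 24 timing records `(rater, method, day, session,
#'   meal, t_pre_s, t_post_s, t_entry_s)`.
#' @examples
#' tab <- load_table2_fixture()
#' nrow(tab)  # 24
#' @export
load_table2_fixture <- function() {
  read_time_records(system.file("extdata", "table2_timing.csv",
                                package = "mealcount"))
}

#' Read / write timing records
#'
#' CSV dialect: UTF-8, comma-separated, header row, times in integer
#' seconds, columns `rater, method, day, session, meal, t_pre_s, t_post_s,
#' t_entry_s`.
#'
#' @param path File path.
#' @param records Data.frame of timing records.
#' @return `read_time_records()` a validated data.frame;
#'   `write_time_records()` the path, invisibly.
#' @export
read_time_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_time_records(x)
  x
}

#' @rdname read_time_records
#' @export
write_time_records <- function(records, path) {
  check_time_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read / write assessment records
#'
#' Columns `tray_id, rater_id, day, meal, estimate_kcal` and optionally
#' `true_kcal`; internally the estimate and reference columns are named
#' `estimate` and `true_value`.
#'
#' @param path File path.
#' @param records Data.frame of assessment records.
#' @return `read_assessment_records()` a data.frame with columns `tray_id`,
#'   `rater_id`, `day`, `meal`, `estimate`, `true_value` (the last `NA` when
#'   absent from the file); `write_assessment_records()` the path,
#'   invisibly.
#' @export
read_assessment_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("tray_id", "rater_id", "estimate_kcal")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("assessment CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(tray_id = as.character(x$tray_id),
                    rater_id = as.character(x$rater_id),
                    day = if ("day" %in% names(x)) x$day else NA,
                    meal = if ("meal" %in% names(x)) x$meal else NA,
                    estimate = as.numeric(x$estimate_kcal),
                    true_value = if ("true_kcal" %in% names(x))
                      as.numeric(x$true_kcal) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(out$estimate < 0, na.rm = TRUE) ||
      any(out$true_value < 0, na.rm = TRUE))
    stop("energy values must be non-negative")
  out
}

#' @rdname read_assessment_records
#' @export
write_assessment_records <- function(records, path) {
  out <- data.frame(tray_id = records$tray_id, rater_id = records$rater_id,
                    day = records$day, meal = records$meal,
                    estimate_kcal = records$estimate,
                    true_kcal = records$true_value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read weighed-food records
#'
#' Columns `tray_id` (optional), `item_id`, `original_g`, `leftover_g`.
#'
#' @param path File path.
#' @return A data.frame of weighed records.
#' @export
read_weighed_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(c("item_id", "original_g", "leftover_g"), names(x))
  if (length(miss)) stop("weighed-record CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  weighed_consumption_pct(x$original_g, x$leftover_g)  # validates
  x
}

#' Read photo-review comparisons
#'
#' Columns `tray_id, item_id, primary_pct, review_pct, reviewer_id`.
#'
#' @param path File path.
#' @return A data.frame of review comparisons for [flag_discrepancies()].
#' @export
read_review_comparisons <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(c("tray_id", "item_id", "primary_pct", "review_pct"), names(x))
  if (length(miss)) stop("review CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Export an analysis result as JSON with provenance
#'
#' Serializes any of the package's result objects (`bland_altman`,
#' `accuracy_fit`, `icc_fit`, `efficiency_fit`, `qc_report`,
#' `intake_report`, `label_resolution`) to JSON, together with the package
#' version, result class, model formula and estimation settings where
#' applicable, and the seed, so that a rerun with identical inputs can be
#' verified to produce identical output.
#'
#' @param x A result object.
#' @param path Output path.
#' @param seed Optional seed to record in the provenance block.
#' @return `path`, invisibly.
#' @export
export_result <- function(x, path, seed = NULL) {
  body <- result_payload(x)
  body$provenance <- c(list(
    package = "mealcount",
    version = as.character(utils::packageVersion("mealcount")),
    class = class(x)[1]),
    if (!is.null(seed)) list(seed = seed))
  if (!is.null(x$fit))
    body$provenance$formula <- deparse1(stats::formula(x$fit))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

result_payload <- function(x) {
  if (inherits(x, "bland_altman"))
    return(list(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                ci_mean_diff = x$ci_mean_diff, loa = x$loa,
                n_outside_loa = x$n_outside_loa,
                corr_diff_vs_mean = x$corr_diff_vs_mean,
                loa_multiplier = x$loa_multiplier))
  if (inherits(x, "accuracy_fit"))
    return(list(coefficients = x$coefficients,
                p_intercept_vs_0 = x$p_intercept_vs_0,
                p_slope_vs_1 = x$p_slope_vs_1,
                varcomp = as.list(x$varcomp), test = x$test))
  if (inherits(x, "icc_fit"))
    return(list(icc = x$icc, ci = x$ci, varcomp = as.list(x$varcomp),
                design = x$design, ci_method = x$ci_method,
                nboot = x$nboot, seed = x$seed))
  if (inherits(x, "efficiency_fit"))
    return(list(ratio_pct = x$ratio_pct, ci = x$ci,
                saving_pct = x$saving_pct, p = x$p,
                meal_effects = as.list(x$meal_effects),
                rater_var = x$rater_var))
  if (inherits(x, "qc_report"))
    return(list(flags = x$flags, n_items_reviewed = x$n_items_reviewed,
                potential_error_rate = x$potential_error_rate,
                retraining_indicated = x$retraining_indicated,
                item_threshold = x$item_threshold,
                rate_threshold = x$rate_threshold,
                by_reviewer = x$by_reviewer))
  if (inherits(x, "intake_report"))
    return(list(scope = x$scope, id = x$id, served = as.list(x$served),
                consumed = as.list(x$consumed), lines = x$lines))
  if (inherits(x, "label_resolution"))
    return(list(n_flips = x$n_flips, flips = x$flips, records = x$records))
  stop("don't know how to export an object of class ", class(x)[1])
}
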