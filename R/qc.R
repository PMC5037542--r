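#' Flag discrepancies between bedside estimates and photo review
#'
#' A second rater periodically re-estimates percent consumed from the tray
#' photographs. An item is flagged when the absolute difference between the
#' bedside and photo-review percentages exceeds `item_threshold` (strictly
#' greater than). Retraining is indicated once the potential-error rate
#' reaches `rate_threshold` (greater than or equal). Both thresholds are
#' applied to the pooled review set and, when `reviewer_id` is present,
#' per reviewer as well.
#'
#' @param comparisons Data.frame with columns `tray_id`, `item_id`,
#'   `primary_pct`, `review_pct`, and optionally `reviewer_id`
#'   (see [read_review_comparisons()]).
#' @param item_threshold Flagging threshold in percentage points
#'   (default 15; strict `>`).
#' @param rate_threshold Retraining trigger as a fraction of reviewed items
#'   (default 0.05; trigger at `>=`).
#' @return A `qc_report`: `flags` (tray, item, absolute difference),
#'   `n_items_reviewed`, `potential_error_rate`, `retraining_indicated`, and
#'   a `by_reviewer` breakdown when reviewer ids are available.
#' @examples
#' cmp <- data.frame(tray_id = "T1", item_id = paste0("I", 1:10),
#'                   primary_pct = c(50, rep(80, 9)),
#'                   review_pct  = c(70, rep(80, 9)))
#' flag_discrepancies(cmp)
#' @export
flag_discrepancies <- function(comparisons, item_threshold = 15,
                               rate_threshold = 0.05) {
  if (is.null(comparisons) || nrow(comparisons) == 0)
    stop("nothing to review")
  stopifnot(item_threshold > 0, rate_threshold > 0)
  p <- comparisons$primary_pct
  r <- comparisons$review_pct
  if (any(p != round(p) | r != round(r), na.rm = TRUE) ||
      any(p < 0 | p > 100 | r < 0 | r > 100, na.rm = TRUE) ||
      anyNA(p) || anyNA(r))
    stop("invalid percentage: review percentages must be integers in [0, 100]")
  d <- abs(p - r)
  hit <- d > item_threshold
  flags <- data.frame(tray_id = comparisons$tray_id[hit],
                      item_id = comparisons$item_id[hit],
                      abs_diff = d[hit], stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  rate <- nrow(flags) / nrow(comparisons)
  by_rev <- NULL
  if ("reviewer_id" %in% names(comparisons)) {
    by_rev <- do.call(rbind, lapply(split(hit, comparisons$reviewer_id), function(h)
      data.frame(n_items_reviewed = length(h), n_flags = sum(h),
                 potential_error_rate = mean(h),
                 retraining_indicated = mean(h) >= rate_threshold)))
    by_rev <- cbind(reviewer_id = rownames(by_rev), by_rev)
    rownames(by_rev) <- NULL
  }
  structure(list(flags = flags, n_items_reviewed = nrow(comparisons),
                 potential_error_rate = rate,
                 retraining_indicated = rate >= rate_threshold,
                 item_threshold = item_threshold,
                 rate_threshold = rate_threshold,
                 by_reviewer = by_rev),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC photo review: %d item(s) reviewed, %d flagged (|diff| > %g)\n",
              x$n_items_reviewed, nrow(x$flags), x$item_threshold))
  cat(sprintf("Potential error rate: %.1f%% (retraining trigger %.0f%%): %s\n",
              100 * x$potential_error_rate, 100 * x$rate_threshold,
              if (x$retraining_indicated) "RETRAINING INDICATED" else "ok"))
  if (!is.null(x$by_reviewer)) print.data.frame(x$by_reviewer, row.names = FALSE)
  invisible(x)
}

#' Resolve a disagreement between bedside and photo-review estimates
#'
#' The default is to accept the estimate made by direct observation; the
#' photo-review value replaces it only when the reviewer judged the original
#' an obvious error (a typo such as 100 entered for 10, or an omission).
#'
#' @param primary_pct Bedside (direct observation) percentage.
#' @param review_pct Photo-review percentage.
#' @param obvious_error Logical; did the reviewer identify an obvious error?
#' @return The resolved percentage.
#' @export
resolve_disagreement <- function(primary_pct, review_pct, obvious_error) {
  ok <- function(v) all(is.finite(v) & v >= 0 & v <= 100)
  if (!ok(primary_pct) || !ok(review_pct))
    stop("invalid percentage")
  ifelse(obvious_error, review_pct, primary_pct)
}

#' Rater proficiency check against weighed reference values
#'
#' Training continues until a rater's meal-energy estimates are generally
#' within `tolerance` (default 15%) of the estimates based on weighing all
#' food items. "Generally" is operationalized as a configurable proportion
#' of trays (`pass_quantile`), with the conservative default requiring every
#' tray to be within tolerance.
#'
#' @param rater_estimates Vector of the rater's meal-energy estimates (kcal).
#' @param weighed_values Paired vector of weighed reference energies (kcal).
#' @param tolerance Maximum relative error per tray (default 0.15).
#' @param pass_quantile Minimum proportion of trays that must be within
#'   tolerance for a pass (default 1.0).
#' @return A list with `pass`, `prop_within`, and a per-tray data.frame of
#'   relative errors (`ratios`). Trays with a zero weighed value are excluded
#'   with a warning (their ratio is undefined).
#' @export
proficiency_check <- function(rater_estimates, weighed_values,
                              tolerance = 0.15, pass_quantile = 1.0) {
  if (length(rater_estimates) != length(weighed_values))
    stop("estimates and weighed values must be paired")
  zero <- weighed_values == 0
  if (any(zero)) {
    warning(sum(zero), " tray(s) with weighed value 0 excluded (ratio undefined)")
    rater_estimates <- rater_estimates[!zero]
    weighed_values <- weighed_values[!zero]
  }
  if (!length(weighed_values)) stop("no trays with a defined ratio")
  rel <- abs(rater_estimates - weighed_values) / weighed_values
  ratios <- data.frame(estimate = rater_estimates, weighed = weighed_values,
                       rel_error = rel, within = rel <= tolerance)
  prop <- mean(ratios$within)
  list(pass = prop >= pass_quantile, prop_within = prop, ratios = ratios)
}
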