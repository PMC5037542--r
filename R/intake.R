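#' Percent of a food item consumed, from pre/post meal weights
#'
#' The reference ("weighed") measurement of consumption:
#' `((original - leftover) / original) * 100`. The exact value is returned;
#' rounding, if any, is the caller's choice.
#'
#' @param original_g Weight of the item as served, grams (> 0). Vectorized.
#' @param leftover_g Weight remaining after the meal, grams
#'   (`0 <= leftover_g <= original_g`).
#' @return Numeric percentage(s) in `[0, 100]`.
#' @examples
#' weighed_consumption_pct(250, 100)  # 60
#' @export
weighed_consumption_pct <- function(original_g, leftover_g) {
  if (length(original_g) != length(leftover_g))
    stop("original and leftover weights must be paired")
  if (any(!is.finite(original_g)) || any(!is.finite(leftover_g)) ||
      any(leftover_g < 0))
    stop("invalid weights")
  if (any(original_g <= 0))
    stop("undefined consumption: original weight must be positive")
  if (any(leftover_g > original_g))
    stop("invalid weights: leftover exceeds original")
  (original_g - leftover_g) / original_g * 100
}

#' Nutrients consumed on one NIAF line
#'
#' Scales the item's per-serving profile by servings and recorded percent
#' consumed: every nutrient equals `profile * servings * pct / 100`.
#'
#' @param line One NIAF line (a one-row data.frame or list with `servings`
#'   and `pct_consumed`).
#' @param item The matching food-database row.
#' @return Named numeric vector of consumed nutrient amounts.
#' @export
line_consumed_profile <- function(line, item) {
  pct <- line$pct_consumed
  if (is.null(pct) || is.na(pct))
    stop("consumption not recorded for item ", line$item_id)
  nut <- nutrient_names(item)
  prof <- as.numeric(item[1, nut]) * line$servings * pct / 100
  names(prof) <- nut
  prof
}

new_intake_report <- function(scope, id, served, consumed, lines) {
  structure(list(scope = scope, id = id, served = served,
                 consumed = consumed, lines = lines),
            class = "intake_report")
}

#' Calorie-count report for one meal
#'
#' Converts a fully recorded NIAF into per-nutrient served and consumed
#' totals, with a per-line breakdown. Served totals treat every line —
#' including mid-meal additions, which did reach the patient — at 100%.
#'
#' @param niaf A fully recorded `niaf`.
#' @param db The [food_db()] object resolving the form's items.
#' @return An `intake_report` with elements `scope` (`"meal"`), `served` and
#'   `consumed` (named numeric totals per nutrient), and `lines` (per-line
#'   served/consumed energy breakdown).
#' @examples
#' db <- read_food_db(system.file("extdata", "food_db.csv", package = "mealcount"))
#' cyc <- read_menu_cycle(system.file("extdata", "menu_cycle.json", package = "mealcount"))
#' n <- generate_niaf(db, cyc, "regular_1800", 1, "breakfast", "T1", "P1")
#' n <- record_consumption(n, stats::setNames(rep(100L, nrow(n$lines)), n$lines$item_id))
#' meal_report(n, db)
#' @export
meal_report <- function(niaf, db) {
  stopifnot(inherits(niaf, "niaf"), inherits(db, "food_db"))
  nut <- nutrient_names(db)
  zero <- stats::setNames(numeric(length(nut)), nut)
  if (nrow(niaf$lines) == 0)
    return(new_intake_report("meal",
                             list(tray_id = niaf$tray_id, patient_id = niaf$patient_id,
                                  date = niaf$date, meal = niaf$meal),
                             zero, zero, data.frame()))
  if (anyNA(niaf$lines$pct_consumed))
    stop("incomplete NIAF: ",
         paste(niaf$lines$item_id[is.na(niaf$lines$pct_consumed)], collapse = ", "),
         " not recorded")
  items <- db_lookup(db, niaf$lines$item_id)
  prof <- as.matrix(items[, nut, drop = FALSE])
  prof[is.na(prof)] <- 0
  served_m <- prof * niaf$lines$servings
  consumed_m <- served_m * niaf$lines$pct_consumed / 100
  lines <- data.frame(item_id = niaf$lines$item_id,
                      description = items$description,
                      servings = niaf$lines$servings,
                      pct_consumed = niaf$lines$pct_consumed,
                      origin = niaf$lines$origin,
                      served_kcal = served_m[, "energy_kcal"],
                      consumed_kcal = consumed_m[, "energy_kcal"],
                      stringsAsFactors = FALSE)
  rownames(lines) <- NULL
  new_intake_report("meal",
                    list(tray_id = niaf$tray_id, patient_id = niaf$patient_id,
                         date = niaf$date, meal = niaf$meal),
                    colSums(served_m), colSums(consumed_m), lines)
}

#' Calorie-count report for a whole day
#'
#' Sums the meal reports of all NIAFs (meals, snacks, outside foods) for one
#' patient on one date. Totals are exactly the sum of the constituent meal
#' totals.
#'
#' @param niafs List of fully recorded `niaf` objects sharing patient and date.
#' @param db The [food_db()] object.
#' @return An `intake_report` with `scope = "day"`.
#' @export
day_report <- function(niafs, db) {
  stopifnot(length(niafs) > 0)
  pat <- unique(vapply(niafs, function(n) n$patient_id, character(1)))
  dat <- unique(vapply(niafs, function(n) as.character(n$date), character(1)))
  if (length(pat) > 1 || length(dat) > 1)
    stop("inconsistent scope: NIAFs span multiple patients or dates")
  reps <- lapply(niafs, meal_report, db = db)
  served <- Reduce(`+`, lapply(reps, `[[`, "served"))
  consumed <- Reduce(`+`, lapply(reps, `[[`, "consumed"))
  lines <- do.call(rbind, lapply(seq_along(reps), function(i) {
    ln <- reps[[i]]$lines
    if (nrow(ln)) cbind(meal = niafs[[i]]$meal, ln, stringsAsFactors = FALSE)
  }))
  new_intake_report("day", list(patient_id = pat, date = dat),
                    served, consumed, lines)
}

#' Total energy consumed at a meal, from weighed-food records
#'
#' The reference-standard meal energy: for each item,
#' `energy_per_gram * (original_g - leftover_g)`, where the energy density
#' comes from the food database's `energy_kcal` and `serving_weight_g`.
#'
#' @param records Data.frame with columns `item_id`, `original_g`,
#'   `leftover_g` (see [read_weighed_records()]).
#' @param db A [food_db()] with a complete `serving_weight_g` column for the
#'   items involved.
#' @return Total consumed energy in kcal.
#' @export
weighed_meal_energy <- function(records, db) {
  stopifnot(inherits(db, "food_db"))
  if (!"serving_weight_g" %in% names(db))
    stop("no gram basis for item: food database lacks serving_weight_g")
  items <- db_lookup(db, records$item_id)
  if (anyNA(items$serving_weight_g) || any(items$serving_weight_g <= 0))
    stop("no gram basis for item: ",
         paste(items$item_id[is.na(items$serving_weight_g) |
                               items$serving_weight_g <= 0], collapse = ", "))
  pct <- weighed_consumption_pct(records$original_g, records$leftover_g)
  served_kcal <- items$energy_kcal / items$serving_weight_g * records$original_g
  sum(served_kcal * pct / 100)
}

#' @export
print.intake_report <- function(x, ...) {
  hdr <- if (x$scope == "meal")
    sprintf("Meal calorie count - tray %s, patient %s, %s",
            x$id$tray_id, x$id$patient_id, x$id$meal)
  else
    sprintf("Day calorie count - patient %s, %s", x$id$patient_id, x$id$date)
  cat(hdr, "\n")
  cat(sprintf("  Energy served:   %8.1f kcal\n", x$served[["energy_kcal"]]))
  cat(sprintf("  Energy consumed: %8.1f kcal\n", x$consumed[["energy_kcal"]]))
  other <- setdiff(names(x$served), "energy_kcal")
  if (length(other)) {
    tab <- data.frame(nutrient = other,
                      served = round(as.numeric(x$served[other]), 1),
                      consumed = round(as.numeric(x$consumed[other]), 1))
    print.data.frame(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.intake_report <- function(x, ...) {
  data.frame(scope = x$scope, nutrient = names(x$served),
             served = as.numeric(x$served),
             consumed = as.numeric(x$consumed),
             row.names = NULL, stringsAsFactors = FALSE)
}
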