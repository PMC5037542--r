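#' @keywords internal
new_niaf <- function(tray_id, patient_id, date, meal, diet_id, lines,
                     photo_pre = NULL, photo_post = NULL,
                     status = "generated", audit = list()) {
  structure(list(tray_id = tray_id, patient_id = patient_id, date = date,
                 meal = meal, diet_id = diet_id, lines = lines,
                 photo_pre = photo_pre, photo_post = photo_post,
                 status = status, audit = audit),
            class = "niaf")
}

niaf_statuses <- c("generated", "verified", "recorded", "finalized")

empty_lines <- function() {
  data.frame(item_id = character(), servings = numeric(),
             pct_consumed = integer(), origin = character(),
             stringsAsFactors = FALSE)
}

#' Generate a Nutritional Intake Assessment Form (NIAF)
#'
#' Builds the per-tray checklist of foods scheduled to be served to a
#' patient at one meal, from the menu cycle and food database. Each line
#' starts with `origin = "menu"` and an unrecorded percent consumed; the
#' form starts in status `"generated"`.
#'
#' @param db A [food_db()] object.
#' @param cycle A [menu_cycle()] object.
#' @param diet_id,cycle_day,meal The menu slot to serve.
#' @param tray_id,patient_id Identifiers for the tray and patient.
#' @param date Calendar date as an ISO `"YYYY-MM-DD"` string (kept verbatim).
#' @return An object of class `niaf`.
#' @examples
#' db <- read_food_db(system.file("extdata", "food_db.csv", package = "mealcount"))
#' cyc <- read_menu_cycle(system.file("extdata", "menu_cycle.json", package = "mealcount"))
#' generate_niaf(db, cyc, "regular_1800", 1, "breakfast", "T1", "P1", "2016-03-01")
#' @export
generate_niaf <- function(db, cycle, diet_id, cycle_day, meal,
                          tray_id, patient_id, date = NA_character_) {
  stopifnot(inherits(db, "food_db"), inherits(cycle, "menu_cycle"))
  e <- cycle$entries
  sel <- e$cycle_day == cycle_day & e$meal == meal & e$diet_id == diet_id
  if (!any(sel))
    stop("menu entry missing for (day ", cycle_day, ", ", meal, ", ", diet_id, ")")
  slot <- e[sel, , drop = FALSE]
  unknown <- setdiff(slot$item_id, db$item_id)
  if (length(unknown))
    stop("unknown food item: ", paste(unknown, collapse = ", "))
  lines <- data.frame(item_id = slot$item_id, servings = slot$servings,
                      pct_consumed = NA_integer_, origin = "menu",
                      stringsAsFactors = FALSE)
  rownames(lines) <- NULL
  new_niaf(tray_id, patient_id, date, meal, diet_id, lines)
}

audit_append <- function(niaf, action, detail) {
  niaf$audit[[length(niaf$audit) + 1L]] <-
    list(seq = length(niaf$audit) + 1L, action = action, detail = detail)
  niaf
}

check_editable <- function(niaf) {
  if (!niaf$status %in% c("generated", "verified", "recorded"))
    stop("NIAF is finalized and can no longer be edited")
}

#' Edit a NIAF at the bedside
#'
#' `edit_niaf()` dispatches to one of the three edit primitives so the tray
#' record can be made to match exactly what the patient received. Every edit
#' is appended to the form's audit trail.
#'
#' `niaf_add_line()` adds a food item; the item must exist in the database
#' (outside foods are first registered with [food_db_add_item()], which keeps
#' them available for future use). `niaf_remove_line()` deletes a line;
#' `niaf_change_servings()` rescales one.
#'
#' @param niaf A `niaf` object with status before `"finalized"`.
#' @param edit One of `"add_line"`, `"remove_line"`, `"change_servings"`.
#' @param ... Passed to the corresponding primitive.
#' @param db A [food_db()] object (for additions).
#' @param item_id Line identifier.
#' @param servings Positive number of servings.
#' @param origin Provenance of an added line: `"bedside_edit"`,
#'   `"outside_food"`, or `"mid_meal_addition"`.
#' @return The updated `niaf`.
#' @export
edit_niaf <- function(niaf, edit = c("add_line", "remove_line", "change_servings"),
                      ...) {
  edit <- match.arg(edit)
  switch(edit,
         add_line = niaf_add_line(niaf, ...),
         remove_line = niaf_remove_line(niaf, ...),
         change_servings = niaf_change_servings(niaf, ...))
}

#' @rdname edit_niaf
#' @export
niaf_add_line <- function(niaf, db, item_id, servings = 1,
                          origin = c("bedside_edit", "outside_food",
                                     "mid_meal_addition")) {
  stopifnot(inherits(niaf, "niaf"))
  check_editable(niaf)
  origin <- match.arg(origin)
  item_id <- as.character(item_id)
  if (item_id %in% niaf$lines$item_id)
    stop("duplicate line: ", item_id)
  db_lookup(db, item_id)  # errors on unknown item
  if (servings <= 0) stop("servings must be positive")
  niaf$lines <- rbind(niaf$lines,
                      data.frame(item_id = item_id, servings = servings,
                                 pct_consumed = NA_integer_, origin = origin,
                                 stringsAsFactors = FALSE))
  rownames(niaf$lines) <- NULL
  audit_append(niaf, "add_line",
               paste0(item_id, " x", servings, " (", origin, ")"))
}

#' @rdname edit_niaf
#' @export
niaf_remove_line <- function(niaf, item_id) {
  stopifnot(inherits(niaf, "niaf"))
  check_editable(niaf)
  i <- match(as.character(item_id), niaf$lines$item_id)
  if (is.na(i)) stop("line not found: ", item_id)
  niaf$lines <- niaf$lines[-i, , drop = FALSE]
  rownames(niaf$lines) <- NULL
  audit_append(niaf, "remove_line", as.character(item_id))
}

#' @rdname edit_niaf
#' @export
niaf_change_servings <- function(niaf, item_id, servings) {
  stopifnot(inherits(niaf, "niaf"))
  check_editable(niaf)
  i <- match(as.character(item_id), niaf$lines$item_id)
  if (is.na(i)) stop("line not found: ", item_id)
  if (servings <= 0) stop("servings must be positive")
  old <- niaf$lines$servings[i]
  niaf$lines$servings[i] <- servings
  audit_append(niaf, "change_servings",
               paste0(item_id, ": ", old, " -> ", servings))
}

#' Record the percentage of each food item consumed
#'
#' Raters score consumption on a continuous 0--100 scale rounded to the
#' nearest integer; fractional input is rejected rather than rounded, so the
#' recorded value is always exactly what the rater entered. Partial entry is
#' allowed (e.g. a shift handoff): the form reaches status `"recorded"` only
#' once every line has a percentage.
#'
#' @param niaf A `niaf` object.
#' @param entries Named vector or list mapping `item_id` to an integer
#'   percentage in `[0, 100]`.
#' @return The updated `niaf`.
#' @export
record_consumption <- function(niaf, entries) {
  stopifnot(inherits(niaf, "niaf"))
  check_editable(niaf)
  entries <- unlist(entries)
  ids <- names(entries)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("entries must be named by item_id")
  i <- match(ids, niaf$lines$item_id)
  if (anyNA(i))
    stop("line not found: ", paste(ids[is.na(i)], collapse = ", "))
  pct <- as.numeric(entries)
  if (any(!is.finite(pct)) || any(pct != round(pct)) ||
      any(pct < 0) || any(pct > 100))
    stop("invalid percentage: must be an integer in [0, 100]")
  niaf$lines$pct_consumed[i] <- as.integer(pct)
  niaf <- audit_append(niaf, "record_consumption",
                       paste(ids, pct, sep = "=", collapse = ", "))
  if (!anyNA(niaf$lines$pct_consumed) && nrow(niaf$lines) > 0 &&
      niaf$status %in% c("generated", "verified"))
    niaf$status <- "recorded"
  niaf
}

#' Advance a NIAF through its status lifecycle
#'
#' Statuses move only forward: generated, verified, recorded, finalized.
#' `verify_niaf()` marks the bedside check against the delivered tray done;
#' `finalize_niaf()` locks the form after photo review and data entry.
#'
#' @param niaf A `niaf` object.
#' @param photo_pre,photo_post Optional opaque photo references
#'   (path + timestamp strings); images are never decoded.
#' @return The updated `niaf`.
#' @export
verify_niaf <- function(niaf, photo_pre = NULL) {
  stopifnot(inherits(niaf, "niaf"))
  if (match(niaf$status, niaf_statuses) > 1L)
    stop("status transitions only move forward")
  if (!is.null(photo_pre)) niaf$photo_pre <- photo_pre
  niaf$status <- "verified"
  audit_append(niaf, "verify", "bedside check complete")
}

#' @rdname verify_niaf
#' @export
finalize_niaf <- function(niaf, photo_post = NULL) {
  stopifnot(inherits(niaf, "niaf"))
  if (niaf$status != "recorded")
    stop("only a fully recorded NIAF can be finalized")
  if (!is.null(photo_post)) niaf$photo_post <- photo_post
  niaf$status <- "finalized"
  audit_append(niaf, "finalize", "locked")
}

#' Write / read a NIAF as JSON
#'
#' The JSON document carries all fields including the audit trail;
#' `read_niaf(write_niaf(x, path))` reproduces `x` exactly.
#'
#' @param niaf A `niaf` object.
#' @param path File path.
#' @return `write_niaf()` returns `path` invisibly; `read_niaf()` a `niaf`.
#' @export
write_niaf <- function(niaf, path) {
  x <- unclass(niaf)
  x$lines <- lapply(seq_len(nrow(niaf$lines)), function(i) {
    ln <- as.list(niaf$lines[i, ])
    if (is.na(ln$pct_consumed)) ln$pct_consumed <- NULL
    ln
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_niaf
#' @export
read_niaf <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lines <- if (length(x$lines)) {
    do.call(rbind, lapply(x$lines, function(ln)
      data.frame(item_id = ln$item_id, servings = as.numeric(ln$servings),
                 pct_consumed = if (is.null(ln$pct_consumed)) NA_integer_
                                else as.integer(ln$pct_consumed),
                 origin = ln$origin, stringsAsFactors = FALSE)))
  } else empty_lines()
  rownames(lines) <- NULL
  audit <- lapply(x$audit, function(a)
    list(seq = as.integer(a$seq), action = a$action, detail = a$detail))
  new_niaf(x$tray_id, x$patient_id,
           if (is.null(x$date)) NA_character_ else x$date,
           x$meal, x$diet_id, lines,
           photo_pre = x$photo_pre, photo_post = x$photo_post,
           status = x$status, audit = audit)
}

#' @export
as.data.frame.niaf <- function(x, ...) {
  if (nrow(x$lines) == 0) {
    out <- cbind(data.frame(tray_id = character(), patient_id = character(),
                            date = character(), meal = character(),
                            diet_id = character()), empty_lines())
    return(out)
  }
  cbind(data.frame(tray_id = x$tray_id, patient_id = x$patient_id,
                   date = x$date, meal = x$meal, diet_id = x$diet_id,
                   stringsAsFactors = FALSE),
        x$lines, row.names = NULL)
}

#' @export
print.niaf <- function(x, ...) {
  cat(sprintf("NIAF %s  patient %s  %s %s  diet %s  [%s]\n",
              x$tray_id, x$patient_id,
              ifelse(is.na(x$date), "<no date>", x$date),
              x$meal, x$diet_id, x$status))
  if (nrow(x$lines)) print.data.frame(x$lines) else cat("  (no lines)\n")
  if (length(x$audit)) cat("Audit trail:", length(x$audit), "entries\n")
  invisible(x)
}
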