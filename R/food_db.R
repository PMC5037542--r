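#' Construct a food-composition database
#'
#' A food database holds one row per food item with its per-serving nutrient
#' profile: energy (kcal), protein, saturated and unsaturated fat,
#' carbohydrate (all grams), and any number of additional micronutrient
#' columns. The optional `serving_weight_g` column gives the as-served weight
#' of one serving and is required only for weighed-food workflows
#' (see [weighed_meal_energy()]).
#'
#' @param x A data.frame with columns `item_id`, `description`,
#'   `serving_label`, `energy_kcal`, `protein_g`, `fat_sat_g`, `fat_unsat_g`,
#'   `carb_g`, optionally `serving_weight_g`, and any further numeric
#'   nutrient columns (e.g. `sodium_mg`, `vitamin_c_mg`).
#' @return An object of class `food_db` (a validated data.frame).
#' @examples
#' db <- read_food_db(system.file("extdata", "food_db.csv", package = "mealcount"))
#' db
#' @export
food_db <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("item_id", "description", "serving_label", "energy_kcal",
           "protein_g", "fat_sat_g", "fat_unsat_g", "carb_g")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("food database missing column(s): ", paste(miss, collapse = ", "))
  x$item_id <- as.character(x$item_id)
  if (anyDuplicated(x$item_id))
    stop("duplicate item_id in food database")
  if (any(is.na(x$description) | !nzchar(x$description)))
    stop("empty description in food database")
  num_cols <- setdiff(names(x), c("item_id", "description", "serving_label"))
  for (cl in num_cols) {
    v <- x[[cl]]
    if (!is.numeric(v))
      stop("non-numeric nutrient column: ", cl)
    if (any(v[!is.na(v)] < 0))
      stop("negative nutrient amount in column: ", cl)
  }
  if (any(!is.finite(x$energy_kcal)))
    stop("energy must be finite for every item")
  class(x) <- c("food_db", "data.frame")
  x
}

#' Read a food database from CSV or JSON
#'
#' The CSV dialect is UTF-8, comma-separated, with a header row. The JSON
#' dialect is an array of item objects with the same field names.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return A [food_db()] object.
#' @export
read_food_db <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
  } else {
    x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  food_db(x)
}

#' Write a food database
#'
#' @param db A [food_db()] object.
#' @param path Output path; `.json` writes the JSON dialect, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(db), path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(db, path, row.names = FALSE)
  }
  invisible(path)
}

#' Add a food item (e.g. an outside food) to the database
#'
#' Non-institutional foods brought in from outside the hospital are added
#' with a complete nutrient profile so they can be reused on later forms.
#'
#' @param db A [food_db()] object.
#' @param item_id Unique identifier for the new item.
#' @param description Human-readable description (non-empty).
#' @param serving_label Serving description, e.g. `"1 bar"`.
#' @param energy_kcal,protein_g,fat_sat_g,fat_unsat_g,carb_g Per-serving
#'   macronutrients; all non-negative, energy finite.
#' @param serving_weight_g Optional as-served weight of one serving (g).
#' @param ... Further named micronutrient amounts matching existing columns
#'   (unmatched columns are filled with `NA` for other items).
#' @return The updated `food_db`.
#' @export
food_db_add_item <- function(db, item_id, description, serving_label = "1 serving",
                             energy_kcal, protein_g = 0, fat_sat_g = 0,
                             fat_unsat_g = 0, carb_g = 0,
                             serving_weight_g = NA_real_, ...) {
  stopifnot(inherits(db, "food_db"))
  if (item_id %in% db$item_id)
    stop("duplicate item_id: ", item_id)
  extra <- list(...)
  row <- data.frame(item_id = as.character(item_id), description = description,
                    serving_label = serving_label, energy_kcal = energy_kcal,
                    protein_g = protein_g, fat_sat_g = fat_sat_g,
                    fat_unsat_g = fat_unsat_g, carb_g = carb_g,
                    stringsAsFactors = FALSE)
  if ("serving_weight_g" %in% names(db) || !is.na(serving_weight_g))
    row$serving_weight_g <- serving_weight_g
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  all_cols <- union(names(db), names(row))
  for (nm in setdiff(all_cols, names(db))) db[[nm]] <- NA_real_
  for (nm in setdiff(all_cols, names(row))) row[[nm]] <- NA_real_
  out <- rbind(as.data.frame(db)[all_cols], row[all_cols])
  food_db(out)
}

#' Names of the nutrient columns of a food database
#'
#' @param db A [food_db()] object.
#' @return Character vector of nutrient column names (energy first).
#' @export
nutrient_names <- function(db) {
  setdiff(names(db), c("item_id", "description", "serving_label", "serving_weight_g"))
}

#' @export
print.food_db <- function(x, ...) {
  cat("Food database:", nrow(x), "items,",
      length(nutrient_names(x)), "nutrient columns\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more items\n")
  invisible(x)
}

db_lookup <- function(db, item_id) {
  i <- match(as.character(item_id), db$item_id)
  if (anyNA(i)) stop("unknown food item: ",
                     paste(item_id[is.na(i)], collapse = ", "))
  db[i, , drop = FALSE]
}

#' Construct a menu cycle
#'
#' A menu cycle maps (cycle day, meal, diet) to the list of items served,
#' keyed by integer cycle day rather than calendar date; mapping calendar
#' dates onto cycle days is site configuration.
#'
#' @param cycle_id Identifier for the cycle.
#' @param entries A data.frame with columns `cycle_day` (integer >= 1),
#'   `meal` (one of breakfast/lunch/dinner), `diet_id`, `item_id`,
#'   `servings` (> 0).
#' @return An object of class `menu_cycle`.
#' @export
menu_cycle <- function(cycle_id, entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  req <- c("cycle_day", "meal", "diet_id", "item_id", "servings")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("menu cycle missing column(s): ", paste(miss, collapse = ", "))
  if (any(entries$cycle_day < 1 | entries$cycle_day != as.integer(entries$cycle_day)))
    stop("cycle_day must be a positive integer")
  bad <- setdiff(entries$meal, c("breakfast", "lunch", "dinner"))
  if (length(bad)) stop("unknown meal: ", paste(bad, collapse = ", "))
  if (any(entries$servings <= 0)) stop("servings must be positive")
  structure(list(cycle_id = cycle_id, entries = entries), class = "menu_cycle")
}

#' Read a menu cycle from JSON
#'
#' Expects `{"cycle_id": ..., "entries": {"<day>": {"<meal>": {"<diet>":`
#' `[{"item_id": ..., "servings": ...}, ...]}}}}`.
#'
#' @param path Path to the JSON file.
#' @return A [menu_cycle()] object.
#' @export
read_menu_cycle <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (day in names(x$entries)) {
    for (meal in names(x$entries[[day]])) {
      for (diet in names(x$entries[[day]][[meal]])) {
        for (it in x$entries[[day]][[meal]][[diet]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            cycle_day = as.integer(day), meal = meal, diet_id = diet,
            item_id = as.character(it$item_id), servings = as.numeric(it$servings),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  menu_cycle(x$cycle_id, do.call(rbind, rows))
}

#' Write a menu cycle to JSON
#'
#' @param cycle A [menu_cycle()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_menu_cycle <- function(cycle, path) {
  e <- cycle$entries
  days <- list()
  for (day in sort(unique(e$cycle_day))) {
    meals <- list()
    for (meal in unique(e$meal[e$cycle_day == day])) {
      diets <- list()
      sub <- e[e$cycle_day == day & e$meal == meal, ]
      for (diet in unique(sub$diet_id)) {
        s2 <- sub[sub$diet_id == diet, ]
        diets[[diet]] <- lapply(seq_len(nrow(s2)), function(i)
          list(item_id = s2$item_id[i], servings = s2$servings[i]))
      }
      meals[[meal]] <- diets
    }
    days[[as.character(day)]] <- meals
  }
  jsonlite::write_json(list(cycle_id = cycle$cycle_id, entries = days),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.menu_cycle <- function(x, ...) {
  cat("Menu cycle", x$cycle_id, "-", nrow(x$entries), "entries over",
      length(unique(x$entries$cycle_day)), "cycle day(s)\n")
  invisible(x)
}
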