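test_that("generate_niaf builds one line per menu entry with unrecorded pcts", {
  n <- toy_niaf()
  expect_s3_class(n, "niaf")
  expect_equal(nrow(n$lines), 2)
  expect_setequal(n$lines$item_id, c("soup", "bread"))
  expect_true(all(is.na(n$lines$pct_consumed)))
  expect_true(all(n$lines$origin == "menu"))
  expect_identical(n$status, "generated")
})

test_that("generate_niaf is deterministic and validates the menu slot", {
  a <- generate_niaf(toy_db(), toy_cycle(), "regular", 1, "lunch", "T1", "P1")
  b <- generate_niaf(toy_db(), toy_cycle(), "regular", 1, "lunch", "T1", "P1")
  expect_identical(a$lines, b$lines)
  expect_error(generate_niaf(toy_db(), toy_cycle(), "regular", 2, "lunch", "T", "P"),
               "menu entry missing")
  expect_error(generate_niaf(toy_db(), toy_cycle(), "npo", 1, "lunch", "T", "P"),
               "menu entry missing")
  cyc <- menu_cycle("bad", data.frame(cycle_day = 1L, meal = "dinner",
                                      diet_id = "regular", item_id = "ghost",
                                      servings = 1))
  expect_error(generate_niaf(toy_db(), cyc, "regular", 1, "dinner", "T", "P"),
               "unknown food item")
})

test_that("bedside edits update lines, enforce uniqueness, and log an audit trail", {
  n <- toy_niaf()
  n <- edit_niaf(n, "add_line", db = toy_db(), item_id = "juice",
                 origin = "outside_food")
  expect_equal(nrow(n$lines), 3)
  expect_identical(n$lines$origin[3], "outside_food")
  expect_error(niaf_add_line(n, toy_db(), "juice"), "duplicate line")
  n <- niaf_change_servings(n, "soup", 2)
  expect_equal(n$lines$servings[n$lines$item_id == "soup"], 2)
  n <- niaf_remove_line(n, "bread")
  expect_error(niaf_remove_line(n, "bread"), "line not found")
  # audit trail length equals the number of applied edits
  expect_length(n$audit, 3)
})

test_that("outside foods registered in the db are reusable with full profiles", {
  db <- food_db_add_item(toy_db(), "granola_bar", "Granola bar", "1 bar",
                         energy_kcal = 190, protein_g = 4, fat_sat_g = 2,
                         fat_unsat_g = 5, carb_g = 28)
  expect_true("granola_bar" %in% db$item_id)
  n <- niaf_add_line(toy_niaf(), db, "granola_bar", origin = "outside_food")
  n <- record_consumption(n, c(soup = 100L, bread = 100L, granola_bar = 50L))
  rep <- meal_report(n, db)
  expect_equal(unname(rep$consumed[["energy_kcal"]]), 200 + 300 + 95)
})

test_that("record_consumption validates entries and drives the status lifecycle", {
  n <- toy_niaf()
  expect_error(record_consumption(n, c(soup = 150)), "invalid percentage")
  expect_error(record_consumption(n, c(soup = 50.5)), "invalid percentage")
  expect_error(record_consumption(n, c(ghost = 10)), "line not found")
  part <- record_consumption(n, c(soup = 40L))
  expect_identical(part$status, "generated")  # partial entry: below recorded
  full <- record_consumption(part, c(bread = 100L))
  expect_identical(full$status, "recorded")
  expect_equal(full$lines$pct_consumed, c(40L, 100L))
  done <- finalize_niaf(full)
  expect_identical(done$status, "finalized")
  expect_error(record_consumption(done, c(soup = 10)), "finalized")
  expect_error(verify_niaf(done), "forward")
})

test_that("NIAF JSON serialization round-trips bit-exactly", {
  n <- toy_niaf(c(soup = 60L))
  n <- verify_niaf(n, photo_pre = list(path = "pre.jpg",
                                       timestamp = "2016-03-01T08:01:00"))
  path <- withr::local_tempfile(fileext = ".json")
  write_niaf(n, path)
  expect_identical(read_niaf(path), n)

  # empty-lines and no-audit edge
  e <- toy_niaf()
  e$lines <- e$lines[0, ]
  write_niaf(e, path)
  back <- read_niaf(path)
  expect_equal(nrow(back$lines), 0)
})

test_that("flat data.frame export carries tray metadata on every line", {
  d <- as.data.frame(toy_niaf(c(soup = 25L, bread = 75L)))
  expect_equal(nrow(d), 2)
  expect_true(all(d$tray_id == "T1"))
  expect_equal(d$pct_consumed, c(25L, 75L))
})

test_that("food db and menu cycle readers validate and round-trip", {
  db <- toy_db()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_food_db(db, csv)
  write_food_db(db, js)
  expect_equal(read_food_db(csv)$energy_kcal, db$energy_kcal)
  expect_equal(read_food_db(js)$item_id, db$item_id)
  expect_error(food_db(data.frame(item_id = c("a", "a"), description = "x",
                                  serving_label = "s", energy_kcal = 1,
                                  protein_g = 0, fat_sat_g = 0,
                                  fat_unsat_g = 0, carb_g = 0)),
               "duplicate item_id")
  expect_error(food_db(transform(as.data.frame(db), energy_kcal = -1)),
               "negative")
  cyc <- toy_cycle()
  jc <- withr::local_tempfile(fileext = ".json")
  write_menu_cycle(cyc, jc)
  back <- read_menu_cycle(jc)
  o <- function(e) e[order(e$cycle_day, e$meal, e$diet_id, e$item_id), ]
  expect_equal(o(back$entries), o(cyc$entries), ignore_attr = TRUE)
})
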