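test_that("weighed consumption percentage follows the weight-change formula", {
  expect_equal(weighed_consumption_pct(100, 0), 100)
  expect_equal(weighed_consumption_pct(100, 100), 0)
  expect_equal(weighed_consumption_pct(250, 100), 60)
  expect_equal(weighed_consumption_pct(c(100, 250), c(0, 100)), c(100, 60))
  expect_error(weighed_consumption_pct(0, 0), "undefined consumption")
  expect_error(weighed_consumption_pct(100, 150), "invalid weights")
  expect_error(weighed_consumption_pct(100, -1), "invalid weights")
})

test_that("line consumed profile is bilinear in servings and pct", {
  db <- toy_db()
  item <- db[db$item_id == "soup", ]  # 200 kcal/serving
  line <- list(item_id = "soup", servings = 1, pct_consumed = 50L)
  expect_equal(line_consumed_profile(line, item)[["energy_kcal"]], 100)
  two25 <- line_consumed_profile(list(servings = 2, pct_consumed = 25L), item)
  one50 <- line_consumed_profile(list(servings = 1, pct_consumed = 50L), item)
  expect_equal(two25, one50)
  zero <- line_consumed_profile(list(servings = 1, pct_consumed = 0L), item)
  expect_true(all(zero == 0))
  expect_error(line_consumed_profile(list(servings = 1, pct_consumed = NA), item),
               "consumption not recorded")
})

test_that("meal report sums line contributions for served and consumed", {
  # soup 200 kcal @50%, bread 300 kcal @100% -> consumed 400, served 500
  n <- toy_niaf(c(soup = 50L, bread = 100L))
  rep <- meal_report(n, toy_db())
  expect_equal(unname(rep$served[["energy_kcal"]]), 500)
  expect_equal(unname(rep$consumed[["energy_kcal"]]), 400)
  expect_equal(sum(rep$lines$consumed_kcal), 400)

  # all at 100%: consumed equals served for every nutrient
  full <- meal_report(toy_niaf(c(soup = 100L, bread = 100L)), toy_db())
  expect_equal(full$consumed, full$served)

  # unrecorded line blocks the report
  expect_error(meal_report(toy_niaf(c(soup = 50L)), toy_db()), "incomplete NIAF")

  # empty NIAF: zero totals
  e <- toy_niaf()
  e$lines <- e$lines[0, ]
  expect_true(all(meal_report(e, toy_db())$served == 0))
})

test_that("consumed never exceeds served, and pct scaling is linear", {
  db <- toy_db()
  set.seed(42)
  for (i in 1:25) {
    pcts <- sample(0:100, 2, replace = TRUE)
    n <- toy_niaf(c(soup = pcts[1], bread = pcts[2]))
    rep <- meal_report(n, db)
    expect_true(all(rep$consumed <= rep$served + 1e-12))
    # halving every pct (even pcts only) halves every consumed nutrient
    if (all(pcts %% 2 == 0)) {
      half <- meal_report(toy_niaf(c(soup = pcts[1] / 2, bread = pcts[2] / 2)), db)
      expect_equal(half$consumed, rep$consumed / 2)
    }
    # raising one pct never decreases any consumed total
    if (pcts[1] < 100) {
      up <- meal_report(toy_niaf(c(soup = pcts[1] + 1, bread = pcts[2])), db)
      expect_true(all(up$consumed >= rep$consumed - 1e-12))
    }
  }
})

test_that("day report is the exact sum of its meal reports", {
  db <- toy_db()
  b <- toy_niaf(c(soup = 50L, bread = 100L))
  l <- generate_niaf(db, toy_cycle(), "regular", 1, "lunch", "T2", "P1", "2016-03-01")
  l <- record_consumption(l, c(soup = 100L, juice = 100L))
  day <- day_report(list(b, l), db)
  expect_equal(day$consumed,
               meal_report(b, db)$consumed + meal_report(l, db)$consumed)
  expect_equal(day_report(list(b), db)$consumed, meal_report(b, db)$consumed)

  # an outside-food snack adds exactly energy * pct / 100
  db2 <- food_db_add_item(db, "bar", "Snack bar", "1 bar", energy_kcal = 190)
  s <- generate_niaf(db2, toy_cycle(), "regular", 1, "breakfast", "T3", "P1",
                     "2016-03-01")
  s$lines <- s$lines[0, ]
  s <- niaf_add_line(s, db2, "bar", origin = "outside_food")
  s <- record_consumption(s, c(bar = 50L))
  with_snack <- day_report(list(b, l, s), db2)
  expect_equal(with_snack$consumed[["energy_kcal"]],
               day$consumed[["energy_kcal"]] + 190 * 0.5)

  bad <- b; bad$patient_id <- "P9"
  expect_error(day_report(list(b, bad), db), "inconsistent scope")
})

test_that("weighed meal energy uses gram-denominated densities", {
  db <- toy_db()
  # soup: fully consumed -> its full 200 kcal
  expect_equal(weighed_meal_energy(
    data.frame(item_id = "soup", original_g = 250, leftover_g = 0), db), 200)
  # soup and bread each 50% consumed by weight: 100 + 150 = 250
  recs <- data.frame(item_id = c("soup", "bread"),
                     original_g = c(250, 50), leftover_g = c(125, 25))
  expect_equal(weighed_meal_energy(recs, db), 250)
  # nothing eaten
  expect_equal(weighed_meal_energy(
    data.frame(item_id = c("soup", "bread"), original_g = c(250, 50),
               leftover_g = c(250, 50)), db), 0)
  nodb <- toy_db()
  nodb$serving_weight_g <- NULL
  expect_error(weighed_meal_energy(recs, food_db(as.data.frame(nodb))),
               "no gram basis")
})
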