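test_that("simulation output is fully reproducible from the configuration", {
  cfg <- sim_config(seed = 123)
  expect_identical(simulate_tray(cfg, "T05"), simulate_tray(cfg, "T05"))
  set.seed(999)  # caller RNG state must not leak in
  expect_identical(simulate_strategy_b(cfg), simulate_strategy_b(cfg))
  expect_identical(simulate_strategy_d(cfg), simulate_strategy_d(cfg))
  # different seeds give different data
  expect_false(identical(simulate_strategy_b(cfg),
                         simulate_strategy_b(sim_config(seed = 124))))
})

test_that("a degenerate tray-energy distribution pins every tray total", {
  cfg <- sim_config(seed = 2, tray_energy = list(mean = 500, sd = 0, min = 100))
  for (tid in c("T01", "T02", "T03")) {
    tray <- simulate_tray(cfg, tid)
    expect_equal(sum(tray$items$energy_kcal), 500)
    expect_true(nrow(tray$items) >= 3 && nrow(tray$items) <= 8)
    expect_true(all(tray$items$energy_kcal >= 0))
  }
})

test_that("weighed records invert to the drawn consumption exactly", {
  cfg <- sim_config(seed = 4)
  tray <- simulate_tray(cfg, "T01")
  cons <- simulate_consumption(tray, cfg)
  expect_equal(weighed_consumption_pct(cons$original_g, cons$leftover_g),
               cons$true_pct)
  # degenerate consumption: everything eaten / nothing eaten
  all_cfg <- sim_config(seed = 4, consumption = list(shape1 = 1, shape2 = 1,
                                                     p_zero = 0, p_full = 1))
  c1 <- simulate_consumption(tray, all_cfg)
  expect_true(all(c1$leftover_g == 0))
  none_cfg <- sim_config(seed = 4, consumption = list(shape1 = 1, shape2 = 1,
                                                      p_zero = 1, p_full = 0))
  c0 <- simulate_consumption(tray, none_cfg)
  expect_equal(c0$leftover_g, c0$original_g)
})

test_that("rater estimates are integers, clipped, and track bias", {
  cfg0 <- sim_config(seed = 6, rater_noise_sd = 0, rater_bias = 0)
  truth <- c(0, 12.4, 55.5, 99.9, 100)
  expect_identical(simulate_rater_estimates(truth, cfg0),
                   as.integer(round(truth)))
  hi <- sim_config(seed = 6, rater_noise_sd = 30)
  est <- simulate_rater_estimates(rep(100, 500), hi)
  expect_true(all(est <= 100L & est >= 0L))
  biased <- sim_config(seed = 8, rater_noise_sd = 5, rater_bias = 10)
  err <- simulate_rater_estimates(rep(50, 2000), biased) - 50
  expect_equal(mean(err), 10, tolerance = 1)
})

test_that("the complete laboratory design has the 3 x 30 factorial shape", {
  b <- simulate_strategy_b(sim_config(seed = 11))
  expect_equal(nrow(b), 90)
  expect_equal(length(unique(b$tray_id)), 30)
  expect_equal(length(unique(b$rater_id)), 3)
  expect_true(all(table(b$tray_id, b$rater_id) == 1))
  expect_equal(sort(unique(b$day)), 1:5)
  expect_setequal(unique(b$meal), c("breakfast", "lunch", "dinner"))
  expect_setequal(unique(b$diet_id), c("regular", "full_liquid"))
  expect_true(all(b$true_value >= 0 & b$estimate >= 0))
  # noise-free raters agree with the weighed truth up to integer rounding
  exact <- simulate_strategy_b(sim_config(seed = 11, rater_noise_sd = 0))
  # each item's pct is rounded to an integer, so within 0.5 pct-pt per item
  expect_lt(max(abs(exact$estimate - exact$true_value)), 10)
})

test_that("the clinical design is incomplete with the stated incidence", {
  cc <- simulate_strategy_c(sim_config(seed = 12, n_raters = 6L))
  expect_equal(nrow(cc), 90)
  expect_equal(length(unique(cc$tray_id)), 30)
  per_rater <- table(cc$rater_id)
  expect_true(all(per_rater == 15))
  expect_true(all(table(cc$rater_id, cc$meal) == 5))
  expect_true(all(table(cc$tray_id) == 3))  # every tray rated by 3 raters
  expect_true(all(is.na(cc$true_value)))
  expect_error(simulate_strategy_c(sim_config(seed = 1, n_raters = 4L)),
               "design infeasible")
})

test_that("clinical reliability recovers a high generating ICC", {
  cfg <- sim_config(seed = 21, n_raters = 6L, rater_noise_sd = 3,
                    tray_energy = list(mean = 550, sd = 250, min = 100))
  cc <- simulate_strategy_c(cfg)
  fit <- suppressMessages(icc_model(cc, covariates = c("day", "meal"),
                                    ci = "none"))
  expect_gt(fit$icc, 0.95)
})

test_that("the timing design is alternating, balanced, and lognormal-scaled", {
  d <- simulate_strategy_d(sim_config(seed = 31))
  expect_equal(nrow(d), 24)
  expect_true(all(table(d$day, d$session, d$method) == 2))  # half and half
  alt <- tapply(d$method, interaction(d$rater, d$day),
                function(m) length(unique(m)))
  expect_true(all(alt == 2))  # every rater switches within a day
  expect_true(all(d[, c("t_pre_s", "t_post_s", "t_entry_s")] >= 1))
  # both sessions of a day use different meals
  meals <- tapply(d$meal, d$day, function(m) length(unique(m)))
  expect_true(all(meals == 2))
  # identical per-method timing: CI for the ratio covers 100%
  flat <- sim_config(seed = 32, timing = timing_spec(mcm_ratio = 1))
  fit <- suppressMessages(time_efficiency(simulate_strategy_d(flat)))
  expect_true(fit$ci[1] <= 100 && 100 <= fit$ci[2])
})

test_that("fitted meal effects reproduce the generator's meal ordering", {
  cfg <- sim_config(seed = 41, timing = timing_spec(sdlog = 0.05))
  # pool three replicate exercises for a stable ordering check
  recs <- do.call(rbind, lapply(41:43, function(s)
    transform(simulate_strategy_d(sim_config(seed = s,
                                             timing = timing_spec(sdlog = 0.05))),
              rater = paste0(s, "_", rater))))
  fit <- suppressMessages(time_efficiency(recs))
  eff <- fit$meal_effects  # reference level: breakfast
  expect_true(eff[["lunch"]] > 0)
  expect_true(eff[["dinner"]] > eff[["lunch"]])
})
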