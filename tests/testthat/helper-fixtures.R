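# Small in-code fixtures shared across tests.

toy_db <- function() {
  food_db(data.frame(
    item_id = c("soup", "bread", "juice"),
    description = c("Tomato soup", "Bread roll", "Apple juice"),
    serving_label = c("1 cup", "1 roll", "180 mL"),
    serving_weight_g = c(250, 50, 186),
    energy_kcal = c(200, 300, 84),
    protein_g = c(4, 8, 0),
    fat_sat_g = c(1, 2, 0),
    fat_unsat_g = c(2, 3, 0),
    carb_g = c(30, 50, 21),
    stringsAsFactors = FALSE))
}

toy_cycle <- function() {
  menu_cycle("cyc1", data.frame(
    cycle_day = c(1L, 1L, 1L, 1L, 1L),
    meal = c("breakfast", "breakfast", "lunch", "lunch", "lunch"),
    diet_id = c("regular", "regular", "regular", "regular", "liquid"),
    item_id = c("soup", "bread", "soup", "juice", "juice"),
    servings = c(1, 1, 1, 1, 2),
    stringsAsFactors = FALSE))
}

toy_niaf <- function(pcts = NULL) {
  n <- generate_niaf(toy_db(), toy_cycle(), "regular", 1, "breakfast",
                     "T1", "P1", "2016-03-01")
  if (!is.null(pcts)) n <- record_consumption(n, pcts)
  n
}

# balanced tray x rater records generated from a variance-components model
vc_records <- function(n_trays, n_raters, var_tray, var_res, mu = 500) {
  tray_eff <- stats::rnorm(n_trays, 0, sqrt(var_tray))
  g <- expand.grid(tray_id = sprintf("T%02d", seq_len(n_trays)),
                   rater_id = sprintf("R%d", seq_len(n_raters)),
                   stringsAsFactors = FALSE)
  g$estimate <- mu + tray_eff[match(g$tray_id, sprintf("T%02d", seq_len(n_trays)))] +
    stats::rnorm(nrow(g), 0, sqrt(var_res))
  g
}

# independent one-way ANOVA method-of-moments ICC (balanced designs)
anova_icc <- function(records) {
  k <- length(unique(records$rater_id))
  a <- stats::anova(stats::lm(estimate ~ factor(tray_id), data = records))
  msb <- a["factor(tray_id)", "Mean Sq"]
  msw <- a["Residuals", "Mean Sq"]
  vt <- max((msb - msw) / k, 0)
  vt / (vt + msw)
}
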