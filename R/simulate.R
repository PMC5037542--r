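#' Simulation configuration
#'
#' Bundles every knob of the evaluation simulator: tray composition, the
#' consumption (plate-waste) distribution, rater estimation error, and the
#' per-method lognormal task-time model. One master `seed` spawns an
#' independent, named substream for every stage and unit (trays,
#' consumption, rater estimates, method assignment, timing), so adding a
#' later stage never perturbs earlier draws and identical configurations
#' reproduce identical data sets byte for byte.
#'
#' Defaults emulate the evaluation conditions: 30 trays arranged as 5 days x
#' 3 meals x 2 diets with 3 raters (the complete laboratory design), trays
#' of 3--8 items, and consumption drawn from Beta(1.2, 0.8) scaled to
#' 0--100 with point masses at 0 and 100 (trays are often untouched or
#' cleaned). `rater_noise_sd` is the per-item SD, in percentage points, of
#' the Gaussian estimation error added before clipping to \[0, 100\] and
#' rounding; its default is calibrated so that the SD of the rater-minus-
#' weighed meal-energy difference is about 40 kcal, the scale observed for
#' trained raters.
#'
#' @param seed Master integer seed.
#' @param n_trays,n_raters Design size (defaults 30 and 3).
#' @param rater_noise_sd Per-item estimation error SD, percentage points.
#' @param rater_bias Systematic per-item estimation bias, percentage points.
#' @param items_per_tray Integer vector of possible item counts per tray.
#' @param tray_energy List `(mean, sd, min)`: total served tray energy is
#'   drawn from Normal(mean, sd) truncated below at `min` (kcal).
#' @param consumption List `(shape1, shape2, p_zero, p_full)`: the scaled
#'   Beta consumption distribution and its point masses at 0% and 100%.
#' @param timing Per-method task-time model; see [timing_spec()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_trays = 30L, n_raters = 3L,
                       rater_noise_sd = 15, rater_bias = 0,
                       items_per_tray = 3:8,
                       tray_energy = list(mean = 550, sd = 150, min = 150),
                       consumption = list(shape1 = 1.2, shape2 = 0.8,
                                          p_zero = 0.05, p_full = 0.15),
                       timing = timing_spec()) {
  stopifnot(rater_noise_sd >= 0, tray_energy$sd >= 0,
            consumption$p_zero >= 0, consumption$p_full >= 0,
            consumption$p_zero + consumption$p_full <= 1,
            consumption$shape1 > 0, consumption$shape2 > 0)
  structure(list(seed = as.integer(seed), n_trays = as.integer(n_trays),
                 n_raters = as.integer(n_raters),
                 rater_noise_sd = rater_noise_sd, rater_bias = rater_bias,
                 items_per_tray = items_per_tray, tray_energy = tray_energy,
                 consumption = consumption, timing = timing),
            class = "sim_config")
}

#' Lognormal task-time model for the timing simulator
#'
#' Each of the three calorie-count tasks has a lognormal duration with a
#' traditional-method median (seconds), multiplied by a method ratio when
#' the multi-component method is used, a meal factor (breakfast counts are
#' quicker than lunch, lunch quicker than dinner), and a lognormal rater
#' effect. Defaults put the method ratio at 0.327 of traditional time and
#' task medians near those observed in practice.
#'
#' @param tm_task_medians Named vector `(pre, post, entry)` of
#'   traditional-method median task times, seconds.
#' @param mcm_ratio Multiplicative method effect on every task (MCM vs TM).
#' @param meal_mult Named multipliers for breakfast/lunch/dinner.
#' @param sdlog Residual SD of log task time.
#' @param rater_sdlog SD of the lognormal rater effect.
#' @return A list used as the `timing` element of [sim_config()].
#' @export
timing_spec <- function(tm_task_medians = c(pre = 430, post = 150, entry = 860),
                        mcm_ratio = 0.327,
                        meal_mult = c(breakfast = 0.85, lunch = 1, dinner = 1.15),
                        sdlog = 0.18, rater_sdlog = 0.08) {
  stopifnot(all(tm_task_medians > 0), mcm_ratio > 0, all(meal_mult > 0),
            sdlog >= 0, rater_sdlog >= 0)
  list(tm_task_medians = tm_task_medians, mcm_ratio = mcm_ratio,
       meal_mult = meal_mult, sdlog = sdlog, rater_sdlog = rater_sdlog)
}

# deterministic substream seed from (master seed, stream name); values stay
# well inside 32-bit integer range
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer(((seed %% 1000003) * 9973 + (h %% 999983) * 131 + 17) %% 2147483629)
}

with_stream <- function(config, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(config$seed, name))
  force(code)
}

#' Simulate one meal tray
#'
#' Draws a tray of 3--8 food items with serving weights and nutrient
#' profiles. Total tray energy comes from the configured distribution and is
#' split across items by normalized Gamma(2) weights; macronutrients are
#' derived from energy with realistic shares. The result is reproducible:
#' the same configuration and `tray_id` always give the same tray.
#'
#' @param config A [sim_config()].
#' @param tray_id Identifier; also keys the tray's random substream.
#' @return A list with `tray_id` and `items` (a data.frame in food-database
#'   column layout, one serving per item).
#' @export
simulate_tray <- function(config, tray_id = "T1") {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config, paste0("tray/", tray_id), {
    k <- if (length(config$items_per_tray) == 1) config$items_per_tray
         else sample(config$items_per_tray, 1)
    te <- config$tray_energy
    total <- max(stats::rnorm(1, te$mean, te$sd), te$min)
    w <- stats::rgamma(k, shape = 2)
    energy <- total * w / sum(w)
    sw <- round(stats::runif(k, 60, 350))
    p_share <- stats::runif(k, 0.10, 0.20)
    f_share <- stats::runif(k, 0.25, 0.35)
    items <- data.frame(
      item_id = paste0(tray_id, "_I", seq_len(k)),
      description = paste0("simulated item ", seq_len(k), " (", tray_id, ")"),
      serving_label = "1 serving",
      serving_weight_g = sw,
      energy_kcal = energy,
      protein_g = energy * p_share / 4,
      fat_sat_g = energy * f_share / 9 * 0.4,
      fat_unsat_g = energy * f_share / 9 * 0.6,
      carb_g = energy * (1 - p_share - f_share) / 4,
      stringsAsFactors = FALSE)
    list(tray_id = tray_id, items = items)
  })
}

#' Simulate consumption of a tray and its weighed-food records
#'
#' True percent consumed is drawn per item from the configured scaled-Beta
#' distribution with point masses at 0 and 100 (emulating a trainer
#' discarding random portions of each item), and leftover weights are set
#' consistently: `leftover = original * (1 - pct/100)`, so
#' [weighed_consumption_pct()] recovers the drawn percentage exactly.
#'
#' @param tray A tray from [simulate_tray()].
#' @param config A [sim_config()].
#' @return A data.frame `(item_id, true_pct, original_g, leftover_g)`.
#' @export
simulate_consumption <- function(tray, config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config, paste0("consumption/", tray$tray_id), {
    k <- nrow(tray$items)
    cn <- config$consumption
    u <- stats::runif(k)
    pct <- 100 * stats::rbeta(k, cn$shape1, cn$shape2)
    pct[u < cn$p_zero] <- 0
    pct[u >= cn$p_zero & u < cn$p_zero + cn$p_full] <- 100
    data.frame(item_id = tray$items$item_id, true_pct = pct,
               original_g = tray$items$serving_weight_g,
               leftover_g = tray$items$serving_weight_g * (1 - pct / 100),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a rater's integer percent-consumed estimates
#'
#' `estimate = round(clip(true + bias + Normal(0, noise_sd), 0, 100))`,
#' independent across items and raters (each (rater, key) pair has its own
#' substream).
#'
#' @param true_pct Vector of true percentages.
#' @param config A [sim_config()].
#' @param rater_id Rater identifier (keys the substream).
#' @param key Extra substream key, e.g. the tray id.
#' @return Integer vector of estimates in `[0, 100]`.
#' @export
simulate_rater_estimates <- function(true_pct, config, rater_id = "R1", key = "") {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config, paste0("rater/", rater_id, "/", key), {
    e <- true_pct + config$rater_bias +
      stats::rnorm(length(true_pct), 0, config$rater_noise_sd)
    as.integer(round(pmin(100, pmax(0, e))))
  })
}

sim_tray_grid <- function(n_trays) {
  g <- expand.grid(diet = c("regular", "full_liquid"),
                   meal = c("breakfast", "lunch", "dinner"),
                   day = 1:ceiling(n_trays / 6), stringsAsFactors = FALSE)
  g <- g[seq_len(n_trays), ]
  g$tray_id <- sprintf("T%02d", seq_len(n_trays))
  g
}

sim_niaf <- function(tray, pct, meal, tray_id, rater_id) {
  lines <- data.frame(item_id = tray$items$item_id, servings = 1,
                      pct_consumed = as.integer(pct), origin = "menu",
                      stringsAsFactors = FALSE)
  new_niaf(tray_id, paste0("sim_", rater_id), NA_character_, meal, "sim",
           lines, status = "recorded")
}

sim_assess <- function(config, grid, rater_ids_per_tray) {
  trays <- lapply(grid$tray_id, function(tid) simulate_tray(config, tid))
  names(trays) <- grid$tray_id
  cons <- lapply(trays, simulate_consumption, config = config)
  dbs <- do.call(rbind, lapply(trays, `[[`, "items"))
  db <- food_db(dbs)
  recs <- list()
  for (i in seq_len(nrow(grid))) {
    tid <- grid$tray_id[i]
    true_kcal <- weighed_meal_energy(cons[[tid]], db)
    for (r in rater_ids_per_tray[[i]]) {
      est_pct <- simulate_rater_estimates(cons[[tid]]$true_pct, config,
                                          rater_id = r, key = tid)
      niaf <- sim_niaf(trays[[tid]], est_pct, grid$meal[i], tid, r)
      rep <- meal_report(niaf, db)
      recs[[length(recs) + 1L]] <- data.frame(
        tray_id = tid, rater_id = r, day = grid$day[i], meal = grid$meal[i],
        diet_id = grid$diet[i],
        estimate = unname(rep$consumed[["energy_kcal"]]),
        true_value = true_kcal, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate the complete laboratory evaluation design
#'
#' Every rater independently assesses every tray: with the defaults,
#' 3 raters x 30 trays (5 days x 3 meals x 2 diets) = 90 assessment
#' records, each pairing the rater's meal-energy estimate — obtained by
#' running the simulated percent-consumed values through the intake engine —
#' with the weighed true value. Feeds [bland_altman()], [accuracy_model()],
#' and [icc_model()].
#'
#' @param config A [sim_config()].
#' @return A data.frame of assessment records `(tray_id, rater_id, day,
#'   meal, diet_id, estimate, true_value)`.
#' @export
simulate_strategy_b <- function(config = sim_config()) {
  grid <- sim_tray_grid(config$n_trays)
  raters <- sprintf("R%d", seq_len(config$n_raters))
  sim_assess(config, grid, rep(list(raters), nrow(grid)))
}

#' Simulate the clinical (incomplete) reliability design
#'
#' Six raters each assess 5 breakfast, 5 lunch, and 5 dinner trays
#' (15 assessments per rater), every tray being rated by exactly three
#' raters, for 90 assessments on 30 trays. The rater-triple incidence is
#' built from 5 random triples per meal together with their complements, so
#' each rater appears exactly once in each triple/complement pair. True
#' (weighed) values are not observed in the clinical setting, so
#' `true_value` is `NA`; the output feeds [icc_model()]'s incomplete-design
#' path.
#'
#' @param config A [sim_config()]; `n_raters` must be 6 and `n_trays` 30.
#' @return A data.frame of assessment records with `true_value = NA`.
#' @export
simulate_strategy_c <- function(config = sim_config(n_raters = 6L)) {
  if (config$n_raters != 6L || config$n_trays != 30L)
    stop("design infeasible: the clinical reliability design needs 6 raters and 30 trays")
  meals <- c("breakfast", "lunch", "dinner")
  triples <- utils::combn(6, 3, simplify = FALSE)
  assign <- list(); grid <- list()
  for (m in meals) {
    pick <- with_stream(config, paste0("incidence/", m), {
      idx <- sample(length(triples), 5)
      triples[idx]
    })
    for (j in seq_along(pick)) {
      t1 <- pick[[j]]; t2 <- setdiff(1:6, t1)
      for (h in 1:2) {
        tid <- sprintf("C_%s_%d%s", substr(m, 1, 1), j, c("a", "b")[h])
        grid[[length(grid) + 1L]] <- data.frame(
          diet = "clinical", meal = m, day = j, tray_id = tid,
          stringsAsFactors = FALSE)
        assign[[length(assign) + 1L]] <-
          sprintf("R%d", if (h == 1) t1 else t2)
      }
    }
  }
  grid <- do.call(rbind, grid)
  out <- sim_assess(config, grid, assign)
  out$true_value <- NA_real_
  out
}

#' Simulate the time-comparison design
#'
#' Four raters, three days, two sessions per day. Within each day the two
#' sessions use different meals, methods are assigned half-and-half within
#' each session, and each rater switches method between the sessions of a
#' day (the alternating balanced assignment). Task times are lognormal per
#' [timing_spec()], rounded to whole seconds.
#'
#' @param config A [sim_config()].
#' @param n_raters,n_days Design size (defaults 4 and 3).
#' @return A data.frame of timing records `(rater, method, day, session,
#'   meal, t_pre_s, t_post_s, t_entry_s)` as consumed by
#'   [time_efficiency()].
#' @export
simulate_strategy_d <- function(config = sim_config(), n_raters = 4L, n_days = 3L) {
  if (n_raters %% 2 != 0) stop("design infeasible: need an even number of raters")
  ts <- config$timing
  rater_eff <- with_stream(config, "timing/raters",
                           stats::rnorm(n_raters, 0, ts$rater_sdlog))
  recs <- list()
  for (dy in seq_len(n_days)) {
    plan <- with_stream(config, paste0("timing/assign/", dy), {
      list(mcm1 = sample(n_raters, n_raters / 2),
           meals = sample(names(ts$meal_mult), 2))
    })
    for (ss in 1:2) {
      meal <- plan$meals[ss]
      for (r in seq_len(n_raters)) {
        is_mcm <- if (ss == 1) r %in% plan$mcm1 else !(r %in% plan$mcm1)
        mult <- ts$meal_mult[[meal]] * (if (is_mcm) ts$mcm_ratio else 1)
        tt <- with_stream(config, sprintf("timing/t/%d/%d/%d", dy, ss, r), {
          pmax(1, round(exp(log(ts$tm_task_medians * mult) + rater_eff[r] +
                              stats::rnorm(3, 0, ts$sdlog))))
        })
        recs[[length(recs) + 1L]] <- data.frame(
          rater = r, method = if (is_mcm) "MCM" else "TM", day = dy,
          session = ss, meal = meal,
          t_pre_s = tt[[1]], t_post_s = tt[[2]], t_entry_s = tt[[3]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
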