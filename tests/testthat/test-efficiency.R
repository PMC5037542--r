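# a fully balanced alternating two-day grid used across the tests below
balanced_grid <- function(mcm_total, tm_total) {
  g <- expand.grid(rater = 1:4, session = 1:2, day = 1:2)
  g$meal <- c("dinner", "lunch", "breakfast", "lunch")[(g$day - 1) * 2 + g$session]
  mcm1 <- list(c(1, 4), c(1, 2))  # session-1 MCM raters per day
  g$method <- ifelse((g$rater %in% mcm1[[1]] & g$day == 1) |
                       (g$rater %in% mcm1[[2]] & g$day == 2),
                     ifelse(g$session == 1, "MCM", "TM"),
                     ifelse(g$session == 1, "TM", "MCM"))
  tot <- ifelse(g$method == "MCM", mcm_total, tm_total)
  g$t_pre_s <- tot * 0.3; g$t_post_s <- tot * 0.2; g$t_entry_s <- tot * 0.5
  g
}

test_that("identical method distributions give a ratio of 100%", {
  rec <- balanced_grid(900, 900)
  fit <- suppressWarnings(suppressMessages(time_efficiency(rec)))
  expect_equal(fit$ratio_pct, 100, tolerance = 1e-8)
})

test_that("halving every total gives exactly 50% and scale invariance holds", {
  rec <- balanced_grid(600, 1200)
  fit <- suppressWarnings(suppressMessages(time_efficiency(rec)))
  expect_equal(fit$ratio_pct, 50, tolerance = 1e-8)
  expect_equal(fit$saving_pct, 50, tolerance = 1e-8)
  # multiplying all times by a positive constant leaves the ratio unchanged
  scaled <- rec
  for (cl in c("t_pre_s", "t_post_s", "t_entry_s"))
    scaled[[cl]] <- scaled[[cl]] * 3.7
  expect_equal(suppressWarnings(suppressMessages(time_efficiency(scaled)))$ratio_pct,
               fit$ratio_pct, tolerance = 1e-8)
})

test_that("in a balanced design the ratio equals the geometric-mean ratio", {
  set.seed(19)
  rec <- balanced_grid(600, 1200)
  tot <- rec$t_pre_s + rec$t_post_s + rec$t_entry_s
  tot <- tot * exp(rnorm(nrow(rec), 0, 0.1))
  rec$t_pre_s <- tot * 0.3; rec$t_post_s <- tot * 0.2; rec$t_entry_s <- tot * 0.5
  fit <- suppressWarnings(suppressMessages(time_efficiency(rec)))
  gm <- exp(mean(log(tot[rec$method == "MCM"])) -
              mean(log(tot[rec$method == "TM"])))
  expect_equal(fit$ratio_pct, 100 * gm, tolerance = 1e-6)
})

test_that("single-method or single-rater data are rejected", {
  rec <- balanced_grid(600, 1200)
  rec$method <- "MCM"
  expect_error(time_efficiency(rec), "contrast unidentifiable")
  one <- balanced_grid(600, 1200)
  one <- one[one$rater == 1, ]
  expect_error(time_efficiency(one), "at least 2 raters")
})

test_that("consistent labels pass through the resolver untouched", {
  rec <- balanced_grid(600, 1200)
  res <- resolve_method_labels(rec)
  expect_equal(res$n_flips, 0)
  expect_identical(res$records$method, rec$method)
})

test_that("a single alternation violation forces exactly that flip", {
  rec <- balanced_grid(600, 1200)
  # corrupt one label: rater 1 day 1 session 2 should be TM
  i <- with(rec, which(rater == 1 & day == 1 & session == 2))
  expect_identical(rec$method[i], "TM")
  rec$method[i] <- "MCM"
  res <- resolve_method_labels(rec)
  expect_equal(res$n_flips, 1)
  expect_equal(res$flips$rater, 1)
  expect_equal(res$flips$day, 1)
  expect_equal(res$flips$session, 2)
  expect_identical(res$flips$to, "TM")
})

test_that("a day with identical session labels is resolved by log-time variance", {
  rec <- balanced_grid(600, 1200)
  # make day 2 session 2 a copy of session 1's labels (alternation broken);
  # times still follow the true methods, so variance pinpoints the bad session
  s1 <- with(rec, day == 2 & session == 1)
  s2 <- with(rec, day == 2 & session == 2)
  rec$method[s2] <- rec$method[s1][match(rec$rater[s2], rec$rater[s1])]
  res <- resolve_method_labels(rec)
  expect_equal(res$n_flips, 4)
  expect_true(all(res$flips$day == 2 & res$flips$session == 2))
  fit <- suppressWarnings(suppressMessages(time_efficiency(res$records)))
  expect_equal(fit$ratio_pct, 50, tolerance = 1e-6)
})

test_that("an odd rater count cannot satisfy the half-and-half design", {
  rec <- balanced_grid(600, 1200)
  expect_error(resolve_method_labels(rec[rec$rater != 4, ]),
               "inconsistent design")
})

test_that("the printed timing table is corrected at the known anomalies", {
  tab <- load_table2_fixture()
  res <- resolve_method_labels(tab)
  expect_gt(res$n_flips, 0)
  key <- paste(res$flips$rater, res$flips$day, res$flips$session)
  expect_true("4 1 2" %in% key)                 # day-1 session-2 imbalance
  expect_true(any(res$flips$day == 3 & res$flips$session == 1))
  # after correction, every session is half MCM / half TM and raters alternate
  r <- res$records
  split_ok <- tapply(r$method == "MCM", interaction(r$day, r$session), sum)
  expect_true(all(split_ok == 2))
  alt <- tapply(r$method, interaction(r$rater, r$day),
                function(m) length(unique(m)))
  expect_true(all(alt == 2))
})
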