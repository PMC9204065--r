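test_that("trials below the 150 ms floor are excluded as outliers", {
  tr <- toy_trials(c(rep(500, 20), 100))
  clean <- screen_trials(tr)
  expect_identical(nrow(clean), 20L)
  expect_false(any(clean$rt_ms < 150))
  rep <- attr(clean, "exclusion_report")$table
  expect_identical(rep$outlier, 1L)
})

test_that("the personal mean + 3 SD ceiling matches hand computation", {
  rt <- c(rep(500, 59), 5000)
  # cell stats over all 60 correct trials: mean 575, sd ~ 580.9 -> the
  # 5000 ms trial exceeds 575 + 3 * 580.9 = 2317.8 and must go
  m <- mean(rt)
  s <- sd(rt)
  expect_gt(5000, m + 3 * s)
  clean <- screen_trials(toy_trials(rt))
  expect_identical(nrow(clean), 59L)
  expect_true(all(clean$rt_ms == 500))
  # equality counts as exclusion ("three or more SDs")
  rt2 <- c(rep(400, 10), 600)
  m2 <- mean(rt2)
  s2 <- sd(rt2)
  at_bound <- m2 + 3 * s2
  tr2 <- toy_trials(c(rt2, at_bound))
  stats_pre <- attr(screen_trials(toy_trials(rt2)), "cell_stats")
  # evaluate the boundary against fixed cached stats to avoid recomputation
  clean2 <- screen_trials(tr2, cell_stats = stats_pre)
  expect_false(any(abs(clean2$rt_ms - at_bound) < 1e-9))
})

test_that("fully clean input passes through with a 100% usable report", {
  tr <- toy_trials(seq(400, 590, by = 10))
  clean <- screen_trials(tr)
  expect_identical(nrow(clean), nrow(tr))
  tab <- exclusion_summary(attr(clean, "exclusion_report"))
  expect_equal(tab$usable_pct, 100)
  expect_equal(tab$missing + tab$incorrect + tab$outlier, 0L)
})

test_that("exclusion categories partition the administered trials", {
  d <- burst_design(n_persons = 40, n_years = 2, sessions_per_year = c(3, 2),
                    trials_per_session = 30)
  sim <- generate_trials(d, attrition = FALSE, seed = 17)
  clean <- suppressWarnings(screen_trials(sim$trials))
  tab <- exclusion_summary(attr(clean, "exclusion_report"))
  expect_identical(tab$missing + tab$incorrect + tab$outlier + tab$usable,
                   tab$possible)
  expect_equal(tab$missing_pct + tab$incorrect_pct + tab$outlier_pct +
                 tab$usable_pct, c(100, 100))
  # BRT possible excludes the unanalysed lead-in trial
  expect_identical(tab$possible[tab$task == "BRT"],
                   tab$possible[tab$task == "CRT"])
})

test_that("injected corruption rates are recovered by the report", {
  d <- burst_design(n_persons = 120, n_years = 1, sessions_per_year = 5)
  p <- generating_params("BRT")  # missing 0.20%, incorrect 10.46%
  sim <- generate_trials(d, params = list(CRT = generating_params("CRT"),
                                          BRT = p),
                         attrition = FALSE, seed = 19)
  clean <- screen_trials(sim$trials)
  tab <- exclusion_summary(attr(clean, "exclusion_report"))
  brt <- tab[tab$task == "BRT", ]
  expect_equal(brt$missing_pct, 0.20, tolerance = 0.35)
  expect_equal(brt$incorrect_pct, 10.46, tolerance = 0.03)
  # outliers: injected 2.42% plus the natural >=3 SD tail of the normal
  expect_equal(brt$outlier_pct, 2.42, tolerance = 0.3)
})

test_that("screening is idempotent under cached cell statistics", {
  d <- burst_design(n_persons = 25, n_years = 1, sessions_per_year = 2,
                    trials_per_session = 40)
  sim <- generate_trials(d, attrition = FALSE, seed = 23)
  clean <- screen_trials(sim$trials)
  again <- screen_trials(clean, cell_stats = attr(clean, "cell_stats"))
  expect_identical(nrow(again), nrow(clean))
})

test_that("no surviving trial violates either latency bound", {
  d <- burst_design(n_persons = 30, n_years = 1, sessions_per_year = 3,
                    trials_per_session = 40)
  sim <- generate_trials(d, attrition = FALSE, seed = 29)
  clean <- screen_trials(sim$trials)
  expect_true(all(clean$rt_ms >= 150))
  stats <- attr(clean, "cell_stats")
  merged <- dplyr::left_join(clean, stats,
                             by = c("person_id", "task", "year", "session"))
  expect_true(all(merged$rt_ms < merged$cell_mean + 3 * merged$cell_sd))
})

test_that("BRT lead-in removal touches exactly trial 1 of BRT sessions", {
  tr <- dplyr::bind_rows(
    toy_trials(rep(500, 61), task = "BRT"),
    toy_trials(rep(400, 60), task = "CRT"))
  out <- omit_first_brt_trial(tr)
  expect_identical(sum(out$task == "BRT"), 60L)
  expect_identical(sum(out$task == "CRT"), 60L)
  expect_false(any(out$task == "BRT" & out$trial == 1))
  expect_identical(omit_first_brt_trial(out), out)      # no-op when done
  empty <- tr[0, ]
  expect_identical(nrow(omit_first_brt_trial(empty)), 0L)
})

test_that("cells too small for an SD are retained with a warning", {
  tr <- toy_trials(c(300, NA))
  tr$missing[2] <- 1L
  expect_warning(clean <- screen_trials(tr), "fewer than 2")
  expect_identical(nrow(clean), 1L)  # retained despite no ceiling
})

test_that("a zero denominator is an error in the summary", {
  rep0 <- structure(list(table = tibble::tibble(
    task = "CRT", possible = 0L, missing = 0L, incorrect = 0L,
    outlier = 0L, usable = 0L)), class = "exclusion_report")
  expect_error(exclusion_summary(rep0), "zero possible")
})
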