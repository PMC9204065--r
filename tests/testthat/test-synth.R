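small_design <- function(n = 24) {
  burst_design(n_persons = n, n_years = 2, sessions_per_year = c(3, 2),
               trials_per_session = 20)
}

test_that("identical config and seed give byte-identical outputs", {
  d <- small_design()
  s1 <- generate_trials(d, seed = 41)
  s2 <- generate_trials(d, seed = 41)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$covariates, s2$covariates)
  s3 <- generate_trials(d, seed = 42)
  expect_false(identical(s1$trials$rt_ms, s3$trials$rt_ms))
})

test_that("attrition is monotone and respected by the trial table", {
  d <- burst_design(n_persons = 150, n_years = 4,
                    sessions_per_year = c(2, 2, 2, 2), trials_per_session = 5)
  sim <- generate_trials(d, attrition = TRUE, seed = 8)
  present <- dplyr::distinct(sim$trials, person_id, year)
  by_person <- split(present$year, present$person_id)
  for (yrs in by_person) {
    expect_identical(sort(unique(yrs)), seq_len(max(yrs)))  # no gaps
  }
  merged <- dplyr::left_join(present, sim$retention, by = "person_id")
  expect_true(all(merged$year <= merged$last_year))
  # hazards leave a plausible fraction of completers (~80% at defaults)
  expect_gt(mean(sim$retention$last_year == 4), 0.6)
})

test_that("administered trial counts match the design before corruption", {
  d <- small_design()
  sim <- generate_trials(d, attrition = FALSE, seed = 3)
  counts <- dplyr::count(sim$trials, task, person_id, year, session)
  expect_true(all(counts$n[counts$task == "CRT"] == 20))
  expect_true(all(counts$n[counts$task == "BRT"] == 21))  # lead-in trial
  expect_identical(nrow(dplyr::distinct(sim$trials, person_id, year, session)),
                   24L * 5L)
})

test_that("degenerate generator collapses to the configured mean structure", {
  d <- small_design(n = 6)
  p <- noiseless_params("CRT",
                        gamma100 = 0, gamma010 = 0, gamma001 = 0,
                        gamma002 = 0, trial_mean_sd = 0,
                        rate_missing = 0, rate_incorrect = 0,
                        rate_outlier = 0, trial_sd_slope = 0,
                        trial_sd_floor = 1e-9)
  sim <- generate_trials(d, params = list(CRT = p, BRT = p),
                         attrition = FALSE, seed = 5)
  crt <- sim$trials[sim$trials$task == "CRT", ]
  expect_equal(crt$rt_ms, rep(900, nrow(crt)), tolerance = 1e-6)
  expect_true(all(crt$correct == 1L))
  expect_true(all(crt$missing == 0L))
})

test_that("with zero corruption rates every administered trial is usable", {
  d <- small_design()
  p <- generating_params("CRT", rate_missing = 0, rate_incorrect = 0,
                         rate_outlier = 0)
  sim <- generate_trials(d, params = list(CRT = p, BRT = p),
                         attrition = FALSE, seed = 6)
  clean <- screen_trials(sim$trials, qc_rules())
  tab <- exclusion_summary(attr(clean, "exclusion_report"))
  expect_equal(tab$missing_pct, c(0, 0))
  expect_equal(tab$incorrect_pct, c(0, 0))
  # natural tail trims only (normal tail beyond 3 SD, ~0.1-0.3%)
  expect_lt(max(tab$outlier_pct), 1)
})

test_that("group mixture reproduces the configured status proportions", {
  p <- generating_params("CRT")
  cv <- generate_covariates(304 * 20, p, seed = 12)
  mix <- table(cv$true_group) / nrow(cv)
  expect_equal(as.numeric(mix), c(136, 88, 80) / 304, tolerance = 0.03)
  expect_true(all(cv$age_baseline >= 64 & cv$age_baseline <= 92))
  expect_true(all(cv$sex %in% 0:1))
  expect_true(all(cv$education >= 7 & cv$education <= 24))
})

test_that("latent variance decomposition matches the generating ratios", {
  d <- burst_design(n_persons = 350)
  r <- simulate_rti(d, uncond_params(34, 3, 13), seed = 21)
  dec <- fit_unconditional(r)
  expect_equal(unname(dec$shares[["person"]]), 68, tolerance = 0.08)
  expect_equal(unname(dec$shares[["year"]]), 6, tolerance = 0.45)
  expect_equal(unname(dec$shares[["week"]]), 26, tolerance = 0.12)
})

test_that("a negative weekly dispersion slope propagates to negative mean RTI slopes", {
  # Monte-Carlo sign check against the generator: the downstream weekly
  # fixed-effect estimate averages negative across seeded replicates
  d <- burst_design(n_persons = 80, n_years = 2, sessions_per_year = c(4, 4),
                    trials_per_session = 30, tasks = "BRT")
  p <- generating_params("BRT", gamma100 = -0.6)
  ests <- vapply(1:8, function(i) {
    sim <- generate_trials(d, params = list(BRT = p), attrition = FALSE,
                           seed = 700 + i)
    clean <- suppressWarnings(screen_trials(sim$trials))
    rti <- compute_rti(clean)
    fit <- fit_conditional(rti, sim$covariates, task = "BRT")
    fit$beta[["week"]]
  }, numeric(1))
  expect_lt(mean(ests), 0)
  expect_gt(mean(ests < 0), 0.7)
})

test_that("domain scores with deterministic deficits propagate to status", {
  d <- burst_design(n_persons = 30)
  p <- generating_params("CRT", domain_noise = 0)
  cv <- generate_covariates(30, p, seed = 31)
  dom <- generate_domain_scores(d, p, cv, seed = 32)
  z <- zscore_domains(dom$scores, dom$norms, cv)
  st <- classify_status(z)
  merged <- dplyr::left_join(st, cv[c("person_id", "true_group")],
                             by = "person_id")
  expect_identical(as.character(merged$label),
                   as.character(merged$true_group))
})

test_that("correlated slope pairs hit the target correlation", {
  sp <- simulate_slope_pairs(20000, rho = 0.5, seed = 44)
  expect_equal(stats::cor(sp$short_term, sp$long_term), 0.5,
               tolerance = 0.05)
})
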