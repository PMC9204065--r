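test_that("a pure linear trial trend residualizes to zero", {
  tr <- toy_trials(600 + 3 * (1:30))
  res <- residualize_trials(tr)
  expect_equal(res$residual, rep(0, 30), tolerance = 1e-10)
})

test_that("residuals are centered within every absorption cell", {
  d <- burst_design(n_persons = 12, n_years = 2, sessions_per_year = c(2, 2),
                    trials_per_session = 15)
  sim <- generate_trials(d, attrition = FALSE, seed = 51)
  clean <- suppressWarnings(screen_trials(sim$trials))
  res <- residualize_trials(clean)
  cellmeans <- dplyr::summarise(
    dplyr::group_by(res, person_id, task, year, session),
    m = mean(residual), .groups = "drop")
  expect_lt(max(abs(cellmeans$m)), 1e-9)
  # no residual linear trend in the trial index remains
  fit <- stats::lm(residual ~ trial, data = res)
  expect_lt(abs(stats::coef(fit)[["trial"]]), 1e-9)
})

test_that("residuals match the normal-equations oracle on a toy table", {
  # two persons, one session each, shared trial-index slope
  tr <- dplyr::bind_rows(
    toy_trials(c(520, 510, 530, 480, 505), person = 1L),
    toy_trials(c(700, 640, 660, 690, 610), person = 2L))
  res <- residualize_trials(tr)
  ref <- stats::lm(rt_ms ~ trial + factor(person_id), data = tr)
  expect_equal(res$residual, unname(stats::residuals(ref)),
               tolerance = 1e-10)
})

test_that("ISD is the n-1 sample SD with the expected special cases", {
  res0 <- toy_trials(rep(500, 10))
  res0$residual <- 0
  expect_equal(compute_isd(res0)$isd_raw, 0)

  res2 <- toy_trials(c(1, 2))
  res2$residual <- c(-1, 1)
  expect_equal(compute_isd(res2)$isd_raw, sqrt(2), tolerance = 1e-12)

  res3 <- res2
  res3$residual <- res2$residual + 7  # translation invariance
  expect_equal(compute_isd(res3)$isd_raw, compute_isd(res2)$isd_raw)

  # a 1-trial cell yields no score
  res1 <- toy_trials(500)
  res1$residual <- 0
  expect_identical(nrow(compute_isd(res1)), 0L)
})

test_that("T standardization fixes the reference cell at mean 50, SD 10", {
  d <- burst_design(n_persons = 60, n_years = 2, sessions_per_year = c(3, 2),
                    trials_per_session = 25)
  sim <- generate_trials(d, attrition = FALSE, seed = 53)
  rti <- compute_rti(suppressWarnings(screen_trials(sim$trials)))
  for (tk in c("CRT", "BRT")) {
    ref <- rti[rti$task == tk & rti$year == 1 & rti$session == 1, ]
    expect_equal(mean(ref$t_score), 50, tolerance = 1e-10)
    expect_equal(stats::sd(ref$t_score), 10, tolerance = 1e-10)
  }
  std <- attr(rti, "standardizer")
  expect_identical(nrow(std), 2L)
  expect_true(all(std$reference_sd > 0))
})

test_that("the T transform is affine in the ISD with slope 10/reference SD", {
  isd <- tibble::tibble(person_id = 1:20, task = "CRT",
                        year = rep(c(1, 2), each = 10),
                        session = 1, n_trials = 30,
                        isd_raw = c(seq(40, 130, by = 10), seq(45, 90, 5)))
  tt <- t_standardize(isd)
  std <- attr(tt, "standardizer")
  expect_equal(tt$t_score,
               50 + 10 * (isd$isd_raw - std$reference_mean) /
                 std$reference_sd)
  # reference landmarks: isd at the reference mean maps to 50, one
  # reference SD above maps to 60
  probe <- isd[1:2, ]
  probe$year <- 2  # outside the reference cell; transform still applies
  probe$isd_raw <- c(std$reference_mean, std$reference_mean +
                       std$reference_sd)
  tp <- t_standardize(dplyr::bind_rows(isd, probe))
  expect_equal(utils::tail(tp$t_score, 2), c(50, 60), tolerance = 1e-10)
  expect_identical(order(tt$t_score), order(isd$isd_raw))
})

test_that("per-occasion standardization pins every occasion at mean 50", {
  d <- burst_design(n_persons = 40, n_years = 1, sessions_per_year = 3,
                    trials_per_session = 20)
  sim <- generate_trials(d, attrition = FALSE, seed = 57)
  isd <- compute_isd(residualize_trials(
    suppressWarnings(screen_trials(sim$trials))))
  tt <- t_standardize(isd, reference = "per_occasion")
  occ <- dplyr::summarise(dplyr::group_by(tt, task, year, session),
                          m = mean(t_score), .groups = "drop")
  expect_equal(occ$m, rep(50, nrow(occ)), tolerance = 1e-9)
})

test_that("a degenerate reference cell raises an error", {
  isd <- tibble::tibble(person_id = 1:3, task = "CRT", year = 1, session = 1,
                        n_trials = 10, isd_raw = c(80, 80, 80))
  expect_error(t_standardize(isd), "degenerate reference")
})

test_that("groups generated with higher dispersion score higher T", {
  # pipeline-recovery property: the latent group shift survives screening,
  # residualization, and standardization, across seeded replicates
  d <- burst_design(n_persons = 60, n_years = 1, sessions_per_year = 3,
                    trials_per_session = 30, tasks = "CRT")
  diffs <- vapply(1:6, function(i) {
    p <- generating_params("CRT",
                           group_shift = c(HC = 0, `CIND-S` = 4,
                                           `CIND-M` = 8))
    sim <- generate_trials(d, params = list(CRT = p), attrition = FALSE,
                           seed = 900 + i)
    rti <- compute_rti(suppressWarnings(screen_trials(sim$trials)))
    m <- dplyr::left_join(rti, sim$covariates[c("person_id", "true_group")],
                          by = "person_id")
    mean(m$t_score[m$true_group == "CIND-M"]) -
      mean(m$t_score[m$true_group == "HC"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})
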