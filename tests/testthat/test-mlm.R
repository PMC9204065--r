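tiny_design <- burst_design(n_persons = 3, n_years = 2,
                            sessions_per_year = c(2, 2))
crt_like <- generating_params("CRT", gamma010 = 0.15)

test_that("marginal log-likelihood matches the dense pairwise oracle", {
  r <- simulate_rti(tiny_design, crt_like, seed = 61)
  params <- list(
    gamma = c(intercept = 50, week = -0.02, year = 0.15, age = 0.21,
              sex = -0.24),
    level3_cov = crt_like$level3_cov,
    level2_vars = crt_like$level2_vars,
    sigma2 = crt_like$level1_var)
  expect_equal(marginal_loglik(params, r),
               dense_loglik_oracle(params, r), tolerance = 1e-8)
  # and at a second, deliberately wrong parameter point
  params2 <- params
  params2$gamma["year"] <- -1
  params2$sigma2 <- 5
  expect_equal(marginal_loglik(params2, r),
               dense_loglik_oracle(params2, r), tolerance = 1e-8)
})

test_that("with all random variances zero the likelihood reduces to iid normal", {
  r <- simulate_rti(tiny_design, crt_like, seed = 62)
  gamma <- c(intercept = 49, week = 0, year = 0.2, age = 0.2, sex = 0)
  sigma2 <- 11
  params <- list(gamma = gamma, level3_cov = matrix(0, 3, 3),
                 level2_vars = c(intercept = 0, week = 0), sigma2 = sigma2)
  mu <- gamma[["intercept"]] + gamma[["week"]] * (2 * (r$session - 1)) +
    gamma[["year"]] * (r$year - 1) + gamma[["age"]] * (r$age_baseline - 74) +
    gamma[["sex"]] * r$sex
  expect_equal(marginal_loglik(params, r),
               sum(stats::dnorm(r$t_score, mu, sqrt(sigma2), log = TRUE)),
               tolerance = 1e-10)
})

test_that("the likelihood is invariant to within-person row permutation", {
  r <- simulate_rti(tiny_design, crt_like, seed = 63)
  params <- list(
    gamma = c(intercept = 50, week = -0.02, year = 0.15, age = 0.21,
              sex = -0.24),
    level3_cov = crt_like$level3_cov, level2_vars = crt_like$level2_vars,
    sigma2 = crt_like$level1_var)
  set.seed(1)
  shuffled <- r[sample(nrow(r)), ]
  expect_equal(marginal_loglik(params, shuffled),
               marginal_loglik(params, r), tolerance = 1e-10)
})

test_that("the fitted likelihood dominates the generating-parameter likelihood", {
  d <- burst_design(n_persons = 50)
  p <- generating_params("CRT", gamma010 = 0.15,
                         group_shift = c(HC = 0, `CIND-S` = 0,
                                         `CIND-M` = 0))
  gen <- list(
    gamma = c(intercept = 50, week = -0.02, year = 0.15, age = 0.21,
              sex = -0.24),
    level3_cov = p$level3_cov, level2_vars = p$level2_vars,
    sigma2 = p$level1_var)
  for (i in 1:3) {
    r <- simulate_rti(d, p, seed = 640 + i)
    fit <- fit_conditional(r)
    expect_gte(fit$loglik, marginal_loglik(gen, r) - 1e-6)
  }
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- burst_design(n_persons = 80, n_years = 3, sessions_per_year = c(3, 2, 2))
  r <- simulate_rti(d, crt_like, seed = 65)
  fit <- fit_conditional(r)
  r$age_c <- r$age_baseline - 74
  m <- lme4::lmer(
    t_score ~ week + year0 + age_c + sex + (year0 + week | person_id) +
      (1 | person_id:year) + (0 + week | person_id:year),
    data = r, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  # same model family; our optimum must not be worse than lme4's
  expect_gte(fit$loglik, as.numeric(stats::logLik(m)) - 0.01)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 0.01)
})

test_that("zero-noise data identify the fixed effects exactly", {
  d <- burst_design(n_persons = 40)
  p0 <- noiseless_params("CRT", gamma010 = 0.15)
  r <- simulate_rti(d, p0, seed = 66)
  fit <- fit_conditional(r)
  expect_equal(unname(fit$beta),
               c(50, -0.02, 0.15, 0.21, -0.24), tolerance = 1e-6)
})

test_that("BLUPs equal the dense conjugate-Gaussian posterior means", {
  r <- simulate_rti(tiny_design, crt_like, seed = 67)
  fit <- fit_conditional(r)
  eb <- extract_random_effects(fit)
  for (pid in unique(r$person_id)) {
    oracle <- dense_blup_oracle(fit, pid)
    row3 <- eb$level3[eb$level3$person_id == pid, ]
    expect_equal(c(row3$u00, row3$u01, row3$u10), oracle[1:3],
                 tolerance = 1e-8)
    rows2 <- eb$level2[eb$level2$person_id == pid, ]
    expect_equal(as.numeric(t(cbind(rows2$mu0, rows2$mu1))),
                 oracle[-(1:3)], tolerance = 1e-8)
  }
})

test_that("empirical-Bayes estimates are centered and shrunken", {
  d <- burst_design(n_persons = 150)
  r <- simulate_rti(d, crt_like, seed = 68)
  fit <- fit_conditional(r)
  eb <- extract_random_effects(fit)
  expect_lt(abs(mean(eb$level3$u01)), 0.05)
  expect_lt(abs(mean(eb$level3$u00)), 0.5)
  # shrinkage: BLUP variance below the generating variance
  expect_lte(stats::var(eb$level3$u01), crt_like$level3_cov[2, 2] + 0.02)
  # ...and correlated with the true simulated effects
  truth <- unique(r[c("person_id", "u00", "u01")])
  expect_gt(stats::cor(eb$level3$u00, truth$u00), 0.8)
})

test_that("degenerate level-3 prior drives all person effects to zero", {
  d <- burst_design(n_persons = 20)
  r <- simulate_rti(d, crt_like, seed = 69)
  fit <- fit_conditional(r)
  fit$varcomp$level3_cov <- matrix(0, 3, 3,
                                   dimnames = dimnames(fit$varcomp$level3_cov))
  eb <- extract_random_effects(fit)
  expect_equal(max(abs(as.matrix(eb$level3[, -1]))), 0)
})

test_that("the unconditional decomposition recovers degenerate corners", {
  d <- burst_design(n_persons = 120)
  # zero within-person variance: between-person share ~100%
  r <- simulate_rti(d, uncond_params(30, 0, 0.05), seed = 70)
  dec <- fit_unconditional(r)
  expect_gt(dec$shares[["person"]], 97)
  # equal unit variances at the three levels: shares ~ a third each
  r2 <- simulate_rti(d, uncond_params(1, 1, 1), seed = 71)
  dec2 <- fit_unconditional(r2)
  expect_equal(unname(dec2$shares), rep(100 / 3, 3), tolerance = 0.2)
  expect_equal(sum(dec2$shares), 100)
})

test_that("malformed inputs are rejected", {
  r <- simulate_rti(tiny_design, crt_like, seed = 72)
  expect_error(fit_unconditional(r[r$year == 1, ]), ">= 2")
  params_bad <- list(gamma = c(intercept = 50, week = 0, year = 0, age = 0,
                               sex = 0),
                     level3_cov = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3),
                     level2_vars = c(intercept = 1, week = 0), sigma2 = 1)
  expect_error(marginal_loglik(params_bad, r), "semi-definite")
})
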