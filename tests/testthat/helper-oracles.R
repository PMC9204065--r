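# Independent oracles and small fixture builders used across the suite.

# Dense multivariate-normal log-likelihood for the three-level model, built
# pairwise from the covariance formula (independent of the package's
# Cholesky/block evaluation path).
dense_loglik_oracle <- function(params, dat, age_center = 74,
                                week_spacing = 2) {
  dat <- dat[order(dat$person_id, dat$year, dat$session), ]
  if (!"week" %in% names(dat)) dat$week <- week_spacing * (dat$session - 1)
  n <- nrow(dat)
  G3 <- params$level3_cov
  g2 <- params$level2_vars
  V <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (dat$person_id[a] != dat$person_id[b]) next
      za <- c(1, dat$year[a] - 1, dat$week[a])
      zb <- c(1, dat$year[b] - 1, dat$week[b])
      v <- as.numeric(t(za) %*% G3 %*% zb)
      if (dat$year[a] == dat$year[b]) {
        v <- v + g2[["intercept"]] + g2[["week"]] * dat$week[a] * dat$week[b]
      }
      if (a == b) v <- v + params$sigma2
      V[a, b] <- v
    }
  }
  mu <- params$gamma[["intercept"]] +
    params$gamma[["week"]] * dat$week +
    params$gamma[["year"]] * (dat$year - 1) +
    params$gamma[["age"]] * (dat$age_baseline - age_center) +
    params$gamma[["sex"]] * dat$sex
  r <- dat$t_score - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% solve(V) %*% r))
}

# Dense conjugate-Gaussian posterior mean of the stacked random effects for
# one person: b | y ~ N(G Z' V^-1 r, .), assembled explicitly.
dense_blup_oracle <- function(fit, person) {
  mf <- fit$frame
  rows <- which(mf$person == person)
  wk <- mf$week[rows]
  yr <- mf$year0[rows]
  r <- (mf$y - as.numeric(mf$X %*% fit$beta))[rows]
  G3 <- fit$varcomp$level3_cov
  g2 <- fit$varcomp$level2_vars
  years <- unique(yr)
  q <- 3 + 2 * length(years)
  Z <- matrix(0, length(rows), q)
  Z[, 1] <- 1
  Z[, 2] <- yr
  Z[, 3] <- wk
  G <- matrix(0, q, q)
  G[1:3, 1:3] <- G3
  for (ji in seq_along(years)) {
    cols <- 3 + 2 * (ji - 1) + 1:2
    sel <- yr == years[ji]
    Z[sel, cols] <- cbind(1, wk[sel])
    G[cols, cols] <- diag(unname(g2), 2)
  }
  V <- Z %*% G %*% t(Z) + diag(fit$varcomp$sigma2, length(rows))
  as.numeric(G %*% t(Z) %*% solve(V, r))
}

# Parameters for an intercepts-only (unconditional) generating process with
# the given person/year/week variances.
uncond_params <- function(person, year, week) {
  generating_params("CRT",
    gamma100 = 0, gamma010 = 0, gamma001 = 0, gamma002 = 0,
    level3_cov = diag(c(person, 0, 0)),
    level2_vars = c(intercept = year, week = 0),
    level1_var = week,
    group_shift = c(HC = 0, `CIND-S` = 0, `CIND-M` = 0))
}

# Zero-noise conditional generating process (all random effects and the
# occasion residual switched off); fixed effects kept at task defaults
# unless overridden.
noiseless_params <- function(task = "CRT", ...) {
  generating_params(task,
    level3_cov = matrix(0, 3, 3),
    level2_vars = c(intercept = 0, week = 0),
    level1_var = 0,
    group_shift = c(HC = 0, `CIND-S` = 0, `CIND-M` = 0),
    ...)
}

# A small hand-assembled trial table: one person, one session, constant
# latency except where stated.
toy_trials <- function(rt, task = "CRT", person = 1L, year = 1L,
                       session = 1L) {
  tibble::tibble(
    person_id = person, task = task, year = year, session = session,
    trial = seq_along(rt), rt_ms = rt, correct = 1L, missing = 0L)
}
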