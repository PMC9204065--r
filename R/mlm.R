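#' Specification of the three-level RTI change model
#'
#' The model nests biweekly sessions (level 1) within annual bursts (level 2)
#' within persons (level 3). T-scored RTI for week i of year j and person k is
#'
#' \deqn{y_{ijk} = \gamma_{000} + \gamma_{100} Week_{ijk} + \gamma_{010}
#'   Year_{jk} + \gamma_{001} Age_k + \gamma_{002} Sex_k + \upsilon_{00k} +
#'   \upsilon_{01k} Year_{jk} + \upsilon_{10k} Week_{ijk} + \mu_{0jk} +
#'   \mu_{1jk} Week_{ijk} + \varepsilon_{ijk}}
#'
#' with week and year both 0-based at baseline (week resets at each year's
#' first session), age centered (default at 74), and sex coded 0 = male /
#' 1 = female. The person-level effects \eqn{(\upsilon_{00k}, \upsilon_{01k},
#' \upsilon_{10k})} carry an unstructured 3x3 covariance; the person-year
#' effects \eqn{(\mu_{0jk}, \mu_{1jk})} a diagonal one; \eqn{\varepsilon} is
#' i.i.d. Estimation is full maximum likelihood over all available occasions
#' (missing cells simply absent, assuming missing at random). The weekly
#' fixed slope \eqn{\gamma_{100}} is the short-term (retest) effect and the
#' yearly slope \eqn{\gamma_{010}} the long-term (developmental) effect.
#'
#' @param age_center Centering constant for baseline age, years.
#' @param week_spacing Weeks between consecutive sessions (used to derive the
#'   week covariate from session indices when the data lack a `week` column).
#' @param include_interactions Include age x year and sex x year fixed terms?
#'   Off by default (the covariate-by-year products are omitted from the
#'   default change model).
#' @param level3 Person-level random-effect structure: `"unstructured"`
#'   (default), `"diagonal"`, or `"intercept"`.
#' @param level2_slope Include the person-year random week slope?
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `mlm_spec`.
#' @export
mlm_spec <- function(age_center = 74, week_spacing = 2,
                     include_interactions = FALSE,
                     level3 = c("unstructured", "diagonal", "intercept"),
                     level2_slope = TRUE, conf_level = 0.95) {
  structure(list(age_center = age_center, week_spacing = week_spacing,
                 include_interactions = include_interactions,
                 level3 = match.arg(level3), level2_slope = level2_slope,
                 conf_level = conf_level),
            class = "mlm_spec")
}

# ---- model-frame assembly ---------------------------------------------------

mlm_frame <- function(rti, covariates = NULL, spec = mlm_spec(),
                      task = NULL) {
  d <- rti
  if (!is.null(task) && "task" %in% names(d)) d <- d[d$task == task, ]
  if ("task" %in% names(d) && length(unique(d$task)) > 1) {
    stop("one task at a time: pass `task = ` to select", call. = FALSE)
  }
  if (!"week" %in% names(d)) d$week <- spec$week_spacing * (d$session - 1)
  if (!"year0" %in% names(d)) d$year0 <- d$year - 1
  if (!is.null(covariates)) {
    keep <- setdiff(names(covariates), names(d))
    d <- dplyr::left_join(d, covariates[c("person_id", keep)],
                          by = "person_id")
  }
  d$age_c <- d$age_baseline - spec$age_center
  if (anyNA(d$age_c) || anyNA(d$sex)) {
    stop("age/sex covariates incomplete for modeled persons", call. = FALSE)
  }
  d <- d[order(d$person_id, d$year0, d$week), ]
  X <- cbind(intercept = 1, week = d$week, year = d$year0,
             age = d$age_c, sex = d$sex)
  if (spec$include_interactions) {
    X <- cbind(X, `age:year` = d$age_c * d$year0,
               `sex:year` = d$sex * d$year0)
  }
  list(data = d, y = d$t_score, X = X, week = d$week, year0 = d$year0,
       person = d$person_id)
}

# ---- variance parameterization ---------------------------------------------
# All random-effect covariances are parameterized as ratios to the residual
# variance; the residual variance and the fixed effects are profiled out of
# the likelihood. Level-3 uses a log-Cholesky parameterization (diagonal on
# the log scale), level-2 log variances.

theta_template <- function(level3, level2_slope) {
  n3 <- switch(level3, unstructured = 6L, diagonal = 3L, intercept = 1L)
  n2 <- if (level2_slope) 2L else 1L
  list(n3 = n3, n2 = n2, level3 = level3, level2_slope = level2_slope)
}

theta_to_cov <- function(theta, tmpl) {
  t3 <- theta[seq_len(tmpl$n3)]
  t2 <- theta[tmpl$n3 + seq_len(tmpl$n2)]
  if (tmpl$level3 == "unstructured") {
    L <- matrix(0, 3, 3)
    diag(L) <- exp(t3[c(1, 3, 6)])
    L[2, 1] <- t3[2]
    L[3, 1] <- t3[4]
    L[3, 2] <- t3[5]
    G3 <- L %*% t(L)
  } else if (tmpl$level3 == "diagonal") {
    G3 <- diag(exp(2 * t3), 3)
  } else {
    G3 <- diag(c(exp(2 * t3), 0, 0), 3)
  }
  g2 <- c(intercept = exp(2 * t2[1]),
          week = if (tmpl$level2_slope) exp(2 * t2[2]) else 0)
  list(G3 = G3, g2 = g2)
}

start_theta <- function(y, X, person, year0, tmpl) {
  r <- stats::lm.fit(X, y)$residuals
  pk <- stats::ave(r, person)
  pjk <- stats::ave(r, person, year0)
  v3 <- max(stats::var(pk), 1e-3)
  v2 <- max(stats::var(pjk - pk), 1e-3)
  s2 <- max(stats::var(r - pjk), 1e-3)
  r3 <- sqrt(v3 / s2)
  r2 <- sqrt(v2 / s2)
  small <- log(0.1 * r3 + 1e-4)
  t3 <- switch(tmpl$level3,
    unstructured = c(log(r3), 0, small, 0, 0, small),
    diagonal = c(log(r3), small, small),
    intercept = log(r3))
  t2 <- if (tmpl$level2_slope) c(log(r2), small) else log(r2)
  c(t3, t2)
}

# ---- pattern-grouped profiled likelihood -----------------------------------

# Persons sharing an identical (week, year0) layout share the same marginal
# covariance; group them so each likelihood evaluation does one Cholesky per
# layout instead of one per person.
build_groups <- function(y, X, week, year0, person) {
  p <- ncol(X)
  idx <- split(seq_along(y), person)
  keys <- vapply(idx, function(i) {
    paste(week[i], year0[i], sep = ",", collapse = ";")
  }, character(1))
  groups <- lapply(split(seq_along(idx), keys), function(gi) {
    rows1 <- idx[[gi[1]]]
    T_g <- length(rows1)
    n_g <- length(gi)
    arr <- array(0, c(T_g, p + 1, n_g))
    for (m in seq_len(n_g)) {
      r <- idx[[gi[m]]]
      arr[, , m] <- cbind(X[r, , drop = FALSE], y[r])
    }
    w <- week[rows1]
    yr <- year0[rows1]
    list(n_g = n_g, T_g = T_g,
         persons = as.integer(names(idx)[gi]),
         Z3 = cbind(1, yr, w),
         week = w, year_blocks = split(seq_len(T_g), yr),
         bigmat = matrix(arr, T_g, (p + 1) * n_g))
  })
  list(groups = groups, p = p, N = length(y), n_persons = length(idx),
       person_rows = idx)
}

group_V0 <- function(g, G3, g2) {
  V0 <- g$Z3 %*% G3 %*% t(g$Z3) + diag(g$T_g)
  for (rows in g$year_blocks) {
    Z2 <- cbind(1, g$week[rows])
    V0[rows, rows] <- V0[rows, rows] + Z2 %*% diag(g2, 2) %*% t(Z2)
  }
  V0
}

profiled_negll <- function(theta, gd, tmpl) {
  cv <- theta_to_cov(theta, tmpl)
  p <- gd$p
  C <- matrix(0, p + 1, p + 1)
  logdet <- 0
  for (g in gd$groups) {
    V0 <- group_V0(g, cv$G3, cv$g2)
    U <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    logdet <- logdet + g$n_g * 2 * sum(log(diag(U)))
    W <- forwardsolve(t(U), g$bigmat)
    arr <- array(W, c(g$T_g, p + 1, g$n_g))
    stacked <- matrix(aperm(arr, c(1, 3, 2)), g$T_g * g$n_g, p + 1)
    C <- C + crossprod(stacked)
  }
  XtWX <- C[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- C[seq_len(p), p + 1]
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  qf <- max(C[p + 1, p + 1] - sum(beta * XtWy), 0)
  sigma2 <- max(qf / gd$N, 1e-12)
  0.5 * (gd$N * log(2 * pi) + gd$N * log(sigma2) + qf / sigma2 + logdet)
}

# GLS quantities at a given theta (for the final fit)
gls_at_theta <- function(theta, gd, tmpl) {
  cv <- theta_to_cov(theta, tmpl)
  p <- gd$p
  C <- matrix(0, p + 1, p + 1)
  logdet <- 0
  for (g in gd$groups) {
    V0 <- group_V0(g, cv$G3, cv$g2)
    U <- chol(V0)
    logdet <- logdet + g$n_g * 2 * sum(log(diag(U)))
    W <- forwardsolve(t(U), g$bigmat)
    arr <- array(W, c(g$T_g, p + 1, g$n_g))
    stacked <- matrix(aperm(arr, c(1, 3, 2)), g$T_g * g$n_g, p + 1)
    C <- C + crossprod(stacked)
  }
  XtWX <- C[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- C[seq_len(p), p + 1]
  beta <- solve(XtWX, XtWy)
  qf <- max(C[p + 1, p + 1] - sum(beta * XtWy), 0)
  sigma2 <- max(qf / gd$N, 1e-12)
  loglik <- -0.5 * (gd$N * log(2 * pi) + gd$N * log(sigma2) +
                      qf / sigma2 + logdet)
  vcov_beta <- sigma2 * solve(XtWX)
  list(beta = beta, vcov_beta = vcov_beta, sigma2 = sigma2,
       G3 = sigma2 * cv$G3, g2 = sigma2 * cv$g2, loglik = loglik)
}

fit_engine <- function(y, X, week, year0, person, level3, level2_slope) {
  gd <- build_groups(y, X, week, year0, person)
  tmpl <- theta_template(level3, level2_slope)
  start <- start_theta(y, X, person, year0, tmpl)
  opt <- stats::nlminb(start, profiled_negll, gd = gd, tmpl = tmpl,
                       control = list(eval.max = 2000, iter.max = 1000,
                                      rel.tol = 1e-10))
  if (opt$convergence != 0) {
    # restart once from the current iterate; accept if the objective is
    # stationary (nlminb reports "singular convergence" at flat optima when
    # a variance sits near its boundary)
    opt2 <- stats::nlminb(opt$par, profiled_negll, gd = gd, tmpl = tmpl,
                          control = list(eval.max = 2000, iter.max = 1000,
                                         rel.tol = 1e-8))
    if (opt2$objective <= opt$objective + 1e-6) opt <- opt2
  }
  converged <- is.finite(opt$objective) &&
    (opt$convergence == 0 ||
       grepl("singular convergence", opt$message %||% ""))
  res <- gls_at_theta(opt$par, gd, tmpl)
  res$theta <- opt$par
  res$converged <- converged
  res$message <- opt$message
  res$gd <- gd
  res$tmpl <- tmpl
  res
}

# ---- public fitting functions ----------------------------------------------

#' Fit the unconditional three-level variance-decomposition model
#'
#' Random intercepts at the person and person-year levels with no fixed
#' predictors beyond the grand mean: decomposes total RTI variability into
#' between-person, within-person-between-year, and within-person-between-week
#' (occasion) components and their percentage shares.
#'
#' @param rti RTI score table with `person_id`, `year`, `session`, `t_score`
#'   (optionally `task`).
#' @param task Task to select when `rti` holds several.
#' @param spec An [mlm_spec()] (only the week coding is used).
#' @return An object of class `variance_decomposition` with `components`
#'   (named variances), `shares` (percentages summing to 100), `loglik`,
#'   `converged`.
#' @export
fit_unconditional <- function(rti, task = NULL, spec = mlm_spec()) {
  d <- rti
  if (!is.null(task) && "task" %in% names(d)) d <- d[d$task == task, ]
  if ("task" %in% names(d) && length(unique(d$task)) > 1) {
    stop("one task at a time: pass `task = `", call. = FALSE)
  }
  if (!"week" %in% names(d)) d$week <- spec$week_spacing * (d$session - 1)
  if (!"year0" %in% names(d)) d$year0 <- d$year - 1
  if (length(unique(d$person_id)) < 2 || length(unique(d$year0)) < 2 ||
      length(unique(d$week)) < 2) {
    stop("need >= 2 persons, years, and weeks", call. = FALSE)
  }
  d <- d[order(d$person_id, d$year0, d$week), ]
  X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "intercept"))
  res <- fit_engine(d$t_score, X, d$week, d$year0, d$person_id,
                    level3 = "intercept", level2_slope = FALSE)
  if (!res$converged) {
    stop("unconditional model did not converge: ", res$message, call. = FALSE)
  }
  comp <- c(person = res$G3[1, 1], year = unname(res$g2["intercept"]),
            week = res$sigma2)
  structure(list(components = comp, shares = 100 * comp / sum(comp),
                 grand_mean = unname(res$beta[1]), loglik = res$loglik,
                 converged = res$converged, n_obs = nrow(d)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Three-level variance decomposition of RTI\n")
  lab <- c(person = "between-person", year = "within-person, across years",
           week = "within-person, across weeks")
  for (nm in names(x$components)) {
    cat(sprintf("  %-30s %8.3f  (%5.1f%%)\n", lab[[nm]],
                x$components[[nm]], x$shares[[nm]]))
  }
  invisible(x)
}

#' Fit the conditional three-level change model
#'
#' Full-maximum-likelihood fit of the three-level model described in
#' [mlm_spec()]: fixed weekly (retest) and yearly (developmental) slopes plus
#' age and sex, person-level random intercept/year-slope/week-slope with
#' unstructured covariance, person-year random intercept and week slope, and
#' an i.i.d. occasion residual. If the requested person-level covariance
#' structure does not converge, the fit falls back automatically
#' (unstructured -> diagonal -> intercept-only) and records the structure
#' used.
#'
#' @param rti RTI score table (`person_id`, `year`, `session`, `t_score`,
#'   optionally `task`/`week`; covariate columns are taken from here if
#'   present).
#' @param covariates Optional person-level tibble with `person_id`,
#'   `age_baseline`, `sex`, joined onto the scores.
#' @param spec An [mlm_spec()].
#' @param task Task to select when `rti` holds several.
#' @return An object of class `mlm_fit`: `gamma` (tibble of fixed-effect
#'   estimates, Wald SEs/CIs/p), `varcomp` (level-3 covariance, level-2
#'   variances, residual variance), `loglik`, `converged`, `structure3`,
#'   counts, and the internals needed by [extract_random_effects()].
#' @export
fit_conditional <- function(rti, covariates = NULL, spec = mlm_spec(),
                            task = NULL) {
  mf <- mlm_frame(rti, covariates, spec, task)
  ladder <- switch(spec$level3,
    unstructured = c("unstructured", "diagonal", "intercept"),
    diagonal = c("diagonal", "intercept"),
    intercept = "intercept")
  res <- NULL
  used <- NULL
  for (str3 in ladder) {
    res <- fit_engine(mf$y, mf$X, mf$week, mf$year0, mf$person,
                      level3 = str3, level2_slope = spec$level2_slope)
    used <- str3
    if (res$converged) break
    if (str3 != ladder[length(ladder)]) {
      warning("level-3 ", str3, " covariance did not converge; refitting ",
              "with a simpler structure", call. = FALSE)
    }
  }
  z <- stats::qnorm(1 - (1 - spec$conf_level) / 2)
  se <- sqrt(diag(res$vcov_beta))
  gamma <- tibble::tibble(
    term = colnames(mf$X),
    estimate = as.numeric(res$beta),
    se = se,
    ci_lb = as.numeric(res$beta) - z * se,
    ci_ub = as.numeric(res$beta) + z * se,
    z = as.numeric(res$beta) / se,
    p = 2 * stats::pnorm(-abs(as.numeric(res$beta) / se))
  )
  G3 <- res$G3
  dimnames(G3) <- list(c("intercept", "year", "week"),
                       c("intercept", "year", "week"))
  structure(list(
    gamma = gamma,
    beta = stats::setNames(as.numeric(res$beta), colnames(mf$X)),
    vcov_beta = res$vcov_beta,
    varcomp = list(level3_cov = G3, level2_vars = res$g2,
                   sigma2 = res$sigma2),
    loglik = res$loglik,
    converged = res$converged,
    structure3 = used,
    level2_slope = spec$level2_slope,
    n_obs = length(mf$y),
    n_persons = length(unique(mf$person)),
    n_person_years = nrow(unique(cbind(mf$person, mf$year0))),
    spec = spec,
    frame = mf,
    theta = res$theta
  ), class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, digits = 3, ...) {
  cat("Three-level RTI change model (full ML)\n")
  cat("  observations:", x$n_obs, "| persons:", x$n_persons,
      "| person-years:", x$n_person_years, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT CONVERGED)" else "", "\n")
  cat("  level-3 structure:", x$structure3, "\n\nFixed effects:\n")
  g <- x$gamma
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-10s %8.*f  [%.*f, %.*f]  p = %s\n", g$term[i],
                digits, g$estimate[i], digits, g$ci_lb[i], digits,
                g$ci_ub[i], format.pval(g$p[i], digits = 3)))
  }
  cat("\nVariance components:\n")
  cat("  residual (week-to-week):", format(x$varcomp$sigma2, digits = 4),
      "\n")
  cat("  person-year: intercept",
      format(x$varcomp$level2_vars[["intercept"]], digits = 4),
      "| week slope", format(x$varcomp$level2_vars[["week"]], digits = 4),
      "\n")
  cat("  person (level-3 covariance):\n")
  print(round(x$varcomp$level3_cov, 4))
  invisible(x)
}

#' Exact marginal log-likelihood of the three-level model
#'
#' Evaluates the Gaussian marginal log-likelihood at user-supplied
#' parameters, person block by person block (occasions missing for a person
#' are simply absent). Intended as a checkable building block: it agrees
#' with a dense multivariate-normal evaluation of the stacked model to
#' numerical precision.
#'
#' @param params List with `gamma` (named fixed-effect vector matching the
#'   model terms), `level3_cov` (3x3, order intercept/year/week),
#'   `level2_vars` (length-2, intercept and week-slope variances), `sigma2`.
#' @param data RTI score table as for [fit_conditional()] (covariates
#'   included or joined beforehand).
#' @param spec An [mlm_spec()].
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(params, data, spec = mlm_spec()) {
  stopifnot(is.matrix(params$level3_cov), params$sigma2 > 0)
  if (!is_psd(params$level3_cov) || any(params$level2_vars < 0)) {
    stop("random-effect covariances must be positive semi-definite",
         call. = FALSE)
  }
  mf <- mlm_frame(data, covariates = NULL, spec = spec)
  gamma <- params$gamma[colnames(mf$X)]
  if (anyNA(gamma)) {
    stop("`params$gamma` must name every fixed-effect term: ",
         paste(colnames(mf$X), collapse = ", "), call. = FALSE)
  }
  r <- mf$y - as.numeric(mf$X %*% gamma)
  ll <- 0
  for (rows in split(seq_along(r), mf$person)) {
    V <- person_V(mf$week[rows], mf$year0[rows], params$level3_cov,
                  params$level2_vars, params$sigma2)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) {  # ridge-stabilized fallback for singular covariance
      warning("singular marginal covariance; ridge-stabilized evaluation",
              call. = FALSE)
      U <- chol(V + diag(1e-8 * mean(diag(V)), nrow(V)))
    }
    w <- forwardsolve(t(U), r[rows])
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(U))) +
                        sum(w^2))
  }
  ll
}

person_V <- function(week, year0, G3, g2, sigma2) {
  Z3 <- cbind(1, year0, week)
  V <- Z3 %*% G3 %*% t(Z3) + diag(sigma2, length(week))
  for (rows in split(seq_along(week), year0)) {
    Z2 <- cbind(1, week[rows])
    V[rows, rows] <- V[rows, rows] + Z2 %*% diag(g2, 2) %*% t(Z2)
  }
  V
}

#' Empirical-Bayes (BLUP) random-effect estimates
#'
#' Conditional means of the random effects given the data at the fitted
#' parameter values: for person k with marginal covariance V and residual r,
#' the stacked effect estimate is G Z' V^{-1} r. Estimates shrink toward
#' zero relative to the generating effects. Persons with no observed
#' occasions receive the prior mean (zero).
#'
#' @param fit An [fit_conditional()] result.
#' @return An object of class `eb_estimates`: `level3` (per person:
#'   `u00`, `u01`, `u10`), `level2` (per person-year: `mu0`, `mu1`), and
#'   `latent` (derived person-year coefficients: intercept `beta0jk` and
#'   week slope `beta1jk`).
#' @export
extract_random_effects <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (!fit$converged) {
    warning("fit did not converge; BLUPs are at the last iterate",
            call. = FALSE)
  }
  mf <- fit$frame
  G3 <- fit$varcomp$level3_cov
  g2 <- fit$varcomp$level2_vars
  sigma2 <- fit$varcomp$sigma2
  r <- mf$y - as.numeric(mf$X %*% fit$beta)

  persons <- unique(mf$person)
  lvl3 <- matrix(0, length(persons), 3,
                 dimnames = list(NULL, c("u00", "u01", "u10")))
  lvl2 <- list()
  for (pi in seq_along(persons)) {
    rows <- which(mf$person == persons[pi])
    wk <- mf$week[rows]
    yr <- mf$year0[rows]
    Z3 <- cbind(1, yr, wk)
    yblocks <- split(seq_along(rows), yr)
    # stacked random-effect design and prior covariance
    Zs <- list(Z3)
    Gs <- list(G3)
    for (b in yblocks) {
      Z2 <- matrix(0, length(rows), 2)
      Z2[b, ] <- cbind(1, wk[b])
      Zs <- c(Zs, list(Z2))
      Gs <- c(Gs, list(diag(g2, 2)))
    }
    Z <- do.call(cbind, Zs)
    G <- as.matrix(Matrix_bdiag(Gs))
    V <- Z %*% G %*% t(Z) + diag(sigma2, length(rows))
    b <- as.numeric(G %*% t(Z) %*% solve(V, r[rows]))
    lvl3[pi, ] <- b[1:3]
    yrs <- as.numeric(names(yblocks))
    lvl2[[pi]] <- tibble::tibble(
      person_id = persons[pi], year0 = yrs, year = yrs + 1,
      mu0 = b[seq(4, by = 2, length.out = length(yrs))],
      mu1 = b[seq(5, by = 2, length.out = length(yrs))])
  }
  level3 <- tibble::tibble(person_id = persons, u00 = lvl3[, 1],
                           u01 = lvl3[, 2], u10 = lvl3[, 3])
  level2 <- dplyr::bind_rows(lvl2)

  # derived latent person-year coefficients
  b <- fit$beta
  covs <- dplyr::distinct(mf$data, .data$person_id, .data$age_c, .data$sex)
  lat <- dplyr::left_join(level2, level3, by = "person_id")
  lat <- dplyr::left_join(lat, covs, by = "person_id")
  g011 <- unname(b["age:year"] %||% 0)
  g012 <- unname(b["sex:year"] %||% 0)
  g011 <- if (is.na(g011)) 0 else g011
  g012 <- if (is.na(g012)) 0 else g012
  lat$beta0jk <- b[["intercept"]] + b[["age"]] * lat$age_c +
    b[["sex"]] * lat$sex + lat$u00 +
    (b[["year"]] + g011 * lat$age_c + g012 * lat$sex + lat$u01) * lat$year0 +
    lat$mu0
  lat$beta1jk <- b[["week"]] + lat$u10 + lat$mu1
  structure(list(level3 = level3, level2 = level2,
                 latent = dplyr::select(lat, "person_id", "year",
                                        "beta0jk", "beta1jk")),
            class = "eb_estimates")
}

# small block-diagonal helper (avoids a Matrix dependency for tiny blocks)
Matrix_bdiag <- function(mats) {
  dims <- vapply(mats, nrow, integer(1))
  out <- matrix(0, sum(dims), sum(dims))
  at <- 0
  for (m in mats) {
    d <- nrow(m)
    out[at + seq_len(d), at + seq_len(d)] <- m
    at <- at + d
  }
  out
}
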