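#' Generating parameters for synthetic burst data
#'
#' Bundles every quantity the synthetic-data generator needs: fixed effects of
#' the three-level change model (T-score units), random-effect covariances at
#' the person (level 3) and person-year (level 2) levels, the occasion-level
#' residual variance, the latent-to-trial dispersion link, trial corruption
#' rates, attrition hazards, the cognitive-status mixture, and covariate
#' distributions.
#'
#' Task presets encode the two response-time tasks of a biweekly burst
#' battery: a four-choice spatial task (`"CRT"`, low executive demand: flat
#' weekly trend, increasing yearly trend) and a one-back variant (`"BRT"`,
#' high executive demand: practice-related weekly decline, flat yearly trend).
#' Level variances default to person/year/week = 34/3/13 (CRT) and
#' 37.5/3.5/9 (BRT), i.e. between-person shares of 68% and 75% of a total
#' variance of 50 T-units^2. Incorrect-response rates default to 1.43% (CRT)
#' and 10.46% (BRT); attrition hazards to 11%/3.5%/4.5% between years 1-2,
#' 2-3, 3-4 and 26% between the last burst year and the long-term follow-up.
#'
#' The level-3 covariance is ordered (intercept, year slope, week slope).
#' The latent dispersion score t (T units) maps to a trial-level latency SD
#' in ms via `sd_ms = trial_sd_intercept + trial_sd_slope * t`, floored at
#' `trial_sd_floor`; the link is linear so generator ground truth is
#' recoverable downstream.
#'
#' @param task `"CRT"` or `"BRT"`; selects the preset that `...` overrides.
#' @param ... Named overrides of any parameter in the preset.
#' @return An object of class `generating_params` (a validated list).
#' @examples
#' p <- generating_params("CRT", gamma010 = 0.15)
#' p$level1_var
#' @export
generating_params <- function(task = c("CRT", "BRT"), ...) {
  task <- match.arg(task)
  base <- list(
    task = task,
    # fixed effects (T-score units); intercept anchored at the T-score center
    gamma000 = 50,
    gamma100 = if (task == "CRT") -0.02 else -0.06,  # per week (retest)
    gamma010 = if (task == "CRT") 0.15 else -0.09,   # per year (development)
    gamma001 = if (task == "CRT") 0.21 else 0.34,    # per year of age over 74
    gamma002 = if (task == "CRT") -0.24 else 0.25,   # female vs male
    gamma011 = 0,                                    # age x year
    gamma012 = 0,                                    # sex x year
    # random effects: level 3 (intercept, year slope, week slope)
    level3_cov = if (task == "CRT") {
      cov_from_sd_corr(sd = c(sqrt(34), 0.5, 0.2),
                       corr = rbind(c(1, 0.3, 0.3),
                                    c(0.3, 1, 0.6),
                                    c(0.3, 0.6, 1)))
    } else {
      cov_from_sd_corr(sd = c(sqrt(37.5), 0.55, 0.22),
                       corr = rbind(c(1, 0.3, 0.3),
                                    c(0.3, 1, 0.8),
                                    c(0.3, 0.8, 1)))
    },
    # level 2 (person-year): intercept and week-slope variances (diagonal)
    level2_vars = if (task == "CRT") c(intercept = 3, week = 0.02)
                  else c(intercept = 3.5, week = 0.02),
    # level 1 (occasion) residual variance
    level1_var = if (task == "CRT") 13 else 9,
    # group-dependent dispersion: latent intercept shift by true status
    group_shift = c(HC = 0, `CIND-S` = 2, `CIND-M` = 4),
    # latent-to-trial link and trial mean structure (ms)
    trial_sd_intercept = 0,
    trial_sd_slope = 2,
    trial_sd_floor = 5,
    trial_mean_rt = if (task == "CRT") 900 else 1100,
    trial_mean_sd = 120,
    rt_distribution = c("normal", "lognormal"),
    # corruption rates (proportions of administered trials)
    rate_missing = if (task == "CRT") 0.0013 else 0.0020,
    rate_incorrect = if (task == "CRT") 0.0143 else 0.1046,
    rate_outlier = if (task == "CRT") 0.0178 else 0.0242,
    # attrition
    attrition_hazard = c(0.110, 0.035, 0.045),
    attrition_followup = 0.26,
    # cognitive-status mixture (HC, CIND-S, CIND-M)
    group_mix = c(HC = 136, `CIND-S` = 88, `CIND-M` = 80) / 304,
    # covariate distributions
    age_mean = 74.02, age_sd = 5.95, age_range = c(64, 92), age_center = 74,
    p_female = 208 / 304,
    edu_mean = 15.15, edu_sd = 3.14, edu_range = c(7, 24),
    mmse_mean = c(HC = 29.0, `CIND-S` = 28.7, `CIND-M` = 28.3),
    mmse_sd = c(HC = 1.0, `CIND-S` = 1.1, `CIND-M` = 1.5),
    mmse_range = c(24, 30),
    # domain-score generation (units of the norm cell SD)
    deficit_shift = -2.0,
    domain_noise = 1.0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop("unknown generating parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(over)] <- over
  base$rt_distribution <- match.arg(base$rt_distribution[1],
                                    c("normal", "lognormal"))
  validate_generating_params(base)
  structure(base, class = "generating_params")
}

cov_from_sd_corr <- function(sd, corr) {
  diag(sd) %*% corr %*% diag(sd)
}

validate_generating_params <- function(p) {
  if (!is_psd(p$level3_cov)) {
    stop("`level3_cov` must be positive semi-definite", call. = FALSE)
  }
  if (any(p$level2_vars < 0) || p$level1_var < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  assert_prob(c(p$rate_missing, p$rate_incorrect, p$rate_outlier,
                p$attrition_hazard, p$attrition_followup, p$p_female),
              "rates")
  if (abs(sum(p$group_mix) - 1) > 1e-8) {
    stop("`group_mix` must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.generating_params <- function(x, ...) {
  cat("Generating parameters (", x$task, ")\n", sep = "")
  cat("  fixed effects: intercept", x$gamma000,
      "| week", x$gamma100, "| year", x$gamma010,
      "| age", x$gamma001, "| sex", x$gamma002, "\n")
  cat("  level variances (person/year/week):",
      x$level3_cov[1, 1], "/", x$level2_vars[["intercept"]], "/",
      x$level1_var, "\n")
  cat("  corruption rates (missing/incorrect/outlier):",
      sprintf("%.2f%% / %.2f%% / %.2f%%", 100 * x$rate_missing,
              100 * x$rate_incorrect, 100 * x$rate_outlier), "\n")
  invisible(x)
}

#' Generate person-level covariates
#'
#' Draws baseline age (truncated normal), sex (0 = male, 1 = female), years
#' of education, a latent cognitive-status group from the configured mixture,
#' and a group-dependent baseline MMSE score.
#'
#' @param n Number of persons.
#' @param params A [generating_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with one row per person.
#' @export
generate_covariates <- function(n, params = generating_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- names(params$group_mix)
  grp <- sample(groups, n, replace = TRUE, prob = params$group_mix)
  tibble::tibble(
    person_id = seq_len(n),
    age_baseline = round(rnorm_trunc(n, params$age_mean, params$age_sd,
                                     params$age_range[1], params$age_range[2]),
                         1),
    sex = stats::rbinom(n, 1, params$p_female),
    education = round(rnorm_trunc(n, params$edu_mean, params$edu_sd,
                                  params$edu_range[1], params$edu_range[2])),
    true_group = factor(grp, levels = groups),
    mmse_baseline = round(rnorm_trunc(n, params$mmse_mean[grp],
                                      params$mmse_sd[grp],
                                      params$mmse_range[1],
                                      params$mmse_range[2]))
  )
}

#' Simulate study retention
#'
#' Applies the per-year attrition hazards once per person: the last burst year
#' attended, and whether a burst completer returns for the long-term
#' follow-up. Dropout is monotone (a person absent in year y is absent in all
#' later years) and independent of the latent outcome process (missing at
#' random).
#'
#' @param n Number of persons.
#' @param design A [burst_design()].
#' @param params A [generating_params()].
#' @param seed Optional integer seed.
#' @return A tibble with `person_id`, `last_year`, `completes_followup`.
#' @export
simulate_retention <- function(n, design, params = generating_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hz <- params$attrition_hazard
  if (length(hz) < design$n_years - 1) {
    hz <- rep_len(hz, design$n_years - 1)
  }
  # a person drops at the first failed year-to-year transition
  last <- rep(design$n_years, n)
  dropped <- rep(FALSE, n)
  for (y in seq_len(design$n_years - 1)) {
    fail <- !dropped & stats::runif(n) < hz[y]
    last[fail] <- y
    dropped <- dropped | fail
  }
  completes <- !dropped & stats::runif(n) >= params$attrition_followup
  tibble::tibble(person_id = seq_len(n), last_year = as.integer(last),
                 completes_followup = completes)
}

#' Simulate latent RTI scores from the three-level change model
#'
#' Draws T-scored response-time-inconsistency outcomes directly from the
#' three-level linear mixed model: person-level random intercept and year/week
#' slopes with the configured covariance, person-year random intercept and
#' week slope, occasion-level residual, and the configured fixed effects
#' (week and year both 0-based at baseline, age centered, sex 0/1).
#'
#' @param design A [burst_design()].
#' @param params A [generating_params()].
#' @param covariates Optional tibble from [generate_covariates()]; generated
#'   if `NULL`. Supply `age_baseline = params$age_center` and `sex = 0` rows
#'   (or set the covariate fixed effects to zero) to simulate without
#'   covariate structure.
#' @param retention Optional tibble from [simulate_retention()]; if supplied,
#'   person-years after a person's `last_year` are removed.
#' @param seed Optional integer seed.
#' @return A tibble with one row per person x year x session: `person_id`,
#'   `year`, `session`, `week`, `year0`, `t_score`, plus the covariates and
#'   ground-truth random effects (`u00`, `u01`, `u10`).
#' @export
simulate_rti <- function(design, params = generating_params(),
                         covariates = NULL, retention = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_persons
  if (is.null(covariates)) covariates <- generate_covariates(n, params)
  stopifnot(nrow(covariates) == n)

  u3 <- matrix(stats::rnorm(n * 3), n, 3) %*% mat_sqrt(params$level3_cov)
  colnames(u3) <- c("u00", "u01", "u10")

  grid <- design_grid(design)
  dat <- tidyr::crossing(person_id = covariates$person_id, grid)
  dat <- dplyr::left_join(dat, covariates, by = "person_id")
  dat <- dplyr::left_join(
    dat, tibble::tibble(person_id = covariates$person_id,
                        u00 = u3[, 1], u01 = u3[, 2], u10 = u3[, 3]),
    by = "person_id")

  # person-year random effects (diagonal covariance)
  py <- dplyr::distinct(dat, .data$person_id, .data$year)
  py$mu0 <- stats::rnorm(nrow(py), 0, sqrt(params$level2_vars[["intercept"]]))
  py$mu1 <- stats::rnorm(nrow(py), 0, sqrt(params$level2_vars[["week"]]))
  dat <- dplyr::left_join(dat, py, by = c("person_id", "year"))

  dat$year0 <- dat$year - 1
  age_c <- dat$age_baseline - params$age_center
  shift <- params$group_shift[as.character(dat$true_group)]
  shift[is.na(shift)] <- 0
  eps <- stats::rnorm(nrow(dat), 0, sqrt(params$level1_var))
  dat$t_score <-
    params$gamma000 + shift +
    (params$gamma100 + dat$u10 + dat$mu1) * dat$week +
    (params$gamma010 + dat$u01) * dat$year0 +
    params$gamma001 * age_c + params$gamma002 * dat$sex +
    params$gamma011 * age_c * dat$year0 +
    params$gamma012 * dat$sex * dat$year0 +
    dat$u00 + dat$mu0 + eps

  if (!is.null(retention)) {
    dat <- dplyr::left_join(dat, retention[c("person_id", "last_year")],
                            by = "person_id")
    dat <- dplyr::filter(dat, .data$year <= .data$last_year)
    dat$last_year <- NULL
  }
  dplyr::select(dat, "person_id", "year", "session", "week", "year0",
                "age_baseline", "sex", "education", "true_group",
                dplyr::any_of("mmse_baseline"), "t_score",
                "u00", "u01", "u10")
}

#' Generate trial-level response-time data
#'
#' Produces the raw long-format trial table the analysis pipeline consumes.
#' For every retained person x year x session x task, a latent dispersion
#' score is drawn from the three-level change model ([simulate_rti()]); trial
#' latencies are then drawn around a person-specific mean with an SD given by
#' the linear latent-to-trial link. Missing responses, incorrect responses,
#' and injected outliers are superimposed at the configured rates with
#' ground-truth flags. The one-back task (BRT) administers one extra lead-in
#' trial (trial 1, no response recorded).
#'
#' @param design A [burst_design()].
#' @param params Named list of [generating_params()], one per task in
#'   `design$tasks`. A single `generating_params` object is accepted for a
#'   single-task design.
#' @param covariates Optional covariate tibble; generated if `NULL`.
#' @param retention Optional retention tibble; simulated if `NULL` and
#'   `attrition = TRUE`.
#' @param attrition Apply study dropout? Default `TRUE`.
#' @param seed Optional integer seed.
#' @return A list with `trials` (one row per administered trial: `person_id`,
#'   `task`, `year`, `session`, `trial`, `rt_ms`, `correct`, `missing`,
#'   `injected_outlier`), `latent` (ground-truth RTI per cell and task),
#'   `covariates`, and `retention`.
#' @export
generate_trials <- function(design, params = NULL, covariates = NULL,
                            retention = NULL, attrition = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) {
    params <- lapply(design$tasks, function(tk) {
      generating_params(if (tk %in% c("CRT", "BRT")) tk else "CRT")
    })
    names(params) <- design$tasks
  }
  if (inherits(params, "generating_params")) {
    params <- stats::setNames(list(params), design$tasks[1])
  }
  stopifnot(all(design$tasks %in% names(params)))
  p1 <- params[[design$tasks[1]]]
  n <- design$n_persons
  if (is.null(covariates)) covariates <- generate_covariates(n, p1)
  if (is.null(retention)) {
    retention <- if (attrition) simulate_retention(n, design, p1)
                 else tibble::tibble(person_id = covariates$person_id,
                                     last_year = design$n_years,
                                     completes_followup = TRUE)
  }

  all_trials <- list()
  all_latent <- list()
  for (tk in design$tasks) {
    p <- params[[tk]]
    latent <- simulate_rti(design, p, covariates = covariates,
                           retention = retention)
    latent$task <- tk
    latent$sd_ms <- pmax(p$trial_sd_intercept + p$trial_sd_slope *
                           latent$t_score, p$trial_sd_floor)
    pm <- stats::rnorm(n, p$trial_mean_rt, p$trial_mean_sd)
    latent$mean_ms <- pm[latent$person_id]

    n_admin <- design$trials_per_session + (tk == "BRT")
    cells <- nrow(latent)
    idx <- rep(seq_len(cells), each = n_admin)
    tr <- tibble::tibble(
      person_id = latent$person_id[idx],
      task = tk,
      year = latent$year[idx],
      session = latent$session[idx],
      trial = rep(seq_len(n_admin), cells),
      cell_mean = latent$mean_ms[idx],
      cell_sd = latent$sd_ms[idx]
    )
    if (p$rt_distribution == "lognormal") {
      sdlog <- sqrt(log(1 + (tr$cell_sd / tr$cell_mean)^2))
      meanlog <- log(tr$cell_mean) - sdlog^2 / 2
      tr$rt_ms <- stats::rlnorm(nrow(tr), meanlog, sdlog)
    } else {
      tr$rt_ms <- stats::rnorm(nrow(tr), tr$cell_mean, tr$cell_sd)
    }
    tr$correct <- 1L
    tr$missing <- 0L
    tr$injected_outlier <- 0L

    miss <- stats::runif(nrow(tr)) < p$rate_missing
    inc <- !miss & stats::runif(nrow(tr)) < p$rate_incorrect
    outl <- !miss & !inc & stats::runif(nrow(tr)) < p$rate_outlier
    tr$missing[miss] <- 1L
    tr$rt_ms[miss] <- NA_real_
    tr$correct[miss] <- NA_integer_
    tr$correct[inc] <- 0L
    if (any(outl)) {
      # planted gross errors (e.g. attention lapses, double key presses):
      # far enough out that single-pass screening reliably flags them even
      # though the planted values themselves inflate the cell SD
      slow <- outl & stats::runif(nrow(tr)) < 0.8
      fast <- outl & !slow
      tr$rt_ms[slow] <- tr$cell_mean[slow] +
        stats::runif(sum(slow), 5, 10) * tr$cell_sd[slow]
      tr$rt_ms[fast] <- stats::runif(sum(fast), 60, 140)
      tr$injected_outlier[outl] <- 1L
    }
    if (tk == "BRT") {
      lead <- tr$trial == 1L
      tr$rt_ms[lead] <- NA_real_
      tr$correct[lead] <- NA_integer_
      tr$missing[lead] <- 0L
      tr$injected_outlier[lead] <- 0L
    }
    tr$cell_mean <- NULL
    tr$cell_sd <- NULL
    all_trials[[tk]] <- tr
    all_latent[[tk]] <- dplyr::select(latent, "person_id", "task", "year",
                                      "session", "week", "t_score", "sd_ms",
                                      "u00", "u01", "u10")
  }

  list(trials = dplyr::bind_rows(all_trials),
       latent = dplyr::bind_rows(all_latent),
       covariates = covariates,
       retention = retention)
}

#' Synthetic normative table for the five cognitive reference domains
#'
#' Builds the age-band x education-band x domain lookup of means and SDs used
#' for cognitive-status classification. Values are synthetic: each domain has
#' a base mean/SD, performance is lower in the 75+ age band and higher in the
#' 13+ education band. The five domains stand in for perceptual speed, verbal
#' fluency, vocabulary, episodic memory, and inductive reasoning indicators.
#'
#' @return A tibble with columns `age_band`, `edu_band`, `domain`, `mean`,
#'   `sd` (20 rows).
#' @export
synth_norm_table <- function() {
  domains <- tibble::tibble(
    domain = c("speed", "fluency", "vocabulary", "memory", "reasoning"),
    base_mean = c(45, 38, 22, 20, 15),
    base_sd = c(10, 9, 6, 4, 4)
  )
  grid <- tidyr::crossing(age_band = c("65-74", "75+"),
                          edu_band = c("0-12", "13+"),
                          domains)
  grid$mean <- grid$base_mean -
    0.6 * grid$base_sd * (grid$age_band == "75+") +
    0.5 * grid$base_sd * (grid$edu_band == "13+")
  grid$sd <- grid$base_sd
  dplyr::select(grid, "age_band", "edu_band", "domain", "mean", "sd")
}

#' Generate five-domain cognitive scores with group-dependent deficits
#'
#' Scores are drawn around each person's own normative cell mean. Persons in
#' the single-domain impairment group (CIND-S) carry one deficit domain and
#' persons in the multi-domain group (CIND-M) two, shifted by
#' `params$deficit_shift` cell SDs (default -2); noise is
#' `params$domain_noise` cell SDs (0 gives deterministic classification).
#' Deficit domains are sampled once per person and persist across years.
#'
#' @param design A [burst_design()].
#' @param params A [generating_params()].
#' @param covariates Covariate tibble (needs `person_id`, `age_baseline`,
#'   `education`, `true_group`).
#' @param retention Optional retention tibble; restricts which persons have
#'   scores at the later assessment years.
#' @param years Assessment years at which scores are generated; defaults to
#'   baseline plus the design's follow-up years.
#' @param norms Norm table; defaults to [synth_norm_table()].
#' @param seed Optional integer seed.
#' @return A list with `scores` (long tibble: `person_id`, `year`, `domain`,
#'   `score`) and `norms`.
#' @export
generate_domain_scores <- function(design, params, covariates,
                                   retention = NULL,
                                   years = NULL, norms = synth_norm_table(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  years <- years %||% sort(unique(c(1L, design$followup_years)))
  domains <- unique(norms$domain)
  if (length(domains) != 5) {
    stop("five cognitive domains are required", call. = FALSE)
  }

  n_def <- c(HC = 0L, `CIND-S` = 1L, `CIND-M` = 2L)
  def_list <- lapply(as.character(covariates$true_group), function(g) {
    k <- n_def[[g]]
    if (k == 0) character(0) else sample(domains, k)
  })

  rows <- list()
  for (yr in years) {
    present <- covariates$person_id
    if (!is.null(retention)) {
      keep <- if (yr > design$n_years) {
        retention$completes_followup
      } else {
        retention$last_year >= yr
      }
      present <- retention$person_id[keep]
    }
    cv <- covariates[covariates$person_id %in% present, ]
    age_now <- cv$age_baseline + (yr - 1)
    cell <- tibble::tibble(
      person_id = rep(cv$person_id, each = length(domains)),
      year = yr,
      domain = rep(domains, nrow(cv)),
      age_band = rep(ifelse(age_now >= 75, "75+", "65-74"),
                     each = length(domains)),
      edu_band = rep(ifelse(cv$education >= 13, "13+", "0-12"),
                     each = length(domains))
    )
    cell <- dplyr::left_join(cell, norms,
                             by = c("age_band", "edu_band", "domain"))
    if (anyNA(cell$mean)) {
      stop("norm cell missing for some person/domain", call. = FALSE)
    }
    is_def <- mapply(function(pid, dom) {
      dom %in% def_list[[match(pid, covariates$person_id)]]
    }, cell$person_id, cell$domain)
    cell$score <- cell$mean + params$deficit_shift * cell$sd * is_def +
      stats::rnorm(nrow(cell), 0, params$domain_noise * cell$sd)
    rows[[as.character(yr)]] <- dplyr::select(cell, "person_id", "year",
                                              "domain", "score")
  }
  list(scores = dplyr::bind_rows(rows), norms = norms)
}

#' Simulate correlated person-slope pairs
#'
#' Draws bivariate-normal (short-term, long-term) slope pairs with a given
#' correlation, for calibration of the slope-association machinery.
#'
#' @param n Number of persons.
#' @param rho Target correlation.
#' @param mean,sd Length-2 means and SDs of the two slopes.
#' @param seed Optional integer seed.
#' @return A tibble with `person_id`, `short_term`, `long_term`.
#' @export
simulate_slope_pairs <- function(n, rho, mean = c(0, 0), sd = c(1, 1),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(rho) <= 1)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tibble::tibble(person_id = seq_len(n),
                 short_term = mean[1] + sd[1] * z1,
                 long_term = mean[2] + sd[2] * z2)
}

#' Simulate a three-category cognitive-status sample from a multinomial logit
#'
#' Generates persons with a standardized slope predictor, centered age and
#' sex, and a cognitive-status outcome (HC referent) drawn from a
#' multinomial-logit model with specified per-unit odds ratios for the slope
#' predictor, for parameter-recovery checks of the outcome models.
#'
#' @param n Number of persons.
#' @param or_cind_s,or_cind_m True per-unit odds ratios of the slope
#'   predictor for CIND-S vs HC and CIND-M vs HC.
#' @param intercepts Length-2 log-odds intercepts (CIND-S, CIND-M vs HC);
#'   defaults reproduce a roughly 56/25/18% category mix at predictor 0.
#' @param beta_age,beta_sex Covariate log-odds coefficients (applied to both
#'   contrasts); default 0.
#' @param seed Optional integer seed.
#' @return A tibble with `status` (factor HC/CIND-S/CIND-M), `slope`,
#'   `age_c`, `sex`.
#' @export
simulate_status_sample <- function(n, or_cind_s = 2.26, or_cind_m = 3.82,
                                   intercepts = c(log(62 / 138),
                                                  log(45 / 138)),
                                   beta_age = 0, beta_sex = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(or_cind_s > 0, or_cind_m > 0)
  slope <- stats::rnorm(n)
  age_c <- stats::rnorm(n, 0, 5.95)
  sex <- stats::rbinom(n, 1, 208 / 304)
  eta_s <- intercepts[1] + log(or_cind_s) * slope + beta_age * age_c +
    beta_sex * sex
  eta_m <- intercepts[2] + log(or_cind_m) * slope + beta_age * age_c +
    beta_sex * sex
  den <- 1 + exp(eta_s) + exp(eta_m)
  p <- cbind(1 / den, exp(eta_s) / den, exp(eta_m) / den)
  u <- stats::runif(n)
  idx <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
  tibble::tibble(
    status = factor(c("HC", "CIND-S", "CIND-M")[idx],
                    levels = c("HC", "CIND-S", "CIND-M")),
    slope = slope, age_c = age_c, sex = sex
  )
}
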