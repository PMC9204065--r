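#' Residualization specification for RTI computation
#'
#' Before computing intraindividual SDs, systematic trends are removed from
#' the screened latencies so that the dispersion score carries only
#' trial-to-trial fluctuation — not mean speed differences between persons,
#' developmental change, or trial-level practice. The fit is pooled least
#' squares with absorbed means: latencies and regressors are demeaned within
#' absorption cells, then regressed jointly across all persons.
#'
#' With the default absorption (`"person_session"`), person x task x year x
#' session means soak up all between-person and between-occasion structure
#' and only within-session regressors (the trial index) remain identifiable;
#' `"person"` absorption removes person x task means only, leaving session,
#' year, and their trends to the regressors.
#'
#' @param regressors Character vector of trend terms, a subset of
#'   `c("trial", "session", "year", "age")`. The trial index is always
#'   included (trial-level practice is the named confound).
#' @param absorb Absorption level, `"person_session"` or `"person"`.
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(regressors = "trial",
                          absorb = c("person_session", "person")) {
  regressors <- union("trial", regressors)
  allowed <- c("trial", "session", "year", "age")
  if (!all(regressors %in% allowed)) {
    stop("regressors must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  structure(list(regressors = regressors, absorb = match.arg(absorb)),
            class = "residual_spec")
}

#' Residualize screened trial latencies
#'
#' Removes absorbed cell means plus pooled linear trends in the configured
#' regressors, separately per task. The returned residuals have mean zero
#' within every absorption cell and carry no linear trend in the regressors.
#'
#' @param trials Screened trial table (see [screen_trials()]); an
#'   `age_baseline` column is required when `"age"` is a regressor.
#' @param spec A [residual_spec()].
#' @return The input table with a `residual` column (ms).
#' @export
residualize_trials <- function(trials, spec = residual_spec()) {
  if (!nrow(trials)) {
    trials$residual <- numeric(0)
    return(trials)
  }
  absorb_cols <- if (spec$absorb == "person_session") {
    c("person_id", "task", "year", "session")
  } else {
    c("person_id", "task")
  }
  out <- lapply(split(trials, trials$task), function(d) {
    X <- build_trend_matrix(d, spec)
    cell <- interaction(d[absorb_cols], drop = TRUE)
    y_dm <- d$rt_ms - stats::ave(d$rt_ms, cell)
    X_dm <- apply(X, 2, function(col) col - stats::ave(col, cell))
    X_dm <- matrix(X_dm, nrow = nrow(d))
    fit <- stats::lm.fit(X_dm, y_dm)
    if (any(is.na(fit$coefficients))) {
      dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
      warning("collinear trend term(s) dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    d$residual <- as.numeric(fit$residuals)
    d
  })
  dplyr::bind_rows(out)
}

build_trend_matrix <- function(d, spec) {
  cols <- list(trial = d$trial)
  if ("session" %in% spec$regressors) cols$session <- d$session
  if ("year" %in% spec$regressors) cols$year <- d$year
  if ("age" %in% spec$regressors) {
    if (is.null(d$age_baseline)) {
      stop("`age` regressor requires an `age_baseline` column", call. = FALSE)
    }
    cols$age <- d$age_baseline
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Intraindividual SD of residualized latencies
#'
#' The sample SD (denominator n - 1) of the residuals within each person x
#' task x year x session cell; the raw response-time-inconsistency score.
#' Cells with fewer than two residuals yield no row (the score is missing
#' and is handled downstream by full-information likelihood fitting).
#'
#' @param residuals Output of [residualize_trials()].
#' @return A tibble with `person_id`, `task`, `year`, `session`, `n_trials`,
#'   `isd_raw`.
#' @export
compute_isd <- function(residuals) {
  out <- dplyr::summarise(
    dplyr::group_by(residuals, .data$person_id, .data$task, .data$year,
                    .data$session),
    n_trials = dplyr::n(),
    isd_raw = stats::sd(.data$residual),
    .groups = "drop")
  out[out$n_trials >= 2, , drop = FALSE]
}

#' T-standardize ISD scores
#'
#' Linearly transforms raw ISDs to T scores (mean 50, SD 10) using one
#' standardizer per task estimated on a fixed reference distribution and
#' applied to all occasions, so that change over sessions and years is
#' preserved. The default reference is the baseline occasion (Year 1,
#' Session 1) pooled across persons. `reference = "per_occasion"`
#' standardizes within every year x session cell instead, which forces each
#' occasion's mean to 50 and removes all average change — retained only for
#' comparison.
#'
#' @param isd Output of [compute_isd()].
#' @param reference `"baseline"` (default) or `"per_occasion"`.
#' @return The input with a `t_score` column; for the baseline reference the
#'   per-task standardizer parameters are attached as attribute
#'   `standardizer`.
#' @export
t_standardize <- function(isd, reference = c("baseline", "per_occasion")) {
  reference <- match.arg(reference)
  if (reference == "per_occasion") {
    out <- dplyr::mutate(
      dplyr::group_by(isd, .data$task, .data$year, .data$session),
      t_score = 50 + 10 * (.data$isd_raw - mean(.data$isd_raw)) /
        stats::sd(.data$isd_raw))
    return(dplyr::ungroup(out))
  }
  std <- dplyr::summarise(
    dplyr::group_by(isd[isd$year == 1 & isd$session == 1, ], .data$task),
    reference_mean = mean(.data$isd_raw),
    reference_sd = stats::sd(.data$isd_raw),
    .groups = "drop")
  if (any(!is.finite(std$reference_sd)) || any(std$reference_sd <= 0)) {
    stop("degenerate reference cell: SD of baseline ISDs is zero",
         call. = FALSE)
  }
  out <- dplyr::left_join(isd, std, by = "task")
  out$t_score <- 50 + 10 * (out$isd_raw - out$reference_mean) /
    out$reference_sd
  out$reference_mean <- NULL
  out$reference_sd <- NULL
  attr(out, "standardizer") <- std
  out
}

#' Compute T-scored RTI from screened trials
#'
#' Convenience wrapper: residualize, compute intraindividual SDs, and
#' T-standardize.
#'
#' @param clean_trials Screened trial table.
#' @param spec A [residual_spec()].
#' @param reference Passed to [t_standardize()].
#' @return RTI score table (one row per person x task x year x session).
#' @export
compute_rti <- function(clean_trials, spec = residual_spec(),
                        reference = "baseline") {
  res <- residualize_trials(clean_trials, spec)
  t_standardize(compute_isd(res), reference = reference)
}
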