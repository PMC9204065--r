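#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline in one serializable object. The
#' run seed drives module-specific substreams (fixed offsets from the base
#' seed), so regenerating one stage does not perturb another's draws and a
#' config round-trips to an identical run.
#'
#' @param seed Integer base seed.
#' @param design A [burst_design()].
#' @param params Named list of [generating_params()], one per task.
#' @param qc A [qc_rules()] object.
#' @param residual A [residual_spec()] object.
#' @param mlm An [mlm_spec()] object.
#' @param status A [status_rules()] object.
#' @param attrition Simulate study dropout?
#' @param scale_factor Short-term slope rescale for outcome models (see
#'   [extract_person_slopes()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = burst_design(n_persons = 304),
                       params = NULL,
                       qc = qc_rules(),
                       residual = residual_spec(),
                       mlm = mlm_spec(),
                       status = status_rules(),
                       attrition = TRUE,
                       scale_factor = 1) {
  if (is.null(params)) {
    params <- lapply(design$tasks, function(tk) {
      generating_params(if (tk %in% c("CRT", "BRT")) tk else "CRT")
    })
    names(params) <- design$tasks
  }
  structure(list(seed = as.integer(seed), design = design, params = params,
                 qc = qc, residual = residual, mlm = mlm, status = status,
                 attrition = attrition, scale_factor = scale_factor),
            class = "run_config")
}

# fixed substream offsets per module (all well below 2^31)
substream <- function(seed, stage) {
  offsets <- c(synth = 11L, domains = 23L)
  seed + offsets[[stage]]
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate trials, screen them, compute residualized-ISD RTI, fit the
#' unconditional and conditional three-level models per task, extract
#' person-specific short- and long-term slopes, classify cognitive status at
#' the follow-up years, and fit the multinomial outcome models (one per
#' slope predictor per follow-up year, adjusted for age and sex). All
#' stages are deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   as CSV/JSON with a manifest (see [write_run()]).
#' @param verbose Print stage progress?
#' @return An object of class `rtiburst_run` holding every stage output.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  design <- config$design
  stage <- "simulate"
  result <- tryCatch({
    say("simulate: generating trials")
    sim <- generate_trials(design, config$params,
                           attrition = config$attrition,
                           seed = substream(config$seed, "synth"))

    stage <- "qc"
    say("qc: screening trials")
    clean <- screen_trials(sim$trials, config$qc)
    report <- attr(clean, "exclusion_report")

    stage <- "rti"
    say("rti: residualized ISD + T scores")
    rti <- compute_rti(clean, config$residual)

    stage <- "fit"
    fits <- list()
    decompositions <- list()
    slopes <- list()
    for (tk in design$tasks) {
      say("fit: ", tk)
      decompositions[[tk]] <- fit_unconditional(rti, task = tk,
                                                spec = config$mlm)
      fits[[tk]] <- fit_conditional(rti, sim$covariates, config$mlm,
                                    task = tk)
      eb <- extract_random_effects(fits[[tk]])
      slopes[[tk]] <- extract_person_slopes(fits[[tk]], eb,
                                            config$scale_factor)
    }

    stage <- "classify"
    say("classify: domain scores and CIND status")
    dom <- generate_domain_scores(design, config$params[[1]],
                                  sim$covariates, sim$retention,
                                  seed = substream(config$seed, "domains"))
    z <- zscore_domains(dom$scores, dom$norms, sim$covariates)
    status <- classify_status(z, config$status)

    stage <- "predict"
    say("predict: multinomial outcome models")
    persons <- sim$covariates
    persons$age_c <- persons$age_baseline - config$mlm$age_center
    outcomes <- list()
    for (yr in design$followup_years) {
      st_yr <- status[status$year == yr & !is.na(status$label), ]
      for (tk in design$tasks) {
        for (kind in c("short_term", "long_term")) {
          d <- dplyr::inner_join(
            st_yr, slopes[[tk]][c("person_id", kind)], by = "person_id")
          d <- dplyr::inner_join(d, persons[c("person_id", "age_c", "sex")],
                                 by = "person_id")
          d$status <- d$label
          key <- paste0("year", yr, "_", tolower(tk), "_",
                        sub("_term", "", kind))
          outcomes[[key]] <- fit_multinomial(d, predictor = kind)
        }
      }
    }
    mmse <- dplyr::inner_join(
      status[status$year == design$followup_years[1] &
               !is.na(status$label), ],
      persons[c("person_id", "age_c", "sex", "mmse_baseline")],
      by = "person_id")
    mmse$status <- mmse$label
    mmse_contrast <- compare_baseline_predictor(mmse)

    slope_assoc <- lapply(slopes, slope_correlation)

    structure(list(config = config, trials = sim$trials,
                   latent = sim$latent, covariates = sim$covariates,
                   retention = sim$retention, exclusions = report,
                   rti = rti, decompositions = decompositions, fits = fits,
                   slopes = slopes, slope_assoc = slope_assoc,
                   domain_scores = dom$scores, norms = dom$norms,
                   status = status, outcomes = outcomes,
                   mmse_contrast = mmse_contrast),
              class = "rtiburst_run")
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Write every pipeline artifact to a directory
#'
#' Writes the tidy long-format CSVs (trials, covariates, RTI scores, slopes,
#' domain scores, norms, status), fit summaries (JSON), the exclusion
#' report, the outcome-model table, the config (YAML), and a machine-
#' readable manifest carrying the seed and package version.
#'
#' @param run An `rtiburst_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(run$trials, "trials.csv")
  wcsv(run$covariates, "covariates.csv")
  wcsv(run$rti, "rti.csv")
  wcsv(run$domain_scores, "domain_scores.csv")
  wcsv(run$norms, "norms.csv")
  wcsv(run$status, "status.csv")
  wcsv(dplyr::bind_rows(run$slopes, .id = "task"), "slopes.csv")
  wcsv(exclusion_summary(run$exclusions), "exclusion_report.csv")

  fit_json <- lapply(run$fits, function(f) {
    list(gamma = f$gamma, loglik = f$loglik, converged = f$converged,
         structure3 = f$structure3,
         varcomp = list(level3_cov = unclass(f$varcomp$level3_cov),
                        level2_vars = as.list(f$varcomp$level2_vars),
                        sigma2 = f$varcomp$sigma2))
  })
  jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  outcome_tab <- dplyr::bind_rows(
    lapply(run$outcomes, function(o) o$table[o$table$term == o$predictor, ]),
    .id = "model")
  wcsv(outcome_tab, "outcomes.csv")
  yaml::write_yaml(serialize_config(run$config),
                   file.path(out_dir, "config.yaml"))
  manifest <- list(
    package = "rtiburst",
    version = as.character(utils::packageVersion("rtiburst")),
    seed = run$config$seed,
    files = c("trials.csv", "covariates.csv", "rti.csv",
              "domain_scores.csv", "norms.csv", "status.csv", "slopes.csv",
              "exclusion_report.csv", "fits.json", "outcomes.csv",
              "config.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

serialize_config <- function(config) {
  rapply(unclass(config), how = "replace", f = function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x
  })
}

#' Validate input tables for the analysis stages
#'
#' Schema, type, and key-uniqueness checks for the pipeline's long-format
#' input dialects, returning an itemized report.
#'
#' @param trials Trial table (or path to a `trials.csv`).
#' @param covariates Optional covariate table or path.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(trials, covariates = NULL) {
  read_maybe <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
      utils::read.csv(x)
    } else x
  }
  trials <- read_maybe(trials)
  problems <- character(0)
  need <- c("person_id", "task", "year", "session", "trial", "rt_ms",
            "correct", "missing")
  absent <- setdiff(need, names(trials))
  if (length(absent)) {
    problems <- c(problems,
                  paste("trials: missing column(s):",
                        paste(absent, collapse = ", ")))
  } else {
    if (!is.numeric(trials$rt_ms)) {
      bad <- which(is.na(suppressWarnings(as.numeric(trials$rt_ms))) &
                     !is.na(trials$rt_ms))
      problems <- c(problems, paste0(
        "trials: rt_ms not numeric (e.g. rows ",
        paste(utils::head(bad, 5), collapse = ", "), ")"))
    }
    key <- trials[c("person_id", "task", "year", "session", "trial")]
    if (anyDuplicated(key)) {
      problems <- c(problems, paste("trials:", sum(duplicated(key)),
                                    "duplicate trial key(s)"))
    }
    if (is.numeric(trials$rt_ms) &&
        any(trials$rt_ms <= 0, na.rm = TRUE)) {
      problems <- c(problems, "trials: non-positive rt_ms values")
    }
  }
  if (!is.null(covariates)) {
    covariates <- read_maybe(covariates)
    need_cv <- c("person_id", "age_baseline", "sex", "education")
    absent <- setdiff(need_cv, names(covariates))
    if (length(absent)) {
      problems <- c(problems,
                    paste("covariates: missing column(s):",
                          paste(absent, collapse = ", ")))
    } else if (anyDuplicated(covariates$person_id)) {
      problems <- c(problems, "covariates: duplicate person_id")
    }
    if (length(problems) == 0 && !is.null(trials$person_id) &&
        !all(trials$person_id %in% covariates$person_id)) {
      problems <- c(problems, "trials reference persons absent from covariates")
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}

#' @export
print.rtiburst_run <- function(x, ...) {
  cat("rtiburst pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  trials:", nrow(x$trials), "| persons:", nrow(x$covariates),
      "| RTI scores:", nrow(x$rti), "\n")
  for (tk in names(x$decompositions)) {
    sh <- x$decompositions[[tk]]$shares
    cat(sprintf("  %s variance shares: person %.0f%% / year %.0f%% / week %.0f%%\n",
                tk, sh[["person"]], sh[["year"]], sh[["week"]]))
  }
  invisible(x)
}
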