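#' Define a measurement-burst study design
#'
#' A burst design nests closely spaced testing sessions (level 1, biweekly)
#' within annual waves (level 2) within persons (level 3). The default layout
#' mirrors a four-year burst study with five baseline sessions and four
#' sessions in each subsequent year, i.e. up to 17 assessments per person,
#' followed by a long-term follow-up four years after the last burst.
#'
#' @param n_persons Number of persons enrolled at baseline.
#' @param n_years Number of annual burst waves.
#' @param sessions_per_year Integer vector, one entry per year, giving the
#'   number of biweekly sessions in that year's burst.
#' @param trials_per_session Analysable trials per task per session. The
#'   one-back task (BRT) administers one extra lead-in trial that is never
#'   analysed; see [omit_first_brt_trial()].
#' @param week_spacing Weeks elapsed between consecutive sessions within a
#'   burst (2 = biweekly). Session s of any year sits at week
#'   `week_spacing * (s - 1)` of that year's burst.
#' @param tasks Character vector of task codes.
#' @param followup_years Years (1-based, baseline = 1) at which cognitive
#'   status is (re)assessed for use as a prospective outcome.
#'
#' @return An object of class `burst_design`.
#' @examples
#' d <- burst_design(n_persons = 304)
#' total_sessions(d)            # 17
#' possible_trials(d, year = 1) # 91200
#' @export
burst_design <- function(n_persons,
                         n_years = 4,
                         sessions_per_year = c(5, 4, 4, 4),
                         trials_per_session = 60,
                         week_spacing = 2,
                         tasks = c("CRT", "BRT"),
                         followup_years = c(4, 8)) {
  if (length(sessions_per_year) != n_years) {
    stop("`sessions_per_year` must have one entry per year (", n_years, ")",
         call. = FALSE)
  }
  counts <- c(n_persons, n_years, sessions_per_year, trials_per_session,
              week_spacing)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all design counts must be positive", call. = FALSE)
  }
  structure(
    list(
      n_persons = as.integer(n_persons),
      n_years = as.integer(n_years),
      sessions_per_year = as.integer(sessions_per_year),
      trials_per_session = as.integer(trials_per_session),
      week_spacing = week_spacing,
      tasks = tasks,
      followup_years = as.integer(followup_years)
    ),
    class = "burst_design"
  )
}

#' @export
print.burst_design <- function(x, ...) {
  cat("Measurement-burst design\n")
  cat("  persons:           ", x$n_persons, "\n")
  cat("  years:             ", x$n_years, "\n")
  cat("  sessions per year: ", paste(x$sessions_per_year, collapse = "/"),
      " (", total_sessions(x), " total)\n", sep = "")
  cat("  trials per session:", x$trials_per_session, "per task\n")
  cat("  tasks:             ", paste(x$tasks, collapse = ", "), "\n")
  invisible(x)
}

#' Total number of testing sessions per person in a design
#'
#' @param design A [burst_design()].
#' @return Integer count (17 for the default design).
#' @export
total_sessions <- function(design) {
  sum(design$sessions_per_year)
}

#' Possible (administered, analysable) trials in one year of the design
#'
#' The accounting denominator for trial-exclusion percentages: analysable
#' trials per session x sessions in the year x persons. For the default
#' design at Year 1 this is 60 x 5 x 304 = 91,200 per task.
#'
#' @param design A [burst_design()].
#' @param year Year index (1-based).
#' @param task Task code; the count is identical across tasks because the
#'   BRT's extra lead-in trial is not analysable.
#' @param n_persons Number of persons contributing; defaults to the design's
#'   enrolment.
#' @return Integer trial count.
#' @export
possible_trials <- function(design, year, task = "CRT",
                            n_persons = design$n_persons) {
  if (year < 1 || year > design$n_years) {
    stop("`year` out of range for this design", call. = FALSE)
  }
  as.integer(design$trials_per_session * design$sessions_per_year[year] *
               n_persons)
}

#' Session-level skeleton of a design
#'
#' One row per year x session with the within-year week covariate used by the
#' three-level model (0-based at each year's first session).
#'
#' @param design A [burst_design()].
#' @return A tibble with columns `year`, `session`, `week`.
#' @export
design_grid <- function(design) {
  out <- lapply(seq_len(design$n_years), function(j) {
    s <- seq_len(design$sessions_per_year[j])
    tibble::tibble(year = j, session = s,
                   week = design$week_spacing * (s - 1))
  })
  dplyr::bind_rows(out)
}
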