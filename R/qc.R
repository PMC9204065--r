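#' Trial-screening rules
#'
#' Screening removes, in order: missing responses, incorrect responses, and
#' latency outliers. A trial is an outlier if it lies below the fixed lower
#' bound (implausibly fast, default 150 ms) or exceeds the person's own mean
#' by `upper_sd_multiplier` or more SDs, with the intraindividual mean and SD
#' computed once per scope cell (default person x task x year x session) over
#' non-missing correct trials, before any bound-based removal.
#'
#' @param lower_bound_ms Fixed lower latency bound in ms.
#' @param upper_sd_multiplier Upper bound is mean + this many SDs (a trial at
#'   or beyond the bound is removed).
#' @param scope Grouping columns defining the intraindividual mean/SD cell:
#'   `"person_session"` (per task x year x session) or `"person_year"`
#'   (pooled over sessions within a year).
#' @param brt_omit_first Remove the BRT lead-in trial (trial 1) before any
#'   accounting?
#' @return An object of class `qc_rules`.
#' @export
qc_rules <- function(lower_bound_ms = 150, upper_sd_multiplier = 3,
                     scope = c("person_session", "person_year"),
                     brt_omit_first = TRUE) {
  if (lower_bound_ms <= 0 || upper_sd_multiplier <= 0) {
    stop("bounds must be positive", call. = FALSE)
  }
  structure(list(lower_bound_ms = lower_bound_ms,
                 upper_sd_multiplier = upper_sd_multiplier,
                 scope = match.arg(scope),
                 brt_omit_first = brt_omit_first),
            class = "qc_rules")
}

scope_cols <- function(rules) {
  if (rules$scope == "person_year") {
    c("person_id", "task", "year")
  } else {
    c("person_id", "task", "year", "session")
  }
}

#' Remove the unanalysed lead-in trial of the one-back task
#'
#' The one-back (BRT) task administers one extra leading trial to which no
#' response is possible; it is dropped before any accounting. Other tasks are
#' untouched, and sessions already reduced to the analysable trial count are
#' left as they are.
#'
#' @param trials Trial table with `task` and `trial` columns.
#' @return The table without BRT trial 1 rows.
#' @export
omit_first_brt_trial <- function(trials) {
  if (!nrow(trials)) return(trials)
  trials[!(trials$task == "BRT" & trials$trial == 1L), , drop = FALSE]
}

#' Screen trials for missing, incorrect, and outlying responses
#'
#' Applies the screening rules and attributes every administered trial to
#' exactly one of four categories: missing, incorrect, outlier-trimmed, or
#' usable. Intraindividual cell statistics are computed in a single pass over
#' non-missing correct trials (no iteration after removal), so re-screening
#' an already screened table with the cached statistics removes nothing.
#'
#' @param trials Trial table (columns `person_id`, `task`, `year`, `session`,
#'   `trial`, `rt_ms`, `correct`, `missing`).
#' @param rules A [qc_rules()] object.
#' @param cell_stats Optional cached cell statistics (as attached to a
#'   previous result via `attr(, "cell_stats")`); recomputed if `NULL`.
#' @return The usable trials, with attributes `exclusion_report` (an
#'   `exclusion_report` object) and `cell_stats`.
#' @export
screen_trials <- function(trials, rules = qc_rules(), cell_stats = NULL) {
  if (rules$brt_omit_first) trials <- omit_first_brt_trial(trials)
  n_possible <- table(factor(trials$task, levels = unique(trials$task)))

  is_missing <- trials$missing == 1L | is.na(trials$rt_ms)
  is_incorrect <- !is_missing & !is.na(trials$correct) & trials$correct == 0L
  ok <- !is_missing & !is_incorrect

  cols <- scope_cols(rules)
  if (is.null(cell_stats)) {
    cell_stats <- dplyr::summarise(
      dplyr::group_by(trials[ok, , drop = FALSE],
                      dplyr::across(dplyr::all_of(cols))),
      cell_mean = mean(.data$rt_ms),
      cell_sd = stats::sd(.data$rt_ms),
      cell_n = dplyr::n(),
      .groups = "drop")
  }
  thin <- cell_stats[cell_stats$cell_n < 2, , drop = FALSE]
  if (nrow(thin)) {
    warning(nrow(thin), " scope cell(s) with fewer than 2 usable trials: ",
            "SD undefined, upper bound not applied there", call. = FALSE)
  }

  with_stats <- dplyr::left_join(trials, cell_stats, by = cols)
  upper <- with_stats$cell_mean +
    rules$upper_sd_multiplier * with_stats$cell_sd
  too_fast <- ok & trials$rt_ms < rules$lower_bound_ms
  too_slow <- ok & !is.na(upper) & with_stats$cell_n >= 2 &
    trials$rt_ms >= upper
  is_outlier <- too_fast | too_slow
  usable <- ok & !is_outlier

  counts <- function(flag) {
    tab <- table(factor(trials$task[flag], levels = names(n_possible)))
    as.integer(tab)
  }
  report <- structure(
    list(table = tibble::tibble(
      task = names(n_possible),
      possible = as.integer(n_possible),
      missing = counts(is_missing),
      incorrect = counts(is_incorrect),
      outlier = counts(is_outlier),
      usable = counts(usable)
    )),
    class = "exclusion_report")

  out <- trials[usable, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  attr(out, "cell_stats") <- cell_stats
  out
}

#' Exclusion percentages from a screening report
#'
#' Expresses the four exclusion categories as percentages of the possible
#' (administered, analysable) trials per task; the categories partition the
#' denominator, so they sum to 100%.
#'
#' @param report An `exclusion_report` (from [screen_trials()], or via
#'   `attr(clean, "exclusion_report")`).
#' @return A tibble with per-task counts and `*_pct` columns.
#' @export
exclusion_summary <- function(report) {
  tab <- report$table
  if (any(tab$possible == 0)) {
    stop("zero possible trials for some task", call. = FALSE)
  }
  for (col in c("missing", "incorrect", "outlier", "usable")) {
    tab[[paste0(col, "_pct")]] <- 100 * tab[[col]] / tab$possible
  }
  tab
}

#' @export
print.exclusion_report <- function(x, ...) {
  tab <- exclusion_summary(x)
  cat("Trial exclusions (% of possible trials)\n")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %s: missing %.2f%%, incorrect %.2f%%, outliers %.2f%%, usable %.2f%% (n = %d)\n",
      tab$task[i], tab$missing_pct[i], tab$incorrect_pct[i],
      tab$outlier_pct[i], tab$usable_pct[i], tab$possible[i]))
  }
  invisible(x)
}
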