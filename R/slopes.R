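#' Person-specific short- and long-term change slopes
#'
#' Combines the fixed weekly and yearly slopes with each person's
#' empirical-Bayes deviations: short-term (retest) slope
#' \eqn{\gamma_{100} + \hat\upsilon_{10k}} (T units per week) and long-term
#' (developmental) slope \eqn{\gamma_{010} + \hat\upsilon_{01k}} (T units
#' per year). Covariate (age/sex) contributions are deliberately excluded so
#' the slopes can be entered in outcome models alongside age and sex without
#' double-counting them. Because small weekly slopes are awkward to read in
#' odds-ratio form, an optional multiplicative rescale of the short-term
#' slope is supported and recorded.
#'
#' @param fit An [fit_conditional()] result.
#' @param eb An [extract_random_effects()] result; computed from `fit` if
#'   `NULL`.
#' @param scale_factor Multiplier applied to the short-term slope (default
#'   1, i.e. T units per week).
#' @return A tibble with `person_id`, `short_term`, `long_term`,
#'   `scale_factor_applied`.
#' @export
extract_person_slopes <- function(fit, eb = NULL, scale_factor = 1) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (is.null(eb)) eb <- extract_random_effects(fit)
  tibble::tibble(
    person_id = eb$level3$person_id,
    short_term = scale_factor * (fit$beta[["week"]] + eb$level3$u10),
    long_term = fit$beta[["year"]] + eb$level3$u01,
    scale_factor_applied = scale_factor
  )
}

#' Association between short- and long-term person slopes
#'
#' Pearson correlation between the person-specific weekly (retest) and
#' yearly (developmental) slopes, with a two-tailed p-value from the t
#' distribution.
#'
#' @param slopes Output of [extract_person_slopes()] (or any table with
#'   `short_term` and `long_term` columns).
#' @return A list with `r`, `p`, `n`.
#' @export
slope_correlation <- function(slopes) {
  ok <- stats::complete.cases(slopes$short_term, slopes$long_term)
  x <- slopes$short_term[ok]
  y <- slopes$long_term[ok]
  if (length(x) < 3) stop("need >= 3 persons with both slopes", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a slope column: correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
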