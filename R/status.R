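#' Cognitive-status classification rules
#'
#' A domain counts as deficient when its normative z-score is at or below
#' the threshold (default -1.5 SD, boundary inclusive). Zero deficits give
#' HC (healthy control); exactly one gives CIND-S (cognitively impaired,
#' not demented, single domain); two or more give CIND-M (multi-domain).
#'
#' @param z_threshold Deficit threshold on the z scale (negative).
#' @param inclusive Does a z-score exactly at the threshold count as a
#'   deficit?
#' @return An object of class `status_rules`.
#' @export
status_rules <- function(z_threshold = -1.5, inclusive = TRUE) {
  if (z_threshold >= 0) stop("`z_threshold` must be negative", call. = FALSE)
  structure(list(z_threshold = z_threshold, inclusive = inclusive),
            class = "status_rules")
}

#' Normative z-scores for the five cognitive domains
#'
#' Standardizes each person-year's domain scores against the mean and SD of
#' the matching normative cell. The age band (65-74 vs 75+) uses age at the
#' classification year (baseline age plus elapsed years); the education band
#' (0-12 vs 13+) uses baseline years of education throughout.
#'
#' @param scores Long table with `person_id`, `year`, `domain`, `score`.
#' @param norms Norm table (`age_band`, `edu_band`, `domain`, `mean`, `sd`),
#'   e.g. [synth_norm_table()].
#' @param covariates Person table with `person_id`, `age_baseline`,
#'   `education`.
#' @param age_at Either `"classification_year"` (default) or `"baseline"`.
#' @return The score table with `age_band`, `edu_band`, `z` columns.
#' @export
zscore_domains <- function(scores, norms, covariates,
                           age_at = c("classification_year", "baseline")) {
  age_at <- match.arg(age_at)
  if (any(norms$sd <= 0)) stop("norm SDs must be positive", call. = FALSE)
  d <- dplyr::left_join(scores,
                        covariates[c("person_id", "age_baseline",
                                     "education")],
                        by = "person_id")
  if (anyNA(d$age_baseline)) {
    bad <- unique(d$person_id[is.na(d$age_baseline)])
    stop("no covariates for person(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  age_now <- if (age_at == "baseline") d$age_baseline else
    d$age_baseline + (d$year - 1)
  d$age_band <- ifelse(age_now >= 75, "75+", "65-74")
  d$edu_band <- ifelse(d$education >= 13, "13+", "0-12")
  d <- dplyr::left_join(d, norms, by = c("age_band", "edu_band", "domain"))
  if (anyNA(d$mean)) {
    bad <- unique(d$person_id[is.na(d$mean)])
    stop("unmatched norm cell for person(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d$z <- (d$score - d$mean) / d$sd
  dplyr::select(d, "person_id", "year", "domain", "score", "age_band",
                "edu_band", "z")
}

#' Classify person-years as HC / CIND-S / CIND-M
#'
#' Counts normative deficits across the five domains per person-year and
#' applies the classification rules. Person-years with any missing domain
#' z-score are unclassifiable and are returned with label `NA` (and counted
#' in the attached `n_unclassifiable` attribute).
#'
#' @param z Output of [zscore_domains()].
#' @param rules A [status_rules()] object.
#' @return A tibble with `person_id`, `year`, `label` (factor
#'   HC/CIND-S/CIND-M), `deficit_count`, `deficit_domains`.
#' @export
classify_status <- function(z, rules = status_rules()) {
  thr <- rules$z_threshold
  z$deficit <- if (rules$inclusive) z$z <= thr else z$z < thr
  out <- dplyr::summarise(
    dplyr::group_by(z, .data$person_id, .data$year),
    n_domains = dplyr::n(),
    n_missing = sum(is.na(.data$z)),
    deficit_count = sum(.data$deficit, na.rm = TRUE),
    deficit_domains = paste(sort(.data$domain[which(.data$deficit)]),
                            collapse = ";"),
    .groups = "drop")
  bad <- out$n_missing > 0 | out$n_domains != 5
  out$label <- factor(
    ifelse(bad, NA,
           ifelse(out$deficit_count == 0, "HC",
                  ifelse(out$deficit_count == 1, "CIND-S", "CIND-M"))),
    levels = c("HC", "CIND-S", "CIND-M"))
  out$deficit_count[bad] <- NA_integer_
  res <- dplyr::select(out, "person_id", "year", "label", "deficit_count",
                       "deficit_domains")
  attr(res, "n_unclassifiable") <- sum(bad)
  res
}
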