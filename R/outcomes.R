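#' Multinomial logistic regression of cognitive status on a slope predictor
#'
#' Fits a polytomous (multinomial) logistic model of cognitive status —
#' healthy controls as the referent — on one person-level predictor plus
#' centered age and sex, by Newton-Raphson on the multinomial
#' log-likelihood. One slope predictor is entered per model (the short- and
#' long-term slopes of one task are collinear enough that entering both
#' would be unstable). Reports per non-referent category the coefficient,
#' Wald SE, odds ratio with confidence interval, and p-value.
#'
#' If one non-referent category is empty the model reduces to binary
#' logistic regression with a warning. Perfect separation is detected by a
#' diverging coefficient norm and raised as an error.
#'
#' @param data Person-level table holding the outcome and predictors.
#' @param predictor Name of the predictor column (e.g. a slope from
#'   [extract_person_slopes()], or `mmse_baseline`).
#' @param covariate_cols Additional adjustment columns (default centered age
#'   and sex).
#' @param outcome Name of the outcome column (factor; first level is the
#'   referent unless `ref` says otherwise).
#' @param ref Referent category label.
#' @param conf_level Wald confidence level.
#' @return An object of class `multinom_result`: `table` (one row per
#'   category x term), `loglik`, `n_category`, `coef`, `vcov`.
#' @export
fit_multinomial <- function(data, predictor, covariate_cols = c("age_c",
                                                                "sex"),
                            outcome = "status", ref = "HC",
                            conf_level = 0.95) {
  cols <- c(outcome, predictor, covariate_cols)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), , drop = FALSE]
  y <- d[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  if (!ref %in% levels(y)) stop("referent category absent", call. = FALSE)
  y <- stats::relevel(y, ref = ref)
  present <- levels(y)[table(y) > 0]
  if (length(present) < length(levels(y))) {
    warning("empty outcome categor(ies): ",
            paste(setdiff(levels(y), present), collapse = ", "),
            "; reducing to the observed categories", call. = FALSE)
    y <- factor(as.character(y), levels = present)
  }
  if (nlevels(y) < 2) stop("need >= 2 observed categories", call. = FALSE)
  X <- cbind(intercept = 1,
             as.matrix(d[c(predictor, covariate_cols)]))
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank deficient (constant predictor?)", call. = FALSE)
  }
  # fit on centered/scaled predictors for conditioning (slope predictors can
  # be numerically tiny, baseline scores far from zero), then map estimates
  # back to the input scale with the exact affine transform
  p <- ncol(X)
  mu <- c(0, colMeans(X[, -1, drop = FALSE]))
  sds <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  Xs[, 1] <- 1
  fit <- multinom_newton(y, Xs)
  m <- nlevels(y) - 1
  Tr <- diag(1 / sds)
  Tr[1, ] <- -mu / sds
  Tr[1, 1] <- 1
  Tm <- kronecker(diag(m), Tr)   # stacked category-major coef transform
  fit$B <- apply(fit$B, 2, function(b) as.numeric(Tr %*% b))
  dimnames(fit$B) <- list(colnames(X), levels(y)[-1])
  fit$coef_vec <- as.vector(fit$B)
  fit$vcov <- Tm %*% fit$vcov %*% t(Tm)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cats <- levels(y)[-1]
  terms <- colnames(X)
  rows <- list()
  for (ci in seq_along(cats)) {
    for (ti in seq_along(terms)) {
      k <- (ci - 1) * length(terms) + ti
      est <- fit$coef_vec[k]
      se <- sqrt(fit$vcov[k, k])
      rows[[length(rows) + 1]] <- tibble::tibble(
        category = cats[ci], term = terms[ti], estimate = est, se = se,
        or = exp(est), or_lb = exp(est - z * se), or_ub = exp(est + z * se),
        p = 2 * stats::pnorm(-abs(est / se)))
    }
  }
  structure(list(table = dplyr::bind_rows(rows),
                 predictor = predictor,
                 loglik = fit$loglik,
                 n_category = table(y),
                 coef = fit$B, vcov = fit$vcov,
                 converged = fit$converged),
            class = "multinom_result")
}

# Newton-Raphson maximum likelihood for the multinomial logit (referent =
# first factor level). Coefficients are stacked category-major:
# (cat2 terms..., cat3 terms...).
multinom_newton <- function(y, X, max_iter = 100, tol = 1e-12,
                            divergence_norm = 30) {
  n <- nrow(X)
  p <- ncol(X)
  K <- nlevels(y)
  m <- K - 1
  Y <- matrix(0, n, m)
  for (j in seq_len(m)) Y[, j] <- as.integer(y == levels(y)[j + 1])
  B <- matrix(0, p, m)

  loglik <- function(B) {
    eta <- X %*% B
    lse <- log1p(rowSums(exp(eta)))
    sum(rowSums(Y * eta) - lse)
  }
  ll <- loglik(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- X %*% B
    expeta <- exp(eta)
    den <- 1 + rowSums(expeta)
    P <- expeta / den
    grad <- as.vector(crossprod(X, Y - P))          # stacked by category
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    H <- matrix(0, p * m, p * m)
    for (a in seq_len(m)) {
      for (b in seq_len(a)) {
        w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
        blk <- crossprod(X, X * w)
        ia <- (a - 1) * p + seq_len(p)
        ib <- (b - 1) * p + seq_len(p)
        H[ia, ib] <- blk
        H[ib, ia] <- blk
      }
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular Hessian in multinomial fit", call. = FALSE)
    }
    # step-halving to guarantee ascent
    lambda <- 1
    repeat {
      Bnew <- B + lambda * matrix(step, p, m)
      llnew <- loglik(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    B <- Bnew
    ll <- llnew
    if (sqrt(sum(B^2)) > divergence_norm) {
      stop("coefficients diverging (norm > ", divergence_norm,
           "): probable perfect separation", call. = FALSE)
    }
  }
  # vcov from the observed information at the optimum
  eta <- X %*% B
  expeta <- exp(eta)
  den <- 1 + rowSums(expeta)
  P <- expeta / den
  if (!converged) {
    converged <- max(abs(as.vector(crossprod(X, Y - P)))) < 1e-6
  }
  H <- matrix(0, p * m, p * m)
  for (a in seq_len(m)) {
    for (b in seq_len(a)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      blk <- crossprod(X, X * w)
      ia <- (a - 1) * p + seq_len(p)
      ib <- (b - 1) * p + seq_len(p)
      H[ia, ib] <- blk
      H[ib, ia] <- blk
    }
  }
  dimnames(B) <- list(colnames(X), levels(y)[-1])
  list(B = B, coef_vec = as.vector(B), vcov = solve(H), loglik = ll,
       converged = converged)
}

#' Predicted category probabilities from a multinomial fit
#'
#' @param object A `multinom_result`.
#' @param newdata Table with the model's predictor and covariate columns.
#' @param ... Unused.
#' @return Matrix of per-person category probabilities (rows sum to 1).
#' @export
predict.multinom_result <- function(object, newdata, ...) {
  term_names <- rownames(object$coef)
  X <- cbind(intercept = 1, as.matrix(newdata[term_names[-1]]))
  eta <- X %*% object$coef
  expeta <- exp(eta)
  den <- 1 + rowSums(expeta)
  probs <- cbind(1 / den, expeta / den)
  colnames(probs) <- names(object$n_category)
  probs
}

#' @export
print.multinom_result <- function(x, ...) {
  cat("Multinomial logistic regression (referent = ",
      names(x$n_category)[1], ")\n", sep = "")
  cat("  predictor:", x$predictor, "| n =",
      paste(names(x$n_category), as.integer(x$n_category), sep = ":",
            collapse = ", "), "\n")
  tab <- x$table[x$table$term == x$predictor, ]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-7s OR = %.2f  [%.2f, %.2f]  p = %s\n", tab$category[i],
                tab$or[i], tab$or_lb[i], tab$or_ub[i],
                format.pval(tab$p[i], digits = 3)))
  }
  invisible(x)
}

#' Percentage increase in likelihood implied by an odds ratio
#'
#' `(OR - 1) * 100`: an odds ratio of 4.33 corresponds to a 333% increase in
#' the odds of the outcome category per unit of the predictor.
#'
#' @param or_value Odds ratio (positive).
#' @return Percentage change.
#' @export
or_percent_increase <- function(or_value) {
  if (any(!is.finite(or_value)) || any(or_value <= 0)) {
    stop("odds ratio must be positive", call. = FALSE)
  }
  (or_value - 1) * 100
}

#' Contrast a baseline predictor against the covariates-only model
#'
#' Fits the same multinomial model with a baseline predictor (e.g. baseline
#' MMSE) in place of a change slope and reports the likelihood-ratio test of
#' the predictor's contribution over the covariates-only model.
#'
#' @param data,predictor,covariate_cols,outcome,ref As [fit_multinomial()].
#' @return A list with `fit` (the full `multinom_result`), `fit_null`
#'   (covariates only), `lr_stat`, `df`, `p`.
#' @export
compare_baseline_predictor <- function(data, predictor = "mmse_baseline",
                                       covariate_cols = c("age_c", "sex"),
                                       outcome = "status", ref = "HC") {
  full <- fit_multinomial(data, predictor, covariate_cols, outcome, ref)
  null <- fit_multinomial(data, covariate_cols[1],
                          covariate_cols[-1], outcome, ref)
  # note: the "null" above still contains all covariates; only `predictor`
  # is removed.
  lr <- 2 * (full$loglik - null$loglik)
  df <- length(full$n_category) - 1
  list(fit = full, fit_null = null, lr_stat = lr, df = df,
       p = stats::pchisq(lr, df, lower.tail = FALSE))
}
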