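`%||%` <- function(x, y) if (is.null(x)) y else x

# Symmetric square root of a PSD matrix; tolerates zero eigenvalues (pure
# chol() would not, and generators legitimately use singular covariances,
# e.g. an intercept-only random-effect structure).
mat_sqrt <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1))) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

is_psd <- function(m, tol = 1e-8) {
  if (any(m != t(m))) m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

# Truncated-normal draws by rejection; bounds are wide relative to sd in all
# package defaults so this is cheap.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
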