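# Low-level maximum-likelihood fitters shared by the association, pathway and
# mediation stages. Linear fits report the Gaussian *profile* log-likelihood
# (sigma^2 maximized with divisor n) so that joint model likelihoods built from
# component fits are genuine maximized likelihoods; Wald p-values use the
# classical t reference (unbiased variance) for linear fits and the normal
# reference for logistic fits.

# Fit y = X b + e by QR. X must include the intercept column. Errors on rank
# deficiency, naming the offending columns.
fit_linear_mle <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2_mle <- rss / n
  sigma2_hat <- rss / (n - p)
  XtX_inv <- matrix(0, p, p)
  XtX_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtX_inv) * sigma2_hat)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(beta), std.error = unname(se),
      statistic = unname(tval), p.value = unname(pval)
    ),
    family = "linear",
    log_likelihood = loglik,
    sigma = sqrt(sigma2_mle),
    n = n,
    # intercept + slopes + residual variance
    n_parameters = p + 1L,
    converged = TRUE,
    separation = FALSE
  )
}

# Logistic fit via IRLS (stats::glm.fit). Flags non-convergence and numerical
# separation (fitted probabilities pinned at 0/1).
fit_logistic_mle <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), control = stats::glm.control(maxit = 50))
  )
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  p1 <- seq_len(fit$qr$rank)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, p)
  se[fit$qr$pivot[p1]] <- sqrt(diag(covmat))
  beta <- fit$coefficients
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(beta), std.error = unname(se),
      statistic = unname(zval), p.value = unname(pval)
    ),
    family = "logistic",
    # binary responses: saturated log-likelihood is 0, so logLik = -deviance/2
    log_likelihood = -fit$deviance / 2,
    sigma = NA_real_,
    n = n,
    n_parameters = p,
    converged = fit$converged,
    separation = separated
  )
}

new_snp_fit <- function(x) structure(x, class = "snp_fit")

# Minimal Wald statistics (estimate, p) for the `snp` column (column 2 of X):
# the screening loops call these thousands of times per replicate, so they
# skip the tibble assembly of the full fitters. NA on non-convergence or
# separation.
wald_snp_linear <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) return(c(NA_real_, NA_real_))
  beta <- qr.coef(qx, y)
  rss <- sum((y - drop(X %*% beta))^2)
  XtX_inv <- matrix(0, p, p)
  XtX_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  se2 <- diag(XtX_inv)[2] * rss / (n - p)
  tval <- beta[2] / sqrt(se2)
  c(beta[2], 2 * stats::pt(-abs(tval), df = n - p))
}

wald_snp_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50))
  )
  eps <- 1e-8
  if (!fit$converged || any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    return(c(NA_real_, NA_real_))
  }
  p1 <- seq_len(fit$qr$rank)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  i <- match(2L, fit$qr$pivot[p1])
  if (is.na(i)) return(c(NA_real_, NA_real_))
  z <- fit$coefficients[2] / sqrt(covmat[i, i])
  c(fit$coefficients[2], 2 * stats::pnorm(-abs(z)))
}

#' Fit a single-SNP regression
#'
#' Maximum-likelihood regression of a response on one SNP dosage column plus
#' covariates: the elementary fit underlying every stage of the causal pathway
#' analysis (SNP--FA, SNP--smoking, and the conditional models with the
#' mediator or outcome added as a predictor). Linear fits report the Gaussian
#' profile log-likelihood (residual variance maximized with divisor n), so
#' log-likelihoods of component fits add up to maximized joint likelihoods.
#'
#' @param data Data frame with one row per subject.
#' @param response Name of the response column. A two-level 0/1 (or logical)
#'   column is modelled by logistic regression under `family = "auto"`.
#' @param snp Name of the SNP dosage column (additive 0/1/2 coding).
#' @param covariates Character vector of covariate column names (may include
#'   the mediator or outcome for the conditional models). Default `c("age", "sex")`.
#' @param family `"auto"` (default), `"linear"` or `"logistic"`.
#' @return An object of class `snp_fit`: coefficients with standard errors and
#'   Wald p-values, log-likelihood, sample size, parameter count, convergence
#'   and separation flags. Use [tidy()][generics::tidy] / [glance()][generics::glance].
#' @examples
#' d <- simulate_dataset(sim_config(n_subjects = 300, n_snps = 2, seed = 1))
#' dat <- dplyr::bind_cols(d$phenotypes, d$genotypes["snp_1"])
#' fit <- fit_snp_regression(dat, response = "fa", snp = "snp_1")
#' tidy(fit)
#' glance(fit)
#' @export
fit_snp_regression <- function(data, response, snp, covariates = c("age", "sex"),
                               family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  cols <- c(response, snp, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  y <- d[[response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (family == "auto") {
    family <- if (is_binary01(y)) "logistic" else "linear"
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(d[c(snp, covariates)]))
  if (nrow(X) < ncol(X) + 1L) {
    stop("too few complete cases (", nrow(X), ") for ", ncol(X), " parameters",
         call. = FALSE)
  }
  out <- switch(family,
    linear = fit_linear_mle(X, y),
    logistic = fit_logistic_mle(X, y)
  )
  out$response <- response
  out$snp <- snp
  new_snp_fit(out)
}

is_binary01 <- function(y) {
  u <- unique(y[!is.na(y)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  fit$coefficients[i, ]
}

#' @export
print.snp_fit <- function(x, ...) {
  cat("<snp_fit> ", x$family, " regression of ", x$response %||% "y",
      " on ", x$snp %||% "snp", "\n", sep = "")
  cat("  n = ", x$n, ", logLik = ", format(x$log_likelihood, digits = 6),
      ", parameters = ", x$n_parameters, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a single-SNP regression fit
#'
#' @param x A [fit_snp_regression()] result.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.snp_fit <- function(x, ...) x$coefficients

#' One-row model summary for a single-SNP regression fit
#'
#' @param x A [fit_snp_regression()] result.
#' @param ... Unused.
#' @return A one-row tibble: family, log-likelihood, sample size, parameter
#'   count, residual standard deviation (linear fits), convergence and
#'   separation flags.
#' @export
glance.snp_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$log_likelihood,
    nobs = x$n,
    n_parameters = x$n_parameters,
    sigma = x$sigma,
    converged = x$converged,
    separation = x$separation
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
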