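#' Partial correlation after covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression of each on an intercept plus the covariates. With no
#' covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (or vector) of covariates, or `NULL`.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(stats::cor(x, y))
  Z <- cbind(1, as.matrix(covariates))
  if (n <= ncol(Z) + 2)
    stop("too few observations for the covariate set", call. = FALSE)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop("covariates are rank deficient (collinear)", call. = FALSE)
  rx <- stats::resid(stats::lm.fit(Z, x))
  ry <- stats::resid(stats::lm.fit(Z, y))
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1e-300))
    stop("a variable is collinear with the covariates; partial correlation undefined",
         call. = FALSE)
  stats::cor(rx, ry)
}

#' Case bootstrap of an arbitrary statistic
#'
#' Draws `B` with-replacement resamples of the rows of `data` (a case/pairs
#' bootstrap: x, y and covariates stay paired) and recomputes the statistic
#' on every resample, including any internal re-residualization or
#' re-standardization the statistic performs. Reports the percentile 95%
#' interval (2.5/97.5) and, because the interval phrasing in some study
#' reports is ambiguous, also the 90% (5/95) interval. `p_boot` is the
#' one-sided proportion of draws at or below zero, matching a
#' positive-alternative "proportion of coefficients greater than zero"
#' criterion.
#'
#' @param statistic_fn function taking a resampled data.frame/matrix and
#'   returning a scalar.
#' @param data data.frame or matrix of cases (rows are resampled).
#' @param B number of bootstrap resamples (default 5000).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return An object of class `bootstrap_result`: `point`, `draws`,
#'   `ci_low`/`ci_high` (95%), `ci90_low`/`ci90_high`, `p_boot`, `B`, `seed`,
#'   `n_failed`.
#' @export
bootstrap_estimate <- function(statistic_fn, data, B = 5000L, seed = 1L) {
  data <- as.data.frame(data)
  n <- nrow(data)
  point <- statistic_fn(data)
  set.seed(seed)
  draws <- numeric(B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic_fn(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
    if (is.na(val)) failed <- failed + 1L
    draws[b] <- val
  }
  if (failed > 0.01 * B)
    stop(sprintf("statistic failed on %d of %d bootstrap resamples", failed, B),
         call. = FALSE)
  ok <- draws[!is.na(draws)]
  q95 <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  q90 <- stats::quantile(ok, c(0.05, 0.95), names = FALSE, type = 7)
  structure(list(point = point, draws = draws,
                 ci_low = q95[1], ci_high = q95[2],
                 ci90_low = q90[1], ci90_high = q90[2],
                 p_boot = mean(ok <= 0), B = as.integer(B),
                 seed = as.integer(seed), n_failed = failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap estimate: %.4f, 95%% CI [%.4f, %.4f], p_boot = %.4g (B = %d)\n",
              x$point, x$ci_low, x$ci_high, x$p_boot, x$B))
  invisible(x)
}

## Point mediation computation on one dataset. Age is negated so that
## "older -> worse" effects carry positive signs; age, mediator and outcome
## are standardized so the coefficients are on a correlation-like scale.
## Binary covariates (sex) are left as coded.
mediation_point <- function(d) {
  neg_age <- scale(-d$age)[, 1]
  med <- scale(d$mediator)[, 1]
  out <- scale(d$outcome)[, 1]
  if (stats::sd(d$mediator) == 0 || abs(stats::cor(neg_age, med)) > 1 - 1e-12)
    stop("mediator is collinear with age", call. = FALSE)
  cv <- as.matrix(d[, setdiff(names(d), c("age", "mediator", "outcome")),
                    drop = FALSE])
  Z1 <- cbind(1, neg_age, cv)
  Z2 <- cbind(1, neg_age, med, cv)
  total <- stats::lm.fit(Z1, out)$coefficients[2]
  direct <- stats::lm.fit(Z2, out)$coefficients[2]
  c(total = unname(total), direct = unname(direct),
    mediation = unname(total - direct))
}

#' Difference-of-coefficients mediation of the age-cognition relationship
#'
#' Fits two least-squares models: (1) outcome on age and covariates, and (2)
#' outcome on age, mediator and covariates. The mediation effect is the drop
#' in the age coefficient between the two models (which, for linear models,
#' equals the product of the age-to-mediator and mediator-to-outcome paths).
#' Age is negated before fitting so that meaningful effects are positive, and
#' age, mediator and outcome are standardized so the coefficients are
#' commensurate with correlations. Inference on the mediation effect is by
#' case bootstrap ([bootstrap_estimate()]), re-standardizing within every
#' resample.
#'
#' @param age age in years.
#' @param mediator brain-based mediator (e.g. cross-validated thickness
#'   predictions, or one vertex's thickness).
#' @param outcome cognitive ability score.
#' @param covariates optional covariate matrix (e.g. sex).
#' @param B bootstrap resamples (default 5000).
#' @param seed seed for the bootstrap.
#' @return An object of class `mediation_estimate`: `total`, `direct`,
#'   `mediation` (= total - direct), `boot` (a [bootstrap_estimate()] result
#'   for the mediation effect), `covariates` (names used).
#' @export
mediation_effect <- function(age, mediator, outcome, covariates = NULL,
                             B = 5000L, seed = 1L) {
  d <- data.frame(age = age, mediator = mediator, outcome = outcome)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (is.null(names(covariates)) && ncol(cv) == 1) names(cv) <- "covariate_1"
    d <- cbind(d, cv)
  }
  pt <- mediation_point(d)
  boot <- bootstrap_estimate(function(dd) mediation_point(dd)[["mediation"]],
                             d, B = B, seed = seed)
  structure(list(total = pt[["total"]], direct = pt[["direct"]],
                 mediation = pt[["mediation"]], boot = boot,
                 covariates = setdiff(names(d), c("age", "mediator", "outcome"))),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat("Difference-of-coefficients mediation (age negated, standardized scale)\n")
  cat(sprintf("  total effect of age:  %.4f\n", x$total))
  cat(sprintf("  direct effect of age: %.4f\n", x$direct))
  cat(sprintf("  mediation effect:     %.4f, 95%% CI [%.4f, %.4f], p_boot = %.4g\n",
              x$mediation, x$boot$ci_low, x$boot$ci_high, x$boot$p_boot))
  if (length(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' @export
coef.mediation_estimate <- function(object, ...) {
  c(total = object$total, direct = object$direct,
    mediation = object$mediation)
}
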