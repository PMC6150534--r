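# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-iteration sub-seed so adding iterations never changes
## earlier folds. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + as.numeric(i)) %% 2147483647L)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## Column-wise z-scoring; constant columns map to 0 rather than NaN.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

## Moments of a normal(mu, sigma) truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

## Find (mu0, sigma0) such that N(mu0, sigma0) truncated to [lo, hi] has the
## requested mean and sd. Truncating N(69.5, 6.58) to [60, 89] directly would
## shift the mean up ~1 year and shrink the SD to ~5.7.
truncnorm_match <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## Rejection sampler for the truncated normal (bounds are mild here, so the
## acceptance rate is high).
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mu, sigma)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}
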