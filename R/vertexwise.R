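#' Vertex-wise bootstrap-ratio map
#'
#' For every vertex, bootstraps a statistic relating that vertex's
#' morphometry to cognition and summarizes it as a bootstrap ratio
#' (BSR = mean of bootstrap draws / SD of bootstrap draws), which is treated
#' as approximately standard normal for thresholding. Two statistics are
#' supported: the sex-adjusted partial correlation of vertex morphometry with
#' ability (`kind = "correlation"`), and the difference-of-coefficients
#' mediation effect of the age-ability relationship with the vertex value as
#' mediator (`kind = "mediation"`, same standardization conventions as
#' [mediation_effect()]). One set of `B` case resamples is drawn and reused
#' across all vertices, which keeps the map coherent and the computation a
#' handful of matrix products per resample.
#'
#' @param ds a [surface_dataset] aligned with the behavioral vectors.
#' @param ability cognitive ability scores.
#' @param age age in years (required for `kind = "mediation"`).
#' @param covariates optional covariate matrix (typically sex).
#' @param B bootstrap resamples (>= 100; default 500, full-scale runs use
#'   5000).
#' @param seed integer seed.
#' @param kind statistic to bootstrap.
#' @return An object of class `bsr_map`: `bsr` (per vertex; `NA` where
#'   undefined), `undefined` (logical: bootstrap SD ~ 0 or zero-variance
#'   vertex), `boot_mean`, `boot_sd`, `labels`, `measure`, `kind`, `B`,
#'   `seed`.
#' @export
vertex_bsr <- function(ds, ability, age = NULL, covariates = NULL,
                       B = 500L, seed = 1L,
                       kind = c("correlation", "mediation")) {
  kind <- match.arg(kind)
  stopifnot(inherits(ds, "surface_dataset"))
  X <- ds$values
  n <- nrow(X)
  V <- ncol(X)
  if (length(ability) != n)
    stop("ability must align with the surface dataset rows", call. = FALSE)
  if (kind == "mediation" && (is.null(age) || length(age) != n))
    stop("mediation maps require an age vector aligned with the rows",
         call. = FALSE)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)

  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)

  draws <- matrix(NA_real_, B, V)
  for (b in seq_len(B)) {
    rows <- idx[b, ]
    draws[b, ] <- if (kind == "correlation")
      vertex_partial_cor(X[rows, , drop = FALSE], ability[rows],
                         if (is.null(cv)) NULL else cv[rows, , drop = FALSE])
    else
      vertex_mediation(X[rows, , drop = FALSE], age[rows], ability[rows],
                       if (is.null(cv)) NULL else cv[rows, , drop = FALSE])
  }
  boot_mean <- colMeans(draws)
  boot_sd <- sqrt(colSums(sweep(draws, 2, boot_mean, "-")^2) / (B - 1))
  undefined <- !is.finite(boot_mean) | boot_sd < 1e-12
  bsr <- ifelse(undefined, NA_real_, boot_mean / boot_sd)
  structure(list(bsr = bsr, undefined = undefined,
                 boot_mean = boot_mean, boot_sd = boot_sd,
                 labels = ds$labels, measure = ds$measure,
                 kind = kind, B = as.integer(B), seed = as.integer(seed)),
            class = "bsr_map")
}

## Partial correlation of every column of X with y given covariates,
## computed via joint residualization on [1, covariates].
vertex_partial_cor <- function(X, y, cv = NULL) {
  Z <- cbind(rep(1, length(y)), cv)
  qz <- qr(Z)
  ry <- stats::resid(stats::lm.fit(Z, y))
  RX <- X - Z %*% qr.coef(qz, X)
  num <- as.vector(crossprod(RX, ry))
  den <- sqrt(colSums(RX^2) * sum(ry^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## Difference-of-coefficients mediation effect per column of X as mediator,
## via the product-of-paths identity (exact for least squares):
## beta(neg_age -> mediator | cv) * beta(mediator -> outcome | neg_age, cv).
## neg_age, outcome and each mediator column are standardized.
vertex_mediation <- function(X, age, y, cv = NULL) {
  na_ <- scale(-age)[, 1]
  out <- scale(y)[, 1]
  Xs <- zscore_cols(X)
  one <- rep(1, length(na_))
  Z1 <- cbind(one, cv)
  ra <- stats::resid(stats::lm.fit(Z1, na_))
  b_am <- as.vector(crossprod(Xs, ra)) / sum(ra^2)
  Z2 <- cbind(one, na_, cv)
  qz2 <- qr(Z2)
  ry <- stats::resid(stats::lm.fit(Z2, out))
  RX <- Xs - Z2 %*% qr.coef(qz2, Xs)
  den <- colSums(RX^2)
  b_my <- as.vector(crossprod(RX, ry)) / den
  med <- b_am * b_my
  med[den < 1e-12] <- NA_real_
  med
}

#' @export
print.bsr_map <- function(x, ...) {
  cat(sprintf("BSR map (%s, %s): %d vertices, B = %d\n",
              x$measure, x$kind, length(x$bsr), x$B))
  cat(sprintf("  undefined vertices: %d; |BSR| >= 1.96: %d\n",
              sum(x$undefined), sum(abs(x$bsr) >= 1.96, na.rm = TRUE)))
  invisible(x)
}

#' Count suprathreshold vertices per network
#'
#' @param map a [vertex_bsr()] map (or a plain numeric BSR vector).
#' @param labels per-vertex network labels; defaults to the map's own.
#' @param thresholds BSR thresholds (defaults 1.96, 2.58, 3.3, 3.9,
#'   i.e. two-sided normal p of .05, .01, .001, .0001).
#' @param sign `"positive"` counts BSR >= t (the default; the substantive
#'   hypotheses concern positive structure-cognition effects);
#'   `"absolute"` counts |BSR| >= t.
#' @return An object of class `network_counts`: `counts` (7 networks x
#'   thresholds), `total` (whole-map suprathreshold count per threshold,
#'   labeled vertices only), `thresholds`, `sign`. Undefined and unlabeled
#'   vertices are excluded.
#' @export
count_suprathreshold <- function(map, labels = NULL,
                                 thresholds = c(1.96, 2.58, 3.3, 3.9),
                                 sign = c("positive", "absolute")) {
  sign <- match.arg(sign)
  if (inherits(map, "bsr_map")) {
    bsr <- map$bsr
    labels <- labels %||% map$labels
  } else {
    bsr <- as.numeric(map)
    if (is.null(labels)) stop("labels are required for a bare BSR vector",
                              call. = FALSE)
  }
  if (length(labels) != length(bsr))
    stop("labels must align with the BSR map", call. = FALSE)
  stat <- if (sign == "absolute") abs(bsr) else bsr
  ok <- !is.na(stat) & labels >= 1L
  counts <- sapply(thresholds, function(t)
    tabulate(labels[ok & stat >= t], nbins = 7L))
  counts <- matrix(counts, nrow = 7L,
                   dimnames = list(network = 1:7,
                                   threshold = format(thresholds)))
  structure(list(counts = counts, total = colSums(counts),
                 thresholds = thresholds, sign = sign),
            class = "network_counts")
}

#' @export
print.network_counts <- function(x, ...) {
  cat(sprintf("Suprathreshold vertex counts (%s tail)\n", x$sign))
  print(x$counts)
  invisible(x)
}

#' Permutation (shuffled-BSR) network enrichment test
#'
#' Shuffles the vertex BSR values across all labeled, defined vertices
#' (equivalently, permutes the network labels), recounts suprathreshold
#' vertices per network and threshold, and reports the proportion of
#' permutations whose count reaches the empirical count (`p_ge`, enrichment)
#' as well as the proportion at or below it (`p_le`, "fewer than chance").
#' The reported p is the plain proportion without a +1 correction, so p = 0
#' is reportable with resolution 1/`n_perm`.
#'
#' @inheritParams count_suprathreshold
#' @param n_perm number of permutations (>= 100; default 2000, full-scale
#'   runs use 100000).
#' @param seed integer seed.
#' @return An object of class `network_perm_test`: `empirical` (7 x
#'   thresholds counts), `null_mean`, `p_ge`, `p_le`, `total`, `n_perm`,
#'   `thresholds`, `sign`, and `null` (the n_perm x 7 x thresholds array of
#'   permuted counts).
#' @export
permutation_network_test <- function(map, labels = NULL,
                                     thresholds = c(1.96, 2.58, 3.3, 3.9),
                                     n_perm = 2000L, seed = 1L,
                                     sign = c("positive", "absolute")) {
  sign <- match.arg(sign)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (inherits(map, "bsr_map")) {
    bsr <- map$bsr
    labels <- labels %||% map$labels
  } else {
    bsr <- as.numeric(map)
    if (is.null(labels)) stop("labels are required for a bare BSR vector",
                              call. = FALSE)
  }
  stat <- if (sign == "absolute") abs(bsr) else bsr
  elig <- which(!is.na(stat) & labels >= 1L)
  vals <- stat[elig]
  labs <- labels[elig]
  E <- length(elig)
  nT <- length(thresholds)
  supra_idx <- lapply(thresholds, function(t) which(vals >= t))
  empirical <- vapply(supra_idx, function(ix) tabulate(labs[ix], nbins = 7L),
                      integer(7))
  set.seed(seed)
  null <- array(0L, dim = c(n_perm, 7L, nT))
  for (p in seq_len(n_perm)) {
    pl <- labs[sample.int(E)]
    for (t in seq_len(nT))
      null[p, , t] <- tabulate(pl[supra_idx[[t]]], nbins = 7L)
  }
  null_mean <- apply(null, c(2, 3), mean)
  p_ge <- matrix(0, 7, nT)
  p_le <- matrix(0, 7, nT)
  for (t in seq_len(nT)) for (k in 1:7) {
    p_ge[k, t] <- mean(null[, k, t] >= empirical[k, t])
    p_le[k, t] <- mean(null[, k, t] <= empirical[k, t])
  }
  dn <- list(network = 1:7, threshold = format(thresholds))
  dimnames(empirical) <- dimnames(null_mean) <- dimnames(p_ge) <-
    dimnames(p_le) <- dn
  structure(list(empirical = empirical, null_mean = null_mean,
                 p_ge = p_ge, p_le = p_le,
                 total = colSums(empirical), n_perm = as.integer(n_perm),
                 thresholds = thresholds, sign = sign, seed = as.integer(seed),
                 null = null),
            class = "network_perm_test")
}

#' @export
print.network_perm_test <- function(x, ...) {
  cat(sprintf("Permutation network enrichment (%s tail, %d permutations)\n",
              x$sign, x$n_perm))
  cat("empirical counts:\n"); print(x$empirical)
  cat("p (count >= empirical):\n"); print(round(x$p_ge, 4))
  invisible(x)
}
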