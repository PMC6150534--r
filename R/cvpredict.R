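#' Cross-validation plan for select-average-regress prediction
#'
#' @param k number of folds (default 5).
#' @param n_iterations number of repeated random partitions (default 100;
#'   tests and examples use 10 for speed).
#' @param alphas p-value selection thresholds, stored strictly decreasing
#'   (defaults .05, .01, .001, .0005, .0001).
#' @param seed master seed; iteration `i` uses a sub-seed derived from it, so
#'   increasing `n_iterations` never changes earlier folds.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(k = 5L, n_iterations = 100L,
                    alphas = c(0.05, 0.01, 0.001, 0.0005, 0.0001),
                    seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(alphas <= 0 | alphas > 1))
    stop("alphas must be in (0, 1]", call. = FALSE)
  alphas <- sort(unique(alphas), decreasing = TRUE)
  structure(list(k = as.integer(k), n_iterations = as.integer(n_iterations),
                 alphas = alphas, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Select vertices by univariate association with ability
#'
#' Marks the vertices whose simple linear regression on the ability score has
#' a two-sided p-value at or below `alpha`. The p-value is the Pearson
#' correlation t-test with n - 2 degrees of freedom, computed for all
#' vertices at once.
#'
#' @param X_scaled numeric matrix (training participants x vertices), already
#'   robust-scaled.
#' @param y ability scores for the training participants.
#' @param alpha selection threshold; vertices with p <= alpha are selected.
#' @return Logical vertex mask (possibly all-FALSE).
#' @export
univariate_select <- function(X_scaled, y, alpha) {
  vertex_pvalues(X_scaled, y) <= alpha
}

## Two-sided correlation-test p-values for every column of X against y.
vertex_pvalues <- function(X, y) {
  n <- length(y)
  if (n <= 3) stop("univariate selection needs more than 3 observations",
                   call. = FALSE)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X), "-")
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(crossprod(Xc, yc)) / (sx * sy)
  r[sx == 0] <- 0
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Fit the one-coefficient average model
#'
#' Averages the (scaled) morphometry of the selected vertices per participant
#' and regresses ability on that single mean by ordinary least squares.
#'
#' @param X_scaled training matrix, robust-scaled.
#' @param mask logical or integer vertex mask; must select at least one vertex.
#' @param y training ability scores.
#' @param scale_params optional `scale_params` from the training fold, stored
#'   so [predict.average_model()] can scale raw test data identically.
#' @return An object of class `average_model` with `intercept`, `slope`,
#'   `mask`, `scale_params`, `n_selected`.
#' @export
fit_average_model <- function(X_scaled, mask, y, scale_params = NULL) {
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("empty vertex mask: no model", call. = FALSE)
  m <- rowMeans(X_scaled[, mask, drop = FALSE])
  mx <- mean(m); my <- mean(y)
  vx <- sum((m - mx)^2)
  slope <- if (vx == 0) 0 else sum((m - mx) * (y - my)) / vx
  structure(list(intercept = my - slope * mx, slope = slope,
                 mask = mask, scale_params = scale_params,
                 n_selected = length(mask)),
            class = "average_model")
}

#' @export
coef.average_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict ability from raw morphometry with a fitted average model
#'
#' @param object an `average_model`.
#' @param newdata raw (unscaled) matrix if the model carries `scale_params`,
#'   otherwise an already-scaled matrix.
#' @param ... unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.average_model <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "surface_dataset")) newdata$values else
    as.matrix(newdata)
  if (!is.null(object$scale_params))
    m <- apply_scale(object$scale_params, m)
  object$intercept + object$slope * rowMeans(m[, object$mask, drop = FALSE])
}

#' Repeated cross-validated select-average-regress prediction
#'
#' Implements the full predictive workflow: for each of `n_iterations` random
#' k-fold partitions and each training fold, (1) robust-scale the training
#' vertices (median/IQR), (2) compute every vertex's univariate p-value
#' against the ability score, (3) for each selection threshold alpha, average
#' the selected vertices and fit a one-coefficient linear model, (4) scale the
#' held-out fold with the training parameters and predict. Scaling, selection
#' and fitting never see test rows. A fold where no vertex survives an alpha
#' contributes no predictions at that alpha (recorded in the diagnostics, not
#' an error). Per-participant predictions are averaged over all test-fold
#' occurrences per alpha, and the across-alpha average uses the alphas at
#' which the participant received any prediction.
#'
#' @param ds a [surface_dataset] (typically one network via
#'   [subset_network()]).
#' @param y ability scores aligned with the rows of `ds`; participants with
#'   missing `y` are dropped with a warning before partitioning.
#' @param plan a [cv_plan()].
#' @return An object of class `cv_prediction`: `predictions` (data.frame:
#'   id, one column per alpha, `average`), `diagnostics` (per alpha: fraction
#'   of folds with zero vertices selected), `fold_models` (data.frame of per
#'   fold x alpha slopes, intercepts and selection counts), `plan`, `n_used`,
#'   `n_predictions` (participants x alphas count of test-fold predictions
#'   received).
#' @export
repeated_cv_predict <- function(ds, y, plan = cv_plan()) {
  stopifnot(inherits(ds, "surface_dataset"), inherits(plan, "cv_plan"))
  X_all <- ds$values
  if (length(y) != nrow(X_all))
    stop("y must align with the rows of the surface dataset", call. = FALSE)
  keep <- !is.na(y)
  if (!all(keep)) {
    warning(sprintf("excluding %d participants with missing ability scores",
                    sum(!keep)))
    X_all <- X_all[keep, , drop = FALSE]
  }
  ids <- ds$participant_ids[keep]
  yy <- y[keep]
  n <- length(yy)
  alphas <- plan$alphas
  A <- length(alphas)
  pred_sum <- matrix(0, n, A)
  pred_cnt <- matrix(0L, n, A)
  zero_folds <- integer(A)
  total_folds <- 0L
  fm <- vector("list", plan$n_iterations)

  for (it in seq_len(plan$n_iterations)) {
    set.seed(derive_seed(plan$seed, it))
    fold_of <- sample(rep_len(seq_len(plan$k), n))
    rows <- vector("list", plan$k * A)
    ri <- 0L
    for (fold in seq_len(plan$k)) {
      test <- which(fold_of == fold)
      train <- which(fold_of != fold)
      sc <- robust_scale(X_all[train, , drop = FALSE])
      Xte <- apply_scale(sc$params, X_all[test, , drop = FALSE])
      pv <- vertex_pvalues(sc$scaled, yy[train])
      total_folds <- total_folds + 1L
      for (a in seq_len(A)) {
        mask <- which(pv <= alphas[a])
        ri <- ri + 1L
        if (!length(mask)) {
          zero_folds[a] <- zero_folds[a] + 1L
          rows[[ri]] <- data.frame(iteration = it, fold = fold,
                                   alpha = alphas[a], n_selected = 0L,
                                   slope = NA_real_, intercept = NA_real_)
          next
        }
        mod <- fit_average_model(sc$scaled, mask, yy[train])
        pred <- mod$intercept + mod$slope *
          rowMeans(Xte[, mask, drop = FALSE])
        pred_sum[test, a] <- pred_sum[test, a] + pred
        pred_cnt[test, a] <- pred_cnt[test, a] + 1L
        rows[[ri]] <- data.frame(iteration = it, fold = fold,
                                 alpha = alphas[a], n_selected = length(mask),
                                 slope = mod$slope, intercept = mod$intercept)
      }
    }
    fm[[it]] <- do.call(rbind, rows)
  }

  per_alpha <- pred_sum / ifelse(pred_cnt > 0, pred_cnt, NA)
  average <- rowMeans(per_alpha, na.rm = TRUE)
  average[is.nan(average)] <- NA
  preds <- data.frame(id = ids, per_alpha, average = average,
                      check.names = FALSE)
  names(preds)[1 + seq_len(A)] <- sprintf("alpha_%g", alphas)
  diagnostics <- data.frame(alpha = alphas,
                            frac_zero_selection = zero_folds /
                              (plan$n_iterations * plan$k))
  colnames(pred_cnt) <- sprintf("alpha_%g", alphas)
  structure(list(predictions = preds, diagnostics = diagnostics,
                 fold_models = do.call(rbind, fm), plan = plan,
                 n_used = n, measure = ds$measure,
                 n_predictions = pred_cnt),
            class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf("Cross-validated predictions (%s): %d participants, %d x %d-fold CV\n",
              x$measure, x$n_used, x$plan$n_iterations, x$plan$k))
  cat(sprintf("  alphas: %s\n", paste(x$plan$alphas, collapse = ", ")))
  cat(sprintf("  folds with empty selection: %s\n",
              paste(sprintf("%.0f%%", 100 * x$diagnostics$frac_zero_selection),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize a cross-validated prediction against observed ability
#'
#' @param object a `cv_prediction`.
#' @param y observed ability scores (aligned with `object$predictions`).
#' @param covariates optional covariate matrix (e.g. sex) for partial
#'   correlations.
#' @param ... unused.
#' @return data.frame with the (partial) correlation of predicted and
#'   observed ability per alpha and for the across-alpha average.
#' @export
summary.cv_prediction <- function(object, y = NULL, covariates = NULL, ...) {
  if (is.null(y)) {
    print(object)
    return(invisible(object))
  }
  cols <- setdiff(names(object$predictions), "id")
  r <- vapply(cols, function(cn) {
    p <- object$predictions[[cn]]
    ok <- !is.na(p) & !is.na(y)
    if (sum(ok) < 5) return(NA_real_)
    cv <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[ok, , drop = FALSE]
    partial_correlation(p[ok], y[ok], cv)
  }, numeric(1))
  data.frame(prediction = cols, r = unname(r))
}
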