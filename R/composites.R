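#' Winsorize a vector at k standard deviations
#'
#' Values more than `k_sd` SDs from the mean are replaced by the boundary
#' value `mean +/- k_sd * SD`. Mean and SD come from the input vector itself
#' in a single pass (the boundaries are not re-estimated after replacement),
#' which is the convention used before composite construction in aging
#' batteries. Constant input is returned unchanged.
#'
#' @param values numeric vector with at least 3 non-missing entries.
#' @param k_sd boundary in SD units (default 3).
#' @return The winsorized vector, with attribute `n_replaced` giving the
#'   number of values that were clamped.
#' @examples
#' x <- c(rnorm(50), 10)
#' attr(winsorize(x), "n_replaced")
#' @export
winsorize <- function(values, k_sd = 3) {
  stopifnot(is.numeric(values), k_sd > 0)
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("winsorize needs at least 3 non-missing values",
                        call. = FALSE)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) {
    attr(values, "n_replaced") <- 0L
    return(values)
  }
  lo <- m - k_sd * s
  hi <- m + k_sd * s
  n_rep <- sum(values[ok] < lo | values[ok] > hi)
  out <- pmin(pmax(values, lo), hi)
  attr(out, "n_replaced") <- as.integer(n_rep)
  out
}

#' Prepare a task battery for composite construction
#'
#' Winsorizes each task and sign-flips tasks where lower raw scores mean
#' better performance (response times, completion times, error/swap counts)
#' so that every column is oriented higher-is-better before PCA. Flipping
#' after winsorization and before standardization leaves the PCA solution's
#' loadings uniformly positive for a two-block battery.
#'
#' @param task_matrix numeric matrix, participants x tasks.
#' @param higher_is_better logical vector per task; `FALSE` columns are
#'   multiplied by -1.
#' @param k_sd winsorization boundary in SD units.
#' @return The winsorized, direction-corrected matrix with attribute
#'   `n_replaced` (per-task clamp counts).
#' @export
prepare_tasks <- function(task_matrix, higher_is_better = NULL, k_sd = 3) {
  x <- as.matrix(task_matrix)
  higher_is_better <- higher_is_better %||% rep(TRUE, ncol(x))
  if (length(higher_is_better) != ncol(x))
    stop("higher_is_better must have one entry per task", call. = FALSE)
  counts <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    w <- winsorize(x[, j], k_sd)
    counts[j] <- attr(w, "n_replaced")
    x[, j] <- if (higher_is_better[j]) w else -w
  }
  names(counts) <- colnames(x)
  attr(x, "n_replaced") <- counts
  x
}

#' Principal components with varimax rotation for a task battery
#'
#' Standardizes the (already winsorized, direction-corrected) task columns,
#' extracts the first `n_components` principal components, and applies a
#' varimax rotation with Kaiser normalization. Loadings are component
#' correlations (eigenvector times singular value on the correlation scale).
#' Component signs are fixed so each component's largest-|loading| task loads
#' positively, and components are ordered by post-rotation variance explained.
#'
#' @param task_matrix numeric matrix, participants x tasks.
#' @param n_components number of components to retain (default 2).
#' @return An object of class `component_solution`: `loadings`
#'   (tasks x components), `variance_explained` (proportions of total
#'   variance of the standardized battery), `assignment` (per task, the
#'   component with the larger |loading|), `n_retained`, and `unrotated`
#'   (pre-rotation loadings, for rotation-identity checks).
#' @export
pca_varimax <- function(task_matrix, n_components = 2) {
  x <- as.matrix(task_matrix)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("task_%d", seq_len(p))
  z <- zscore_cols(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  if (sum(pc$sdev > 1e-10) < n_components)
    stop("task matrix rank is below the number of requested components",
         call. = FALSE)
  ## loadings on the correlation metric: eigvec * component SD
  A <- pc$rotation[, seq_len(n_components), drop = FALSE] %*%
    diag(pc$sdev[seq_len(n_components)], n_components)
  rot <- stats::varimax(A, normalize = TRUE, eps = 1e-6)
  Lr <- A %*% rot$rotmat
  ## sign: the dominant task of each component loads positively
  for (j in seq_len(n_components)) {
    k <- which.max(abs(Lr[, j]))
    if (Lr[k, j] < 0) Lr[, j] <- -Lr[, j]
  }
  ve <- colSums(Lr^2) / p
  ord <- order(ve, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  ve <- ve[ord]
  colnames(Lr) <- sprintf("component_%d", seq_len(n_components))
  rownames(Lr) <- colnames(x)
  assignment <- apply(abs(Lr), 1, which.max)
  structure(list(loadings = Lr,
                 variance_explained = unname(ve),
                 assignment = assignment,
                 n_retained = n_components,
                 unrotated = A),
            class = "component_solution")
}

#' @export
print.component_solution <- function(x, digits = 2, ...) {
  cat(sprintf("Component solution: %d components, variance explained %s\n",
              x$n_retained,
              paste(sprintf("%.2f", x$variance_explained), collapse = " / ")))
  L <- round(x$loadings, digits)
  tag <- matrix("", nrow(L), ncol(L))
  tag[cbind(seq_len(nrow(L)), x$assignment)] <- "*"
  out <- matrix(paste0(format(L), tag), nrow(L),
                dimnames = dimnames(L))
  print(out, quote = FALSE)
  cat("(* = assigned component)\n")
  invisible(x)
}

#' Build composite ability scores from a component solution
#'
#' Each composite is the mean of the z-scored tasks assigned to that
#' component (assignment = larger |loading|). With tasks oriented
#' higher-is-better, higher composite values mean better ability; each
#' composite has mean zero by construction.
#'
#' @param task_matrix the same direction-corrected, winsorized matrix the
#'   solution was fit on.
#' @param solution a `component_solution` from [pca_varimax()].
#' @return A matrix (participants x components) of composite scores, columns
#'   named `composite_1`, ... (for the default battery: executive function,
#'   episodic memory).
#' @export
build_composites <- function(task_matrix, solution) {
  stopifnot(inherits(solution, "component_solution"))
  x <- as.matrix(task_matrix)
  if (nrow(solution$loadings) != ncol(x))
    stop("solution and task matrix disagree on the number of tasks",
         call. = FALSE)
  z <- zscore_cols(x)
  out <- sapply(seq_len(solution$n_retained), function(j) {
    members <- which(solution$assignment == j)
    if (!length(members))
      stop(sprintf("component %d has no assigned tasks", j), call. = FALSE)
    rowMeans(z[, members, drop = FALSE])
  })
  colnames(out) <- sprintf("composite_%d", seq_len(solution$n_retained))
  rownames(out) <- rownames(task_matrix)
  out
}

#' Compute executive-function and episodic-memory composites for a cohort
#'
#' Convenience wrapper running the full composite workflow on a participant
#' table: winsorize, orient higher-is-better, PCA + varimax with two
#' components, and average standardized member tasks. The component whose
#' dominant tasks overlap the executive block is labeled
#' `executive_function`; the other `episodic_memory`.
#'
#' @param participants data.frame with task columns.
#' @param task_cols names of the 11 task columns (default: everything except
#'   id/age/sex).
#' @param higher_is_better logical per task; defaults to all `TRUE`
#'   (synthetic batteries are generated higher-is-better).
#' @param executive_tasks task names regarded as the executive block when
#'   labeling the two components; the component to which the majority of
#'   these tasks is assigned becomes `executive_function`. Defaults to the
#'   executive block of the default synthetic battery.
#' @return A list: `composites` (data.frame id, executive_function,
#'   episodic_memory), `solution` (the `component_solution`), `prepared`
#'   (the corrected task matrix).
#' @export
cohort_composites <- function(participants, task_cols = NULL,
                              higher_is_better = NULL,
                              executive_tasks = c("flanker", "trail_b",
                                                  "spatial_wm", "n_back",
                                                  "dot_comparison",
                                                  "digit_symbol")) {
  task_cols <- task_cols %||%
    setdiff(names(participants), c("id", "age", "sex"))
  x <- as.matrix(participants[, task_cols])
  prepared <- prepare_tasks(x, higher_is_better)
  sol <- pca_varimax(prepared, 2)
  comp <- build_composites(prepared, sol)
  # label by which component absorbs the executive block (component order is
  # by variance explained, which can swap under sampling variability)
  ef_idx <- which(task_cols %in% executive_tasks)
  if (length(ef_idx)) {
    ef_comp <- as.integer(names(which.max(table(sol$assignment[ef_idx]))))
    colnames(comp)[ef_comp] <- "executive_function"
    colnames(comp)[3 - ef_comp] <- "episodic_memory"
  } else {
    colnames(comp) <- c("executive_function", "episodic_memory")
  }
  comp <- comp[, c("executive_function", "episodic_memory")]
  res <- data.frame(id = participants$id %||% seq_len(nrow(x)),
                    comp, check.names = FALSE)
  list(composites = res, solution = sol, prepared = prepared)
}
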