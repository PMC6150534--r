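# Shared fixture builders. Everything is generated in code; no stored data.

## Small default-structure cohort for fast tests.
small_cohort <- function(n = 80, V = 120, seed = 42, mutate = identity) {
  cfg <- default_sim_config(n_participants = n, n_vertices = V, seed = seed)
  cfg <- mutate(cfg)
  simulate_cohort(cfg)
}

## Config with every structure-cognition/age coupling removed.
zero_coupling <- function(cfg) {
  cfg$network_coupling[, ] <- 0
  cfg
}

## Population PCA + varimax oracle: the large-n limit of pca_varimax() under
## the generator's task model, computed from the closed-form population
## correlation matrix (no sampling). Used to check finite-sample recovery.
population_pca_oracle <- function(cfg, n_components = 2) {
  L <- cfg$task_loading_matrix
  r <- cfg$age_effect_per_factor
  rho <- cfg$latent_factor_correlation
  Phi <- matrix(c(1, rho, rho, 1), 2, 2)
  Sigma <- L %*% Phi %*% t(L) + diag(cfg$task_noise_sd^2)
  R <- stats::cov2cor(Sigma)
  ee <- eigen(R, symmetric = TRUE)
  A <- ee$vectors[, seq_len(n_components)] %*%
    diag(sqrt(ee$values[seq_len(n_components)]))
  rot <- stats::varimax(A, normalize = TRUE, eps = 1e-6)
  Lr <- A %*% rot$rotmat
  for (j in seq_len(n_components)) {
    k <- which.max(abs(Lr[, j]))
    if (Lr[k, j] < 0) Lr[, j] <- -Lr[, j]
  }
  ve <- colSums(Lr^2) / nrow(L)
  ord <- order(ve, decreasing = TRUE)
  rownames(Lr) <- rownames(L)
  list(loadings = Lr[, ord, drop = FALSE], variance_explained = ve[ord])
}

## Random surface dataset with iid noise (no structure), for null checks.
noise_surface <- function(n = 40, V = 60, seed = 1, labels = NULL) {
  set.seed(seed)
  labels <- labels %||% rep_len(1:7, V)
  surface_dataset(matrix(rnorm(n * V), n, V), labels, measure = "thickness")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
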