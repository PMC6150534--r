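#' Default simulation configuration for a synthetic aging cohort
#'
#' Returns the configuration used throughout the package's tests and examples:
#' a cohort of 165 older adults (ages 60--89, mean 69.5, SD 6.58, 105 female)
#' with two correlated latent cognitive factors (executive function, episodic
#' memory), an 11-task behavioral battery with a two-block loading structure,
#' and vertex-wise cortical thickness (mean 2.39 mm, global-mean SD 0.12 mm)
#' and surface area (total 157,614 mm\eqn{^2}, SD 15,776 mm\eqn{^2}) over a
#' 7-network parcellation. The vertex count defaults to 2,000, a scaled-down
#' stand-in for a full fsaverage cortex (~300k vertices); network sizes are
#' proportional to the 7-network parcellation with a small unlabeled
#' (medial-wall) remainder.
#'
#' @param n_participants cohort size.
#' @param n_vertices total vertex count across both hemispheres.
#' @param seed integer seed stored in the config; [simulate_cohort()] uses it.
#' @return An object of class `sim_config` (a named list). Key fields:
#'   `network_sizes` (7 labeled counts + `unlabeled`), `age_mean`, `age_sd`,
#'   `age_range`, `female_fraction`, `latent_factor_correlation`,
#'   `age_effect_per_factor`, `task_loading_matrix` (11 x 2),
#'   `task_noise_sd`, `thickness_mean`, `thickness_sd`, `thickness_vertex_sd`,
#'   `area_total_mean`, `area_total_sd`, `area_vertex_cv`,
#'   `network_coupling` (7 x 5: thickness-factor1, thickness-factor2,
#'   thickness-age, area-factor1, area-factor2; network-average effect sizes
#'   on the local-SD scale), `network_cluster_fraction` (the contiguous
#'   fraction of each network's vertices that actually carries its effect,
#'   at amplitude coupling / fraction), `spatial_smoothness`
#'   (half-width of the 1-D vertex moving-average neighborhood),
#'   `sex_effects` (additive thickness shift in mm and multiplicative area
#'   scale for females), `seed`.
#' @seealso [simulate_cohort()]
#' @export
default_sim_config <- function(n_participants = 165L, n_vertices = 2000L,
                               seed = 1L) {
  sizes <- round(n_vertices * c(0.14, 0.15, 0.11, 0.11, 0.06, 0.16, 0.22))
  unlabeled <- n_vertices - sum(sizes)
  if (unlabeled < 0) {
    sizes[7] <- sizes[7] + unlabeled
    unlabeled <- 0L
  }
  tasks <- c("flanker", "trail_b", "spatial_wm", "n_back",
             "category_fluency", "face_scene", "spatial_reconstruction",
             "dot_comparison", "digit_symbol", "cvlt_recall", "story_recall")
  loadings <- matrix(c(
    0.59, 0.04,
    0.71, 0.19,
    0.62, 0.21,
    0.52, 0.14,
    0.27, 0.56,
    0.17, 0.58,
    0.13, 0.69,
    0.74, 0.09,
    0.69, 0.31,
    0.22, 0.74,
    0.04, 0.68), ncol = 2, byrow = TRUE,
    dimnames = list(tasks, c("executive_function", "episodic_memory")))
  rho <- 0.35
  # per-task residual SD so each indicator has approximately unit variance
  comm <- loadings[, 1]^2 + loadings[, 2]^2 + 2 * rho * loadings[, 1] * loadings[, 2]
  noise_sd <- sqrt(pmax(0.10, 1 - comm))
  networks <- c("visual", "somatomotor", "dorsal_attention", "salience",
                "limbic", "control", "default_mode")
  ## vertex-level effect sizes; calibrated so the emergent cohort-level
  ## correlations of global mean thickness with the abilities and age land
  ## near 0.25 / 0.26 / -0.32 (effects aggregate across a network's vertices,
  ## so cohort-level correlations exceed the vertex-level couplings)
  coupling <- matrix(c(
    # th_f1  th_f2 th_age ar_f1 ar_f2
    0.060, 0.050, 0.090, 0, 0,   # visual
    0.100, 0.090, 0.150, 0, 0,   # somatomotor
    0.060, 0.050, 0.090, 0, 0,   # dorsal attention
    0.125, 0.040, 0.150, 0, 0,   # salience
    0.060, 0.060, 0.090, 0, 0,   # limbic
    0.075, 0.050, 0.090, 0, 0,   # control
    0.100, 0.100, 0.150, 0, 0),  # default mode
    ncol = 5, byrow = TRUE,
    dimnames = list(networks,
                    c("thickness_factor1", "thickness_factor2",
                      "thickness_age", "area_factor1", "area_factor2")))
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_vertices = as.integer(n_vertices),
    network_sizes = stats::setNames(as.integer(sizes), networks),
    unlabeled_vertices = as.integer(unlabeled),
    age_mean = 69.5, age_sd = 6.58, age_range = c(60, 89),
    female_fraction = 105 / 165,
    latent_factor_correlation = rho,
    age_effect_per_factor = c(executive_function = -0.30,
                              episodic_memory = -0.36),
    task_loading_matrix = loadings,
    task_noise_sd = noise_sd,
    thickness_mean = 2.39, thickness_sd = 0.12, thickness_vertex_sd = 0.25,
    area_total_mean = 157614.2, area_total_sd = 15775.83, area_vertex_cv = 0.20,
    network_coupling = coupling,
    network_cluster_fraction = 0.4,
    spatial_smoothness = 5L,
    sex_effects = c(thickness_shift = 0.065, area_scale = 0.90),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("(config)", "is not a sim_config")
  if (cfg$n_participants < 2) stop_config("n_participants", "must be >= 2")
  if (cfg$n_vertices < 1) stop_config("n_vertices", "must be >= 1")
  if (length(cfg$network_sizes) != 7)
    stop_config("network_sizes", "must have 7 entries")
  if (sum(cfg$network_sizes) + cfg$unlabeled_vertices != cfg$n_vertices)
    stop_config("network_sizes", "must sum (with unlabeled) to n_vertices")
  if (any(cfg$network_sizes < 0) || cfg$unlabeled_vertices < 0)
    stop_config("network_sizes", "must be non-negative")
  for (f in c("age_sd", "thickness_sd", "thickness_vertex_sd",
              "area_total_sd", "area_vertex_cv"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) stop_config(f, "must be > 0")
  if (any(!is.finite(cfg$task_loading_matrix)))
    stop_config("task_loading_matrix", "must be finite")
  if (!identical(dim(cfg$task_loading_matrix), c(11L, 2L)))
    stop_config("task_loading_matrix", "must be 11 x 2")
  if (any(cfg$task_noise_sd < 0))
    stop_config("task_noise_sd", "must be >= 0")
  if (cfg$age_mean < cfg$age_range[1] || cfg$age_mean > cfg$age_range[2])
    stop_config("age_range", "must contain age_mean")
  if (abs(cfg$latent_factor_correlation) >= 1)
    stop_config("latent_factor_correlation", "must be in (-1, 1)")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    stop_config("female_fraction", "must be in [0, 1]")
  if (any(dim(cfg$network_coupling) != c(7L, 5L)))
    stop_config("network_coupling", "must be 7 x 5")
  if (cfg$spatial_smoothness < 0)
    stop_config("spatial_smoothness", "must be >= 0")
  if (cfg$network_cluster_fraction <= 0 || cfg$network_cluster_fraction > 1)
    stop_config("network_cluster_fraction", "must be in (0, 1]")
  invisible(cfg)
}

## 1-D moving-average smoothing across vertex index within one network
## segment, rescaled so each smoothed column keeps unit variance.
smooth_segment <- function(E, half_width) {
  V <- ncol(E)
  if (half_width == 0 || V == 1) return(E)
  out <- E
  for (v in seq_len(V)) {
    win <- max(1, v - half_width):min(V, v + half_width)
    out[, v] <- rowMeans(E[, win, drop = FALSE]) * sqrt(length(win))
  }
  out
}

#' Simulate a synthetic cohort with network-structured morphometry
#'
#' Generates a cohort under the generative model described in the methods
#' vignette: ages from a truncated normal whose post-truncation moments match
#' the configured mean/SD; two latent cognitive factors with a configured
#' mutual correlation, each negatively correlated with age; 11 task scores as
#' noisy linear images of the factors; and, per morphometric measure, vertex
#' values composed of a cohort baseline, a sex effect, a participant-level
#' global component, network-specific linear terms in the factors and
#' (negated, standardized) age, and spatially smoothed vertex noise
#' (moving average over the 1-D vertex neighborhood within each network).
#' All effect sizes are on a correlation-like scale relative to the local
#' vertex SD.
#'
#' @param config a `sim_config`, e.g. from [default_sim_config()].
#' @return An object of class `synthetic_cohort` with components
#'   `participants` (data.frame: id, age, sex with 1 = female, task_1..task_11
#'    named by task), `thickness` and `area` ([surface_dataset] objects),
#'   `latent_truth` (n x 2 factor scores), `planted_effects` (the
#'   `network_coupling` matrix used), and `config`.
#' @examples
#' cfg <- default_sim_config(n_participants = 40, n_vertices = 100, seed = 7)
#' coh <- simulate_cohort(cfg)
#' coh
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  V <- cfg$n_vertices

  ## --- demographics ------------------------------------------------------
  n_f <- round(n * cfg$female_fraction)
  sex <- sample(c(rep(1L, n_f), rep(0L, n - n_f)))
  tn <- truncnorm_match(cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  age <- rtruncnorm(n, tn["mu"], tn["sigma"], cfg$age_range[1], cfg$age_range[2])
  zage <- (age - cfg$age_mean) / cfg$age_sd

  ## --- latent factors ----------------------------------------------------
  r <- cfg$age_effect_per_factor
  rho <- cfg$latent_factor_correlation
  rho_e <- (rho - r[1] * r[2]) / sqrt((1 - r[1]^2) * (1 - r[2]^2))
  if (abs(rho_e) > 1)
    stop_config("latent_factor_correlation",
                "is unattainable given age_effect_per_factor")
  e1 <- stats::rnorm(n)
  e2 <- rho_e * e1 + sqrt(1 - rho_e^2) * stats::rnorm(n)
  f1 <- r[1] * zage + sqrt(1 - r[1]^2) * e1
  f2 <- r[2] * zage + sqrt(1 - r[2]^2) * e2
  F <- cbind(executive_function = f1, episodic_memory = f2)

  ## --- task battery (all tasks generated higher-is-better) ---------------
  L <- cfg$task_loading_matrix
  tasks <- F %*% t(L) +
    matrix(stats::rnorm(n * 11), n, 11) %*% diag(cfg$task_noise_sd)
  colnames(tasks) <- rownames(L)

  ## --- vertex labels: contiguous network blocks, unlabeled last ----------
  labels <- rep.int(c(1:7, 0L), times = c(cfg$network_sizes, cfg$unlabeled_vertices))
  vertex_ids <- sprintf("v%05d", seq_len(V))

  ## covariance bookkeeping for signal variance:
  ## signals are built from (f1, f2, -zage) with unit variances and
  ## cov(f1,f2)=rho, cov(f_j, -zage) = -r_j
  S3cov <- matrix(c(1, rho, -r[1],
                    rho, 1, -r[2],
                    -r[1], -r[2], 1), 3, 3)
  neg_age <- -zage

  make_measure <- function(which) {
    cp <- cfg$network_coupling
    if (which == "thickness") {
      C <- cbind(cp[, "thickness_factor1"], cp[, "thickness_factor2"],
                 cp[, "thickness_age"])
    } else {
      C <- cbind(cp[, "area_factor1"], cp[, "area_factor2"], 0)
    }
    ## effects are concentrated in a contiguous cluster covering a fraction
    ## of each network's vertices, at amplitude coupling / fraction, so the
    ## network-average coupling equals the configured value while individual
    ## cluster vertices carry a selectable signal
    frac <- cfg$network_cluster_fraction
    Ca <- C / frac
    sig_var <- vapply(1:7, function(k) drop(Ca[k, ] %*% S3cov %*% Ca[k, ]),
                      numeric(1))
    noise_sd <- sqrt(pmax(0.05, 1 - sig_var))
    E <- matrix(stats::rnorm(n * V), n, V)
    std <- matrix(0, n, V)   # standardized vertex deviations
    for (k in 0:7) {
      idx <- which(labels == k)
      if (!length(idx)) next
      Ek <- smooth_segment(E[, idx, drop = FALSE], cfg$spatial_smoothness)
      if (k == 0) {
        std[, idx] <- Ek
      } else {
        n_cl <- ceiling(frac * length(idx))
        cl <- idx[seq_len(n_cl)]
        rest <- idx[-seq_len(n_cl)]
        signal <- drop(cbind(f1, f2, neg_age) %*% Ca[k, ])
        std[, cl] <- signal + noise_sd[k] * Ek[, seq_len(n_cl), drop = FALSE]
        if (length(rest))
          std[, rest] <- Ek[, -seq_len(n_cl), drop = FALSE]
      }
    }
    ## mean-signal variance across the cortex (drives the global component)
    cbar <- colSums(C * as.numeric(cfg$network_sizes)) / V
    var_mean_signal <- drop(cbar %*% S3cov %*% cbar)
    list(std = std, var_mean_signal = var_mean_signal)
  }

  p_f <- mean(sex)

  ## --- thickness ---------------------------------------------------------
  th <- make_measure("thickness")
  tvs <- cfg$thickness_vertex_sd
  shift <- cfg$sex_effects[["thickness_shift"]]
  var_sex <- p_f * (1 - p_f) * shift^2
  g_sd <- sqrt(max(0, cfg$thickness_sd^2 - tvs^2 * th$var_mean_signal - var_sex))
  g <- stats::rnorm(n, 0, g_sd)
  baseline <- cfg$thickness_mean - p_f * shift
  thickness <- baseline + shift * sex + g + tvs * th$std
  rownames(thickness) <- NULL

  ## --- surface area ------------------------------------------------------
  ar <- make_measure("area")
  scale_f <- cfg$sex_effects[["area_scale"]]
  mean_s <- 1 - p_f * (1 - scale_f)
  cv_target <- cfg$area_total_sd / cfg$area_total_mean
  var_sex_a <- p_f * (1 - p_f) * (1 - scale_f)^2
  cv_a <- cfg$area_vertex_cv
  g_a_sd <- sqrt(max(1e-8, cv_target^2 - var_sex_a -
                       cv_a^2 * ar$var_mean_signal)) / mean_s
  g_a <- stats::rnorm(n, 0, g_a_sd)
  s_i <- ifelse(sex == 1, scale_f, 1)
  base_a <- cfg$area_total_mean / (V * mean_s)
  area <- base_a * s_i * (1 + g_a + cv_a * ar$std)

  ids <- sprintf("p%03d", seq_len(n))
  participants <- data.frame(id = ids, age = age, sex = sex,
                             tasks, check.names = FALSE,
                             stringsAsFactors = FALSE)
  cohort <- list(
    participants = participants,
    thickness = surface_dataset(thickness, labels, measure = "thickness",
                                participant_ids = ids, vertex_ids = vertex_ids),
    area = surface_dataset(area, labels, measure = "area",
                           participant_ids = ids, vertex_ids = vertex_ids),
    latent_truth = F,
    planted_effects = cfg$network_coupling,
    config = cfg)
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d (female fraction %.3f)\n",
              x$n_participants, x$female_fraction))
  cat(sprintf("  vertices: %d (%d labeled across 7 networks, %d unlabeled)\n",
              x$n_vertices, sum(x$network_sizes), x$unlabeled_vertices))
  cat(sprintf("  age: mean %.1f, SD %.2f, range [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2]))
  cat(sprintf("  thickness: %.2f mm (global SD %.2f); total area: %.0f mm^2 (SD %.0f)\n",
              x$thickness_mean, x$thickness_sd,
              x$area_total_mean, x$area_total_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort\n")
  cat(sprintf("  %d participants, %d vertices (thickness + area)\n",
              nrow(x$participants), ncol(x$thickness$values)))
  cat(sprintf("  age: mean %.1f (SD %.2f); %d female\n",
              mean(x$participants$age), stats::sd(x$participants$age),
              sum(x$participants$sex)))
  cat(sprintf("  global mean thickness: %.3f mm; mean total area: %.0f mm^2\n",
              mean(rowMeans(x$thickness$values)),
              mean(rowSums(x$area$values))))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `participants.csv` (id, age, sex, 11 task columns),
#' `thickness.csv` / `area.csv` (rows = participants, first column `id`,
#' remaining columns named by vertex id; 17 significant digits so a
#' write-then-read round trip is bit-exact), `labels.csv`
#' (vertex_id, network_id) and `config.yaml`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             thickness = file.path(dir, "thickness.csv"),
             area = file.path(dir, "area.csv"),
             labels = file.path(dir, "labels.csv"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  write_surface_dataset(cohort$thickness, paths["thickness"], paths["labels"])
  write_surface_dataset(cohort$area, paths["area"], labels_path = NULL)
  cfg <- cohort$config
  cfg$task_loading_matrix <- apply(cfg$task_loading_matrix, 1, as.numeric,
                                   simplify = FALSE)
  cfg$network_coupling <- apply(cohort$config$network_coupling, 1, as.numeric,
                                simplify = FALSE)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
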