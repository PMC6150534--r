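#' Default end-to-end study configuration
#'
#' Settings for [run_study()] on a simulated cohort, scaled for interactive
#' use (10 CV iterations, B = 200 bootstrap resamples, 500 permutations,
#' 2,000 vertices). Full-scale settings (100 iterations, B = 5000,
#' 100,000 permutations) are reached by editing the returned list or the
#' corresponding YAML.
#'
#' @param seed master seed propagated to every stage.
#' @return A nested list understood by [run_study()].
#' @export
default_study_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_participants = 165L, n_vertices = 2000L),
    measures = c("thickness", "area"),
    networks = c("whole", 1:7),
    abilities = c("executive_function", "episodic_memory"),
    cv = list(k = 5L, n_iterations = 10L,
              alphas = c(0.05, 0.01, 0.001, 0.0005, 0.0001)),
    bootstrap = list(B = 200L),
    vertexwise = list(enabled = TRUE, B = 200L, n_perm = 500L,
                      thresholds = c(1.96, 2.58, 3.3, 3.9)))
}

global_summary <- function(ds) {
  keep <- ds$labels >= 1L
  if (ds$measure == "thickness") rowMeans(ds$values[, keep, drop = FALSE])
  else rowSums(ds$values[, keep, drop = FALSE])
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full network-guided morphometry study on a configuration
#'
#' Executes the pipeline in methods order: simulate (or load) the cohort,
#' build the two cognitive composites, then for every measure x network x
#' ability fit the repeated cross-validated predictive model and bootstrap
#' (a) the sex-adjusted partial correlation of the averaged predictions with
#' the ability, (b) the same after additionally adjusting for the global
#' summary of the measure (mean thickness / total area), (c) the
#' sex-adjusted correlation of predictions with age, and (d) the
#' difference-of-coefficients mediation of the age-ability relationship by
#' the predictions. Optionally computes vertex-wise BSR maps with the
#' permutation network-enrichment test per measure x ability. All tables are
#' written as CSV/JSON under `out_dir` together with a manifest (config,
#' seed, file inventory with MD5 checksums).
#'
#' @param config a list as from [default_study_config()], or the path to a
#'   YAML file with the same structure.
#' @param out_dir output directory.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_study <- function(config = default_study_config(), out_dir = tempfile("study")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  files <- character(0)
  stage <- "simulate"
  result <- tryCatch({
    ## --- cohort ---------------------------------------------------------
    sim <- config$simulate
    cfg <- default_sim_config(n_participants = sim$n_participants %||% 165L,
                              n_vertices = sim$n_vertices %||% 2000L,
                              seed = seed)
    cohort <- simulate_cohort(cfg)
    stage_log(stage, "n=%d, vertices=%d", cfg$n_participants, cfg$n_vertices)

    stage <- "composites"
    comp <- cohort_composites(cohort$participants)
    f <- file.path(out_dir, "composites.csv")
    utils::write.csv(comp$composites, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "component_loadings.csv")
    utils::write.csv(data.frame(task = rownames(comp$solution$loadings),
                                comp$solution$loadings,
                                assignment = comp$solution$assignment),
                     f, row.names = FALSE)
    files <- c(files, f)
    stage_log(stage, "variance explained %.2f / %.2f",
              comp$solution$variance_explained[1],
              comp$solution$variance_explained[2])

    sex <- cohort$participants$sex
    age <- cohort$participants$age
    B <- as.integer(config$bootstrap$B %||% 200L)
    inference_rows <- list()

    stage <- "predict"
    for (measure in config$measures) {
      ds_full <- cohort[[measure]]
      gsum <- global_summary(ds_full)
      for (net in config$networks) {
        ds <- subset_network(ds_full, net)
        for (ability in config$abilities) {
          y <- comp$composites[[ability]]
          plan <- cv_plan(k = config$cv$k %||% 5L,
                          n_iterations = config$cv$n_iterations %||% 10L,
                          alphas = config$cv$alphas %||%
                            c(0.05, 0.01, 0.001, 0.0005, 0.0001),
                          seed = seed)
          fit <- repeated_cv_predict(ds, y, plan)
          tag <- sprintf("%s_net%s_%s", measure, net, ability)
          f <- file.path(out_dir, sprintf("predictions_%s.csv", tag))
          utils::write.csv(fit$predictions, f, row.names = FALSE)
          files <- c(files, f)
          f <- file.path(out_dir, sprintf("diagnostics_%s.csv", tag))
          utils::write.csv(fit$diagnostics, f, row.names = FALSE)
          files <- c(files, f)

          pred <- fit$predictions$average
          ok <- !is.na(pred)
          d <- data.frame(pred = pred, y = y, age = age, sex = sex,
                          gsum = gsum)[ok, ]
          boots <- list(
            r_ability_sex = bootstrap_estimate(function(dd)
              partial_correlation(dd$pred, dd$y, dd$sex), d, B, seed),
            r_ability_sex_global = bootstrap_estimate(function(dd)
              partial_correlation(dd$pred, dd$y, cbind(dd$sex, dd$gsum)),
              d, B, seed),
            r_age_sex = bootstrap_estimate(function(dd)
              partial_correlation(dd$pred, -dd$age, dd$sex), d, B, seed))
          med <- mediation_effect(d$age, d$pred, d$y, covariates = d["sex"],
                                  B = B, seed = seed)
          inference_rows[[tag]] <- list(
            measure = measure, network = as.character(net), ability = ability,
            r_ability_sex = boots$r_ability_sex$point,
            r_ability_sex_ci = c(boots$r_ability_sex$ci_low,
                                 boots$r_ability_sex$ci_high),
            r_ability_sex_p = boots$r_ability_sex$p_boot,
            r_ability_sex_global = boots$r_ability_sex_global$point,
            r_ability_sex_global_p = boots$r_ability_sex_global$p_boot,
            r_age_sex = boots$r_age_sex$point,
            mediation = med$mediation, mediation_total = med$total,
            mediation_direct = med$direct,
            mediation_ci = c(med$boot$ci_low, med$boot$ci_high),
            mediation_p = med$boot$p_boot)
          stage_log(stage, "%s: r=%.3f mediation=%.3f", tag,
                    boots$r_ability_sex$point, med$mediation)
        }
      }
    }
    f <- file.path(out_dir, "inference.json")
    jsonlite::write_json(inference_rows, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)

    if (isTRUE(config$vertexwise$enabled %||% TRUE)) {
      stage <- "vertexwise"
      vw <- config$vertexwise
      for (measure in config$measures) {
        ds_full <- cohort[[measure]]
        for (ability in config$abilities) {
          y <- comp$composites[[ability]]
          map <- vertex_bsr(ds_full, y, age = age, covariates = cbind(sex = sex),
                            B = as.integer(vw$B %||% 200L), seed = seed,
                            kind = "correlation")
          tag <- sprintf("%s_%s", measure, ability)
          f <- file.path(out_dir, sprintf("bsr_%s.csv", tag))
          utils::write.csv(data.frame(vertex_id = ds_full$vertex_ids,
                                      network_id = ds_full$labels,
                                      bsr = map$bsr), f, row.names = FALSE)
          files <- c(files, f)
          pt <- permutation_network_test(map,
                                         thresholds = vw$thresholds %||%
                                           c(1.96, 2.58, 3.3, 3.9),
                                         n_perm = as.integer(vw$n_perm %||% 500L),
                                         seed = seed)
          f <- file.path(out_dir, sprintf("network_counts_%s.csv", tag))
          utils::write.csv(data.frame(network = rep(1:7, length(pt$thresholds)),
                                      threshold = rep(pt$thresholds, each = 7),
                                      count = as.vector(pt$empirical),
                                      null_mean = as.vector(pt$null_mean),
                                      p_ge = as.vector(pt$p_ge),
                                      p_le = as.vector(pt$p_le)),
                           f, row.names = FALSE)
          files <- c(files, f)
          stage_log(stage, "%s: %d suprathreshold at 1.96", tag, pt$total[1])
        }
      }
    }
    list(files = files)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (outputs so far: %s)",
                 stage, conditionMessage(e),
                 paste(basename(files), collapse = ", ")), call. = FALSE)
  })

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("netmorph")),
                   files = lapply(result$files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
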