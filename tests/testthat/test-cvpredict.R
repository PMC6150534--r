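test_that("univariate selection equals the brute-force per-vertex t-test", {
  set.seed(10)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rnorm(20)
  for (alpha in c(0.5, 0.05, 0.01)) {
    mask <- univariate_select(X, y, alpha)
    oracle <- vapply(seq_len(50), function(v) {
      summary(lm(y ~ X[, v]))$coefficients[2, 4] <= alpha
    }, logical(1))
    expect_identical(mask, oracle)
  }
  # a vertex equal to y is selected at every alpha
  X[, 1] <- y
  expect_true(univariate_select(X, y, 1e-10)[1])
  expect_error(univariate_select(X[1:3, ], y[1:3], 0.05), "3 observations")
})

test_that("selection under a permuted target has the nominal type-I rate", {
  set.seed(11)
  X <- matrix(rnorm(40 * 200), 40, 200)
  y <- rnorm(40)
  counts <- vapply(1:50, function(i) sum(univariate_select(X, sample(y), 0.05)),
                   numeric(1))
  expect_lt(abs(mean(counts) - 10), 2)  # 200 * 0.05 = 10 expected
})

test_that("the average model reduces to simple regression and matches normal equations", {
  set.seed(12)
  X <- matrix(rnorm(10 * 6), 10, 6)
  mask <- c(1, 3, 5)
  y <- rowMeans(X[, mask])
  mod <- fit_average_model(X, mask, y)
  expect_equal(mod$slope, 1, tolerance = 1e-12)
  expect_equal(mod$intercept, 0, tolerance = 1e-12)
  expect_equal(predict(mod, X), y, tolerance = 1e-12)

  y2 <- rnorm(10)
  mod1 <- fit_average_model(X, 2L, y2)
  lm1 <- lm(y2 ~ X[, 2])
  expect_equal(unname(coef(mod1)), unname(coef(lm1)), tolerance = 1e-12)

  # closed-form least-squares oracle on the averaged predictor
  m <- rowMeans(X[, mask])
  slope_oracle <- cov(m, y2) / var(m)
  mod2 <- fit_average_model(X, mask, y2)
  expect_equal(mod2$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(mod2$intercept, mean(y2) - slope_oracle * mean(m),
               tolerance = 1e-12)
  expect_error(fit_average_model(X, integer(0), y2), "empty")
})

test_that("noise-free planted signal in one network is recovered", {
  set.seed(20)
  n <- 100
  y <- rnorm(n)
  # vertices are exact affine images of the ability, with distinct slopes
  slopes <- runif(30, 0.5, 2)
  X <- 2.4 + outer(y, slopes)
  ds <- surface_dataset(X, rep(7L, 30))
  fit <- repeated_cv_predict(ds, y, cv_plan(n_iterations = 5, seed = 1))
  expect_gt(cor(fit$predictions$average, y), 0.95)
})

test_that("cross-validation never leaks test rows into fitting", {
  # fold primitive: fit on train, predict test; altering test rows leaves the
  # model untouched and changes only the altered participants' predictions
  set.seed(21)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  train <- 1:30; test <- 31:40
  sc <- robust_scale(X[train, ])
  mask <- which(univariate_select(sc$scaled, y[train], 0.5))
  mod <- fit_average_model(sc$scaled, mask, y[train], scale_params = sc$params)
  p1 <- predict(mod, X[test, ])
  X2 <- X; X2[test, ] <- 99
  sc2 <- robust_scale(X2[train, ])
  mask2 <- which(univariate_select(sc2$scaled, y[train], 0.5))
  mod2 <- fit_average_model(sc2$scaled, mask2, y[train], scale_params = sc2$params)
  expect_identical(coef(mod2), coef(mod))
  expect_identical(mask2, mask)
  expect_false(any(predict(mod2, X2[test, ]) == p1))
})

test_that("each participant is tested exactly once per iteration", {
  coh <- small_cohort(n = 40, V = 60, seed = 22)
  y <- coh$latent_truth[, 1]
  fit <- repeated_cv_predict(coh$thickness, y,
                             cv_plan(alphas = c(1, 0.05), n_iterations = 4,
                                     seed = 3))
  # at alpha = 1 a prediction is produced in every fold, so the count per
  # participant equals the iteration count exactly; at any alpha it cannot
  # exceed it
  expect_true(all(fit$n_predictions[, "alpha_1"] == 4))
  expect_true(all(fit$n_predictions <= 4))
})

test_that("alphas = 1 reduces to cross-validated regression on the mean vertex", {
  coh <- small_cohort(n = 50, V = 40, seed = 23)
  y <- coh$latent_truth[, 1]
  plan <- cv_plan(alphas = 1, n_iterations = 2, seed = 5)
  fit <- repeated_cv_predict(coh$thickness, y, plan)
  expect_true(all(fit$fold_models$n_selected == 40))
  expect_true(all(fit$n_predictions == 2))
  # oracle: rebuild one fold by hand
  set.seed(netmorph:::derive_seed(5L, 1L))
  fold_of <- sample(rep_len(1:5, 50))
  test <- which(fold_of == 1); train <- which(fold_of != 1)
  sc <- robust_scale(coh$thickness$values[train, ])
  mod <- fit_average_model(sc$scaled, seq_len(40), y[train],
                           scale_params = sc$params)
  manual <- predict(mod, coh$thickness$values[test, ])
  # iteration 1 contributes these exact predictions for fold-1 participants
  f1only <- repeated_cv_predict(coh$thickness, y,
                                cv_plan(alphas = 1, n_iterations = 1, seed = 5))
  expect_equal(f1only$predictions$alpha_1[test], manual, tolerance = 1e-12)
})

test_that("runs are deterministic and earlier iterations are stable", {
  coh <- small_cohort(n = 40, V = 50, seed = 24)
  y <- coh$latent_truth[, 1]
  a <- repeated_cv_predict(coh$thickness, y, cv_plan(n_iterations = 3, seed = 7))
  b <- repeated_cv_predict(coh$thickness, y, cv_plan(n_iterations = 3, seed = 7))
  expect_identical(a$predictions, b$predictions)
  c5 <- repeated_cv_predict(coh$thickness, y, cv_plan(n_iterations = 5, seed = 7))
  expect_identical(subset(c5$fold_models, iteration <= 3), a$fold_models)
})

test_that("empty-selection folds are recorded, not fatal", {
  set.seed(25)
  ds <- noise_surface(n = 30, V = 40, seed = 26)
  y <- rnorm(30)
  plan <- cv_plan(alphas = c(0.05, 1e-8), n_iterations = 3, seed = 2)
  fit <- repeated_cv_predict(ds, y, plan)
  dg <- fit$diagnostics
  expect_gt(dg$frac_zero_selection[dg$alpha == 1e-8], 0.5)
  # across-alpha average uses only available alpha predictions
  p <- fit$predictions
  has_strict <- !is.na(p[["alpha_1e-08"]])
  expect_equal(p$average[!has_strict], p$alpha_0.05[!has_strict])
})

test_that("missing ability scores are excluded with a warning", {
  coh <- small_cohort(n = 30, V = 40, seed = 27)
  y <- coh$latent_truth[, 1]
  y[c(3, 9)] <- NA
  expect_warning(
    fit <- repeated_cv_predict(coh$thickness, y, cv_plan(n_iterations = 1, seed = 1)),
    "excluding 2")
  expect_equal(nrow(fit$predictions), 28)
})

test_that("predictions under a shuffled target are null-centered", {
  r <- vapply(1:20, function(i) {
    coh <- small_cohort(n = 60, V = 80, seed = 500 + i)
    y <- coh$latent_truth[, 1]
    set.seed(i); ys <- sample(y)
    fit <- repeated_cv_predict(coh$thickness, ys,
                               cv_plan(n_iterations = 3, seed = i))
    ok <- !is.na(fit$predictions$average)
    cor(fit$predictions$average[ok], ys[ok])
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})
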