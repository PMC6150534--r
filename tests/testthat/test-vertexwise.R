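test_that("a vertex identical to the ability is flagged undefined", {
  set.seed(40)
  n <- 30
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 5), n, 5))
  ds <- surface_dataset(X, rep(1, 6))
  map <- vertex_bsr(ds, y, B = 100, seed = 1)
  expect_true(map$undefined[1])   # all bootstrap draws equal 1, SD = 0
  expect_true(is.na(map$bsr[1]))
  expect_false(any(map$undefined[-1]))
})

test_that("bootstrapped vertex correlations agree with partial_correlation per draw", {
  set.seed(41)
  n <- 25
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  r <- netmorph:::vertex_partial_cor(X, y, cbind(sex))
  oracle <- vapply(1:8, function(v) partial_correlation(X[, v], y, sex),
                   numeric(1))
  expect_equal(r, oracle, tolerance = 1e-12)
})

test_that("vertex mediation statistic equals the scalar mediation computation", {
  set.seed(42)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6)
  age <- runif(n, 60, 89)
  y <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  vm <- netmorph:::vertex_mediation(X, age, y, cbind(sex))
  for (v in 1:6) {
    d <- data.frame(age = age, mediator = X[, v], outcome = y, sex = sex)
    expect_equal(vm[v], netmorph:::mediation_point(d)[["mediation"]],
                 tolerance = 1e-12)
  }
})

test_that("BSR null calibration: ~5% of pure-noise vertices exceed 1.96", {
  # iid vertices: a cohort-level shared component (e.g. global thickness)
  # would make vertex nulls dependent, which is exactly what this fixture
  # excludes
  ds <- noise_surface(n = 100, V = 2000, seed = 43)
  set.seed(44)
  y <- rnorm(100)
  map <- vertex_bsr(ds, y, B = 200, seed = 45)
  frac <- mean(abs(map$bsr) >= 1.96, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("planted coupling elevates the planted network's BSR", {
  coh <- small_cohort(n = 165, V = 300, seed = 46, mutate = function(cfg) {
    cfg <- zero_coupling(cfg)
    cfg$network_coupling["default_mode", "thickness_factor1"] <- 0.4
    cfg
  })
  y <- coh$latent_truth[, 1]
  map <- vertex_bsr(coh$thickness, y,
                    covariates = cbind(coh$participants$sex),
                    B = 200, seed = 47)
  expect_gt(median(map$bsr[map$labels == 7]),
            median(map$bsr[map$labels %in% 1:6]))
})

test_that("suprathreshold counting matches a brute-force loop and is monotone", {
  set.seed(48)
  bsr <- rnorm(100, sd = 2)
  labels <- sample(0:7, 100, replace = TRUE)
  th <- c(1, 2, 3)
  nc <- count_suprathreshold(bsr, labels, thresholds = th, sign = "positive")
  for (t in seq_along(th)) for (k in 1:7) {
    manual <- 0L
    for (v in 1:100)
      if (labels[v] == k && !is.na(bsr[v]) && bsr[v] >= th[t])
        manual <- manual + 1L
    expect_identical(nc$counts[k, t], manual)
  }
  # counts are non-increasing in the threshold and sum to the labeled total
  expect_true(all(apply(nc$counts, 1, diff) <= 0))
  expect_equal(unname(nc$total), unname(colSums(nc$counts)))

  abs_nc <- count_suprathreshold(bsr, labels, thresholds = th, sign = "absolute")
  expect_true(all(abs_nc$counts >= nc$counts))
  zero <- count_suprathreshold(rep(0, 100), labels, thresholds = th)
  expect_true(all(zero$counts == 0))
})

test_that("permutation null mean matches the hypergeometric expectation", {
  set.seed(49)
  V <- 1400
  labels <- rep(1:7, each = 200)
  bsr <- rnorm(V)
  pt <- permutation_network_test(bsr, labels, thresholds = c(1, 2),
                                 n_perm = 2000, seed = 50)
  for (t in 1:2) {
    expected <- 200 / V * pt$total[t]   # network share of the whole-map count
    mc_se <- sqrt(pt$total[t] * (200 / V) * (1 - 200 / V) / 2000) * 3 + 0.5
    expect_true(all(abs(pt$null_mean[, t] - expected) < 3 * mc_se))
  }
})

test_that("network counts are conserved in every permutation", {
  set.seed(51)
  labels <- sample(1:7, 400, replace = TRUE)
  bsr <- rnorm(400)
  pt <- permutation_network_test(bsr, labels, thresholds = c(0.5, 1.5),
                                 n_perm = 300, seed = 52)
  for (t in 1:2)
    expect_true(all(rowSums(pt$null[, , t]) == pt$total[t]))
})

test_that("a single network containing all vertices gives p = 1", {
  set.seed(53)
  bsr <- rnorm(50, mean = 1)
  pt <- permutation_network_test(bsr, rep(3, 50), thresholds = 1,
                                 n_perm = 200, seed = 54)
  expect_equal(pt$p_ge[3, 1], 1)
  expect_equal(pt$p_le[3, 1], 1)
})

test_that("Monte-Carlo p converges to the exact permutation p on a tiny map", {
  # 6 vertices, two networks of 3; 2 suprathreshold vertices
  bsr <- c(3, 3, 0, 0, 0, 0)
  labels <- c(1, 1, 1, 2, 2, 2)
  # exact enumeration over all 6! label orderings
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  counts <- vapply(all_perms(1:6), function(p) {
    pl <- labels[p]
    sum(pl[bsr >= 1.96] == 1)
  }, numeric(1))
  empirical <- sum(labels[bsr >= 1.96] == 1)  # = 2
  p_exact <- mean(counts >= empirical)
  pt <- permutation_network_test(bsr, labels, thresholds = 1.96,
                                 n_perm = 4000, seed = 55)
  expect_lt(abs(pt$p_ge[1, 1] - p_exact), 2 / sqrt(4000))
})

test_that("permuting values and permuting labels give indistinguishable p's", {
  set.seed(56)
  V <- 600
  labels <- sample(1:7, V, replace = TRUE)
  bsr <- rnorm(V) + (labels == 4) * 0.3
  pt <- permutation_network_test(bsr, labels, thresholds = 1.5,
                                 n_perm = 2000, seed = 57)
  # independent implementation permuting the BSR values instead
  supra <- function(v) v >= 1.5
  emp <- tabulate(labels[supra(bsr)], 7)
  set.seed(58)
  null4 <- replicate(2000, {
    vp <- bsr[sample.int(V)]
    sum(labels[supra(vp)] == 4)
  })
  p_vals <- mean(null4 >= emp[4])
  se <- sqrt(p_vals * (1 - p_vals) / 2000)
  expect_lt(abs(pt$p_ge[4, 1] - p_vals), 4 * se + 0.01)
})

test_that("undefined and unlabeled vertices are excluded from counts and nulls", {
  bsr <- c(NA, 5, 5, 5, 0, 0)
  labels <- c(1, 0, 1, 2, 1, 2)
  nc <- count_suprathreshold(bsr, labels, thresholds = 1.96)
  expect_equal(unname(nc$counts[1:2, 1]), c(1L, 1L))  # NA and label-0 dropped
  expect_equal(unname(nc$total[1]), 2L)
})
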