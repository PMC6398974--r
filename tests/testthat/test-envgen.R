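test_that("environment generator is a pure function of its seed", {
  p <- env_ensemble_params(15, seed = 4)
  e1 <- random_environment(p)
  e2 <- random_environment(p)
  expect_identical(e1$gamma, e2$gamma)
  e3 <- random_environment(env_ensemble_params(15, seed = 5))
  expect_false(identical(e1$gamma, e3$gamma))
  # the session RNG stream is not disturbed
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(random_environment(p)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("generated covariances are valid and beta tunes correlations", {
  for (seed in 1:5) {
    env <- random_environment(env_ensemble_params(20, beta = 8, seed = seed))
    ev <- eigen(env$gamma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
    expect_true(all(diag(env$gamma) > 0))
  }
  # larger beta -> weaker off-diagonal correlations (ensemble mean |cor|)
  mean_abs_cor <- function(beta) {
    mean(vapply(1:8, function(s) {
      g <- random_environment(env_ensemble_params(30, beta = beta,
                                                  seed = 100 + s))$gamma
      C <- stats::cov2cor(g)
      mean(abs(C[upper.tri(C)]))
    }, numeric(1)))
  }
  expect_gt(mean_abs_cor(0.5), mean_abs_cor(16))
})

test_that("variances follow the configured lognormal law", {
  # pooled log-variances across draws at the fly odorant panel size
  logs <- unlist(lapply(1:200, function(s) {
    log(diag(random_environment(env_ensemble_params(
      110, logvar_mu = 0.3, logvar_sigma = 0.8, seed = 5000 + s))$gamma))
  }))
  ks <- suppressWarnings(stats::ks.test(logs, "pnorm", mean = 0.3, sd = 0.8))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-variance perturbation is a rank-one diagonal update", {
  env <- odor_environment(diag(2))
  expect_identical(perturb_single_variance(env, 1, 0)$gamma, env$gamma)
  expect_equal(unname(perturb_single_variance(env, 1, 3)$gamma),
               diag(c(4, 1)))
  expect_error(perturb_single_variance(env, 1, -1), ">= 0")
  expect_error(perturb_single_variance(env, 5, 1), "range")
  # min eigenvalue can only grow under a PSD rank-one update
  set.seed(33)
  g <- random_psd(6)
  e0 <- min(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
  g1 <- perturb_single_variance(odor_environment(g), 3, 2.5)$gamma
  e1 <- min(eigen(g1, symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(e1, e0 - 1e-12)
})

test_that("variance-set perturbation touches only the chosen diagonal", {
  set.seed(35)
  env <- random_environment(env_ensemble_params(12, seed = 1))
  expect_identical(perturb_variance_set(env, indices = integer(0))$gamma,
                   env$gamma)
  g1 <- perturb_variance_set(env, indices = c(1, 2), added_variance = 5)$gamma
  g2 <- perturb_variance_set(env, indices = c(4, 7), added_variance = 5)$gamma
  d <- g1 - g2
  off <- d; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  expect_identical(unname(which(diag(d) != 0)), c(1L, 2L, 4L, 7L))
  # default magnitude dominates the base variance scale
  gd <- perturb_variance_set(env, indices = 3)$gamma
  expect_gt(gd[3, 3] / stats::median(diag(env$gamma)), 60)
})

test_that("non-overlapping pairs have disjoint high-variance odorants", {
  p <- env_ensemble_params(30, seed = 6)
  pr <- nonoverlapping_pair(p, split_seed = 2)
  pr2 <- nonoverlapping_pair(p, split_seed = 2)
  expect_identical(pr$env1$gamma, pr2$env1$gamma)
  hi1 <- diag(pr$env1$gamma) > 10 * pr$floor_variance
  hi2 <- diag(pr$env2$gamma) > 10 * pr$floor_variance
  expect_false(any(hi1 & hi2))
  expect_error(nonoverlapping_pair(env_ensemble_params(1, seed = 1)),
               "at least 2")
})

test_that("covariance changes are narrower for non-overlapping pairs", {
  iqr_of <- function(nonoverlap) {
    p <- env_ensemble_params(40, seed = 7)
    pairs <- environment_pairs(p, 100, nonoverlapping = nonoverlap)
    d <- unlist(lapply(pairs, function(pp) {
      pp[[2]]$gamma - pp[[1]]$gamma
    }))
    stats::IQR(d)
  }
  expect_lt(iqr_of(TRUE), iqr_of(FALSE))
})

test_that("square-root jitter preserves PSD and scales linearly", {
  set.seed(37)
  env <- odor_environment(random_psd(8))
  expect_lt(max(abs(jitter_sqrt(env, 0, seed = 1)$gamma - env$gamma)), 1e-10)
  eps <- 10^seq(-3, -1, length.out = 6)
  dist <- vapply(eps, function(e) {
    g <- jitter_sqrt(env, e, seed = 11)$gamma
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
    sqrt(sum((g - env$gamma)^2))
  }, numeric(1))
  fit <- stats::lm(dist ~ eps)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("sensing generator controls the per-row strong fraction", {
  sm <- random_sensing_matrix(24, 110, 0.2, seed = 3)
  mask <- attr(sm, "strong_mask")
  expect_true(all(rowSums(mask) == 22))
  expect_true(all(abs(rowMeans(mask) - 0.2) <= 1 / 110))
  expect_true(all(attr(random_sensing_matrix(4, 10, 1, seed = 1),
                       "strong_mask")))
  expect_error(random_sensing_matrix(4, 10, 0.01, seed = 1), "larger N")
  expect_identical(random_sensing_matrix(5, 20, 0.4, seed = 2)$S,
                   random_sensing_matrix(5, 20, 0.4, seed = 2)$S)
})

test_that("wider tuning increases response correlations", {
  env <- random_environment(env_ensemble_params(40, seed = 8))
  mean_cor <- function(width) {
    mean(vapply(1:20, function(s) {
      sm <- random_sensing_matrix(8, 40, width, seed = 300 + s)
      C <- stats::cov2cor(overlap_matrix(sm, env))
      mean(C[upper.tri(C)])
    }, numeric(1)))
  }
  expect_gt(mean_cor(0.8), mean_cor(0.1))
})
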