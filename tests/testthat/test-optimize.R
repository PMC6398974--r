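test_that("water-filling on independent channels has the known solution", {
  opt <- optimal_distribution(Q = diag(c(2, 1)), noise = 1, Ktot = 10)
  expect_equal(unname(opt$K$K), c(5.25, 4.75), tolerance = 1e-8)
  expect_equal(opt$info, 0.5 * (log(11.5) + log(5.75)), tolerance = 1e-9)
  expect_true(opt$converged)
  expect_lt(opt$kkt_residual, 1e-6)
})

test_that("single receptor takes the whole budget", {
  for (kt in c(0.1, 7, 1e5)) {
    opt <- optimal_distribution(Q = matrix(2), noise = 1, Ktot = kt)
    expect_equal(unname(opt$K$K), kt)
    expect_equal(opt$kkt_residual, 0)
  }
})

test_that("tiny budgets concentrate on the highest-SNR receptor", {
  opt <- optimal_distribution(Q = diag(c(4, 1)), noise = 1, Ktot = 0.1)
  expect_gt(opt$K$K[1] / 0.1, 0.99)
  set.seed(21)
  for (trial in 1:5) {
    inst <- random_instance(5)
    idx <- lowsnr_support(inst$Q, inst$sigma2)
    opt <- optimal_distribution(Q = inst$Q, noise = inst$sigma2,
                                Ktot = 1e-4)
    expect_gt(opt$K$K[idx] / 1e-4, 0.99)
  }
})

test_that("lowsnr_support picks argmax Qaa/sigma2 with low-index ties", {
  expect_equal(lowsnr_support(diag(c(1, 5, 2)), c(1, 1, 1)), 2L)
  expect_equal(lowsnr_support(diag(c(1, 5, 2)), c(1, 25, 1)), 3L)
  expect_equal(lowsnr_support(diag(c(3, 3)), c(1, 1)), 1L)
})

test_that("optimizer beats the uniform start and matches grid search", {
  set.seed(31)
  for (trial in 1:8) {
    m <- sample(2:3, 1)
    inst <- random_instance(m, Ktot = runif(1, 5, 15))
    opt <- optimal_distribution(Q = inst$Q, noise = inst$sigma2,
                                Ktot = inst$Ktot)
    I_unif <- mutual_information(rep(inst$Ktot / m, m), inst$Q, inst$sigma2)
    expect_gte(opt$info, I_unif - 1e-9)
    I_grid <- grid_search_info(inst$Q, inst$sigma2, inst$Ktot, n_grid = 400)
    expect_gte(opt$info, I_grid - 1e-9)
  }
})

test_that("high-SNR closed form approaches the optimizer", {
  set.seed(41)
  for (trial in 1:3) {
    inst <- random_instance(5, scale = 2)
    A <- solve(inst$Q)
    Ktot <- 1e6 * max(inst$sigma2 * diag(A))
    Ka <- highsnr_distribution(inst$Q, inst$sigma2, Ktot)
    expect_equal(sum(Ka), Ktot)  # exact by construction
    opt <- optimal_distribution(Q = inst$Q, noise = inst$sigma2, Ktot = Ktot)
    expect_lt(max(abs(Ka - opt$K$K)) / Ktot, 0.01)
  }
  # uniform case and singular Q error
  expect_equal(unname(highsnr_distribution(diag(3), 1, 9)), rep(3, 3))
  expect_error(highsnr_distribution(matrix(c(1, 1, 1, 1), 2), 1, 10),
               "singular")
})

test_that("kkt_residual is zero at optima and positive away from them", {
  opt <- optimal_distribution(Q = diag(c(2, 1)), noise = 1, Ktot = 10)
  expect_lt(kkt_residual(opt$K, diag(c(2, 1)), 1), 1e-6)
  expect_equal(kkt_residual(5, matrix(2), 1), 0)  # single active receptor
  expect_gt(kkt_residual(c(5, 5), diag(c(2, 1)), 1), 1e-3)
  expect_error(kkt_residual(c(0, 0), diag(2), 1), "empty active set")
})

test_that("permuting receptors permutes the optimum identically", {
  set.seed(51)
  inst <- random_instance(4, Ktot = 20)
  opt <- optimal_distribution(Q = inst$Q, noise = inst$sigma2, Ktot = 20)
  p <- c(3, 1, 4, 2)
  opt_p <- optimal_distribution(Q = inst$Q[p, p], noise = inst$sigma2[p],
                                Ktot = 20)
  expect_equal(unname(opt_p$K$K), unname(opt$K$K[p]), tolerance = 1e-6)
})

test_that("optimized information is non-decreasing in the budget", {
  set.seed(61)
  inst <- random_instance(4)
  infos <- vapply(c(0.5, 2, 8, 32, 128), function(kt) {
    optimal_distribution(Q = inst$Q, noise = inst$sigma2, Ktot = kt)$info
  }, numeric(1))
  expect_true(all(diff(infos) > -1e-10))
})

test_that("receptor diversity grows in steps with the OSN budget", {
  set.seed(71)
  sm <- random_sensing_matrix(10, 30, 0.3, seed = 8)
  env <- random_environment(env_ensemble_params(30, seed = 9))
  Q <- overlap_matrix(sm, env)
  noise <- calibrate_noise(Q, Ktot = 100, snr2 = 10)
  grid <- 10^seq(-3, 4, length.out = 20)
  curve <- receptor_count_curve(noise = noise, Ktot_grid = grid, Q = Q)
  expect_equal(curve$n_expressed[1], 1)            # tiny budget: one type
  expect_equal(curve$n_expressed[nrow(curve)], 10) # huge budget: all types
  steps <- diff(curve$n_expressed)
  expect_gte(mean(steps >= 0), 0.95)               # monotone step transitions
  expect_error(receptor_count_curve(noise = noise, Ktot_grid = numeric(0),
                                    Q = Q), "empty")
  expect_error(receptor_count_curve(noise = noise, Ktot_grid = c(2, 1),
                                    Q = Q), "increasing")
})

test_that("optimum is independent of the environment mean, exactly", {
  set.seed(81)
  S <- matrix(rnorm(3 * 6), 3)
  gamma <- random_psd(6)
  o1 <- optimal_distribution(S, odor_environment(gamma), 1, 50)
  o2 <- optimal_distribution(S, odor_environment(gamma, c0 = rnorm(6, 5)),
                             1, 50)
  expect_identical(o1$K$K, o2$K$K)
  expect_identical(o1$info, o2$info)
})
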