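# Scaled-down in-silico experiments: small receptor panels and odorant
# counts keep each block fast while exercising the full pipelines.

test_that("identical environments and mean-only changes give zero deltas", {
  set.seed(43)
  sm <- random_sensing_matrix(6, 20, 0.4, seed = 1)
  env <- random_environment(env_ensemble_params(20, seed = 2))
  env_shift <- odor_environment(env$gamma, c0 = rnorm(20),
                                odorant_labels = env$odorant_labels)
  Q <- overlap_matrix(sm, env)
  noise <- calibrate_noise(Q, 500, snr2 = 10)
  res <- delta_k_experiment(sm, noise, 500,
                            list(list(env, env), list(env, env_shift)))
  expect_true(all(res$deltas == 0))
  expect_equal(unname(res$fractions[["frac_below_low"]]), 1)
  expect_equal(unname(res$fractions[["frac_above_mid"]]), 0)
  expect_equal(length(res$deltas), 2 * 6)  # n_pairs x M pooling
})

test_that("delta-k pooling respects flagged pairs and thresholds", {
  set.seed(47)
  sm <- random_sensing_matrix(6, 20, 0.4, seed = 3)
  pairs <- environment_pairs(env_ensemble_params(20, seed = 5), 4)
  Q <- overlap_matrix(sm, pairs[[1]][[1]])
  noise <- calibrate_noise(Q, 500, snr2 = 10)
  res <- delta_k_experiment(sm, noise, 500, pairs,
                            thresholds = list(low = 1e-9, mid = 0, high = 1e9,
                                              mean_frac = 1e9))
  expect_equal(length(res$deltas), 4 * 6)
  expect_true(all(abs(res$deltas) <= 500 + 1e-9))
  # with mid cut at 0, below-low + above-mid partition the nonzero deltas
  expect_equal(unname(res$fractions[["frac_above_high"]]), 0)
  expect_equal(unname(res$fractions[["frac_below_mean_frac"]]), 1)
})

test_that("context dependence: identical backgrounds sit on the diagonal", {
  set.seed(53)
  sm <- random_sensing_matrix(6, 15, 0.4, seed = 7)
  p <- env_ensemble_params(15, seed = 7)
  env <- random_environment(p)
  Q <- overlap_matrix(sm, env)
  noise <- calibrate_noise(Q, 300, snr2 = 10)
  # same background twice: both contexts respond identically
  av <- 50 * stats::median(diag(env$gamma))
  d1 <- olfadapt:::pair_delta(sm, env, perturb_single_variance(env, 4, av),
                              noise, 300)
  expect_identical(d1, olfadapt:::pair_delta(
    sm, env, perturb_single_variance(env, 4, av), noise, 300))
  # zero-magnitude perturbation changes nothing
  d0 <- olfadapt:::pair_delta(sm, env, perturb_single_variance(env, 4, 0),
                              noise, 300)
  expect_true(all(d0 == 0))
})

test_that("the same perturbation can flip sign across backgrounds", {
  sm <- random_sensing_matrix(8, 20, 0.5, seed = 11)
  p <- env_ensemble_params(20, seed = 13)
  env0 <- random_environment(p)
  Q <- overlap_matrix(sm, env0)
  noise <- calibrate_noise(Q, 400, snr2 = 10)
  res <- context_dependence_experiment(sm, noise, 400, n_pairs = 12,
                                       env_params = p)
  expect_equal(nrow(res$scatter), 12 * 8)
  expect_gt(res$opposite_sign_fraction, 0)
  expect_identical(res$seed, 13L)
})

test_that("tuning sweep: log-SNR predicts abundance only for narrow tuning", {
  env <- random_environment(env_ensemble_params(60, seed = 17))
  # noise fixed across widths from a mid-width reference matrix
  Q_ref <- overlap_matrix(random_sensing_matrix(10, 60, 0.4, seed = 0), env)
  noise <- calibrate_noise(Q_ref, 600, snr2 = 10)
  sweep <- tuning_correlation_sweep(c(0.08, 0.7), M = 10, N = 60, env = env,
                                    noise = noise, Ktot = 600,
                                    n_matrices = 12, seed = 19)
  expect_equal(nrow(sweep), 2)
  # narrow tuning: response variance is a good predictor; wide: it degrades
  expect_gt(sweep$cor_logsnr_mean[1], sweep$cor_logsnr_mean[2])
  # the inverse-overlap diagonal predicts (negatively) at all widths
  expect_true(all(sweep$cor_invdiag_mean < 0))
})

test_that("subsampling robustness degrades gracefully with removal", {
  sm <- random_sensing_matrix(12, 40, 0.4, seed = 23)
  p <- env_ensemble_params(40, seed = 23)
  Q <- overlap_matrix(sm, random_environment(p))
  noise <- calibrate_noise(Q, 600, snr2 = 10)
  r0 <- subsampling_experiment(sm, p, noise, 600, 0, "receptors",
                               n_trials = 3, seed = 1)
  expect_identical(r0$correlations, rep(1, 3))  # exactly 1, no removal
  means <- vapply(c(0, 0.2, 0.4, 0.6), function(f) {
    subsampling_experiment(sm, p, noise, 600, f, "receptors",
                           n_trials = 4, seed = 1)$mean
  }, numeric(1))
  expect_true(all(means >= -1 & means <= 1))
  expect_lte(sum(diff(means) > 0), 1)  # non-increasing, one inversion allowed
  # odorant mode runs and stays bounded
  ro <- subsampling_experiment(sm, p, noise, 600, 0.3, "odorants",
                               n_trials = 2, seed = 2)
  expect_true(all(abs(ro$correlations) <= 1))
  expect_error(subsampling_experiment(sm, p, noise, 600, 0.95, "receptors",
                                      n_trials = 1, seed = 1), "retained")
})

test_that("exposure experiment: zero perturbation and jitter give zero ratios", {
  sm <- random_sensing_matrix(8, 20, 0.4, seed = 29)
  env <- random_environment(env_ensemble_params(20, seed = 29))
  Q <- overlap_matrix(sm, env)
  noise <- calibrate_noise(Q, 400, snr2 = 10)
  res <- exposure_insilico(sm, noise, 400, env, env, n_replicates = 3,
                           jitter_scale = 0, seed = 1)
  expect_true(all(res$table$log_ratio_median == 0 |
                    res$table$n_zero_flagged > 0))
  expect_true(all(res$table$log_ratio_max == 0, na.rm = TRUE))
})

test_that("abundant receptors change least under exposure", {
  sm <- random_sensing_matrix(10, 30, 0.4, seed = 31)
  p <- env_ensemble_params(30, seed = 31)
  base <- random_environment(p)
  pert <- perturb_variance_set(base, indices = 1:4,
                               added_variance = 30 * median(diag(base$gamma)))
  Q <- overlap_matrix(sm, base)
  noise <- calibrate_noise(Q, 500, snr2 = 10)
  res <- exposure_insilico(sm, noise, 500, base, pert, n_replicates = 8,
                           seed = 3)
  tab <- res$table[res$table$n_zero_flagged == 0, ]
  expect_gt(nrow(tab), 3)
  # top-abundance receptors have median |log-ratio| below the overall median
  topk <- tab$K_base >= stats::quantile(tab$K_base, 0.7)
  expect_lte(stats::median(abs(tab$log_ratio_median[topk])),
             stats::median(abs(tab$log_ratio_median)) + 1e-12)
  # replicate ranges widen for rarer receptors (rank correlation <= 0)
  width <- tab$log_ratio_max - tab$log_ratio_min
  if (stats::sd(width) > 0) {
    expect_lte(stats::cor(tab$K_base, width, method = "spearman"), 0.2)
  }
})
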