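# Scripted in-silico experiments: statistics of optimal-abundance changes
# between environments, context dependence of perturbations, tuning-width
# sweeps, subsampling robustness, and the odor-exposure experiment.

#' Distribution of optimal-abundance changes across environment pairs
#'
#' For each pair of environments, solves the information maximization in
#' both and records the per-receptor changes `delta_K = K' - K`. Summary
#' fractions report how much of the pooled distribution falls below/above
#' configured cuts: a small-change cut, a mid and a high cut, and a
#' "moderate" cut at a fraction of the mean abundance `Ktot / M`.
#'
#' @param S A [sensing_matrix] shared by all environments.
#' @param noise A [noise_profile], positive vector or scalar.
#' @param Ktot Total OSN budget.
#' @param env_pairs List of 2-element lists/pairs of [odor_environment]s.
#' @param thresholds Named list with elements `low`, `mid`, `high`,
#'   `mean_frac` (defaults 0.1, 50, 800, 0.2).
#' @param ... Passed to [optimal_distribution()].
#' @return An object of class `delta_k_result`: `deltas` (pooled), `per_pair`
#'   (list of lists with `K`, `K_prime`), `fractions` (named vector:
#'   `frac_below_low`, `frac_above_mid`, `frac_above_high`,
#'   `frac_below_mean_frac`), `n_pairs_used`, `flagged_pairs`, `thresholds`.
#' @export
delta_k_experiment <- function(S, noise, Ktot, env_pairs,
                               thresholds = list(low = 0.1, mid = 50,
                                                 high = 800, mean_frac = 0.2),
                               ...) {
  S <- as_sensing(S)
  m <- nrow(S$S)
  per_pair <- vector("list", length(env_pairs))
  flagged <- integer(0)
  for (i in seq_along(env_pairs)) {
    pair <- env_pairs[[i]]
    fit <- tryCatch({
      o1 <- optimal_distribution(S, pair[[1]], noise, Ktot, ...)
      o2 <- optimal_distribution(S, pair[[2]], noise, Ktot, ...)
      if (!o1$converged || !o2$converged) stop("optimizer did not converge")
      list(K = o1$K$K, K_prime = o2$K$K)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("pair ", i, " flagged and excluded: ", conditionMessage(fit))
      flagged <- c(flagged, i)
    } else {
      per_pair[[i]] <- fit
    }
  }
  used <- setdiff(seq_along(env_pairs), flagged)
  deltas <- unlist(lapply(per_pair[used],
                          function(p) p$K_prime - p$K), use.names = FALSE)
  adel <- abs(deltas)
  fractions <- c(
    frac_below_low = mean(adel < thresholds$low),
    frac_above_mid = mean(adel > thresholds$mid),
    frac_above_high = mean(adel > thresholds$high),
    frac_below_mean_frac = mean(adel < thresholds$mean_frac * Ktot / m)
  )
  structure(
    list(deltas = deltas, per_pair = per_pair[used], fractions = fractions,
         n_pairs_used = length(used), flagged_pairs = flagged,
         thresholds = thresholds, Ktot = Ktot, M = m),
    class = "delta_k_result"
  )
}

#' @export
print.delta_k_result <- function(x, ...) {
  cat("<delta_k_result> ", x$n_pairs_used, " environment pairs, M = ", x$M,
      ", Ktot = ", format(x$Ktot), "\n", sep = "")
  f <- x$fractions
  cat(sprintf("  P(|dK| < %g)        = %.4f\n", x$thresholds$low,
              f[["frac_below_low"]]))
  cat(sprintf("  P(|dK| > %g)         = %.4f\n", x$thresholds$mid,
              f[["frac_above_mid"]]))
  cat(sprintf("  P(|dK| > %g)        = %.4f\n", x$thresholds$high,
              f[["frac_above_high"]]))
  cat(sprintf("  P(|dK| < %g*Ktot/M) = %.4f\n", x$thresholds$mean_frac,
              f[["frac_below_mean_frac"]]))
  invisible(x)
}

#' Context dependence of a fixed environmental perturbation
#'
#' Applies the same odorant-variance increase to pairs of different
#' background environments and compares the induced abundance changes. In a
#' correlated-channel code, the optimal response to one perturbation
#' depends on the background: the same added variance can raise a
#' receptor's abundance in one context and lower it in another.
#'
#' @param S A [sensing_matrix].
#' @param noise,Ktot As in [delta_k_experiment()].
#' @param n_pairs Number of background-environment pairs.
#' @param env_params [env_ensemble_params] for the backgrounds (its `seed`
#'   anchors the whole experiment).
#' @param added_variance Variance added to the chosen odorant (default 100
#'   times the median ensemble variance per pair).
#' @param ... Passed to [optimal_distribution()].
#' @return List with `scatter` (data frame: pair, receptor, dK1, dK2),
#'   `opposite_sign_fraction` (fraction of receptors, both changes nonzero,
#'   with opposite signs), and `seed`.
#' @export
context_dependence_experiment <- function(S, noise, Ktot, n_pairs,
                                          env_params, added_variance = NULL,
                                          ...) {
  S <- as_sensing(S)
  m <- nrow(S$S)
  n <- env_params$n_odorants
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    p1 <- modify_params(env_params, seed = next_seed(env_params$seed, 2L * i))
    p2 <- modify_params(env_params, seed = next_seed(env_params$seed, 2L * i + 1L))
    e1 <- random_environment(p1)
    e2 <- random_environment(p2)
    idx <- with_local_seed(next_seed(env_params$seed, 7919L * i), sample.int(n, 1))
    av <- added_variance %||%
      (100 * stats::median(c(diag(e1$gamma), diag(e2$gamma))))
    d1 <- pair_delta(S, e1, perturb_single_variance(e1, idx, av), noise,
                     Ktot, ...)
    d2 <- pair_delta(S, e2, perturb_single_variance(e2, idx, av), noise,
                     Ktot, ...)
    rows[[i]] <- data.frame(pair = i, receptor = S$receptor_labels,
                            dK1 = d1, dK2 = d2)
  }
  scatter <- do.call(rbind, rows)
  nz <- scatter$dK1 != 0 & scatter$dK2 != 0
  frac <- if (any(nz)) mean(sign(scatter$dK1[nz]) != sign(scatter$dK2[nz])) else 0
  list(scatter = scatter, opposite_sign_fraction = frac,
       seed = env_params$seed)
}

pair_delta <- function(S, env_a, env_b, noise, Ktot, ...) {
  oa <- optimal_distribution(S, env_a, noise, Ktot, ...)
  ob <- optimal_distribution(S, env_b, noise, Ktot, ...)
  ob$K$K - oa$K$K
}

#' Sweep of abundance-predictor correlations over receptor tuning width
#'
#' For each tuning width, draws an ensemble of random sensing matrices on a
#' fixed environment, optimizes the receptor distribution, and correlates
#' the optimal abundances with two candidate predictors: the log
#' signal-to-noise ratio `log(Q_aa / sigma_a^2)` (a good predictor only for
#' narrow tuning, where responses are weakly correlated) and the
#' noise-scaled diagonal of the inverse overlap matrix
#' `sigma_a^2 (Q^{-1})_aa` (predictive at all widths; the correlation is
#' negative, and its magnitude is reported with the sign attached).
#'
#' @param widths Vector of tuning widths in (0, 1].
#' @param M,N Sensing-matrix dimensions.
#' @param env A fixed [odor_environment].
#' @param noise,Ktot As elsewhere.
#' @param n_matrices Sensing matrices per width (default 24).
#' @param seed Base RNG seed.
#' @param ... Passed to [optimal_distribution()].
#' @return Data frame with one row per width: mean and 20th/80th
#'   percentiles of `cor(K, log SNR)` and of `cor(K, sigma^2 (Q^{-1})_aa)`
#'   across the ensemble (correlations undefined for constant K are
#'   dropped as NA).
#' @export
tuning_correlation_sweep <- function(widths, M, N, env, noise, Ktot,
                                     n_matrices = 24, seed = 1L, ...) {
  if (any(widths <= 0 | widths > 1)) stop("widths must be in (0, 1]")
  env <- as_env(env)
  rows <- lapply(seq_along(widths), function(wi) {
    w <- widths[wi]
    cors_snr <- cors_inv <- rep(NA_real_, n_matrices)
    for (j in seq_len(n_matrices)) {
      sm <- random_sensing_matrix(M, N, w, seed = next_seed(seed, 1000L * wi + j))
      Q <- overlap_matrix(sm, env)
      noise_m <- as_noise(noise, M)
      opt <- optimal_distribution(noise = noise_m, Ktot = Ktot, Q = Q, ...)
      K <- opt$K$K
      if (stats::sd(K) > 0) {
        cors_snr[j] <- stats::cor(K, log(diag(Q) / noise_m$sigma2))
        inv_diag <- noise_m$sigma2 * diag(solve(Q))
        cors_inv[j] <- stats::cor(K, inv_diag)
      }
    }
    data.frame(
      width = w,
      cor_logsnr_mean = mean(cors_snr, na.rm = TRUE),
      cor_logsnr_p20 = stats::quantile(cors_snr, 0.2, na.rm = TRUE, names = FALSE),
      cor_logsnr_p80 = stats::quantile(cors_snr, 0.8, na.rm = TRUE, names = FALSE),
      cor_invdiag_mean = mean(cors_inv, na.rm = TRUE),
      cor_invdiag_p20 = stats::quantile(cors_inv, 0.2, na.rm = TRUE, names = FALSE),
      cor_invdiag_p80 = stats::quantile(cors_inv, 0.8, na.rm = TRUE, names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Robustness of predicted abundances to subsampling
#'
#' Measures how well the optimal abundances survive incomplete knowledge
#' of the sensing matrix: a fraction of receptors (or odorants) is removed,
#' the optimization re-run, and the retained receptors' abundances
#' correlated (Pearson) with the full solution. Odorant removal drops the
#' corresponding environment rows/columns and sensing-matrix columns. Each
#' trial draws a fresh random environment and a fresh removal subset.
#'
#' @param S A [sensing_matrix].
#' @param env_params [env_ensemble_params] for the per-trial environments.
#' @param noise,Ktot As elsewhere.
#' @param removal_fraction Fraction removed, in [0, 1).
#' @param mode `"receptors"` or `"odorants"`.
#' @param n_trials Number of trials (default 10).
#' @param seed Base RNG seed.
#' @param ... Passed to [optimal_distribution()].
#' @return List with `correlations` (length `n_trials`), `mean`, `p20`,
#'   `p80`, `mode`, `removal_fraction`, `seed`.
#' @export
subsampling_experiment <- function(S, env_params, noise, Ktot,
                                   removal_fraction,
                                   mode = c("receptors", "odorants"),
                                   n_trials = 10, seed = 1L, ...) {
  mode <- match.arg(mode)
  if (removal_fraction < 0 || removal_fraction >= 1) {
    stop("`removal_fraction` must be in [0, 1)")
  }
  S <- as_sensing(S)
  m <- nrow(S$S)
  n <- ncol(S$S)
  cors <- rep(NA_real_, n_trials)
  for (tr in seq_len(n_trials)) {
    p <- modify_params(env_params, seed = next_seed(env_params$seed, 131L * tr + seed))
    env <- random_environment(p)
    full <- optimal_distribution(S, env, noise, Ktot, ...)
    if (mode == "receptors") {
      n_remove <- round(removal_fraction * m)
      if (m - n_remove < 2) stop("fewer than 2 receptors retained")
      if (n_remove == 0) { cors[tr] <- 1; next }  # identical problem
      drop <- with_local_seed(next_seed(seed, 977L * tr), sample.int(m, n_remove))
      keep <- setdiff(seq_len(m), drop)
      S_sub <- sensing_matrix(S$S[keep, , drop = FALSE])
      sub <- optimal_distribution(S_sub, env, as_noise(noise, m)$sigma2[keep],
                                  Ktot, ...)
      cors[tr] <- stats::cor(full$K$K[keep], sub$K$K)
    } else {
      n_remove <- round(removal_fraction * n)
      if (n_remove == 0) { cors[tr] <- 1; next }
      drop <- with_local_seed(next_seed(seed, 977L * tr), sample.int(n, n_remove))
      keep <- setdiff(seq_len(n), drop)
      S_sub <- sensing_matrix(S$S[, keep, drop = FALSE])
      env_sub <- odor_environment(env$gamma[keep, keep, drop = FALSE])
      sub <- optimal_distribution(S_sub, env_sub, noise, Ktot, ...)
      cors[tr] <- stats::cor(full$K$K, sub$K$K)
    }
  }
  list(correlations = cors, mean = mean(cors),
       p20 = stats::quantile(cors, 0.2, names = FALSE),
       p80 = stats::quantile(cors, 0.8, names = FALSE),
       mode = mode, removal_fraction = removal_fraction, seed = seed)
}

#' In-silico odor-exposure experiment
#'
#' Compares the optimal receptor distribution between a base and a
#' perturbed odor environment, replicated under small random jitters of
#' both covariances (through their matrix square roots) to gauge the
#' sensitivity of each receptor's predicted change. Reports the
#' per-receptor median log-ratio `log(K'/K)` against baseline abundance
#' with min-max replicate ranges; abundant receptors barely move, while
#' rare receptors change more and are also more sensitive to the jitter.
#'
#' @param S A [sensing_matrix] (e.g. a mammalian-shaped panel).
#' @param noise,Ktot As elsewhere.
#' @param base_env,perturbed_env [odor_environment]s being compared.
#' @param n_replicates Number of jittered replicates (default 24).
#' @param jitter_scale Scale of the square-root jitter (default 0.05 times
#'   the median base standard deviation).
#' @param seed Base RNG seed.
#' @param zero_tol Abundances at or below this count as unexpressed and are
#'   flagged instead of producing infinite log-ratios.
#' @param ... Passed to [optimal_distribution()].
#' @return List with `table` (data frame: receptor, K_base [median across
#'   replicates], log_ratio_median, log_ratio_min, log_ratio_max,
#'   n_zero_flagged) and `seed`.
#' @export
exposure_insilico <- function(S, noise, Ktot, base_env, perturbed_env,
                              n_replicates = 24, jitter_scale = NULL,
                              seed = 1L, zero_tol = 1e-6, ...) {
  S <- as_sensing(S)
  m <- nrow(S$S)
  base_env <- as_env(base_env)
  perturbed_env <- as_env(perturbed_env)
  if (is.null(jitter_scale)) {
    jitter_scale <- 0.05 * stats::median(sqrt(diag(base_env$gamma)))
  }
  K_base <- matrix(NA_real_, n_replicates, m)
  K_pert <- matrix(NA_real_, n_replicates, m)
  for (r in seq_len(n_replicates)) {
    e1 <- jitter_sqrt(base_env, jitter_scale, seed = next_seed(seed, 2L * r))
    e2 <- jitter_sqrt(perturbed_env, jitter_scale, seed = next_seed(seed, 2L * r + 1L))
    K_base[r, ] <- optimal_distribution(S, e1, noise, Ktot, ...)$K$K
    K_pert[r, ] <- optimal_distribution(S, e2, noise, Ktot, ...)$K$K
  }
  zero_tol_abs <- zero_tol * Ktot / m
  log_ratio <- matrix(NA_real_, n_replicates, m)
  ok <- K_base > zero_tol_abs & K_pert > zero_tol_abs
  log_ratio[ok] <- log(K_pert[ok] / K_base[ok])
  tab <- data.frame(
    receptor = S$receptor_labels,
    K_base = apply(K_base, 2, stats::median),
    log_ratio_median = apply(log_ratio, 2, stats::median, na.rm = TRUE),
    log_ratio_min = suppressWarnings(apply(log_ratio, 2, min, na.rm = TRUE)),
    log_ratio_max = suppressWarnings(apply(log_ratio, 2, max, na.rm = TRUE)),
    n_zero_flagged = colSums(!ok)
  )
  tab$log_ratio_min[!is.finite(tab$log_ratio_min)] <- NA_real_
  tab$log_ratio_max[!is.finite(tab$log_ratio_max)] <- NA_real_
  list(table = tab, seed = seed, jitter_scale = jitter_scale,
       n_replicates = n_replicates)
}

# Copy an env_ensemble_params with fields replaced.
modify_params <- function(params, ...) {
  mod <- list(...)
  for (nm in names(mod)) params[[nm]] <- mod[[nm]]
  env_ensemble_params(params$n_odorants, params$beta, params$logvar_mu,
                      params$logvar_sigma, params$seed)
}

#' Generate a list of generic environment pairs
#'
#' Convenience builder for [delta_k_experiment()]: draws `n_pairs`
#' independent pairs of environments from the generic random ensemble, or
#' non-overlapping pairs when `nonoverlapping = TRUE`.
#'
#' @param params An [env_ensemble_params] object; its seed anchors all draws.
#' @param n_pairs Number of pairs.
#' @param nonoverlapping Build odor-content-disjoint pairs instead of
#'   independent generic draws.
#' @return List of length `n_pairs`; each element is a list of two
#'   [odor_environment]s.
#' @export
environment_pairs <- function(params, n_pairs, nonoverlapping = FALSE) {
  stopifnot(inherits(params, "env_ensemble_params"))
  lapply(seq_len(n_pairs), function(i) {
    if (nonoverlapping) {
      pr <- nonoverlapping_pair(
        modify_params(params, seed = next_seed(params$seed, 541L * i)),
        split_seed = next_seed(params$seed, 1000003L + i)
      )
      list(pr$env1, pr$env2)
    } else {
      list(
        random_environment(modify_params(params, seed = next_seed(params$seed, 2L * i))),
        random_environment(modify_params(params, seed = next_seed(params$seed, 2L * i + 1L)))
      )
    }
  })
}
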