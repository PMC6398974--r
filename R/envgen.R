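# Synthetic ensembles: random correlated odor-environment covariances,
# environment perturbations and pairs, and random sensing matrices with
# controlled tuning width. All generators are pure functions of their
# parameters and seed.

#' Parameters for the random-environment ensemble
#'
#' The ensemble draws a random correlation matrix `C` by normalizing a
#' Wishart-type Gram matrix `G %*% t(G)` (with `G` an N x ceiling(beta*N)
#' standard-normal matrix) to unit diagonal, and scales it by lognormal
#' variances: `Gamma = D^{1/2} C D^{1/2}`. Larger `beta` gives more
#' independent columns in `G`, hence weaker off-diagonal correlations.
#'
#' @param n_odorants Number of odorants N.
#' @param beta Correlation-strength parameter (> 0); default 8.
#' @param logvar_mu,logvar_sigma Mean and s.d. of the log of the odorant
#'   variances (defaults 0 and 1).
#' @param seed RNG seed used by the generators.
#' @return An object of class `env_ensemble_params`.
#' @export
env_ensemble_params <- function(n_odorants, beta = 8, logvar_mu = 0,
                                logvar_sigma = 1, seed = 1L) {
  if (n_odorants < 1) stop("`n_odorants` must be >= 1")
  if (beta <= 0) stop("`beta` must be > 0")
  if (logvar_sigma < 0) stop("`logvar_sigma` must be >= 0")
  structure(list(n_odorants = as.integer(n_odorants), beta = beta,
                 logvar_mu = logvar_mu, logvar_sigma = logvar_sigma,
                 seed = as.integer(seed)),
            class = "env_ensemble_params")
}

#' Draw a random odor environment
#'
#' @param params An [env_ensemble_params] object.
#' @return An [odor_environment] with zero mean and covariance
#'   `D^{1/2} C D^{1/2}` as described in [env_ensemble_params()].
#' @examples
#' env <- random_environment(env_ensemble_params(20, seed = 7))
#' min(eigen(env$gamma, symmetric = TRUE, only.values = TRUE)$values) >= 0
#' @export
random_environment <- function(params) {
  stopifnot(inherits(params, "env_ensemble_params"))
  n <- params$n_odorants
  with_local_seed(params$seed, {
    G <- matrix(stats::rnorm(n * ceiling(params$beta * n)), n)
    C <- G %*% t(G)
    d <- sqrt(diag(C))
    C <- C / (d %o% d)
    v <- stats::rlnorm(n, meanlog = params$logvar_mu,
                       sdlog = params$logvar_sigma)
    sv <- sqrt(v)
    gamma <- C * (sv %o% sv)
    odor_environment((gamma + t(gamma)) / 2)
  })
}

#' Increase the variance of one odorant
#'
#' Adds `added_variance` to the diagonal entry of the covariance for one
#' odorant (a rank-one PSD update `Gamma + v e_i e_i^T`), leaving every
#' other entry untouched.
#'
#' @param env An [odor_environment].
#' @param odorant_index Index (1-based) of the affected odorant.
#' @param added_variance Non-negative variance to add.
#' @return A new [odor_environment].
#' @export
perturb_single_variance <- function(env, odorant_index, added_variance) {
  env <- as_env(env)
  n <- length(env$c0)
  if (odorant_index < 1 || odorant_index > n) stop("odorant index out of range")
  if (added_variance < 0) stop("`added_variance` must be >= 0")
  gamma <- env$gamma
  gamma[odorant_index, odorant_index] <-
    gamma[odorant_index, odorant_index] + added_variance
  odor_environment(gamma, c0 = env$c0, odorant_labels = env$odorant_labels)
}

#' Increase the variances of a set of odorants
#'
#' Applies [perturb_single_variance()] to each index in `indices`. The
#' default magnitude, `magnitude_factor` times the median base variance,
#' makes the affected odorants dominate the scene statistics (factor 100
#' by default).
#'
#' @param env An [odor_environment].
#' @param indices Odorant indices to perturb (default: 10 drawn with
#'   `seed`).
#' @param added_variance Variance added to each index; default
#'   `magnitude_factor * median(diag(gamma))`.
#' @param magnitude_factor Multiplier used for the default magnitude.
#' @param seed Seed used only when `indices` is NULL.
#' @return A new [odor_environment].
#' @export
perturb_variance_set <- function(env, indices = NULL, added_variance = NULL,
                                 magnitude_factor = 100, seed = 1L) {
  env <- as_env(env)
  n <- length(env$c0)
  if (is.null(indices)) {
    indices <- with_local_seed(seed, sample.int(n, min(10L, n)))
  }
  if (length(indices) == 0) return(env)
  if (any(indices < 1 | indices > n)) stop("odorant indices out of range")
  if (is.null(added_variance)) {
    added_variance <- magnitude_factor * stats::median(diag(env$gamma))
  }
  gamma <- env$gamma
  diag(gamma)[indices] <- diag(gamma)[indices] + added_variance
  odor_environment(gamma, c0 = env$c0, odorant_labels = env$odorant_labels)
}

#' Pair of environments with non-overlapping odor content
#'
#' Randomly partitions the odorants into two halves and builds one
#' generic-ensemble environment per half: within its own half an
#' environment has the full ensemble variances and correlations, while the
#' other half is silenced down to a small floor variance (uncorrelated).
#' Every odorant therefore has appreciable variance in at most one of the
#' two environments.
#'
#' @param params An [env_ensemble_params] object (shared base statistics).
#' @param split_seed Seed for the random partition.
#' @param floor_frac Floor variance as a fraction of the median ensemble
#'   variance (default `1e-4`).
#' @return List of two [odor_environment]s (`env1`, `env2`) plus the index
#'   sets `half1`, `half2`.
#' @export
nonoverlapping_pair <- function(params, split_seed = 1L, floor_frac = 1e-4) {
  stopifnot(inherits(params, "env_ensemble_params"))
  n <- params$n_odorants
  if (n < 2) stop("need at least 2 odorants to split")
  base <- random_environment(params)
  half1 <- with_local_seed(split_seed, sort(sample.int(n, floor(n / 2))))
  half2 <- setdiff(seq_len(n), half1)
  eps <- floor_frac * stats::median(diag(base$gamma))
  restrict <- function(keep) {
    gamma <- matrix(0, n, n)
    gamma[keep, keep] <- base$gamma[keep, keep]
    diag(gamma)[setdiff(seq_len(n), keep)] <- eps
    odor_environment(gamma, odorant_labels = base$odorant_labels)
  }
  list(env1 = restrict(half1), env2 = restrict(half2),
       half1 = half1, half2 = half2, floor_variance = eps)
}

#' Jitter an environment through its matrix square root
#'
#' Perturbs a covariance as `(Gamma^{1/2} + eps * Z)(Gamma^{1/2} + eps *
#' Z)^T` with `Gamma^{1/2}` the symmetric principal square root and `Z` a
#' standard-normal matrix, modeling small environment perturbations while
#' guaranteeing a valid (PSD) covariance by construction.
#'
#' @param env An [odor_environment].
#' @param jitter_scale Non-negative perturbation scale `eps`.
#' @param seed RNG seed for `Z`.
#' @return A new [odor_environment].
#' @export
jitter_sqrt <- function(env, jitter_scale, seed = 1L) {
  env <- as_env(env)
  if (jitter_scale < 0) stop("`jitter_scale` must be >= 0")
  n <- length(env$c0)
  e <- eigen(env$gamma, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Z <- with_local_seed(seed, matrix(stats::rnorm(n * n), n))
  B <- root + jitter_scale * Z
  gamma <- B %*% t(B)
  odor_environment((gamma + t(gamma)) / 2, c0 = env$c0,
                   odorant_labels = env$odorant_labels)
}

#' Random sensing matrix with controlled tuning width
#'
#' Each receptor responds strongly to a random subset of
#' `round(tuning_width * N)` odorants and only weakly to the rest. Strong
#' magnitudes are lognormal(`strong_meanlog`, `strong_sdlog`); weak entries
#' are drawn from the same distribution scaled by `weak_factor`. Wider
#' tuning makes different receptors share more strongly-sensed odorants,
#' increasing the correlation of their noiseless responses.
#'
#' @param M,N Numbers of receptors and odorants.
#' @param tuning_width Fraction of odorants sensed strongly, in (0, 1].
#' @param seed RNG seed.
#' @param strong_meanlog,strong_sdlog Lognormal parameters of strong
#'   magnitudes (defaults 0, 0.5).
#' @param weak_factor Scale of weak relative to strong entries (default 0.02).
#' @return A [sensing_matrix].
#' @examples
#' sm <- random_sensing_matrix(24, 110, 0.2, seed = 3)
#' rowSums(attr(sm, "strong_mask"))  # 22 strong entries per row
#' @export
random_sensing_matrix <- function(M, N, tuning_width, seed = 1L,
                                  strong_meanlog = 0, strong_sdlog = 0.5,
                                  weak_factor = 0.02) {
  if (M < 1 || N < 1) stop("`M` and `N` must be >= 1")
  if (tuning_width <= 0 || tuning_width > 1) {
    stop("`tuning_width` must be in (0, 1]")
  }
  k <- round(tuning_width * N)
  if (k < 1) {
    stop("tuning_width * N < 1: no strong odorants per receptor; ",
         "use a larger N or wider tuning")
  }
  out <- with_local_seed(seed, {
    S <- matrix(stats::rlnorm(M * N, strong_meanlog, strong_sdlog), M, N) *
      weak_factor
    mask <- matrix(FALSE, M, N)
    for (a in seq_len(M)) {
      idx <- sample.int(N, k)
      mask[a, idx] <- TRUE
      S[a, idx] <- stats::rlnorm(k, strong_meanlog, strong_sdlog)
    }
    list(S = S, mask = mask)
  })
  sm <- sensing_matrix(out$S)
  attr(sm, "strong_mask") <- out$mask
  attr(sm, "tuning_width") <- k / N
  sm
}

# Combine a base seed with an offset, staying inside the 32-bit integer
# range R's RNG accepts.
next_seed <- function(base, k) {
  as.integer((as.numeric(base) + as.numeric(k)) %% 2147483629)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of
# (params, seed) and do not disturb the session stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
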