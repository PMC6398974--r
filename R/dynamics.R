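# Experience-dependent birth/death dynamics of OSN abundances:
#   dK_a/dt = alpha * { K_a - lambda K_a^2 - sigma_a^2 (R^{-1})_aa K_a^2 },
# with R the glomerular response covariance at the current K. Without the
# experience term the dynamics are logistic with carrying capacity 1/lambda
# per type (total M/lambda). With it, interior fixed points satisfy
# gradient_a = lambda/2 for every expressed type: exactly the KKT condition
# of the constrained information maximization with multiplier lambda/2, so
# the dynamics relax to the information optimum at an emergent total budget.

#' Parameters of the birth/death dynamics
#'
#' @param alpha Learning rate (1/time).
#' @param lam Density-dependent death coefficient lambda (1/(neuron time));
#'   `M / lam` sets the asymptotic total population in the logistic limit.
#' @param dt Integration step (time). Default `min(1e-2 / alpha, t_max/100)`
#'   so that `alpha * dt <= 1e-2`.
#' @param t_max Integration horizon (time).
#' @param noise_floor Abundances below this are treated as extinct when
#'   reporting (neurons).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(alpha = 1, lam = 0.01, dt = NULL, t_max = 1000,
                            noise_floor = 1e-6) {
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (lam <= 0) stop("`lam` must be > 0")
  if (is.null(dt)) dt <- min(1e-2 / alpha, t_max / 100)
  if (dt <= 0) stop("`dt` must be > 0")
  if (t_max <= dt) stop("`t_max` must exceed `dt`")
  structure(list(alpha = alpha, lam = lam, dt = dt, t_max = t_max,
                 noise_floor = noise_floor),
            class = "dynamics_params")
}

#' Simulate the experience-dependent birth/death dynamics
#'
#' Integrates the abundance ODE with explicit Euler steps, halving the step
#' whenever an abundance would overshoot below zero. The experience term
#' `sigma_a^2 (R^{-1})_aa K_a^2` is evaluated through the algebraically
#' equivalent form `K_a [(I + Sigma^{-1} Q diag(K))^{-1}]_aa`, which stays
#' finite as abundances reach zero (where the literal response covariance R
#' is singular); the two agree on the interior (see the methods vignette).
#' Trajectories are recorded on a log-spaced time grid, matching the
#' logarithmic time axis on which convergence is naturally displayed.
#'
#' @param K0 Length-M vector of non-negative initial abundances.
#' @param S,env Sensing matrix and environment (or pass `Q`).
#' @param noise A [noise_profile], positive vector or scalar.
#' @param params A [dynamics_params] object.
#' @param experience_term If `FALSE`, drop the experience-dependent death
#'   term; the dynamics reduce to independent logistic growth toward
#'   `K_a = 1/lambda`.
#' @param Q Optional precomputed overlap matrix.
#' @param n_record Number of log-spaced sample times to record.
#' @return An object of class `osn_dynamics`: `times`, `K_path`
#'   (steps x M), `K_final`, `Ktot_final`, `kkt_residual_final`, `params`.
#' @examples
#' tr <- simulate_dynamics(rep(1, 3), Q = diag(3), noise = 1,
#'                         params = dynamics_params(lam = 0.01, t_max = 50),
#'                         experience_term = FALSE)
#' tr$K_final  # approaches 1/lambda = 100 per type
#' @export
simulate_dynamics <- function(K0, S = NULL, env = NULL, noise, params,
                              experience_term = TRUE, Q = NULL,
                              n_record = 200) {
  if (is.null(Q)) Q <- overlap_matrix(S, env)
  m <- nrow(Q)
  K <- as.numeric(K0)
  if (length(K) != m) stop("`K0` has length ", length(K), ", expected ", m)
  if (any(K < 0)) stop("`K0` must be non-negative")
  noise <- as_noise(noise, m)
  sigma2 <- noise$sigma2
  stopifnot(inherits(params, "dynamics_params"))

  # log-spaced recording grid (plus t = 0)
  rec_times <- unique(c(0, exp(seq(log(params$dt), log(params$t_max),
                                   length.out = n_record))))
  K_path <- matrix(NA_real_, length(rec_times), m)
  colnames(K_path) <- rownames(Q)
  K_path[1, ] <- K
  rec_i <- 2L

  t <- 0
  dt <- params$dt
  while (t < params$t_max) {
    dt_step <- min(dt, params$t_max - t)
    rate <- dK_dt(K, Q, sigma2, params$lam, experience_term)
    K_new <- K + params$alpha * dt_step * rate
    # adaptive halving on overshoot below zero
    tries <- 0L
    while (any(K_new < -params$noise_floor) && tries < 60L) {
      dt_step <- dt_step / 2
      K_new <- K + params$alpha * dt_step * rate
      tries <- tries + 1L
    }
    K <- pmax(K_new, 0)
    t <- t + dt_step
    while (rec_i <= length(rec_times) && rec_times[rec_i] <= t) {
      K_path[rec_i, ] <- K
      rec_i <- rec_i + 1L
    }
  }
  if (rec_i <= length(rec_times)) {
    K_path[rec_i:length(rec_times), ] <- matrix(K, length(rec_times) - rec_i + 1L,
                                                m, byrow = TRUE)
  }

  res_final <- if (sum(K) > 0) {
    kkt_residual(K, Q, noise, active_tol = params$noise_floor)
  } else NA_real_
  structure(
    list(times = rec_times, K_path = K_path, K_final = K,
         Ktot_final = sum(K), kkt_residual_final = res_final,
         params = params, experience_term = experience_term),
    class = "osn_dynamics"
  )
}

# Right-hand side (without the alpha prefactor):
#   K - lam K^2 - sigma^2 (R^{-1})_aa K^2
# evaluated via sigma_a^2 (R^{-1})_aa K_a^2 = K_a [(I + Sigma^{-1} Q D)^{-1}]_aa,
# finite for all K >= 0.
dK_dt <- function(K, Q, sigma2, lam, experience_term) {
  rate <- K - lam * K^2
  if (experience_term) rate <- rate - K * experience_death(K, Q, sigma2)
  rate
}

# diag of (I + Sigma^{-1} Q diag(K))^{-1}. With Qs = Sigma^{-1/2} Q
# Sigma^{-1/2} and A = I + K^{1/2} Qs K^{1/2} (symmetric, well conditioned),
# the push-through identity gives
#   (I + Qs D)^{-1} = I - Qs K^{1/2} A^{-1} K^{1/2},
# and the diagonal similarity by Sigma^{1/2} leaves the diagonal unchanged:
#   diag = 1 - sqrt(K) * diag(A^{-1} K^{1/2} Qs).
experience_death <- function(K, Q, sigma2) {
  m <- length(K)
  si <- 1 / sqrt(sigma2)
  Qs <- Q * (si %o% si)
  rk <- sqrt(K)
  A <- diag(m) + Qs * (rk %o% rk)
  Y <- solve((A + t(A)) / 2, Qs * rk)   # A^{-1} K^{1/2} Qs
  pmax(1 - rk * diag(Y), 0)
}

#' Per-receptor convergence report for a dynamics run
#'
#' For each receptor type, finds the first recorded time after which the
#' trajectory stays within `tol_frac * Ktot / M` of its target abundance,
#' and summarizes the association between final abundance and convergence
#' speed (types that end up rare converge more slowly, because the growth
#' rate vanishes as abundances approach zero).
#'
#' @param traj An `osn_dynamics` object from [simulate_dynamics()].
#' @param K_opt Target abundances: a [receptor_distribution] or vector.
#' @param tol_frac Convergence band, as a fraction of the mean target
#'   abundance `Ktot / M` (default 0.05).
#' @return A list with `table` (data frame: receptor, K_target, K_final,
#'   convergence_time, converged, final_error) and
#'   `speed_abundance_rank_cor` (Spearman correlation between target
#'   abundance and convergence time; negative association means rare types
#'   are slow).
#' @export
convergence_report <- function(traj, K_opt, tol_frac = 0.05) {
  stopifnot(inherits(traj, "osn_dynamics"))
  K_opt <- if (inherits(K_opt, "receptor_distribution")) K_opt$K else as.numeric(K_opt)
  m <- ncol(traj$K_path)
  if (length(K_opt) != m) stop("`K_opt` length mismatch")
  band <- tol_frac * sum(K_opt) / m

  conv_time <- rep(NA_real_, m)
  for (a in seq_len(m)) {
    dev <- abs(traj$K_path[, a] - K_opt[a])
    inside <- dev <= band
    # first index after which the trajectory never leaves the band
    idx <- if (all(!inside)) NA_integer_ else {
      last_out <- if (any(!inside)) max(which(!inside)) else 0L
      if (last_out >= length(inside)) NA_integer_ else last_out + 1L
    }
    if (!is.na(idx)) {
      conv_time[a] <- if (idx == 1L) 0 else traj$times[idx]
    }
  }
  tab <- data.frame(
    receptor = colnames(traj$K_path) %||% paste0("receptor_", seq_len(m)),
    K_target = K_opt,
    K_final = traj$K_final,
    convergence_time = conv_time,
    converged = !is.na(conv_time),
    final_error = abs(traj$K_final - K_opt)
  )
  cor_val <- if (sum(!is.na(conv_time)) >= 3 &&
                 stats::sd(K_opt[!is.na(conv_time)]) > 0 &&
                 stats::sd(conv_time, na.rm = TRUE) > 0) {
    stats::cor(K_opt[!is.na(conv_time)], conv_time[!is.na(conv_time)],
               method = "spearman")
  } else NA_real_
  list(table = tab, speed_abundance_rank_cor = cor_val)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
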