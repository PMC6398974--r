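# Response statistics and the information objective.
#
# Model: a glomerulus pooling K_a neurons of receptor type a responds
#   r_a = K_a * sum_i S_ai c_i + sqrt(K_a) * eta_a,
# with c ~ N(c0, Gamma) and eta_a ~ N(0, sigma_a^2) per neuron (summed
# noise s.d. grows as sqrt(K_a)). Under this linear-Gaussian model the
# mutual information between responses and concentrations is
#   I(r, c) = 1/2 Tr log(I + K Sigma^{-1} Q),   Q = S Gamma S^T,
# the multi-channel generalization of 1/2 log(1 + SNR^2).

#' Overlap matrix of noiseless glomerular signals
#'
#' Computes `Q = S %*% Gamma %*% t(S)`, the covariance of noiseless
#' per-neuron responses `S c` under the Gaussian environment. Its diagonal,
#' divided by the noise variances, is the squared per-receptor
#' signal-to-noise ratio. Independent of the environment mean `c0`.
#'
#' @param S A [sensing_matrix] (or bare M x N matrix).
#' @param env An [odor_environment] (or bare N x N covariance matrix).
#' @return Symmetric positive semi-definite M x M matrix with receptor
#'   labels on both dimensions.
#' @examples
#' overlap_matrix(diag(2), matrix(c(1, .5, .5, 1), 2))
#' @export
overlap_matrix <- function(S, env) {
  S <- as_sensing(S)
  env <- as_env(env)
  if (ncol(S$S) != nrow(env$gamma)) {
    stop("sensing matrix has ", ncol(S$S), " odorants but environment has ",
         nrow(env$gamma))
  }
  Q <- S$S %*% env$gamma %*% t(S$S)
  Q <- (Q + t(Q)) / 2
  dimnames(Q) <- list(S$receptor_labels, S$receptor_labels)
  Q
}

#' Covariance of glomerular responses including receptor noise
#'
#' For abundances `K`, the response covariance is
#' `R = diag(K) Q diag(K) + diag(K * sigma2)`: the signal term scales with
#' `K_a K_b` because each glomerulus sums its neurons' responses, while the
#' independent per-neuron noise adds variance linearly in `K_a`.
#'
#' @param K A [receptor_distribution] or non-negative numeric vector.
#' @param S,env Sensing matrix and odor environment (see [overlap_matrix]);
#'   alternatively pass a precomputed overlap matrix as `Q`.
#' @param noise A [noise_profile] or positive numeric vector.
#' @param Q Optional precomputed overlap matrix (overrides `S`/`env`).
#' @return Symmetric PSD M x M matrix.
#' @examples
#' response_covariance(c(2), Q = matrix(3), noise = 1)  # 2*3*2 + 2*1 = 14
#' @export
response_covariance <- function(K, S = NULL, env = NULL, noise, Q = NULL) {
  if (is.null(Q)) Q <- overlap_matrix(S, env)
  K <- distribution_vector(K, nrow(Q))
  noise <- as_noise(noise, nrow(Q))
  R <- (K %o% K) * Q
  diag(R) <- diag(R) + K * noise$sigma2
  (R + t(R)) / 2
}

#' Mutual information between glomerular responses and odor scenes
#'
#' Evaluates `1/2 Tr log(I + K Sigma^{-1} Q)` in nats (or bits), via the
#' symmetric similarity `K^{1/2} Sigma^{-1/2} Q Sigma^{-1/2} K^{1/2}`,
#' which has the same spectrum and is numerically stable.
#'
#' @param K A [receptor_distribution] or non-negative numeric vector.
#' @param Q Overlap matrix (M x M PSD), e.g. from [overlap_matrix()].
#' @param noise A [noise_profile] or positive numeric vector.
#' @param bits If `TRUE`, return the information in bits instead of nats.
#' @return Non-negative scalar; zero iff the signal term `K Q K` vanishes.
#' @examples
#' mutual_information(4, matrix(1), 1)  # 0.5 * log(5)
#' @export
mutual_information <- function(K, Q, noise, bits = FALSE) {
  K <- distribution_vector(K, nrow(Q))
  noise <- as_noise(noise, nrow(Q))
  if (!all(is.finite(Q))) stop("`Q` contains non-finite entries")
  w <- sqrt(K / noise$sigma2)
  B <- Q * (w %o% w)            # K^{1/2} Sigma^{-1/2} Q Sigma^{-1/2} K^{1/2}
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)             # PSD up to rounding
  info <- 0.5 * sum(log1p(ev))
  if (bits) info / log(2) else info
}

#' Gradient of the mutual information with respect to OSN abundances
#'
#' Component `a` is `1/2 [Sigma^{-1} Q (I + K Sigma^{-1} Q)^{-1}]_aa`,
#' evaluated through the symmetric form used by [mutual_information()].
#' All components are non-negative: information never decreases when a
#' receptor type gains neurons.
#'
#' @inheritParams mutual_information
#' @return Length-M numeric vector of partial derivatives (nats per neuron).
#' @examples
#' mi_gradient(0, matrix(3), 1)  # 1/2 * Q / sigma^2 = 1.5 at K = 0
#' @export
mi_gradient <- function(K, Q, noise) {
  K <- distribution_vector(K, nrow(Q))
  noise <- as_noise(noise, nrow(Q))
  if (!all(is.finite(Q))) stop("`Q` contains non-finite entries")
  0.5 * diag(mi_resolvent(K, Q, noise$sigma2))
}

# G = Sigma^{-1} Q (I + K Sigma^{-1} Q)^{-1}, computed via the symmetric
# similarity: with W = diag(sqrt(K/sigma2)) and B = W Q W,
#   G = Sigma^{-1/2} W^{-} [ W Q W (I + B)^{-1} ] W^{-} Sigma^{1/2} ... ;
# in practice solve the well-conditioned symmetric system directly:
#   G = Sigma^{-1} Q - Sigma^{-1} Q K Sigma^{-1} Q (I + ...)^{-1} ...
# We use: G = Sigma^{-1/2} [ Qs (I + Ks Qs)^{-1} ] Sigma^{1/2} with
# Qs = Sigma^{-1/2} Q Sigma^{-1/2} (symmetric) and Ks = diag(K); the inner
# solve is done on the symmetrized matrix I + Ks^{1/2} Qs Ks^{1/2}.
mi_resolvent <- function(K, Q, sigma2) {
  m <- nrow(Q)
  si <- 1 / sqrt(sigma2)
  Qs <- Q * (si %o% si)
  rk <- sqrt(K)
  B <- Qs * (rk %o% rk)                  # symmetric PSD
  A <- diag(m) + (B + t(B)) / 2
  # G_s = Qs (I + K Qs)^{-1}; use (I + K Qs)^{-1} = I - K^{1/2}A^{-1}K^{1/2}Qs
  # (push-through identity), so G_s = Qs - Qs K^{1/2} A^{-1} K^{1/2} Qs.
  X <- t(Qs * rk)                         # Qs %*% diag(rk) (Qs symmetric)
  Gs <- Qs - X %*% solve(A, t(X))
  # back to Sigma^{-1} Q (...)^{-1} frame: G = Sigma^{-1/2} Gs Sigma^{1/2};
  # the diagonal (all we ever use downstream) is unchanged, but return the
  # full matrix for Hessian computations.
  Gs * (si %o% (1 / si))
}

# Hessian of mutual_information: H = -1/2 (G * t(G)) elementwise, with G
# the resolvent above. Negative semi-definite (the objective is concave).
mi_hessian <- function(K, Q, sigma2) {
  G <- mi_resolvent(K, Q, sigma2)
  -0.5 * (G * t(G))
}

# Accept receptor_distribution or numeric vector; validate length and sign.
distribution_vector <- function(K, m) {
  if (inherits(K, "receptor_distribution")) K <- K$K
  K <- as.numeric(K)
  if (length(K) == 1L && m > 1L) stop("`K` must have length ", m)
  if (length(K) != m) stop("`K` has length ", length(K), ", expected ", m)
  if (!all(is.finite(K))) stop("`K` must be finite")
  if (any(K < 0)) {
    tol <- 1e-9 * max(sum(K), 1)
    if (any(K < -tol)) stop("`K` must be non-negative")
    K[K < 0] <- 0
  }
  K
}

#' Calibrate a noise profile to a target signal-to-noise ratio
#'
#' The information objective depends on abundances, signal and noise only
#' through the glomerular SNR matrix `K Sigma^{-1} Q`, so the regime of the
#' model (noise-dominated, intermediate, or effectively noiseless) is set
#' by the noise variance relative to the signal variance and the neuron
#' budget. This helper returns the flat noise profile for which the
#' per-glomerulus SNR^2 at the uniform allocation,
#' `(Ktot / M) * mean(diag(Q)) / sigma^2`, equals `snr2`. Intermediate
#' values (order 1-10) put the model in the regime where receptor
#' abundances are non-uniform and adapt visibly to the environment.
#'
#' @param Q Overlap matrix.
#' @param Ktot Total OSN budget the calibration refers to.
#' @param snr2 Target squared SNR per glomerulus at uniform allocation.
#' @return A [noise_profile] with equal variances.
#' @export
calibrate_noise <- function(Q, Ktot, snr2 = 10) {
  m <- nrow(Q)
  noise_profile(rep((Ktot / m) * mean(diag(Q)) / snr2, m))
}
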