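# Fixture builders shared across test files. All randomness is drawn from
# the caller's RNG state; tests set their own seeds.

# Random symmetric PSD matrix with eigenvalues of order `scale`.
random_psd <- function(m, scale = 1, df = 2 * m) {
  A <- matrix(rnorm(m * df), m)
  Q <- A %*% t(A) / df * scale
  (Q + t(Q)) / 2
}

# A random small problem instance: overlap matrix, noise, budget.
random_instance <- function(m, scale = 1, Ktot = 10) {
  list(
    Q = random_psd(m, scale),
    sigma2 = runif(m, 0.5, 2),
    Ktot = Ktot
  )
}

# Closed-form det(I + K Sigma^{-1} Q) for M = 2 and 3, vectorized over
# abundance vectors. Independent of the package's eigen-based path; used as
# the exhaustive grid-search oracle.
det_2x2 <- function(k1, k2, Q, sigma2) {
  d1 <- k1 / sigma2[1]; d2 <- k2 / sigma2[2]
  (1 + d1 * Q[1, 1]) * (1 + d2 * Q[2, 2]) - d1 * d2 * Q[1, 2]^2
}
det_3x3 <- function(k1, k2, k3, Q, sigma2) {
  d1 <- k1 / sigma2[1]; d2 <- k2 / sigma2[2]; d3 <- k3 / sigma2[3]
  m12 <- Q[1, 1] * Q[2, 2] - Q[1, 2]^2
  m13 <- Q[1, 1] * Q[3, 3] - Q[1, 3]^2
  m23 <- Q[2, 2] * Q[3, 3] - Q[2, 3]^2
  1 + d1 * Q[1, 1] + d2 * Q[2, 2] + d3 * Q[3, 3] +
    d1 * d2 * m12 + d1 * d3 * m13 + d2 * d3 * m23 +
    d1 * d2 * d3 * det(Q)
}

# Exhaustive simplex grid search for the maximal information, M in {2, 3},
# grid resolution Ktot / n_grid. Returns the best information in nats.
grid_search_info <- function(Q, sigma2, Ktot, n_grid = 2000) {
  m <- nrow(Q)
  step <- Ktot / n_grid
  if (m == 2) {
    k1 <- seq(0, Ktot, by = step)
    dets <- det_2x2(k1, Ktot - k1, Q, sigma2)
    0.5 * max(log(dets))
  } else if (m == 3) {
    best <- -Inf
    for (i in 0:n_grid) {
      k1 <- i * step
      k2 <- seq(0, Ktot - k1, by = step)
      dets <- det_3x3(k1, k2, Ktot - k1 - k2, Q, sigma2)
      best <- max(best, max(log(dets)))
    }
    0.5 * best
  } else {
    stop("grid search oracle supports M in {2, 3}")
  }
}

# Monte-Carlo covariance of noiseless responses S %*% c, c ~ N(c0, Gamma).
mc_overlap <- function(S, gamma, c0 = NULL, n = 1e5) {
  n_od <- ncol(S)
  if (is.null(c0)) c0 <- numeric(n_od)
  L <- chol(gamma + 1e-12 * mean(diag(gamma)) * diag(n_od))
  C <- matrix(rnorm(n * n_od), n) %*% L
  C <- sweep(C, 2, c0, "+")
  stats::cov(C %*% t(S))
}
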