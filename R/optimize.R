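# Constrained information maximization over OSN abundances:
#   maximize 1/2 Tr log(I + K Sigma^{-1} Q)  s.t.  K >= 0, sum(K) = Ktot.
#
# The objective is concave in K: with v_a = Gamma^{1/2} S_a^T,
# det(I + K Sigma^{-1} Q) = det(I_N + sum_a (K_a / sigma_a^2) v_a v_a^T),
# a logdet of an affine function of K. The solver is projected gradient
# ascent (Barzilai-Borwein steps, Euclidean simplex projection) followed by
# an active-set Newton polish using the analytic Hessian; concavity makes
# the optimum unique in value, so a single deterministic start suffices.

#' Information-optimal receptor distribution
#'
#' Solves for the OSN abundances that maximize the mutual information
#' between glomerular responses and odor scenes subject to a fixed total
#' neuron budget and non-negativity. This is the correlated-channel
#' analogue of water-filling: at the optimum all expressed receptor types
#' share a common marginal information gain (the KKT multiplier), while
#' unexpressed types have a lower gain.
#'
#' @param S A [sensing_matrix] or M x N matrix. Alternatively supply `Q`.
#' @param env An [odor_environment] or N x N covariance matrix.
#' @param noise A [noise_profile], positive vector, or scalar (recycled).
#' @param Ktot Total OSN budget (> 0).
#' @param Q Optional precomputed overlap matrix; overrides `S`/`env`.
#' @param K0 Optional starting point (defaults to the uniform distribution).
#' @param n_restarts Number of additional random (Dirichlet) starts. The
#'   objective is concave so the default is 0; restarts are retained as a
#'   safeguard for near-degenerate problems. Randomness uses the session RNG.
#' @param tol Relative KKT residual required for convergence.
#' @param max_iter Iteration cap for the projected-gradient phase.
#' @param bits Report the achieved information in bits instead of nats.
#' @return An object of class `osn_optimum`: fields `K`
#'   ([receptor_distribution]), `info` (achieved information), `gradient`,
#'   `multiplier` (KKT multiplier, the common gradient on the active set),
#'   `kkt_residual`, `n_restarts_used`, `converged`.
#' @seealso [highsnr_distribution()], [lowsnr_support()], [kkt_residual()]
#' @examples
#' opt <- optimal_distribution(Q = diag(c(2, 1)), noise = 1, Ktot = 10)
#' opt$K$K  # c(5.25, 4.75): water-filling on two independent channels
#' @export
optimal_distribution <- function(S = NULL, env = NULL, noise, Ktot,
                                 Q = NULL, K0 = NULL, n_restarts = 0,
                                 tol = 1e-6, max_iter = 1e4, bits = FALSE) {
  if (is.null(Q)) Q <- overlap_matrix(S, env)
  m <- nrow(Q)
  if (!is.numeric(Ktot) || length(Ktot) != 1L || !is.finite(Ktot) || Ktot <= 0) {
    stop("`Ktot` must be a positive scalar")
  }
  noise <- as_noise(noise, m)
  sigma2 <- noise$sigma2
  if (length(sigma2) != m) stop("noise profile length mismatch")
  Q <- clip_psd((Q + t(Q)) / 2)

  if (m == 1L) {
    K <- Ktot
    info <- mutual_information(K, Q, noise)
    g <- mi_gradient(K, Q, noise)
    return(new_osn_optimum(K, Ktot, info, g, g, 0, 0L, TRUE, Q, noise, bits))
  }

  starts <- list(if (is.null(K0)) rep(Ktot / m, m)
                 else distribution_vector(K0, m) * (Ktot / sum(K0)))
  if (n_restarts > 0) {
    for (i in seq_len(n_restarts)) {
      w <- stats::rgamma(m, shape = 1)
      starts[[i + 1L]] <- Ktot * w / sum(w)
    }
  }

  best <- NULL
  for (i in seq_along(starts)) {
    fit <- solve_simplex_concave(starts[[i]], Q, sigma2, Ktot, tol, max_iter)
    if (is.null(best) || fit$info > best$info) {
      best <- fit
      best$n_restarts_used <- i - 1L
    }
    if (best$converged && i == 1L && n_restarts == 0) break
  }
  if (!best$converged) {
    warning("optimizer did not reach KKT residual ", format(tol),
            " (achieved ", format(best$residual), ")")
  }
  new_osn_optimum(best$K, Ktot, best$info, best$gradient, best$multiplier,
                 best$residual, best$n_restarts_used, best$converged,
                 Q, noise, bits)
}

new_osn_optimum <- function(K, Ktot, info, gradient, multiplier, residual,
                            n_restarts_used, converged, Q, noise, bits) {
  labels <- rownames(Q)
  K <- as.numeric(K)
  if (!is.null(labels)) names(K) <- labels
  structure(
    list(
      K = receptor_distribution(K, Ktot),
      info = if (bits) info / log(2) else info,
      bits = bits,
      gradient = gradient,
      multiplier = as.numeric(multiplier),
      kkt_residual = residual,
      n_restarts_used = as.integer(n_restarts_used),
      converged = converged
    ),
    class = "osn_optimum"
  )
}

#' @export
print.osn_optimum <- function(x, ...) {
  cat("<osn_optimum> M = ", length(x$K$K), ", Ktot = ", format(x$K$Ktot),
      "\n  information: ", format(x$info, digits = 8),
      if (x$bits) " bits" else " nats",
      "\n  expressed types: ", sum(x$K$K > 0),
      "\n  KKT residual: ", format(x$kkt_residual, digits = 3),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}

# Core solver; returns list(K, info, gradient, multiplier, residual, converged).
solve_simplex_concave <- function(K, Q, sigma2, Ktot, tol, max_iter) {
  m <- length(K)
  noise <- noise_profile(sigma2)
  obj <- function(K) mutual_information(K, Q, noise)
  grad <- function(K) 0.5 * diag(mi_resolvent(K, Q, sigma2))

  f <- obj(K)
  g <- grad(K)
  step <- Ktot / max(sum(abs(g)), 1e-12)
  K_prev <- NULL
  g_prev <- NULL
  iter <- 0L

  repeat {
    iter <- iter + 1L
    res <- kkt_residual_core(K, g, Ktot)
    if (res$residual <= tol || iter > max_iter) break

    # Newton polish once the active set looks settled: equality-constrained
    # Newton step on the free set, truncated at the boundary.
    if (iter > 3L) {
      pol <- newton_polish(K, Q, sigma2, Ktot, tol, obj, grad)
      if (!is.null(pol)) {
        K <- pol$K; f <- pol$f; g <- pol$g
        res <- kkt_residual_core(K, g, Ktot)
        if (res$residual <= tol) break
      }
    }

    # Barzilai-Borwein spectral step with projection and backtracking.
    if (!is.null(K_prev)) {
      dK <- K - K_prev
      dg <- g - g_prev
      denom <- -sum(dK * dg)          # > 0 for concave f
      step <- if (denom > 1e-300) sum(dK * dK) / denom else step * 2
      step <- min(max(step, 1e-12 * Ktot), 1e12 * Ktot)
    }
    K_prev <- K
    g_prev <- g
    repeat {
      K_new <- project_simplex(K + step * g, Ktot)
      f_new <- obj(K_new)
      if (f_new >= f - 1e-12 * abs(f) || step < 1e-14 * Ktot) break
      step <- step / 2
    }
    K <- K_new
    f <- f_new
    g <- grad(K)
  }

  list(K = K, info = f, gradient = g, multiplier = res$mu,
       residual = res$residual, converged = res$residual <= tol)
}

# One equality-constrained Newton step restricted to the current free set,
# iterated to convergence while the free set is stable. Returns NULL if the
# step is not useful (e.g. singular system).
newton_polish <- function(K, Q, sigma2, Ktot, tol, obj, grad) {
  m <- length(K)
  for (outer in 1:30) {
    g <- grad(K)
    res <- kkt_residual_core(K, g, Ktot)
    if (res$residual <= tol * 0.1) break
    free <- which(K > 0 | g > res$mu)
    if (length(free) < 1L) return(NULL)
    H <- mi_hessian(K, Q, sigma2)[free, free, drop = FALSE]
    nf <- length(free)
    # KKT system: [-H 1; 1' 0] [d; nu] = [g_free - mu; 0]
    A <- rbind(cbind(-H + diag(1e-14 * max(abs(H), 1e-300), nf), rep(1, nf)),
               c(rep(1, nf), 0))
    rhs <- c(g[free], 0)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    d <- numeric(m)
    d[free] <- sol[seq_len(nf)]
    # truncate at the non-negativity boundary
    hit <- d < 0 & K > 0
    alpha <- if (any(hit)) min(1, min(-K[hit] / d[hit])) else 1
    if (!is.finite(alpha) || alpha <= 0) return(NULL)
    K_new <- pmax(K + alpha * d, 0)
    K_new <- K_new * (Ktot / sum(K_new))
    if (obj(K_new) < obj(K) - 1e-12) {  # safeguard: shrink toward K
      alpha <- alpha / 4
      K_new <- pmax(K + alpha * d, 0)
      K_new <- K_new * (Ktot / sum(K_new))
      if (obj(K_new) < obj(K) - 1e-12) return(NULL)
    }
    if (max(abs(K_new - K)) <= 1e-15 * Ktot) { K <- K_new; break }
    K <- K_new
  }
  g <- grad(K)
  list(K = K, f = obj(K), g = g)
}

# Relative KKT residual and multiplier estimate for a feasible K.
kkt_residual_core <- function(K, g, Ktot, active_tol = NULL) {
  if (is.null(active_tol)) active_tol <- 1e-9 * max(Ktot, 1)
  active <- K > active_tol
  if (!any(active)) stop("empty active set: all abundances at zero")
  mu <- max(g[active])
  spread <- mu - min(g[active])
  inactive_violation <- if (all(active)) 0 else max(0, max(g[!active]) - mu)
  denom <- max(abs(mu), 1e-300)
  list(residual = max(spread, inactive_violation) / denom, mu = mu)
}

#' KKT residual of a feasible receptor distribution
#'
#' Measures how far a feasible abundance vector is from first-order
#' optimality: the spread of the information gradient over expressed
#' receptor types, together with any excess gradient on unexpressed types,
#' normalized by the multiplier estimate (the maximum active gradient).
#' Zero at a true optimum.
#'
#' @param K A [receptor_distribution] or non-negative vector summing to `Ktot`.
#' @param Q Overlap matrix.
#' @param noise A [noise_profile], positive vector or scalar.
#' @param Ktot Total budget; defaults to `sum(K)`.
#' @param active_tol Threshold above which a receptor counts as expressed
#'   (default `1e-9 * Ktot`).
#' @return Non-negative scalar residual.
#' @examples
#' kkt_residual(c(5.25, 4.75), diag(c(2, 1)), 1)
#' @export
kkt_residual <- function(K, Q, noise, Ktot = NULL, active_tol = NULL) {
  K <- distribution_vector(K, nrow(Q))
  if (is.null(Ktot)) Ktot <- sum(K)
  noise <- as_noise(noise, nrow(Q))
  g <- mi_gradient(K, Q, noise)
  kkt_residual_core(K, g, Ktot, active_tol)$residual
}

#' High-SNR closed form for the optimal receptor distribution
#'
#' In the large-budget limit the optimum approaches
#' `K_a = Ktot / M - (sigma_a^2 A_aa - mean_b(sigma_b^2 A_bb))` with
#' `A = Q^{-1}`: a uniform allocation corrected by the noise-scaled
#' diagonal of the inverse overlap matrix. The formula is an asymptotic
#' approximation and can return negative entries at moderate budgets;
#' these are returned raw unless `project = TRUE`.
#'
#' @param Q Invertible overlap matrix.
#' @param noise A [noise_profile], positive vector or scalar.
#' @param Ktot Total OSN budget.
#' @param project If `TRUE`, project the raw formula onto the simplex.
#' @return Length-M vector summing to `Ktot` (exactly, by construction).
#' @examples
#' highsnr_distribution(diag(2), 1, 10)  # uniform: c(5, 5)
#' @export
highsnr_distribution <- function(Q, noise, Ktot, project = FALSE) {
  m <- nrow(Q)
  noise <- as_noise(noise, m)
  A <- tryCatch(solve(Q), error = function(e) {
    stop("overlap matrix is singular; regularize Q (e.g. add a small ",
         "multiple of the identity) before using the high-SNR formula")
  })
  d <- noise$sigma2 * diag(A)
  K <- Ktot / m - (d - mean(d))
  if (project) K <- project_simplex(K, Ktot)
  if (!is.null(rownames(Q))) names(K) <- rownames(Q)
  K
}

#' Receptor favored in the small-population (low-SNR) limit
#'
#' With very few neurons the optimum concentrates the whole budget on the
#' single receptor whose signal variance relative to noise, `Q_aa /
#' sigma_a^2`, is largest. Ties are broken toward the lowest index.
#'
#' @param Q Overlap matrix.
#' @param noise A [noise_profile], positive vector or scalar.
#' @return Integer index (1-based) of the favored receptor type.
#' @examples
#' lowsnr_support(diag(c(1, 5, 2)), c(1, 25, 1))  # 3: 2/1 beats 5/25
#' @export
lowsnr_support <- function(Q, noise) {
  noise <- as_noise(noise, nrow(Q))
  which.max(diag(Q) / noise$sigma2)
}

#' Number of expressed receptor types as the OSN budget grows
#'
#' For each total budget in `Ktot_grid`, solves the information
#' maximization and counts receptor types with abundance above
#' `expression_threshold * Ktot / M`. Receptor diversity increases in step
#' transitions as the budget (hence SNR) grows, from a single type at tiny
#' budgets to all M types at large ones.
#'
#' @inheritParams optimal_distribution
#' @param Ktot_grid Strictly increasing vector of total budgets.
#' @param expression_threshold Fraction of the uniform abundance above
#'   which a type counts as expressed (default `1e-3`).
#' @param ... Passed to [optimal_distribution()].
#' @return Data frame with columns `Ktot`, `n_expressed`, `info`.
#' @export
receptor_count_curve <- function(S = NULL, env = NULL, noise, Ktot_grid,
                                 expression_threshold = 1e-3, Q = NULL, ...) {
  if (length(Ktot_grid) == 0) stop("`Ktot_grid` is empty")
  if (any(diff(Ktot_grid) <= 0)) stop("`Ktot_grid` must be strictly increasing")
  if (is.null(Q)) Q <- overlap_matrix(S, env)
  m <- nrow(Q)
  rows <- lapply(Ktot_grid, function(kt) {
    opt <- optimal_distribution(noise = noise, Ktot = kt, Q = Q, ...)
    data.frame(
      Ktot = kt,
      n_expressed = sum(opt$K$K > expression_threshold * kt / m),
      info = opt$info
    )
  })
  do.call(rbind, rows)
}

# Euclidean projection onto {x >= 0, sum(x) = total}.
project_simplex <- function(x, total) {
  n <- length(x)
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u) - total
  rho <- max(which(u - css / seq_len(n) > 0))
  theta <- css[rho] / rho
  pmax(x - theta, 0)
}
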