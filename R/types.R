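# S3 containers for the olfactory efficient-coding model:
# odor environment (Gaussian scene statistics), sensing matrix,
# per-receptor noise profile, and receptor (OSN) distribution.

#' Gaussian odor environment
#'
#' Describes the statistics of olfactory scenes as a multivariate Gaussian
#' over odorant concentrations, with mean vector `c0` and covariance matrix
#' `gamma`. Only the covariance affects the information-optimal receptor
#' distribution; the mean corresponds to odors that are always present and
#' carries no information about scene-to-scene variation.
#'
#' @param gamma N x N symmetric positive semi-definite covariance matrix of
#'   odorant concentrations (concentration units squared). Eigenvalues in
#'   `[-1e-10 * max eigenvalue, 0)` are treated as rounding error and
#'   clipped to zero; more negative eigenvalues are an error.
#' @param c0 Length-N vector of mean concentrations. Default all zero.
#' @param odorant_labels Character vector of N unique odorant names.
#'   Defaults to dimnames of `gamma`, else `odorant_1 ...`.
#' @return An object of class `odor_environment` with fields `c0`, `gamma`,
#'   `odorant_labels`.
#' @examples
#' env <- odor_environment(diag(3))
#' env$gamma
#' @export
odor_environment <- function(gamma, c0 = NULL, odorant_labels = NULL) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != ncol(gamma)) {
    stop("`gamma` must be square, got ", nrow(gamma), " x ", ncol(gamma))
  }
  n <- nrow(gamma)
  if (!all(is.finite(gamma))) stop("`gamma` contains non-finite entries")
  asym <- max(abs(gamma - t(gamma)))
  scale <- max(abs(gamma), 1e-300)
  if (asym > 1e-8 * scale) {
    stop("`gamma` is asymmetric beyond tolerance (max asymmetry ",
         format(asym), ")")
  }
  gamma <- (gamma + t(gamma)) / 2
  gamma <- clip_psd(gamma)

  if (is.null(c0)) c0 <- numeric(n)
  c0 <- as.numeric(c0)
  if (length(c0) != n) {
    stop("`c0` has length ", length(c0), " but `gamma` is ", n, " x ", n)
  }
  if (is.null(odorant_labels)) {
    odorant_labels <- rownames(gamma)
    if (is.null(odorant_labels)) {
      odorant_labels <- paste0("odorant_", seq_len(n))
    }
  }
  odorant_labels <- as.character(odorant_labels)
  if (length(odorant_labels) != n) stop("need ", n, " odorant labels")
  if (anyDuplicated(odorant_labels)) stop("odorant labels must be unique")
  dimnames(gamma) <- list(odorant_labels, odorant_labels)
  names(c0) <- odorant_labels

  structure(
    list(c0 = c0, gamma = gamma, odorant_labels = odorant_labels),
    class = "odor_environment"
  )
}

#' Receptor sensing matrix
#'
#' The M x N matrix of expected single-neuron responses per unit odorant
#' concentration: entry `(a, i)` is the mean response of one sensory neuron
#' expressing receptor type `a` to a unit concentration of odorant `i`.
#'
#' @param S Numeric M x N matrix with finite entries.
#' @param receptor_labels,odorant_labels Unique label vectors; default to
#'   dimnames of `S`, else generated.
#' @return An object of class `sensing_matrix`.
#' @examples
#' sm <- sensing_matrix(matrix(rnorm(12), 3, 4))
#' dim(sm$S)
#' @export
sensing_matrix <- function(S, receptor_labels = NULL, odorant_labels = NULL) {
  S <- as.matrix(S)
  if (!is.numeric(S) || !all(is.finite(S))) {
    stop("`S` must be a numeric matrix with finite entries")
  }
  if (is.null(receptor_labels)) {
    receptor_labels <- rownames(S)
    if (is.null(receptor_labels)) {
      receptor_labels <- paste0("receptor_", seq_len(nrow(S)))
    }
  }
  if (is.null(odorant_labels)) {
    odorant_labels <- colnames(S)
    if (is.null(odorant_labels)) {
      odorant_labels <- paste0("odorant_", seq_len(ncol(S)))
    }
  }
  receptor_labels <- as.character(receptor_labels)
  odorant_labels <- as.character(odorant_labels)
  if (length(receptor_labels) != nrow(S)) stop("receptor label length mismatch")
  if (length(odorant_labels) != ncol(S)) stop("odorant label length mismatch")
  if (anyDuplicated(receptor_labels)) stop("receptor labels must be unique")
  if (anyDuplicated(odorant_labels)) stop("odorant labels must be unique")
  dimnames(S) <- list(receptor_labels, odorant_labels)
  structure(
    list(S = S, receptor_labels = receptor_labels,
         odorant_labels = odorant_labels),
    class = "sensing_matrix"
  )
}

#' Per-receptor noise profile
#'
#' Single-neuron response noise variances, one per receptor type. Noise is
#' modeled as additive Gaussian per neuron; pooling `K` neurons of a type
#' scales the summed-noise standard deviation by `sqrt(K)`.
#'
#' @param sigma2 Length-M vector of strictly positive noise variances
#'   (response units squared). A scalar is recycled to length `m`.
#' @param m Optional number of receptors, used to recycle a scalar.
#' @return An object of class `noise_profile`.
#' @examples
#' noise_profile(1, m = 24)
#' @export
noise_profile <- function(sigma2, m = NULL) {
  sigma2 <- as.numeric(sigma2)
  if (!is.null(m) && length(sigma2) == 1L) sigma2 <- rep(sigma2, m)
  if (!all(is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("noise variances must be finite and > 0")
  }
  structure(list(sigma2 = sigma2), class = "noise_profile")
}

#' Receptor (OSN) distribution
#'
#' Real-valued counts of olfactory sensory neurons per receptor type,
#' constrained to be non-negative and to sum to the total budget `Ktot`.
#'
#' @param K Length-M vector of OSN counts (treated as real numbers).
#'   Entries in `[-1e-9 * Ktot, 0)` are clipped to zero.
#' @param Ktot Total neuron budget; defaults to `sum(K)`. `sum(K)` must
#'   match within `1e-6 * Ktot`.
#' @return An object of class `receptor_distribution` with fields `K`, `Ktot`.
#' @examples
#' receptor_distribution(c(3, 7))
#' @export
receptor_distribution <- function(K, Ktot = NULL) {
  K <- as.numeric(K)
  if (!all(is.finite(K))) stop("`K` must be finite")
  if (is.null(Ktot)) Ktot <- sum(K)
  if (Ktot < 0) stop("`Ktot` must be non-negative")
  tol0 <- 1e-9 * max(Ktot, 1)
  if (any(K < -tol0)) {
    stop("negative OSN counts (min ", format(min(K)), ")")
  }
  K[K < 0] <- 0
  if (abs(sum(K) - Ktot) > 1e-6 * max(Ktot, 1)) {
    stop("sum(K) = ", format(sum(K)), " does not match Ktot = ", format(Ktot))
  }
  structure(list(K = K, Ktot = Ktot), class = "receptor_distribution")
}

#' @export
print.odor_environment <- function(x, ...) {
  cat("<odor_environment> ", length(x$c0), " odorants\n", sep = "")
  v <- diag(x$gamma)
  cat("  variance range: [", format(min(v), digits = 4), ", ",
      format(max(v), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.sensing_matrix <- function(x, ...) {
  cat("<sensing_matrix> ", nrow(x$S), " receptors x ", ncol(x$S),
      " odorants\n", sep = "")
  invisible(x)
}

#' @export
print.receptor_distribution <- function(x, ...) {
  cat("<receptor_distribution> M = ", length(x$K),
      ", Ktot = ", format(x$Ktot), "\n", sep = "")
  cat("  expressed types (K > 0): ", sum(x$K > 0), "\n", sep = "")
  invisible(x)
}

# Clip tiny negative eigenvalues arising from rounding; error on genuinely
# indefinite input. Tolerance: eigenvalues >= -1e-10 * max eigenvalue pass.
clip_psd <- function(gamma) {
  e <- eigen(gamma, symmetric = TRUE)
  lmax <- max(e$values, 0)
  lmin <- min(e$values)
  if (lmin < -1e-10 * max(lmax, 1e-300)) {
    stop("matrix is not positive semi-definite: min eigenvalue ",
         format(lmin), " vs max ", format(lmax))
  }
  if (lmin < 0) {
    vals <- pmax(e$values, 0)
    gamma <- e$vectors %*% (vals * t(e$vectors))
    gamma <- (gamma + t(gamma)) / 2
  }
  gamma
}

# Coerce helpers: accept bare matrices/vectors where a typed object is
# expected, so internal code can be called with plain numerics in tests.
as_env <- function(env) {
  if (inherits(env, "odor_environment")) env else odor_environment(env)
}
as_sensing <- function(S) {
  if (inherits(S, "sensing_matrix")) S else sensing_matrix(S)
}
as_noise <- function(noise, m) {
  if (inherits(noise, "noise_profile")) {
    if (length(noise$sigma2) == 1L && m > 1L) noise_profile(noise$sigma2, m)
    else noise
  } else {
    noise_profile(noise, m)
  }
}
as_distribution <- function(K, Ktot = NULL) {
  if (inherits(K, "receptor_distribution")) K
  else receptor_distribution(K, Ktot)
}
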