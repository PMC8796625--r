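#' Construct an autoregressive hidden Markov model
#'
#' An ARHMM couples a K-state Markov chain with state-specific linear
#' (autoregressive) observation dynamics: given state k, the P-dimensional
#' observation follows
#' \deqn{y_t = A_k^{(1)} y_{t-1} + \dots + A_k^{(L)} y_{t-L} + b_k + \epsilon_t,
#'   \quad \epsilon_t \sim N(0, Q_k).}
#' Behavioral syllables correspond to recurring states of these switching
#' dynamics.
#'
#' @param trans K x K row-stochastic transition matrix.
#' @param A list of length K; element k is a P x (L*P) matrix of stacked AR
#'   coefficient blocks `[A^(1) ... A^(L)]`.
#' @param b list of length K of P-vectors (per-state intercepts).
#' @param Q list of length K of P x P symmetric positive-definite innovation
#'   covariances.
#' @param init length-K initial state distribution; default stationary
#'   distribution of `trans`.
#' @param L AR lag order (inferred from `A` when omitted).
#' @return An object of class `arhmm_model`.
#' @export
arhmm_model <- function(trans, A, b, Q, init = NULL, L = NULL) {
  trans <- as.matrix(trans)
  K <- nrow(trans)
  P <- length(b[[1L]])
  if (is.null(L)) L <- ncol(A[[1L]]) / P
  if (L != round(L)) stop("AR coefficient width is not a multiple of P")
  if (is.null(init)) init <- stationary_distribution(trans)
  m <- structure(
    list(K = K, P = P, L = as.integer(L), trans = trans,
         A = A, b = b, Q = Q, init = init),
    class = "arhmm_model")
  validate_arhmm(m)
  m
}

validate_arhmm <- function(m) {
  with(m, {
    if (ncol(trans) != K) stop("transition matrix must be square")
    if (any(trans < 0)) stop("transition matrix has negative entries")
    if (any(abs(rowSums(trans) - 1) > 1e-12))
      stop("transition rows must sum to 1 (non-stochastic transition matrix)")
    if (abs(sum(init) - 1) > 1e-8) stop("initial distribution must sum to 1")
    if (length(A) != K || length(b) != K || length(Q) != K)
      stop("A, b, Q must each have one element per state")
    for (k in seq_len(K)) {
      if (!isTRUE(all.equal(Q[[k]], t(Q[[k]]), tolerance = 1e-8)))
        stop("innovation covariance must be symmetric")
      ev <- eigen(Q[[k]], symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 0)) stop("innovation covariance must be positive-definite")
    }
  })
  invisible(m)
}

#' @export
print.arhmm_model <- function(x, ...) {
  cat(sprintf("ARHMM: K = %d states, P = %d dims, AR lag L = %d\n",
              x$K, x$P, x$L))
  occ <- stationary_distribution(x$trans)
  cat("stationary occupancy:", paste(sprintf("%.3f", occ), collapse = " "), "\n")
  invisible(x)
}

#' Randomly generate a well-posed ARHMM
#'
#' Builds a stable K-state model whose states differ both in their fixed
#' points (drawn at distance `mean_sep` from the origin) and in their
#' rotational AR dynamics — the kind of separation expected between distinct
#' behavioral syllables in pose-feature space. The chain is sticky, with
#' per-state stay probability `stay` and Dirichlet-distributed exits, giving
#' bout durations of roughly `1 / (1 - stay)` frames.
#'
#' @param K number of states (study-scale default 15).
#' @param P observation dimensionality (study-scale default 15).
#' @param L AR lag order (only `L = 1` generation is implemented).
#' @param seed RNG seed.
#' @param stay per-state self-transition probability.
#' @param ar_coef modulus of the AR eigenvalues (< 1 for stability).
#' @param mean_sep distance of each state's fixed point from the origin, in
#'   units of the innovation SD.
#' @param noise_sd innovation standard deviation (isotropic).
#' @return An `arhmm_model`.
#' @export
random_arhmm <- function(K = 15, P = 15, L = 1L, seed = 1L, stay = 0.94,
                         ar_coef = 0.85, mean_sep = 10, noise_sd = 1) {
  if (L != 1L) stop("random model generation implemented for L = 1")
  set.seed(check_seed(seed))
  A <- b <- Q <- vector("list", K)
  for (k in seq_len(K)) {
    # random orthogonal matrix scaled to modulus ar_coef: stable rotation
    M <- matrix(rnorm(P * P), P, P)
    O <- qr.Q(qr(M))
    A[[k]] <- ar_coef * O
    dir <- rnorm(P)
    mu <- mean_sep * noise_sd * dir / sqrt(sum(dir^2))
    b[[k]] <- as.vector((diag(P) - A[[k]]) %*% mu)
    Q[[k]] <- diag(noise_sd^2, P)
  }
  trans <- matrix(0, K, K)
  for (k in seq_len(K)) {
    if (K == 1L) { trans[k, k] <- 1; next }
    ex <- rgamma(K - 1L, shape = 2)
    trans[k, -k] <- (1 - stay) * ex / sum(ex)
    trans[k, k] <- stay
  }
  arhmm_model(trans, A, b, Q, L = 1L)
}

# Stationary observation distribution (mean, covariance) of state k's AR(1).
state_stationary <- function(model, k) {
  if (model$L != 1L)
    stop("stationary observation distribution implemented for L = 1")
  A <- model$A[[k]]
  mu <- solve(diag(model$P) - A, model$b[[k]])
  S <- stationary_cov(A, model$Q[[k]])
  list(mean = as.vector(mu), cov = (S + t(S)) / 2)
}
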