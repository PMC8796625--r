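#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of ground-truth states by decoded or consensus
#' labels. Pairs with `NA` in either labeling are dropped.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions up to label
#'   permutation, 0 is the chance level.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Best label permutation matching a reference labeling
#'
#' Exhaustively searches permutations of the candidate labels (feasible for
#' small K) for the one maximizing frame-wise agreement with the reference.
#' Used in recovery checks where state identities are arbitrary.
#'
#' @param labels integer labels in `1:K` (NA allowed).
#' @param reference integer labels in `1:K` of the same length.
#' @param K number of labels; defaults to the maximum seen.
#' @return list with `labels` (permuted input), `perm` (perm\[k\] is the new
#'   identity of original label k) and `accuracy`.
#' @export
match_labels <- function(labels, reference, K = max(c(labels, reference), na.rm = TRUE)) {
  if (K > 7L) stop("exhaustive matching supported for K <= 7")
  perms <- permutations_of(K)
  keep <- !(is.na(labels) | is.na(reference))
  best_acc <- -1
  best_perm <- seq_len(K)
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    acc <- mean(p[labels[keep]] == reference[keep])
    if (acc > best_acc) { best_acc <- acc; best_perm <- p }
  }
  out <- labels
  out[keep] <- best_perm[labels[keep]]
  list(labels = out, perm = best_perm, accuracy = best_acc)
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, nrow(sub) * K, K)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(K)) {
      out[row, ] <- append(sub[i, ], K, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Contiguous valid blocks of a logical mask
#'
#' @param mask logical vector; `TRUE` marks valid (non-gap) frames.
#' @return data.frame with `start` and `end` (inclusive) frame indices of each
#'   maximal run of `TRUE`.
#' @export
valid_blocks <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Draws n multivariate normal rows with given mean and chol(Sigma) upper factor.
rmvnorm_chol <- function(n, mean, chol_upper) {
  P <- length(mean)
  z <- matrix(rnorm(n * P), n, P)
  sweep(z %*% chol_upper, 2L, mean, "+")
}

# Solves the discrete Lyapunov equation S = A S A' + Q (stationary covariance
# of a stable VAR(1)), via the vectorized linear system.
stationary_cov <- function(A, Q) {
  P <- nrow(A)
  M <- diag(P * P) - kronecker(A, A)
  matrix(solve(M, as.vector(Q)), P, P)
}

#' Stationary distribution of a Markov transition matrix
#'
#' Leading left eigenvector of the transition matrix, normalized to sum to 1.
#'
#' @param trans row-stochastic K x K matrix.
#' @return length-K probability vector.
#' @export
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  as.integer(seed)
}

# Independent per-unit seeds derived from a master seed (kept below 2^31).
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(check_seed(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
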