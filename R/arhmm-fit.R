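# Internal: decompose score sessions into contiguous valid blocks and build
# the stacked AR design (lagged scores + intercept) shared by the E and M
# steps. Frames 1..L of each block have no AR context; their emission factor
# is constant (state-independent), so only frames L+1..n enter the design.
prepare_blocks <- function(sessions, L) {
  blocks <- list()
  Xl <- list(); Yl <- list()
  d <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    if (!inherits(s, "score_session")) stop("expected score_session inputs")
    vb <- valid_blocks(s$valid_mask)
    for (bi in seq_len(nrow(vb))) {
      a <- vb$start[bi]; b <- vb$end[bi]
      n <- b - a + 1L
      Y <- s$scores[a:b, , drop = FALSE]
      if (anyNA(Y)) stop("non-finite scores inside a valid block")
      ent <- list(session = si, start = a, end = b, n = n, d0 = NA_integer_,
                  d1 = NA_integer_, Y = Y)
      if (n > L) {
        P <- ncol(Y)
        lag_cols <- lapply(seq_len(L), function(l)
          Y[(L + 1L - l):(n - l), , drop = FALSE])
        X <- do.call(cbind, lag_cols)
        ent$d0 <- d + 1L
        ent$d1 <- d + (n - L)
        d <- ent$d1
        Xl[[length(Xl) + 1L]] <- X
        Yl[[length(Yl) + 1L]] <- Y[(L + 1L):n, , drop = FALSE]
      }
      blocks[[length(blocks) + 1L]] <- ent
    }
  }
  list(blocks = blocks,
       X = do.call(rbind, Xl),
       Y = do.call(rbind, Yl),
       n_design = d)
}

# Per-state AR-Gaussian log-density of each stacked design row.
emission_loglik <- function(prep, model) {
  K <- model$K; P <- model$P
  n <- prep$n_design
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    pred <- prep$X %*% t(model$A[[k]])
    pred <- sweep(pred, 2L, model$b[[k]], "+")
    res <- prep$Y - pred
    U <- chol(model$Q[[k]])
    halfsolve <- backsolve(U, t(res), transpose = TRUE)
    quad <- colSums(halfsolve^2)
    logdet <- 2 * sum(log(diag(U)))
    out[, k] <- -0.5 * (P * log(2 * pi) + logdet + quad)
  }
  if (any(!is.finite(out))) stop("non-finite likelihood")
  out
}

block_logB <- function(block, logE, K, L) {
  lb <- matrix(0, block$n, K)
  if (!is.na(block$d0))
    lb[(L + 1L):block$n, ] <- logE[block$d0:block$d1, , drop = FALSE]
  lb
}

# Weighted least-squares M-step for one state; returns A, b, Q.
mstep_state <- function(prep, w) {
  X1 <- cbind(prep$X, 1)
  sw <- sqrt(w)
  Xw <- X1 * sw
  Yw <- prep$Y * sw
  G <- crossprod(Xw)
  diag(G) <- diag(G) + 1e-10 * (1 + mean(diag(G)))
  beta <- solve(G, crossprod(Xw, Yw))
  p_lag <- ncol(prep$X)
  A <- t(beta[seq_len(p_lag), , drop = FALSE])
  b <- as.vector(beta[p_lag + 1L, ])
  res <- prep$Y - X1 %*% beta
  Q <- crossprod(res * sw, res * sw) / sum(w)
  Q <- (Q + t(Q)) / 2
  diag(Q) <- diag(Q) + 1e-9 * (1 + mean(diag(Q)))
  list(A = A, b = b, Q = Q)
}

# Seed-controlled initialization: multi-start k-means on lag-stacked scores.
# On large inputs k-means runs on a subsample and the remaining frames are
# assigned to the nearest center; single-start k-means tends to merge the
# two closest states, which EM cannot always undo.
init_arhmm <- function(prep, K, L, seed, n_starts = 10L,
                       max_kmeans_rows = 20000L) {
  set.seed(seed)
  Z <- cbind(prep$Y, prep$X)
  n <- nrow(Z)
  rows <- if (n > max_kmeans_rows) sample.int(n, max_kmeans_rows)
          else seq_len(n)
  km <- suppressWarnings(kmeans(Z[rows, , drop = FALSE], centers = K,
                                iter.max = 30L, nstart = n_starts))
  # assign every frame to its nearest center
  cross <- Z %*% t(km$centers)
  cn <- rowSums(km$centers^2)
  lab <- max.col(sweep(cross, 2L, cn / 2, "-"), ties.method = "first")
  gamma <- matrix(1e-3, prep$n_design, K)
  gamma[cbind(seq_along(lab), lab)] <- 1
  gamma / rowSums(gamma)
}

#' Fit an ARHMM to embedded sessions by expectation-maximization
#'
#' Baum-Welch EM with state-specific AR(L) Gaussian emissions, from a
#' seed-controlled k-means initialization on lag-stacked scores. The
#' likelihood factorizes over contiguous valid blocks: no transition is
#' counted across an acquisition gap, and the first `L` frames of each block
#' contribute a state-independent (constant) emission factor. Iteration stops
#' at the likelihood "equilibrium": when the relative improvement falls below
#' `tol`, or at `max_iter`. The total log-likelihood is non-decreasing across
#' iterations. A state left with (essentially) no assigned frames triggers a
#' re-seeded restart.
#'
#' @param sessions list of `score_session` objects (see [embed_sessions]).
#' @param K number of states (study default 15).
#' @param L AR lag order (default 1).
#' @param seed RNG seed controlling initialization.
#' @param max_iter maximum EM iterations.
#' @param tol stopping tolerance: iteration stops once the mean per-frame
#'   log-likelihood improvement falls below `tol` (default 1e-4 nats).
#' @param max_restarts re-seeded attempts allowed on state degeneracy.
#' @return object of class `arhmm_fit`: `model` ([arhmm_model]), `state_seqs`
#'   (per-session full-length Viterbi labels, `NA` in gaps), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
fit_arhmm <- function(sessions, K = 15, L = 1L, seed = 1L, max_iter = 200L,
                      tol = 1e-4, max_restarts = 3L) {
  if (K < 1) stop("K must be >= 1")
  seed <- check_seed(seed)
  prep <- prepare_blocks(sessions, L)
  if (is.null(prep$X)) stop("no valid block longer than L frames")
  P <- ncol(prep$Y)
  if (prep$n_design <= K * (L * P + 1))
    stop("too few valid frames for the requested K and L")

  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    res <- try(em_arhmm(prep, K, L, seed + 7919L * (attempt - 1L),
                        max_iter, tol), silent = TRUE)
    if (!inherits(res, "try-error")) break
    msg <- attr(res, "condition")$message
    if (!grepl("degenerate state", msg) || attempt > max_restarts)
      stop(msg)
    warning(sprintf("degenerate state; re-seeded restart %d", attempt),
            call. = FALSE)
  }

  model <- res$model
  state_seqs <- lapply(sessions, function(s) viterbi_decode(model, s))
  structure(
    list(model = model, state_seqs = state_seqs, loglik = res$loglik,
         loglik_trace = res$trace, n_iter = res$n_iter,
         converged = res$converged, seed = seed, K = K, L = L),
    class = "arhmm_fit")
}

em_arhmm <- function(prep, K, L, seed, max_iter, tol) {
  P <- ncol(prep$Y)
  gamma_d <- init_arhmm(prep, K, L, seed)
  pars <- lapply(seq_len(K), function(k) mstep_state(prep, gamma_d[, k]))
  # transitions from hard initial labels within blocks
  lab <- max.col(gamma_d)
  trans_c <- matrix(1 / K, K, K)
  init_c <- rep(1 / K, K)
  for (blk in prep$blocks) {
    if (is.na(blk$d0)) next
    l <- lab[blk$d0:blk$d1]
    if (length(l) > 1L)
      for (t in 2:length(l)) trans_c[l[t - 1L], l[t]] <- trans_c[l[t - 1L], l[t]] + 1
    init_c[l[1L]] <- init_c[l[1L]] + 1
  }
  trans <- trans_c / rowSums(trans_c)
  init <- init_c / sum(init_c)

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  model <- NULL
  repeat {
    iter <- iter + 1L
    model <- make_model(K, P, L, trans, pars, init)
    logE <- emission_loglik(prep, model)
    logA <- log(trans)
    logpi <- log(init)
    ll <- 0
    xi <- matrix(0, K, K)
    start_g <- rep(0, K)
    gamma_d <- matrix(0, prep$n_design, K)
    for (blk in prep$blocks) {
      lb <- block_logB(blk, logE, K, L)
      fb <- .fb_block(lb, logpi, logA)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi
      start_g <- start_g + fb$gamma[1L, ]
      if (!is.na(blk$d0))
        gamma_d[blk$d0:blk$d1, ] <- fb$gamma[(L + 1L):blk$n, , drop = FALSE]
    }
    trace <- c(trace, ll)
    if (ll < ll_prev - 1e-8 * (abs(ll_prev) + 1))
      warning("log-likelihood decreased during EM", call. = FALSE)
    # stop at the likelihood plateau: mean per-frame improvement below tol
    done <- is.finite(ll_prev) && (ll - ll_prev) / prep$n_design < tol
    if (done) converged <- TRUE
    if (done || iter >= max_iter) break
    ll_prev <- ll

    wsum <- colSums(gamma_d)
    if (any(wsum < L * P + 2)) stop("degenerate state in M-step")
    pars <- lapply(seq_len(K), function(k) mstep_state(prep, gamma_d[, k]))
    xs <- rowSums(xi)
    trans <- if (all(xs > 0)) xi / xs else matrix(1 / K, K, K)
    trans <- trans + 1e-12
    trans <- trans / rowSums(trans)
    init <- (start_g + 1e-12) / sum(start_g + 1e-12)
  }
  list(model = model, loglik = trace[length(trace)], trace = trace,
       n_iter = iter, converged = converged)
}

make_model <- function(K, P, L, trans, pars, init) {
  arhmm_model(trans,
              A = lapply(pars, `[[`, "A"),
              b = lapply(pars, `[[`, "b"),
              Q = lapply(pars, `[[`, "Q"),
              init = init, L = L)
}

#' @export
print.arhmm_fit <- function(x, ...) {
  cat(sprintf("ARHMM fit: K = %d, L = %d, seed %d; loglik %.2f after %d iterations (%s)\n",
              x$K, x$L, x$seed, x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Viterbi decoding of one embedded session
#'
#' Maximum a posteriori state path per contiguous valid block, with ties
#' broken toward the lowest state index. Blocks shorter than `L + 1` frames
#' carry no AR evidence and are labeled by the most probable initial state
#' (flagged via the `short_blocks` attribute).
#'
#' @param model an [arhmm_model].
#' @param session a `score_session`.
#' @return integer vector over all frames (1-based state labels, `NA` inside
#'   gaps), with attribute `short_blocks` counting under-length blocks.
#' @export
viterbi_decode <- function(model, session) {
  validate_arhmm(model)
  prep <- prepare_blocks(list(session), model$L)
  logE <- if (is.null(prep$X)) NULL else emission_loglik(prep, model)
  logA <- log(model$trans)
  logpi <- log(model$init)
  labels <- rep(NA_integer_, length(session$valid_mask))
  short <- 0L
  for (blk in prep$blocks) {
    if (is.na(blk$d0)) {          # block of length <= L: no dynamics evidence
      labels[blk$start:blk$end] <- which.max(model$init)
      short <- short + 1L
      next
    }
    lb <- block_logB(blk, logE, model$K, model$L)
    labels[blk$start:blk$end] <- .viterbi_block(lb, logpi, logA)
  }
  attr(labels, "short_blocks") <- short
  labels
}

#' Run an ensemble of independent ARHMM fits
#'
#' The per-frame state assignment of a single fit is partially stochastic
#' (it depends on the initialization seed), so the model is fitted R times
#' independently; the R state labels of each frame form its signature for
#' consensus clustering. Fit r uses seed `master_seed + r - 1`.
#'
#' @param sessions list of `score_session` objects.
#' @param K,L,max_iter,tol see [fit_arhmm].
#' @param R number of independent fits (study default 8).
#' @param master_seed base seed.
#' @param seeds optional explicit per-fit seeds overriding the default rule.
#' @return object of class `ensemble_result`: `fits` (list of `arhmm_fit`),
#'   `R`, `K`, `L`, `session_info`.
#' @export
run_ensemble <- function(sessions, K = 15, L = 1L, R = 8L, master_seed = 1L,
                         max_iter = 200L, tol = 1e-4, seeds = NULL) {
  if (R < 1) stop("R must be >= 1")
  if (is.null(seeds)) seeds <- check_seed(master_seed) + seq_len(R) - 1L
  if (length(seeds) != R) stop("need one seed per fit")
  fits <- vector("list", R)
  for (r in seq_len(R)) {
    fit <- try(fit_arhmm(sessions, K = K, L = L, seed = seeds[r],
                         max_iter = max_iter, tol = tol), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop(sprintf("ensemble fit with seed %d failed: %s", seeds[r],
                   attr(fit, "condition")$message))
    fit$fit_id <- r
    fits[[r]] <- fit
  }
  structure(
    list(fits = fits, R = R, K = K, L = L,
         session_info = data.frame(
           animal_id = vapply(sessions, `[[`, "", "animal_id"),
           genotype = vapply(sessions, `[[`, "", "genotype"),
           fps = vapply(sessions, `[[`, numeric(1), "fps"))),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ARHMM ensemble: R = %d fits, K = %d states, %d session(s)\n",
              x$R, x$K, nrow(x$session_info)))
  invisible(x)
}
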