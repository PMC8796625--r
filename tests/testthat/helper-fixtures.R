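# Shared fixtures: small ARHMMs, label chains, EEG traces with injected
# bursts, and independent oracles used across test files.

# sticky K-state transition matrix with uniform exits
base_trans <- function(K, stay = 0.95) {
  tm <- matrix((1 - stay) / (K - 1), K, K)
  diag(tm) <- stay
  tm
}

# well-separated small ARHMM used for recovery tests
sticky_arhmm <- function(K = 5, P = 5, seed = 42, stay = 0.95,
                         mean_sep = 8) {
  random_arhmm(K = K, P = P, seed = seed, stay = stay, mean_sep = mean_sep)
}

# full behavioral pipeline on a simulated cohort; returns consensus labels,
# pooled ground truth and per-fit ARIs
run_recovery_pipeline <- function(model, n_animals = 6, minutes = 10,
                                  K = 5, R = 8, n_clusters = 5,
                                  cohort_seed = 7, fit_seed = 100) {
  cohort <- make_cohort(model,
                        n_per_genotype = c(wt = n_animals),
                        minutes = minutes, fps = 30, seed = cohort_seed)
  pca <- fit_pca(cohort, n_components = model$P)
  scores <- embed_sessions(pca, cohort)
  ens <- run_ensemble(scores, K = K, L = 1, R = R, master_seed = fit_seed)
  cons <- consensus_syllables(ens, n_clusters = n_clusters)
  truth <- unlist(lapply(cohort, function(x) x$truth$states))
  list(consensus = unlist(cons$labels), truth = truth,
       single_ari = vapply(ens$fits, function(f)
         adjusted_rand_index(unlist(f$state_seqs), truth), numeric(1)),
       assignment = cons, ensemble = ens, cohort = cohort)
}

# compliant / non-compliant burst event tables for the EEG generator
burst_events <- function(n = 10, dur = 60, ratio = 4, cycles = 6,
                         freq = 300) {
  data.frame(time_s = seq(2, dur - 2, length.out = n), channel = 1,
             freq_hz = freq, n_cycles = cycles, amplitude_ratio = ratio)
}

# interval-overlap matching between detections and injected ground truth
match_events <- function(detected, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(pmax(detected$start_sample, truth$start_sample[i]) <=
          pmin(detected$end_sample, truth$end_sample[i])), logical(1))
  matched <- if (nrow(detected)) vapply(seq_len(nrow(detected)), function(i)
    any(pmax(truth$start_sample, detected$start_sample[i]) <=
          pmin(truth$end_sample, detected$end_sample[i])), logical(1))
    else logical(0)
  list(n_truth = nrow(truth), n_det = nrow(detected),
       tp_truth = sum(hit), tp_det = sum(matched))
}

# noiseless burst train at known amplitude (in units of a supplied baseline
# SD), for deterministic threshold-margin checks of the detector
pure_burst_trace <- function(ratio, cycles, sd_ref, dur = 60, fs = 4000,
                             freq = 300, n = 10) {
  x <- numeric(dur * fs)
  for (t0 in seq(2, dur - 2, length.out = n)) {
    len <- round(cycles / freq * fs)
    i0 <- round(t0 * fs) + 1L
    x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
      ratio * sd_ref * tukey_window(len, 0.5) *
        sin(2 * pi * freq * (0:(len - 1)) / fs)
  }
  x
}

# tiny hand-sized ARHMM and session for decoder oracles
toy_model <- function(K, P = 2, sep = 3, seed = 1) {
  set.seed(seed)
  A <- lapply(1:K, function(k) diag(0.3, P))
  b <- lapply(1:K, function(k) rnorm(P, mean = sep * k))
  Q <- lapply(1:K, function(k) diag(runif(P, 0.5, 1.5)))
  tm <- if (K == 1) matrix(1, 1, 1) else base_trans(K, stay = 0.6)
  arhmm_model(tm, A, b, Q, L = 1)
}

toy_session <- function(model, T, seed) {
  sim <- simulate_arhmm_session(model, minutes = T / 30 / 60, fps = 30,
                                gaps = NULL, seed = seed)
  structure(list(animal_id = "a", genotype = "wt", fps = 30,
                 scores = sim$session$features,
                 valid_mask = sim$session$valid_mask,
                 session_minutes = T / 30 / 60),
            class = "score_session")
}

# Independent emission log-density for an L=1 ARHMM with diagonal Q
# (per-coordinate normal densities), used by the exhaustive Viterbi oracle.
oracle_logB <- function(model, Y) {
  T <- nrow(Y); K <- model$K
  lb <- matrix(0, T, K)
  for (t in 2:T) {
    for (k in 1:K) {
      mu <- as.vector(model$A[[k]] %*% Y[t - 1, ]) + model$b[[k]]
      lb[t, k] <- sum(dnorm(Y[t, ], mu, sqrt(diag(model$Q[[k]])), log = TRUE))
    }
  }
  lb
}

# Brute-force best path over all K^T state sequences (lexicographically
# smallest among ties, matching lowest-index tie-breaking).
oracle_viterbi <- function(logB, logpi, logA) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(1:K), T)))[, T:1, drop = FALSE]
  # order rows lexicographically so the first maximum is the tie-break winner
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  score <- logpi[paths[, 1]] + logB[cbind(1, paths[, 1])]
  for (t in 2:T)
    score <- score + logA[cbind(paths[, t - 1], paths[, t])] +
      logB[cbind(t, paths[, t])]
  best <- which.max(score)
  list(path = as.integer(paths[best, ]), score = score[best])
}

# Permutation reference for Dunn z-test p-values: proportion of label
# shuffles whose mean-rank difference is at least the observed one (the
# scaling of z is permutation-invariant, so comparing |rank-mean diffs|
# is equivalent to comparing |z|).
dunn_perm_p <- function(x, g, pair, n_perm = 10000, seed = 1) {
  set.seed(seed)
  r <- rank(x)
  i1 <- g == pair[1]; i2 <- g == pair[2]
  obs <- abs(mean(r[i1]) - mean(r[i2]))
  n <- length(x)
  hits <- vapply(seq_len(n_perm), function(...) {
    idx <- sample.int(n)
    abs(mean(r[idx[which(i1)]]) - mean(r[idx[which(i2)]])) >= obs - 1e-12
  }, logical(1))
  mean(hits)
}

# hand-built signature catalog with known pairwise Hamming distances
# A-B = 2, A-C = 4, A-D = 6, B-C = 4, B-D = 6, C-D = 3 (over R = 6 fits)
four_point_catalog <- function(counts = c(4, 3, 2, 1)) {
  sig <- rbind(A = c(0, 0, 0, 0, 0, 0),
               B = c(1, 1, 0, 0, 0, 0),
               C = c(2, 2, 1, 1, 0, 0),
               D = c(2, 2, 1, 3, 3, 3))
  structure(list(signatures = unname(sig),
                 key = apply(sig, 1, paste, collapse = "-"),
                 count = as.integer(counts), R = 6L, K = 4L,
                 total_frames = sum(counts)),
            class = "signature_catalog")
}
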