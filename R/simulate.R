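#' Acquisition-gap specification
#'
#' Depth-video pose recordings are acquired in roughly 20-second blocks
#' separated by 1-2 second storage interruptions. The generator reproduces
#' that structure in the session's validity mask: valid-block durations are
#' drawn uniformly in `block_s + c(-1, 1) * block_jitter_s` and gap durations
#' uniformly in `gap_s`.
#'
#' @param block_s nominal valid-block duration, seconds.
#' @param block_jitter_s half-width of the uniform jitter on block duration.
#' @param gap_s length-2 range of gap durations, seconds.
#' @return list of class `gap_spec`.
#' @export
gap_spec <- function(block_s = 20, block_jitter_s = 1, gap_s = c(1, 2)) {
  if (block_s - block_jitter_s <= 0) stop("block duration must stay positive")
  if (length(gap_s) != 2L || any(gap_s < 0) || gap_s[2] < gap_s[1])
    stop("gap_s must be an increasing non-negative range")
  structure(list(block_s = block_s, block_jitter_s = block_jitter_s,
                 gap_s = gap_s), class = "gap_spec")
}

# Build a validity mask of length T frames from a gap spec (uses the current
# RNG stream). NULL spec means no gaps.
build_mask <- function(T, fps, spec) {
  if (is.null(spec)) return(rep(TRUE, T))
  mask <- logical(T)
  pos <- 1L
  while (pos <= T) {
    bl <- spec$block_s + runif(1, -1, 1) * spec$block_jitter_s
    nb <- max(1L, round(bl * fps))
    mask[pos:min(T, pos + nb - 1L)] <- TRUE
    pos <- pos + nb
    gl <- runif(1, spec$gap_s[1], spec$gap_s[2])
    pos <- pos + max(1L, round(gl * fps))
  }
  mask
}

#' Simulate one pose-feature session from a known ARHMM
#'
#' Draws a hidden state chain over the full session (the chain runs
#' continuously through acquisition gaps; gaps affect only the validity mask)
#' and emits features by the state-conditional AR recursion with Gaussian
#' innovations. The first `L` frames are drawn from the initial state's
#' stationary observation distribution (AR warm-up).
#'
#' @param model an [arhmm_model].
#' @param minutes session length (study default 20).
#' @param fps frames per second (study default 30).
#' @param gaps a [gap_spec] describing acquisition interruptions, or `NULL`
#'   for a gap-free session.
#' @param seed RNG seed; identical seeds give identical output.
#' @param animal_id,genotype metadata attached to the session.
#' @return list with `session` (class `pose_session`: `features` T x P,
#'   `valid_mask`, `fps`, `session_minutes`, ids) and `truth` (class
#'   `ground_truth`: full-length `states`, the generating `model`).
#' @export
simulate_arhmm_session <- function(model, minutes = 20, fps = 30,
                                   gaps = gap_spec(), seed = 1L,
                                   animal_id = "animal", genotype = "wt") {
  stopifnot(inherits(model, "arhmm_model"))
  validate_arhmm(model)
  if (minutes <= 0) stop("`minutes` must be positive")
  T <- round(minutes * 60 * fps)
  if (model$L >= T) stop("AR order exceeds warm-up frames available")
  set.seed(check_seed(seed))
  states <- .markov_chain(runif(T), model$init, model$trans)
  mask <- build_mask(T, fps, gaps)

  P <- model$P; L <- model$L
  cholQ <- lapply(model$Q, function(q) chol(q))
  z <- matrix(rnorm(T * P), T, P)
  y <- matrix(NA_real_, T, P)
  st1 <- state_stationary(model, states[1L])
  cs <- chol(st1$cov)
  for (t in seq_len(L))
    y[t, ] <- st1$mean + as.vector(z[t, ] %*% cs)
  for (t in (L + 1L):T) {
    k <- states[t]
    lagvec <- as.vector(t(y[(t - 1L):(t - L), , drop = FALSE]))
    y[t, ] <- model$A[[k]] %*% lagvec + model$b[[k]] +
      as.vector(z[t, ] %*% cholQ[[k]])
  }
  session <- structure(
    list(animal_id = animal_id, genotype = genotype, fps = fps,
         features = y, valid_mask = mask, session_minutes = minutes),
    class = "pose_session")
  truth <- structure(list(states = states, model = model),
                     class = "ground_truth")
  list(session = session, truth = truth)
}

#' @export
print.pose_session <- function(x, ...) {
  cat(sprintf("pose session %s (%s): %d frames x %d features at %g fps, %.1f min, %.1f%% valid\n",
              x$animal_id, x$genotype, nrow(x$features), ncol(x$features),
              x$fps, x$session_minutes, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Simulate a label-only session from a Markov chain
#'
#' Draws the syllable/state chain and validity mask without emitting features.
#' Used for statistical calibration studies of the syllable metrics, where
#' the inference stage is not under test and ground-truth labels stand in for
#' decoded syllables.
#'
#' @inheritParams simulate_arhmm_session
#' @param trans row-stochastic transition matrix.
#' @param init initial distribution; default the stationary distribution.
#' @return list with `labels` (full length, defined in gaps too), `valid_mask`,
#'   `fps`, `animal_id`, `genotype`.
#' @export
simulate_label_session <- function(trans, minutes = 20, fps = 30,
                                   gaps = gap_spec(), seed = 1L,
                                   init = NULL, animal_id = "animal",
                                   genotype = "wt") {
  trans <- as.matrix(trans)
  if (any(abs(rowSums(trans) - 1) > 1e-12)) stop("non-stochastic transition matrix")
  if (is.null(init)) init <- stationary_distribution(trans)
  T <- round(minutes * 60 * fps)
  set.seed(check_seed(seed))
  labels <- .markov_chain(runif(T), init, trans)
  mask <- build_mask(T, fps, gaps)
  list(labels = labels, valid_mask = mask, fps = fps,
       animal_id = animal_id, genotype = genotype)
}

# Column-scale transition mass into each state and renormalize rows.
scale_transitions <- function(trans, multipliers) {
  K <- nrow(trans)
  if (length(multipliers) != K) stop("need one multiplier per state")
  if (any(multipliers <= 0)) stop("occupancy multipliers must be positive")
  out <- sweep(trans, 2L, multipliers, "*")
  rs <- rowSums(out)
  if (any(rs == 0)) stop("occupancy effect leaves a state with no exits")
  out <- out / rs
  if (any(colSums(out) == 0))
    stop("occupancy effect makes a state unreachable")
  out
}

#' Occupancy multiplier achieving a target stationary-occupancy ratio
#'
#' Column scaling of the transition matrix shifts a state's stationary
#' occupancy nonlinearly (on a sticky chain, scaling also shortens bouts).
#' This solves for the multiplier under which the state's stationary
#' occupancy equals `target_ratio` times its baseline value — e.g.
#' `target_ratio = 0.5` emulates a genotype that halves time spent in a
#' syllable.
#'
#' @param trans row-stochastic transition matrix.
#' @param state state whose occupancy is targeted.
#' @param target_ratio desired occupancy ratio (in (0, 1\]) relative to the
#'   unscaled chain.
#' @return length-K multiplier vector usable in [make_cohort] /
#'   [make_label_cohort] `genotype_effects`.
#' @export
occupancy_multiplier <- function(trans, state, target_ratio) {
  if (target_ratio <= 0 || target_ratio > 1)
    stop("target_ratio must be in (0, 1]")
  K <- nrow(trans)
  base <- stationary_distribution(trans)[state]
  f <- function(m) {
    mult <- rep(1, K); mult[state] <- m
    stationary_distribution(scale_transitions(trans, mult))[state] -
      target_ratio * base
  }
  m <- stats::uniroot(f, c(1e-6, 1), tol = 1e-10)$root
  mult <- rep(1, K); mult[state] <- m
  mult
}

#' Simulate a genotype cohort of pose sessions
#'
#' Each genotype's sessions are drawn from the base model after scaling the
#' transition-matrix columns of target states by that genotype's occupancy
#' multipliers (rows re-normalized), which shifts time spent in those states
#' — emulating, e.g., a mutant that sits less and moves forward more. Group
#' sizes default to the study design (6 wild-type, 10 heterozygous,
#' 5 homozygous animals).
#'
#' @param base_model an [arhmm_model] shared by all genotypes.
#' @param genotype_effects named list mapping genotype to a length-K vector of
#'   positive occupancy multipliers (1 = no change). Genotypes present in
#'   `n_per_genotype` but absent here get multipliers of 1.
#' @param n_per_genotype named integer vector of animals per genotype.
#' @param minutes,fps,gaps session parameters, see [simulate_arhmm_session].
#' @param seed master seed; every animal receives an independent seed derived
#'   from it.
#' @return list of `list(session, truth)` entries, one per animal.
#' @export
make_cohort <- function(base_model, genotype_effects = list(),
                        n_per_genotype = c(wt = 6L, het = 10L, hom = 5L),
                        minutes = 20, fps = 30, gaps = gap_spec(),
                        seed = 1L) {
  stopifnot(inherits(base_model, "arhmm_model"))
  genos <- names(n_per_genotype)
  if (is.null(genos)) stop("`n_per_genotype` must be named by genotype")
  models <- lapply(genos, function(g) {
    mult <- genotype_effects[[g]]
    if (is.null(mult)) return(base_model)
    m <- base_model
    m$trans <- scale_transitions(base_model$trans, mult)
    m$init <- stationary_distribution(m$trans)
    m
  })
  names(models) <- genos
  total <- sum(n_per_genotype)
  seeds <- derive_seeds(seed, total)
  out <- vector("list", total)
  i <- 0L
  for (g in genos) {
    for (j in seq_len(n_per_genotype[[g]])) {
      i <- i + 1L
      out[[i]] <- simulate_arhmm_session(
        models[[g]], minutes = minutes, fps = fps, gaps = gaps,
        seed = seeds[i], animal_id = sprintf("%s_%d", g, j), genotype = g)
    }
  }
  out
}

#' Simulate a genotype cohort of label-only sessions
#'
#' Label-space counterpart of [make_cohort], for calibration and power studies
#' of the syllable statistics: ground-truth syllable chains are drawn directly
#' (no features, no inference).
#'
#' @inheritParams make_cohort
#' @param trans base transition matrix.
#' @return list of label sessions, see [simulate_label_session].
#' @export
make_label_cohort <- function(trans, genotype_effects = list(),
                              n_per_genotype = c(wt = 6L, mut = 6L),
                              minutes = 2, fps = 30, gaps = gap_spec(),
                              seed = 1L) {
  genos <- names(n_per_genotype)
  if (is.null(genos)) stop("`n_per_genotype` must be named by genotype")
  mats <- lapply(genos, function(g) {
    mult <- genotype_effects[[g]]
    if (is.null(mult)) trans else scale_transitions(trans, mult)
  })
  names(mats) <- genos
  total <- sum(n_per_genotype)
  seeds <- derive_seeds(seed, total)
  out <- vector("list", total)
  i <- 0L
  for (g in genos) {
    for (j in seq_len(n_per_genotype[[g]])) {
      i <- i + 1L
      out[[i]] <- simulate_label_session(
        mats[[g]], minutes = minutes, fps = fps, gaps = gaps,
        seed = seeds[i], animal_id = sprintf("%s_%d", g, j), genotype = g)
    }
  }
  out
}
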