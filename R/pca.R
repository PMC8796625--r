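#' Fit a PCA embedding to merged pose sessions
#'
#' Pose descriptors from all sessions are merged (valid frames only) and a
#' principal-component basis is fitted; downstream state inference runs on
#' the component scores. The study-scale default keeps 15 dimensions.
#'
#' @param sessions list of `pose_session` objects, or of `list(session, truth)`
#'   pairs as returned by [make_cohort].
#' @param n_components number of components to retain (default 15).
#' @return object of class `pca_model` with `mean`, `loadings` (D x P,
#'   orthonormal columns), `explained_variance` (top-P covariance
#'   eigenvalues, non-increasing) and `explained_fraction`.
#' @export
fit_pca <- function(sessions, n_components = 15) {
  sessions <- lapply(sessions, as_pose_session)
  X <- do.call(rbind, lapply(sessions, function(s)
    s$features[s$valid_mask, , drop = FALSE]))
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in valid frames")
  D <- ncol(X)
  if (n_components > D) stop("n_components exceeds feature dimensionality")
  if (nrow(X) < n_components) stop("fewer valid frames than components")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(
    list(mean = pc$center,
         loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
         explained_variance = pc$sdev[seq_len(n_components)]^2,
         explained_fraction = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2),
         n_components = n_components),
    class = "pca_model")
}

as_pose_session <- function(x) {
  if (inherits(x, "pose_session")) return(x)
  if (is.list(x) && inherits(x$session, "pose_session")) return(x$session)
  stop("expected a pose_session (or list with a $session element)")
}

#' Project a session onto a fitted PCA basis
#'
#' Scores are computed for every frame (including gap frames, which stay
#' flagged by the mask) so that the frame indexing of the session is
#' preserved.
#'
#' @param pca a `pca_model` from [fit_pca].
#' @param session a `pose_session`.
#' @return a `score_session`: list with `scores` (T x P), `valid_mask`,
#'   `fps`, `session_minutes`, `animal_id`, `genotype`.
#' @export
pca_scores <- function(pca, session) {
  session <- as_pose_session(session)
  sc <- sweep(session$features, 2L, pca$mean, "-") %*% pca$loadings
  structure(
    list(animal_id = session$animal_id, genotype = session$genotype,
         fps = session$fps, scores = sc, valid_mask = session$valid_mask,
         session_minutes = session$session_minutes),
    class = "score_session")
}

#' Embed a list of sessions with one PCA model
#'
#' @param pca a `pca_model`.
#' @param sessions list of `pose_session` objects or `list(session, truth)`
#'   pairs.
#' @return list of `score_session` objects.
#' @export
embed_sessions <- function(pca, sessions) {
  lapply(sessions, function(s) pca_scores(pca, as_pose_session(s)))
}
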