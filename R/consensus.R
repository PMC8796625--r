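#' Build per-frame signatures from an ensemble of fits
#'
#' Each valid frame receives the ordered R-tuple of state labels it was
#' assigned across the independent fits — its syllable signature. The catalog
#' collects the unique signatures with their frame counts; clustering the
#' catalog resolves the stochastic per-fit assignments into consensus
#' syllables.
#'
#' @param ensemble an `ensemble_result` from [run_ensemble].
#' @return list with `signatures` (per session, a T x R integer matrix, `NA`
#'   rows in gaps) and `catalog` (class `signature_catalog`: unique signature
#'   matrix, keys, counts).
#' @export
build_signatures <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  R <- ensemble$R
  n_sessions <- length(ensemble$fits[[1L]]$state_seqs)
  ref_valid <- lapply(ensemble$fits[[1L]]$state_seqs, function(l) !is.na(l))
  for (f in ensemble$fits) {
    if (length(f$state_seqs) != n_sessions)
      stop("fits cover different session sets")
    for (si in seq_len(n_sessions)) {
      v <- !is.na(f$state_seqs[[si]])
      if (length(v) != length(ref_valid[[si]]) || any(v != ref_valid[[si]]))
        stop("fits with mismatched frame counts")
    }
  }
  signatures <- vector("list", n_sessions)
  keys_all <- character(0)
  for (si in seq_len(n_sessions)) {
    Tn <- length(ref_valid[[si]])
    m <- matrix(NA_integer_, Tn, R)
    for (r in seq_len(R)) m[, r] <- as.integer(ensemble$fits[[r]]$state_seqs[[si]])
    signatures[[si]] <- m
    keys_all <- c(keys_all, signature_keys(m[ref_valid[[si]], , drop = FALSE]))
  }
  tab <- table(keys_all)
  keys <- names(tab)
  sig_mat <- do.call(rbind, lapply(strsplit(keys, "-", fixed = TRUE),
                                   as.integer))
  catalog <- structure(
    list(signatures = sig_mat, key = keys, count = as.integer(tab),
         R = R, K = ensemble$K, total_frames = length(keys_all)),
    class = "signature_catalog")
  list(signatures = signatures, catalog = catalog)
}

signature_keys <- function(m) {
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), sep = "-"))
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("signature catalog: %d unique signatures (R = %d fits) over %d frames\n",
              length(x$key), x$R, x$total_frames))
  invisible(x)
}

#' Distance between two frame signatures
#'
#' Normalized Hamming distance: the fraction of fits on which the two frames
#' received different state labels, in \[0, 1\]. Each fit is weighted equally.
#'
#' @param a,b integer vectors of equal length R (one state id per fit).
#' @return a number in \[0, 1\].
#' @export
signature_distance <- function(a, b) {
  if (length(a) != length(b)) stop("signatures must have equal length")
  mean(a != b)
}

#' Cluster the signature catalog into consensus syllables
#'
#' Agglomerative clustering of the unique signatures under the normalized
#' Hamming distance with WPGMA (weighted average, `hclust` method
#' `"mcquitty"`) linkage; the tree is cut to exactly `n_clusters` syllables
#' (study default 44). Syllables are re-indexed by descending total frame
#' count, so syllable 1 is always the most used. Signatures rarer than
#' `min_count` can be held out of the tree (they are mapped afterwards to the
#' nearest clustered signature), which bounds the distance-matrix size.
#'
#' @param catalog a `signature_catalog`.
#' @param n_clusters number of syllables to cut (default 44).
#' @param linkage `hclust` linkage method; `"mcquitty"` is WPGMA.
#' @param count_weighted if `TRUE`, signatures enter the linkage weighted by
#'   their frame counts (average linkage over frame-replicated points);
#'   default `FALSE` clusters the deduplicated catalog unweighted.
#' @param min_count signatures with fewer frames are attached by nearest
#'   neighbor instead of entering the tree.
#' @param max_signatures guard on the distance-matrix size.
#' @return object of class `syllable_map`: data.frame mapping `key` to
#'   `syllable`, plus the `hclust` tree, the catalog, and bookkeeping.
#' @export
cluster_signatures <- function(catalog, n_clusters = 44,
                               linkage = "mcquitty", count_weighted = FALSE,
                               min_count = 1L, max_signatures = 20000L) {
  stopifnot(inherits(catalog, "signature_catalog"))
  keep <- catalog$count >= min_count
  if (!any(keep)) stop("min_count removes every signature")
  U <- sum(keep)
  if (U > max_signatures)
    stop(sprintf(paste0(
      "distance matrix would need %d x %d entries; subsample the catalog ",
      "by raising `min_count` (count threshold) or `max_signatures`"), U, U))
  if (n_clusters > U)
    stop("n_clusters exceeds the number of clustered signatures")
  sig <- catalog$signatures[keep, , drop = FALSE]
  cnt <- catalog$count[keep]
  if (U == 1L) {                      # degenerate catalog: one signature
    tree <- NULL
    cl <- 1L
  } else {
    d <- .hamming_matrix(sig) / catalog$R
    if (count_weighted) {
      tree <- hclust(as.dist(d), method = "average", members = cnt)
    } else {
      tree <- hclust(as.dist(d), method = linkage)
    }
    cl <- cutree(tree, k = n_clusters)
  }
  # attach held-out signatures to the nearest clustered signature
  full_cl <- integer(length(catalog$key))
  full_cl[keep] <- cl
  if (any(!keep)) {
    rest <- catalog$signatures[!keep, , drop = FALSE]
    nn <- nearest_signature(rest, sig)
    full_cl[!keep] <- cl[nn]
  }
  # syllable ids ordered by descending total frame count
  totals <- tapply(catalog$count, full_cl, sum)
  ord <- order(-as.numeric(totals), as.integer(names(totals)))
  relabel <- integer(n_clusters)
  relabel[as.integer(names(totals))[ord]] <- seq_len(n_clusters)
  syllable <- relabel[full_cl]
  structure(
    list(map = data.frame(key = catalog$key, syllable = syllable,
                          stringsAsFactors = FALSE),
         tree = tree, clustered_keys = catalog$key[keep],
         clustered_signatures = sig, n_clusters = n_clusters,
         linkage = if (count_weighted) "average (count-weighted)" else linkage,
         catalog = catalog),
    class = "syllable_map")
}

# For each row of `x`, index of the Hamming-nearest row of `ref`
# (lowest index on ties).
nearest_signature <- function(x, ref) {
  vapply(seq_len(nrow(x)), function(i) {
    h <- colSums(t(ref) != x[i, ])
    which.min(h)
  }, integer(1))
}

#' @export
print.syllable_map <- function(x, ...) {
  cat(sprintf("syllable map: %d signatures -> %d syllables (%s linkage)\n",
              nrow(x$map), x$n_clusters, x$linkage))
  invisible(x)
}

#' Apply a syllable map to per-frame signatures
#'
#' Frames with identical signatures receive identical syllables; gap frames
#' stay `NA`. A signature absent from the map (possible when a frozen map is
#' applied to new data) falls back to the nearest catalogued signature and is
#' counted in the `unseen` attribute.
#'
#' @param signatures a T x R signature matrix, or the list of them returned
#'   by [build_signatures].
#' @param map a `syllable_map`.
#' @return integer syllable labels per frame (`NA` in gaps), or a list of
#'   them; attribute `unseen` counts fallback assignments.
#' @export
assign_syllables <- function(signatures, map) {
  stopifnot(inherits(map, "syllable_map"))
  if (is.list(signatures) && !is.matrix(signatures))
    return(lapply(signatures, assign_syllables, map = map))
  m <- signatures
  valid <- !is.na(m[, 1L])
  keys <- signature_keys(m[valid, , drop = FALSE])
  idx <- match(keys, map$map$key)
  syl <- map$map$syllable[idx]
  unseen <- which(is.na(idx))
  if (length(unseen)) {
    cat_idx <- match(map$map$key, map$catalog$key)
    nn <- nearest_signature(m[valid, , drop = FALSE][unseen, , drop = FALSE],
                            map$catalog$signatures)
    syl[unseen] <- map$map$syllable[match(map$catalog$key[nn], map$map$key)]
  }
  out <- rep(NA_integer_, nrow(m))
  out[valid] <- syl
  attr(out, "unseen") <- length(unseen)
  out
}

#' Full consensus step: signatures, clustering, assignment
#'
#' Convenience wrapper running [build_signatures], [cluster_signatures] and
#' [assign_syllables] over an ensemble.
#'
#' @param ensemble an `ensemble_result`.
#' @param n_clusters number of consensus syllables (study default 44).
#' @param ... passed to [cluster_signatures].
#' @return object of class `syllable_assignment`: `labels` (per-session
#'   syllable vectors), `map`, `catalog`, `session_info`, `fps`.
#' @export
consensus_syllables <- function(ensemble, n_clusters = 44, ...) {
  sigs <- build_signatures(ensemble)
  map <- cluster_signatures(sigs$catalog, n_clusters = n_clusters, ...)
  labels <- assign_syllables(sigs$signatures, map)
  structure(
    list(labels = labels, map = map, catalog = sigs$catalog,
         session_info = ensemble$session_info,
         n_clusters = n_clusters),
    class = "syllable_assignment")
}

#' @export
print.syllable_assignment <- function(x, ...) {
  cat(sprintf("consensus syllables: %d sessions, %d syllables from %d signatures\n",
              length(x$labels), x$n_clusters, length(x$catalog$key)))
  invisible(x)
}
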