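#' Build a syllable transition network
#'
#' Counts ordered pairs of consecutive distinct syllables, pooled across the
#' supplied sessions (typically one genotype). Transitions never bridge an
#' acquisition gap, and self-edges are structurally impossible (a repeated
#' label continues a bout rather than starting a transition). Edge weights
#' are the percentage of all recorded transitions; the full weight matrix
#' sums to 100 before thresholding. Edges below `edge_threshold` (% of
#' transitions, default 0.01) are excluded from the exported graph but kept
#' in the matrix. Node attributes carry the pooled time proportion (%) of
#' each syllable.
#'
#' @param x a `syllable_assignment`, a list of label sessions, or a single
#'   labels vector (`NA` in gaps).
#' @param n_syllables number of syllables (nodes); defaults to the maximum
#'   label seen.
#' @param edge_threshold minimum edge weight (%) retained in the graph.
#' @param genotype optional genotype to subset a `syllable_assignment` to.
#' @return object of class `transition_graph`: `graph` (igraph, thresholded),
#'   `weights` (full S x S percentage matrix), `counts`, `n_transitions`,
#'   `proportions` (per-node %), `edge_threshold`.
#' @export
build_transition_graph <- function(x, n_syllables = NULL,
                                   edge_threshold = 0.01, genotype = NULL) {
  if (is.atomic(x)) x <- list(list(labels = x, valid_mask = !is.na(x),
                                   fps = NA, animal_id = "a", genotype = "g"))
  sessions <- as_label_sessions(x)
  if (!is.null(genotype))
    sessions <- Filter(function(s) s$genotype == genotype, sessions)
  if (!length(sessions)) stop("no sessions to pool")
  labs <- unlist(lapply(sessions, function(s) {
    l <- s$labels
    l[!s$valid_mask] <- NA_integer_
    l
  }))
  if (is.null(n_syllables))
    n_syllables <- max(labs, na.rm = TRUE)
  S <- n_syllables
  counts <- matrix(0, S, S)
  # consecutive distinct pairs within valid runs, per session
  offset <- 0L
  for (s in sessions) {
    l <- s$labels
    l[!s$valid_mask] <- NA_integer_
    vb <- valid_blocks(!is.na(l))
    for (i in seq_len(nrow(vb))) {
      seg <- rle(l[vb$start[i]:vb$end[i]])$values
      if (length(seg) > 1L)
        for (t in 2:length(seg))
          counts[seg[t - 1L], seg[t]] <- counts[seg[t - 1L], seg[t]] + 1
    }
  }
  total <- sum(counts)
  weights <- if (total > 0) 100 * counts / total else counts
  prop <- 100 * tabulate(labs[!is.na(labs)], nbins = S) /
    sum(!is.na(labs))
  keep <- weights >= edge_threshold & weights > 0
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1L], to = idx[, 2L],
               weight = weights[keep]),
    directed = TRUE,
    vertices = data.frame(name = seq_len(S), proportion = prop))
  structure(
    list(graph = g, weights = weights, counts = counts,
         n_transitions = total, proportions = prop,
         edge_threshold = edge_threshold),
    class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("syllable transition graph: %d nodes, %d edges >= %.3g%% of %d transitions\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$edge_threshold, x$n_transitions))
  invisible(x)
}

#' Per-genotype transition networks
#'
#' @param assignment a `syllable_assignment`.
#' @param edge_threshold see [build_transition_graph].
#' @return named list of `transition_graph` objects, one per genotype.
#' @export
genotype_graphs <- function(assignment, edge_threshold = 0.01) {
  genos <- unique(assignment$session_info$genotype)
  out <- lapply(genos, function(g)
    build_transition_graph(assignment, n_syllables = assignment$n_clusters,
                           edge_threshold = edge_threshold, genotype = g))
  names(out) <- genos
  out
}

#' Export a transition graph
#'
#' Writes the thresholded graph as GraphML and the full edge-weight matrix as
#' an edge-list CSV (all pairs with nonzero weight, including sub-threshold
#' ones, flagged by `shown`).
#'
#' @param tg a `transition_graph`.
#' @param graphml_path,edges_path output files (`NULL` to skip either).
#' @return invisibly, the edge-list data.frame.
#' @export
export_transition_graph <- function(tg, graphml_path = NULL,
                                    edges_path = NULL) {
  idx <- which(tg$weights > 0, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1L], to = idx[, 2L],
                      weight_pct = tg$weights[idx],
                      count = tg$counts[idx],
                      shown = tg$weights[idx] >= tg$edge_threshold)
  edges <- edges[order(-edges$weight_pct), , drop = FALSE]
  if (!is.null(graphml_path))
    igraph::write_graph(tg$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write.csv(edges, edges_path, row.names = FALSE)
  invisible(edges)
}
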