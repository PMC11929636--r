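# Centrality indices on weighted signed networks. Distances follow the
# psychometric-network convention: traversing an edge of weight w costs
# 1/|w|, so strong associations are "short". Strength and expected influence
# are direct sums; shortest-path machinery (Dijkstra, Brandes betweenness
# with fractional tie credit) is delegated to igraph on the 1/|w| graph.

as_igraph_dist <- function(g) {
  A <- abs(g$adjacency)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::E(ig)$weight <- 1 / igraph::E(ig)$weight
  ig
}

check_node <- function(g, node) {
  if (!is.null(node) && !all(node %in% g$labels)) {
    config_error(paste0("unknown node(s): ",
                        paste(setdiff(node, g$labels), collapse = ", ")))
  }
}

#' Node strength
#'
#' Sum of the absolute weights of the edges incident to a node.
#'
#' @param g a [network_graph()].
#' @param node optional node label(s); default: all nodes.
#' @return Named numeric vector.
#' @export
node_strength <- function(g, node = NULL) {
  check_node(g, node)
  s <- rowSums(abs(g$adjacency))
  if (is.null(node)) s else s[node]
}

#' Expected influence
#'
#' Signed sum of the weights of the edges incident to a node; unlike
#' strength it lets negative edges cancel positive ones.
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
expected_influence <- function(g, node = NULL) {
  check_node(g, node)
  s <- rowSums(g$adjacency)
  if (is.null(node)) s else s[node]
}

#' All-pairs shortest-path distances and geodesic counts
#'
#' Edge lengths are `1/|weight|`; distances come from Dijkstra's algorithm.
#' Unreachable pairs have infinite distance. The geodesic-count matrix
#' records, for each ordered pair, how many distinct shortest paths connect
#' it (used for fractional betweenness credit under ties).
#'
#' @param g a [network_graph()].
#' @return List with matrices `distance` and `n_geodesics`.
#' @export
network_distances <- function(g) {
  ig <- as_igraph_dist(g)
  D <- igraph::distances(ig, algorithm = "dijkstra")
  p <- length(g$labels)
  nge <- matrix(0, p, p, dimnames = list(g$labels, g$labels))
  for (s in seq_len(p)) {
    # igraph warns about unreachable targets; infinite distance is the
    # intended answer on disconnected networks
    asp <- withCallingHandlers(
      igraph::all_shortest_paths(ig, from = s),
      warning = function(w) {
        if (grepl("Couldn't reach", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    nge[s, ] <- asp$nrgeo
  }
  diag(nge) <- 1
  list(distance = D, n_geodesics = nge)
}

#' Betweenness centrality
#'
#' For each node `v`, the sum over unordered pairs `(s, t)` (both distinct
#' from `v`) of the fraction of shortest `s`-`t` paths, on the `1/|weight|`
#' distance graph, that pass through `v`. Ties in path length share credit
#' fractionally (Brandes' algorithm).
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
node_betweenness <- function(g, node = NULL) {
  check_node(g, node)
  ig <- as_igraph_dist(g)
  b <- igraph::betweenness(ig, directed = FALSE)
  b <- stats::setNames(as.numeric(b), g$labels)
  if (is.null(node)) b else b[node]
}

#' Closeness centrality
#'
#' Inverse of the total shortest-path distance from a node to every other
#' node it can reach. On a disconnected network the sum runs within the
#' node's component (the component size is attached as an attribute);
#' an isolated node scores 0. `harmonic = TRUE` instead averages the
#' reciprocal distances to all other nodes, which stays comparable across
#' components.
#'
#' @inheritParams node_strength
#' @param harmonic use the harmonic variant.
#' @return Named numeric vector with attribute `component_size`.
#' @export
node_closeness <- function(g, node = NULL, harmonic = FALSE) {
  check_node(g, node)
  D <- network_distances(g)$distance
  p <- ncol(D)
  comp_size <- rowSums(is.finite(D))   # includes self
  cl <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    if (harmonic) mean(1 / d) else 1 / sum(d)
  }, numeric(1))
  names(cl) <- g$labels
  attr(cl, "component_size") <- stats::setNames(comp_size, g$labels)
  if (is.null(node)) cl else {
    out <- cl[node]
    attr(out, "component_size") <- comp_size[node]
    out
  }
}

#' Z-standardize a vector of centrality values
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation. A constant
#' input returns all zeros with a warning.
#'
#' @param values numeric vector, length `>= 2`.
#' @return Standardized vector (mean 0, unit sample variance).
#' @export
zscore <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    warning("constant input to zscore; returning zeros")
    return(stats::setNames(rep(0, length(values)), names(values)))
  }
  (values - mean(values)) / s
}

#' Centrality table for a network
#'
#' Computes strength, expected influence, closeness and betweenness for
#' every node, raw and z-standardized across nodes.
#'
#' @param g a [network_graph()].
#' @param harmonic_closeness use harmonic closeness (see [node_closeness()]).
#' @return A `centrality_table` data frame with columns `node`, `strength`,
#'   `expected_influence`, `closeness`, `betweenness` and their `z_`
#'   counterparts.
#' @export
centrality_table <- function(g, harmonic_closeness = FALSE) {
  s <- node_strength(g)
  ei <- expected_influence(g)
  cl <- node_closeness(g, harmonic = harmonic_closeness)
  b <- node_betweenness(g)
  out <- data.frame(node = g$labels, strength = as.numeric(s),
                    expected_influence = as.numeric(ei),
                    closeness = as.numeric(cl), betweenness = as.numeric(b))
  out$z_strength <- as.numeric(zscore(out$strength))
  out$z_expected_influence <- as.numeric(zscore(out$expected_influence))
  out$z_closeness <- as.numeric(zscore(out$closeness))
  out$z_betweenness <- as.numeric(zscore(out$betweenness))
  class(out) <- c("centrality_table", "data.frame")
  out
}
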