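#' Per-node out-degree
#'
#' @param net a [directed_network()].
#' @return integer vector: number of distinct edges leaving each node.
#' @export
out_degree <- function(net) {
  validate_network(net)
  tabulate(net$edges[, 1L], nbins = net$n_nodes)
}

#' Per-node k-shell-out index
#'
#' Directed k-core decomposition on out-degree: for k = 1, 2, ... every node
#' whose out-degree within the surviving subgraph falls below k is deleted,
#' repeatedly, until stable; a node's index is the largest k for which it
#' survives (nodes deleted in the k = 1 sweep, e.g. sinks, get 0). The result
#' is order-independent. The index quantifies a node's *downstream reach*: a
#' node can have a large out-degree yet a k-shell-out index of 0 if all its
#' targets are sinks.
#'
#' @param net a [directed_network()].
#' @return integer vector of per-node shell indices; `k_shell_out(v) <=
#'   out_degree(v)` for all v.
#' @export
k_shell_out <- function(net) {
  validate_network(net)
  as.integer(k_shell_out_cpp(net$n_nodes, net$edges[, 1L], net$edges[, 2L]))
}

#' Average local clustering coefficient
#'
#' Computed on the undirected projection of the graph (the small-world
#' literature the index is normalized against is undirected). Nodes of
#' projected degree < 2 contribute 0.
#'
#' @param net a [directed_network()] with at least 3 nodes.
#' @return average local clustering coefficient in \[0, 1\]; if every node has
#'   projected degree < 2 the value is 0 and a warning is raised.
#' @export
clustering_coefficient <- function(net) {
  if (net$n_nodes < 3L) stop("clustering needs at least 3 nodes")
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  if (max(igraph::degree(g)) < 2) {
    warning("all nodes have degree < 2; clustering coefficient degenerate")
    return(0)
  }
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Average shortest-path length
#'
#' Mean geodesic distance over reachable ordered node pairs of the undirected
#' projection; unreachable pairs are excluded and their count attached as the
#' attribute `unreachable_pairs` so callers can reject fragmented graphs.
#'
#' @param net a [directed_network()] with at least one edge.
#' @return numeric path length with attribute `unreachable_pairs`.
#' @export
average_shortest_path <- function(net) {
  if (nrow(net$edges) == 0L) stop("average shortest path undefined on an edgeless graph")
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  l <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  comp <- igraph::components(g)
  reachable <- sum(as.numeric(comp$csize) * (comp$csize - 1))
  structure(l, unreachable_pairs = as.numeric(net$n_nodes) * (net$n_nodes - 1) - reachable)
}

#' Small-world index
#'
#' `SWI = (C / C_r) / (L / L_r)`: the clustering coefficient and average
#' shortest-path length of the network, each normalized by the mean value over
#' `n_references` Erdos-Renyi reference networks with identical node and edge
#' counts. `SWI > 1` indicates small-world structure (clustering well above,
#' path length near, the random expectation).
#'
#' @param net a [directed_network()].
#' @param n_references number of ER reference draws (>= 1).
#' @param seed integer RNG seed for the references.
#' @return An object of class `small_world_result` with fields `clustering`,
#'   `path_length`, `clustering_rand`, `path_length_rand`, `swi`,
#'   `n_references`.
#' @export
small_world_index <- function(net, n_references = 10L, seed = 1L) {
  stopifnot(n_references >= 1L)
  cc <- clustering_coefficient(net)
  l <- as.numeric(average_shortest_path(net))
  inh_frac <- mean(net$node_kind == "I")
  cr <- numeric(n_references); lr <- numeric(n_references)
  for (i in seq_len(n_references)) {
    ref <- generate_er_network(net$n_nodes, nrow(net$edges), inh_frac,
                               seed = seed + i - 1L)
    cr[i] <- withCallingHandlers(
      clustering_coefficient(ref),
      warning = function(w) stop("degenerate ER reference (all degrees < 2)")
    )
    lr[i] <- as.numeric(average_shortest_path(ref))
  }
  c_r <- mean(cr); l_r <- mean(lr)
  if (c_r == 0 || !is.finite(l_r) || l_r == 0) {
    stop("degenerate ER reference ensemble (zero clustering or undefined path length)")
  }
  structure(
    list(clustering = cc, path_length = l,
         clustering_rand = c_r, path_length_rand = l_r,
         swi = (cc / c_r) / (l / l_r), n_references = n_references),
    class = "small_world_result"
  )
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world_result> SWI = %.3f  (C=%.4f C_r=%.4f  L=%.3f L_r=%.3f, %d refs)\n",
              x$swi, x$clustering, x$clustering_rand, x$path_length,
              x$path_length_rand, x$n_references))
  invisible(x)
}

#' Per-node betweenness centrality
#'
#' Standard shortest-path betweenness on the directed graph, unnormalized.
#'
#' @param net a [directed_network()].
#' @return numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(net) {
  as.numeric(igraph::betweenness(as_igraph(net), directed = TRUE, normalized = FALSE))
}

#' Per-node embeddedness profile
#'
#' Bundles the structural embeddedness metrics into one table.
#'
#' @param net a [directed_network()].
#' @param include_betweenness also compute betweenness centrality (costs
#'   O(V*E); off by default for large networks).
#' @return a data.frame of class `embeddedness_profile` with columns `node`,
#'   `out_degree`, `k_shell_out` and optionally `betweenness`; one row per
#'   node, no missing entries.
#' @export
embeddedness_profile <- function(net, include_betweenness = FALSE) {
  prof <- data.frame(node = seq_len(net$n_nodes),
                     out_degree = out_degree(net),
                     k_shell_out = k_shell_out(net))
  if (include_betweenness) prof$betweenness <- betweenness_centrality(net)
  stopifnot(all(prof$k_shell_out <= prof$out_degree))
  class(prof) <- c("embeddedness_profile", "data.frame")
  prof
}
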