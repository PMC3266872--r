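#' Directed network with excitatory/inhibitory node labels
#'
#' The central data structure of the package: a simple directed graph (no
#' self-loops, no multi-edges) whose nodes are labelled excitatory (`"E"`) or
#' inhibitory (`"I"`). Node ids are 1-based integers `1..n_nodes`, matching the
#' 1-based node numbering used in figures; serialized edge lists are written
#' 0-based (see [write_network()]).
#'
#' @param n_nodes number of nodes (integer >= 1).
#' @param edges two-column integer matrix of directed edges `(pre, post)`,
#'   1-based. May have zero rows.
#' @param node_kind character vector of length `n_nodes` with entries `"E"` or
#'   `"I"`.
#' @param gen_meta list recording provenance: at least `generator` (character)
#'   and `seed`; generator parameters go in `params`.
#'
#' @return An object of class `directed_network`: a list with elements
#'   `n_nodes`, `edges`, `node_kind`, `gen_meta`.
#' @export
directed_network <- function(n_nodes, edges, node_kind,
                             gen_meta = list(generator = "manual", seed = NA)) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have two columns (pre, post)")
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("pre", "post")
  net <- structure(
    list(n_nodes = n_nodes, edges = edges,
         node_kind = as.character(node_kind), gen_meta = gen_meta),
    class = "directed_network"
  )
  validate_network(net)
  net
}

#' Validate a directed_network object
#'
#' Checks the structural invariants: node ids in range, no self-loops, at most
#' one edge per ordered pair, and node kinds in `{E, I}`.
#'
#' @param net a `directed_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  e <- net$edges
  n <- net$n_nodes
  if (length(net$node_kind) != n) {
    stop("node_kind must have one entry per node")
  }
  if (!all(net$node_kind %in% c("E", "I"))) {
    stop("unknown node kind: ", paste(setdiff(net$node_kind, c("E", "I")), collapse = ", "))
  }
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) stop("edge endpoint out of range 1..n_nodes")
    if (any(e[, 1L] == e[, 2L])) stop("self-loops are not allowed")
    key <- (as.numeric(e[, 1L]) - 1) * n + as.numeric(e[, 2L])
    if (anyDuplicated(key)) stop("duplicate directed edges are not allowed")
  }
  invisible(net)
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes (%d E, %d I), %d edges\n",
              x$n_nodes, sum(x$node_kind == "E"), sum(x$node_kind == "I"),
              nrow(x$edges)))
  cat(sprintf("  generator: %s (seed %s)\n",
              x$gen_meta$generator %||% "?", format(x$gen_meta$seed %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of edges in a network
#' @param net a `directed_network`.
#' @return integer edge count.
#' @export
edge_count <- function(net) nrow(net$edges)

#' Ids of excitatory / inhibitory nodes
#' @param net a `directed_network`.
#' @return integer vector of 1-based node ids.
#' @export
excitatory_nodes <- function(net) which(net$node_kind == "E")

#' @rdname excitatory_nodes
#' @export
inhibitory_nodes <- function(net) which(net$node_kind == "I")

#' Convert to an igraph graph
#'
#' Used internally for the standard graph measures; node kind is carried as a
#' vertex attribute.
#'
#' @param net a `directed_network`.
#' @return an `igraph` directed graph with vertex attribute `kind`.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = TRUE)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, t(net$edges))
  }
  igraph::V(g)$kind <- net$node_kind
  g
}

#' Assign excitatory/inhibitory labels by prefix layout
#'
#' Helper shared by the generators: the first `n - round(f * n)` nodes are
#' excitatory, the remainder inhibitory, matching the conventional presentation
#' of excitatory ids before inhibitory ids.
#'
#' @param n_nodes number of nodes.
#' @param inh_fraction fraction of inhibitory nodes (rounded to a count).
#' @return character vector of `"E"`/`"I"` labels.
#' @keywords internal
prefix_kinds <- function(n_nodes, inh_fraction) {
  n_inh <- round(inh_fraction * n_nodes)
  c(rep("E", n_nodes - n_inh), rep("I", n_inh))
}
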