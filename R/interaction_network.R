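#' Construct an undirected interaction network
#'
#' A simple undirected graph with a confidence score in \[0, 1\] on every
#' edge, the in-memory form of a STRING-style scored edge list. Self-loops
#' are forbidden; duplicate unordered pairs are collapsed keeping the maximum
#' confidence, so construction is deterministic regardless of edge order.
#'
#' @param nodes character vector of node identifiers (deduplicated, order
#'   preserved). Endpoints appearing in `edges` are added automatically.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `confidence` (defaults to 1).
#' @return An object of class `interaction_network`: a list with elements
#'   `nodes` (character) and `edges` (data.frame `from`, `to`, `confidence`,
#'   one row per unordered pair with `from` < `to`).
#' @examples
#' net <- interaction_network(edges = data.frame(
#'   from = c("A", "B"), to = c("B", "C"), confidence = c(0.9, 0.8)))
#' n_edges(net)
#' @export
interaction_network <- function(nodes = character(),
                                edges = data.frame(from = character(),
                                                   to = character())) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence)
          else rep(1, length(from))
  if (any(!is.finite(conf) | conf < 0 | conf > 1))
    stop("edge confidence must lie in [0, 1]")
  if (any(from == to)) stop("self-loops are not allowed")
  nodes <- unique(c(as.character(nodes), from, to))
  # canonical unordered orientation, then dedup keeping max confidence
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(conf, key, max)[unique(key)]
    lo <- lo[!duplicated(key)]
    hi <- hi[!duplicated(key)]
  }
  e <- data.frame(from = lo, to = hi, confidence = as.numeric(conf),
                  stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = e), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net an `interaction_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Keep only edges at or above a confidence cutoff
#'
#' The standard STRING-style construction step: edges below `min_confidence`
#' are dropped; nodes are retained (possibly isolated) unless `drop_isolated`.
#'
#' @param net an `interaction_network`
#' @param min_confidence inclusive lower bound, default 0.7 (the usual
#'   "high confidence" STRING cutoff)
#' @param drop_isolated drop nodes left without edges? default FALSE
#' @return filtered `interaction_network`
#' @export
filter_confidence <- function(net, min_confidence = 0.7,
                              drop_isolated = FALSE) {
  keep <- net$edges$confidence >= min_confidence
  e <- net$edges[keep, , drop = FALSE]
  nodes <- net$nodes
  if (drop_isolated) nodes <- nodes[nodes %in% c(e$from, e$to)]
  interaction_network(nodes, e)
}

#' Induced subnetwork on a node subset
#' @param net an `interaction_network`
#' @param keep character vector of node ids to keep
#' @return `interaction_network` on `keep` with both-endpoint edges
#' @export
induced_subnetwork <- function(net, keep) {
  keep <- as.character(keep)
  e <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                 drop = FALSE]
  interaction_network(net$nodes[net$nodes %in% keep], e)
}

# igraph view of a network; confidence kept as an attribute deliberately NOT
# named "weight" so igraph's algorithms treat the graph as unweighted.
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0)
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to),
                           confidence = net$edges$confidence)
  g
}
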