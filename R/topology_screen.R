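#' Degree, closeness and betweenness of every node
#'
#' The three centralities used for core-target screening of PPI networks:
#'
#' * `dc` - raw degree (integer edge count);
#' * `cc` - Wasserman-Faust closeness, `((r-1)/S) * ((r-1)/(N-1))` where `S`
#'   is the sum of shortest-path distances to the `r-1` reachable nodes and
#'   `r` the reachable-component size. The component-size factor keeps the
#'   value in \[0, 1\] and well-defined on disconnected graphs; isolated
#'   nodes score 0. On a connected graph this is the usual normalized
#'   closeness (1 exactly for a node adjacent to all others).
#' * `bc` - shortest-path betweenness, endpoints excluded, pair
#'   contributions split among equally short paths, normalized by
#'   `(N-1)(N-2)/2`.
#'
#' Edge confidences are ignored: centralities treat the graph as unweighted
#' (confidence belongs to network construction, not topology).
#'
#' @param net an [interaction_network()]
#' @return data.frame with columns `node`, `dc`, `cc`, `bc`, one row per
#'   node in `net$nodes` order; zero rows for an empty network
#' @examples
#' p3 <- interaction_network(edges = data.frame(from = c("A", "B"),
#'                                              to = c("B", "C")))
#' centralities(p3)  # B: dc 2, cc 1, bc 1
#' @export
centralities <- function(net) {
  n <- n_nodes(net)
  if (n == 0)
    return(data.frame(node = character(), dc = integer(),
                      cc = numeric(), bc = numeric()))
  g <- as_igraph(net)
  dc <- as.integer(igraph::degree(g))
  if (n == 1) {
    cc <- 0
    bc <- 0
  } else {
    d <- igraph::distances(g)        # unweighted: no "weight" attribute set
    reach <- is.finite(d)
    r <- rowSums(reach)              # includes self
    s <- rowSums(ifelse(reach, d, 0))
    cc <- ifelse(r > 1, (r - 1)^2 / (s * (n - 1)), 0)
    bc_raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    bc <- if (n > 2) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  }
  data.frame(node = net$nodes, dc = dc, cc = as.numeric(cc),
             bc = as.numeric(bc), row.names = NULL)
}

#' Centrality thresholds for one screening round
#' @param dc_min minimum degree (integer, >= 0)
#' @param cc_min minimum closeness, in \[0, 1\]
#' @param bc_min minimum betweenness, in \[0, 1\]
#' @return a `screen_criteria` list
#' @export
screen_criteria <- function(dc_min = 0, cc_min = 0, bc_min = 0) {
  stopifnot(dc_min >= 0, cc_min >= 0, cc_min <= 1, bc_min >= 0, bc_min <= 1)
  structure(list(dc_min = dc_min, cc_min = cc_min, bc_min = bc_min),
            class = "screen_criteria")
}

#' Iterative centrality-threshold screening of a PPI network
#'
#' Each round keeps the nodes whose degree, closeness and betweenness all
#' meet that round's thresholds (inclusive `>=`). In the default
#' `"fixed-centralities"` mode centralities are computed once on the input
#' network and every round thresholds those same values, so survivors are
#' nested and late-round degree cutoffs refer to the original network (a
#' round-2 cutoff like DC >= 26 is unsatisfiable inside an 18-node
#' subnetwork, which is why this mode is the default). `"recompute"` mode
#' recomputes centralities on each induced subnetwork first.
#'
#' A round with zero survivors terminates the sequence; remaining rounds
#' report empty survivor sets.
#'
#' @param net an [interaction_network()]
#' @param rounds non-empty list of [screen_criteria()]
#' @param mode `"fixed-centralities"` (default) or `"recompute"`
#' @return list of per-round results, each a list with `criteria`,
#'   `survivors` (character), `induced_edge_count` (edges of `net` with both
#'   endpoints surviving) and `centralities` (the data.frame thresholded in
#'   that round, restricted to the round's candidate nodes)
#' @export
iterative_screen <- function(net, rounds,
                             mode = c("fixed-centralities", "recompute")) {
  mode <- match.arg(mode)
  stopifnot(length(rounds) > 0)
  if (mode == "fixed-centralities" && length(rounds) > 1) {
    for (k in 2:length(rounds)) {
      prev <- rounds[[k - 1]]; cur <- rounds[[k]]
      if (cur$dc_min < prev$dc_min || cur$cc_min < prev$cc_min ||
          cur$bc_min < prev$bc_min)
        warning("round ", k, " thresholds are below round ", k - 1,
                "'s; survivors are still nested by construction")
    }
  }
  cent_full <- centralities(net)
  survivors <- net$nodes
  out <- vector("list", length(rounds))
  for (k in seq_along(rounds)) {
    crit <- rounds[[k]]
    if (length(survivors) == 0) {
      out[[k]] <- list(criteria = crit, survivors = character(),
                       induced_edge_count = 0L,
                       centralities = cent_full[0, ])
      next
    }
    cent <- if (mode == "recompute")
      centralities(induced_subnetwork(net, survivors))
    else cent_full[cent_full$node %in% survivors, , drop = FALSE]
    pass <- cent$dc >= crit$dc_min & cent$cc >= crit$cc_min &
            cent$bc >= crit$bc_min
    survivors <- cent$node[pass]
    sub <- induced_subnetwork(net, survivors)
    out[[k]] <- list(criteria = crit, survivors = survivors,
                     induced_edge_count = n_edges(sub),
                     centralities = cent)
  }
  out
}

#' Rank nodes by one centrality
#'
#' Stable descending sort on the chosen measure, ties broken alphabetically
#' by node id.
#'
#' @param cent data.frame as from [centralities()]
#' @param key `"dc"`, `"cc"` or `"bc"`
#' @return `cent` reordered
#' @export
rank_nodes <- function(cent, key = c("dc", "cc", "bc")) {
  key <- match.arg(key)
  cent[order(-cent[[key]], cent$node), , drop = FALSE]
}

#' Quantile-based screening thresholds
#'
#' A convenience for users without hand-picked cutoffs: the `q`-quantile of
#' each centrality over the supplied records (degree rounded up to an
#' integer). `q = 0.5` gives medians, `q = 0` minima.
#'
#' @param cent non-empty data.frame as from [centralities()]
#' @param q quantile in \[0, 1\]
#' @return a [screen_criteria()]
#' @export
quantile_thresholds <- function(cent, q) {
  if (nrow(cent) == 0) stop("no centrality records")
  stopifnot(q >= 0, q <= 1)
  screen_criteria(
    dc_min = as.integer(ceiling(quantile(cent$dc, q, names = FALSE))),
    cc_min = quantile(cent$cc, q, names = FALSE),
    bc_min = quantile(cent$bc, q, names = FALSE))
}
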