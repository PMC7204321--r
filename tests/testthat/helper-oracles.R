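# Independent brute-force oracles. Deliberately igraph-free and slow:
# adjacency matrices, hand-rolled BFS, explicit shortest-path enumeration,
# combinatorial enumeration of hypergeometric draws.

# all-pairs shortest distances by BFS on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (d[s, v] > depth) { d[s, v] <- depth; nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# every shortest s->t path, as a list of vertex sequences (explicit DFS over
# distance-decreasing edges)
oracle_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (u in which(adj[, t] > 0)) {
    if (d[s, u] == d[s, t] - 1) {
      for (p in oracle_shortest_paths(adj, d, s, u))
        out[[length(out) + 1]] <- c(p, t)
    }
  }
  out
}

# degree / Wasserman-Faust closeness / normalized betweenness by explicit
# enumeration of all shortest paths
oracle_centralities <- function(adj, nodes = rownames(adj)) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  dc <- rowSums(adj > 0)
  cc <- numeric(n); bc <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]))
    r <- length(reach)
    cc[v] <- if (r > 1 && n > 1)
      ((r - 1) / sum(d[v, reach])) * ((r - 1) / (n - 1)) else 0
  }
  if (n > 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(adj, d, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  data.frame(node = nodes, dc = as.integer(dc), cc = cc, bc = bc,
             row.names = NULL)
}

# Erdos-Renyi test graph as (interaction_network, adjacency) under the
# caller's RNG state
random_er <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < p
  adj[pairs[on, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  net <- interaction_network(
    nodes = nodes,
    edges = data.frame(from = nodes[e[, 1]], to = nodes[e[, 2]]))
  list(net = net, adj = adj)
}

# P(overlap >= k) by enumerating every size-n draw from a size-N background
# containing a size-K set
oracle_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# textbook BH step-up on sorted p-values, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o] * m / seq_len(m)
  sorted <- rev(cummin(rev(sorted)))
  adj <- numeric(m)
  adj[o] <- pmin(sorted, 1)
  adj
}
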