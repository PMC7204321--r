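p3 <- interaction_network(edges = data.frame(from = c("A", "B"),
                                             to = c("B", "C")))
k4 <- interaction_network(edges = do.call(rbind, lapply(
  asplit(combn(LETTERS[1:4], 2), 2),
  function(p) data.frame(from = p[1], to = p[2]))))

test_that("centralities match closed forms on P3 and K4", {
  cent <- centralities(p3)
  b <- cent[cent$node == "B", ]
  expect_equal(b$dc, 2)
  expect_equal(b$cc, 1)
  expect_equal(b$bc, 1)
  a <- cent[cent$node == "A", ]
  expect_equal(a$dc, 1)
  expect_equal(a$cc, 2 / 3)
  expect_equal(a$bc, 0)

  cent4 <- centralities(k4)
  expect_equal(cent4$dc, rep(3L, 4))
  expect_equal(cent4$cc, rep(1, 4))
  expect_equal(cent4$bc, rep(0, 4))
})

test_that("centralities match the path-enumeration oracle on random graphs", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    g <- random_er(n, runif(1, 0.2, 0.7))
    got <- centralities(g$net)
    want <- oracle_centralities(g$adj)
    got <- got[match(want$node, got$node), ]
    expect_equal(got$dc, want$dc)
    expect_equal(got$cc, want$cc, tolerance = 1e-10)
    expect_equal(got$bc, want$bc, tolerance = 1e-10)
    # handshake identity
    expect_equal(sum(got$dc), 2 * n_edges(g$net))
  }
})

test_that("degenerate and disconnected graphs are well-defined", {
  expect_equal(nrow(centralities(interaction_network())), 0)
  lone <- centralities(interaction_network(nodes = "X"))
  expect_equal(lone$dc, 0L)
  expect_equal(lone$cc, 0)

  # two components + an isolated node: values stay in [0, 1]
  net <- interaction_network(nodes = "Z",
                             edges = data.frame(from = c("A", "B", "D"),
                                                to = c("B", "C", "E")))
  cent <- centralities(net)
  expect_true(all(cent$cc >= 0 & cent$cc <= 1))
  expect_true(all(cent$bc >= 0 & cent$bc <= 1))
  expect_equal(cent$cc[cent$node == "Z"], 0)

  # star: center adjacent to all others has cc exactly 1; leaves have bc 0
  star <- interaction_network(edges = data.frame(
    from = "HUB", to = sprintf("L%d", 1:6)))
  cent <- centralities(star)
  expect_equal(cent$cc[cent$node == "HUB"], 1)
  expect_equal(cent$bc[cent$node != "HUB"], rep(0, 6))
  expect_equal(cent$bc[cent$node == "HUB"], 1)
})

test_that("iterative_screen keeps nested survivors and reports edges", {
  set.seed(66)
  g <- random_er(15, 0.3)$net
  zero <- screen_criteria(0, 0, 0)
  rounds <- iterative_screen(g, list(zero, zero))
  expect_setequal(rounds[[1]]$survivors, g$nodes)
  expect_setequal(rounds[[2]]$survivors, g$nodes)
  expect_equal(rounds[[2]]$induced_edge_count, n_edges(g))

  # thresholds above every node empty the first round and terminate
  high <- screen_criteria(dc_min = 100)
  rounds <- suppressWarnings(iterative_screen(g, list(high, zero)))
  expect_length(rounds[[1]]$survivors, 0)
  expect_length(rounds[[2]]$survivors, 0)

  # nestedness across random threshold ladders (fixed-centralities mode)
  for (i in 1:10) {
    g <- random_er(sample(8:14, 1), 0.35)$net
    cent <- centralities(g)
    qs <- sort(runif(3))
    rounds <- iterative_screen(g, lapply(qs, quantile_thresholds,
                                         cent = cent))
    for (k in 2:3)
      expect_true(all(rounds[[k]]$survivors %in% rounds[[k - 1]]$survivors))
    # induced edge counts match a direct tally on the parent network
    for (k in 1:3) {
      s <- rounds[[k]]$survivors
      expect_equal(rounds[[k]]$induced_edge_count,
                   sum(g$edges$from %in% s & g$edges$to %in% s))
    }
  }

  # decreasing thresholds warn in fixed mode
  expect_warning(
    iterative_screen(g, list(screen_criteria(2, 0, 0),
                             screen_criteria(1, 0, 0))),
    "below")
})

test_that("recompute mode rescores centralities on the induced subnetwork", {
  # P4: ends have dc 1; interior dc 2. Fixed mode keeps the interior pair in
  # round 2 (original dc 2); recompute mode drops everything at dc_min 2
  # because the induced P2 has max degree 1.
  p4 <- interaction_network(edges = data.frame(
    from = c("A", "B", "C"), to = c("B", "C", "D")))
  fixed <- iterative_screen(p4, list(screen_criteria(2), screen_criteria(2)))
  expect_setequal(fixed[[2]]$survivors, c("B", "C"))
  recomp <- iterative_screen(p4, list(screen_criteria(2), screen_criteria(2)),
                             mode = "recompute")
  expect_length(recomp[[2]]$survivors, 0)
})

test_that("rank_nodes sorts stably with alphabetical tie-break", {
  cent <- data.frame(node = c("C", "A", "B"), dc = c(2L, 2L, 2L),
                     cc = c(0.5, 0.5, 0.5), bc = c(0, 0, 0))
  expect_equal(rank_nodes(cent, "dc")$node, c("A", "B", "C"))
  set.seed(71)
  cent <- data.frame(node = sprintf("N%02d", 1:20), dc = sample(1:5, 20, TRUE),
                     cc = runif(20), bc = runif(20))
  for (key in c("dc", "cc", "bc")) {
    got <- rank_nodes(cent, key)
    expect_equal(got$node,
                 cent$node[order(-cent[[key]], cent$node)])
  }
})

test_that("quantile_thresholds matches sorting oracle", {
  cent <- data.frame(node = c("A", "B"), dc = c(3L, 3L), cc = c(0.4, 0.4),
                     bc = c(0.1, 0.1))
  const <- quantile_thresholds(cent, 0.7)
  expect_equal(const$dc_min, 3L)
  expect_equal(const$cc_min, 0.4)
  expect_equal(const$bc_min, 0.1)

  set.seed(72)
  cent <- data.frame(node = sprintf("N%d", 1:15), dc = sample(0:9, 15, TRUE),
                     cc = runif(15), bc = runif(15))
  lo <- quantile_thresholds(cent, 0)
  expect_equal(lo$dc_min, min(cent$dc))
  expect_equal(lo$cc_min, min(cent$cc))
  q <- quantile_thresholds(cent, 0.5)
  expect_equal(q$cc_min, stats::median(cent$cc))
  expect_equal(q$dc_min, as.integer(ceiling(stats::median(cent$dc))))
  expect_error(quantile_thresholds(cent[0, ], 0.5), "no centrality")
})
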