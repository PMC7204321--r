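test_that("packaged fixtures load and satisfy their invariants", {
  comp <- dchd_compounds()
  expect_equal(nrow(comp), 77)
  expect_true(all(comp$herb %in% HERB_CODES))
  expect_true(all(comp$mw > 0))
  expect_true(all(comp$dl >= 0 & comp$dl <= 1))
  expect_true(all(comp$hdon == round(comp$hdon)))
  # OB above 100 occurs in the published table; no upper bound
  expect_gt(max(comp$ob), 100)

  targ <- dchd_targets()
  expect_equal(nrow(targ), 161)
  expect_true(all(nzchar(targ$gene_symbol)))
  expect_true(all(unlist(targ$herb_list) %in% HERB_CODES))
  # variant herb spelling is canonicalized on input
  expect_false(any(grepl("RRER", targ$herbs)))

  dis <- t2dm_targets()
  expect_equal(nrow(dis), 38)
  expect_true(all(is.na(dis$inference_score)))
})

test_that("compound table round-trips through write/read", {
  gen <- gen_compound_table(sim_config(seed = 11, n_compounds = 10,
                                       pass_fraction = 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(gen$compounds, path)
  back <- read_compound_table(path)
  expect_equal(back, gen$compounds, tolerance = 1e-12)
})

test_that("compound reader rejects malformed tables with named errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  comp <- dchd_compounds()

  writeLines("mol_id\tname\therb\tmw\talogp\thdon\thacc\tob", path)
  expect_error(read_compound_table(path), "dl")

  bad <- comp[1:3, ]
  bad$mw <- c("302.25", "oops", "290")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_compound_table(path), "row 2")

  bad <- comp[1:2, ]
  bad$herb <- c("RB", "XYZ")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_compound_table(path), "XYZ")

  # header-only file gives an empty table, not an error
  writeLines("mol_id\tname\therb\tmw\talogp\thdon\thacc\tob\tdl", path)
  expect_equal(nrow(read_compound_table(path)), 0)
})

test_that("edge list reader collapses duplicates and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B 700", "B A 700", "C C 900"), path)
  expect_warning(net <- read_edge_list(path, "string1000"), "self-loop")
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$confidence, 0.7)

  writeLines(character(0), path)
  expect_equal(n_nodes(read_edge_list(path, "unit")), 0)

  # asymmetric duplicate scores keep the max, regardless of row order
  writeLines(c("A B 0.4", "B A 0.9"), path)
  expect_equal(read_edge_list(path, "unit")$edges$confidence, 0.9)

  writeLines(c("A B 1700"), path)
  expect_error(read_edge_list(path, "string1000"), "row 1")
  writeLines(c("A B 1.3"), path)
  expect_error(read_edge_list(path, "unit"), "row 1")
})

test_that("random edge file matches a set-based dedup oracle", {
  set.seed(402)
  nodes <- sprintf("N%02d", 1:12)
  from <- sample(nodes, 50, replace = TRUE)
  to <- sample(nodes, 50, replace = TRUE)
  score <- sample(0:999, 50)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%s\t%s\t%d", from, to, score), path)
  net <- suppressWarnings(read_edge_list(path, "string1000"))
  keep <- from != to
  oracle_pairs <- unique(paste(pmin(from[keep], to[keep]),
                               pmax(from[keep], to[keep])))
  expect_equal(n_edges(net), length(oracle_pairs))
  expect_false(any(net$edges$from == net$edges$to))
  expect_false(anyDuplicated(paste(net$edges$from, net$edges$to)) > 0)
})

test_that("SIF and GraphML exports round-trip", {
  set.seed(77)
  net <- random_er(9, 0.3)$net
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, sif, "sif")
  write_network(net, gml, "graphml")
  for (back in list(read_sif(sif), read_graphml(gml))) {
    expect_setequal(back$nodes, net$nodes)
    expect_equal(back$edges[order(back$edges$from, back$edges$to),
                            c("from", "to")],
                 net$edges[order(net$edges$from, net$edges$to),
                           c("from", "to")],
                 ignore_attr = TRUE)
  }
  # GraphML preserves confidences too
  expect_equal(sort(read_graphml(gml)$edges$confidence),
               sort(net$edges$confidence))

  # 3-node path -> 2 SIF lines; empty network -> empty SIF, valid GraphML
  p3 <- interaction_network(edges = data.frame(from = c("A", "B"),
                                               to = c("B", "C")))
  write_network(p3, sif, "sif")
  expect_length(readLines(sif), 2)
  empty <- interaction_network()
  write_network(empty, sif, "sif")
  expect_length(readLines(sif), 0)
  write_network(empty, gml, "graphml")
  expect_equal(n_nodes(read_graphml(gml)), 0)

  expect_error(write_network(p3, sif, "sif",
                             node_attrs = data.frame(node = "Z", x = 1)),
               "unknown node")
})

test_that("GMT reader enforces format and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst set\tTP53\tJUN\tTP53",
               "S2\tsecond set\tCAT"), path)
  col <- read_gmt(path)
  expect_equal(col$sets, list(S1 = c("TP53", "JUN"), S2 = "CAT"))
  expect_equal(unname(col$descriptions["S2"]), "second set")

  writeLines(c("S1\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 1")

  writeLines(character(0), path)
  expect_length(read_gmt(path)$sets, 0)

  ann <- gen_annotation_collection(sim_config(seed = 5, n_sets = 4,
                                              background_size = 60,
                                              planted_set_size = 12,
                                              query_size = 15,
                                              planted_overlap = 6))
  write_gmt(ann$collection, path)
  back <- read_gmt(path)
  expect_equal(back$sets, ann$collection$sets)
  expect_equal(back$descriptions, ann$collection$descriptions)
})
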