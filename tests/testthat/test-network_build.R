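mk_pool <- function(ids, mapping = NULL) gene_pool(ids, mapping)

test_that("build_bipartite constructs typed layers and rejects bad edges", {
  assoc <- data.frame(herb = c("H1", "H2", "H3", "H1"),
                      pc = c("P1", "P1", "P1", "P2"))
  net <- build_bipartite(assoc, "herb", "compound")
  expect_identical(unname(igraph::degree(net, "P1")), 3)
  nl <- network_nodes(net)
  expect_identical(sum(nl$layer == "herb"), 3L)
  expect_warning(build_bipartite(assoc[0, ], "herb", "compound"), "empty")
  # intra-layer edges rejected by the constructor
  expect_error(layered_network(
    data.frame(name = c("a", "b"), layer = "compound"),
    data.frame(from = "a", to = "b")), "intra-layer")
  # undeclared endpoint rejected
  expect_error(layered_network(
    data.frame(name = "a", layer = "compound"),
    data.frame(from = "a", to = "zzz")), "declared")
})

test_that("filter_to_pool keeps pool-protein edges, drops isolates, keeps votes", {
  pairs <- data.frame(compound_id = c("c1", "c1", "c2", "c3"),
                      protein_id = c("P00001", "P00002", "P00002", "P00003"),
                      votes = c(3L, 1L, 2L, 1L))
  net <- build_bipartite(pairs, "compound", "protein")
  pool <- mk_pool(c("P00001", "P00002"))
  sub <- filter_to_pool(net, pool)
  ed <- network_edges(sub)
  expect_identical(nrow(ed), 3L)
  expect_false("c3" %in% network_nodes(sub)$name)
  expect_setequal(ed$votes, c(3L, 1L, 2L))
  # boundary identities
  all_pool <- mk_pool(unique(pairs$protein_id))
  expect_equal(igraph::ecount(filter_to_pool(net, all_pool)),
                   igraph::ecount(net))
  disjoint <- mk_pool("P99999")
  expect_equal(igraph::vcount(filter_to_pool(net, disjoint)), 0L)
})

test_that("ppi_subgraph normalizes score scales and reports provenance", {
  pool <- mk_pool(c("P00001", "P00002", "P00003", "P00004"))
  # 0-1000 milli-score dialect
  ed <- data.frame(protein_a = c("P00001", "P00002", "P00003"),
                   protein_b = c("P00002", "P00003", "P00003"),
                   score = c(900, 889, 990))
  net <- ppi_subgraph(ed, pool, 0.9)   # self-loop P3-P3 dropped
  expect_equal(igraph::ecount(net), 1L)
  expect_setequal(network_nodes(net)$name, c("P00001", "P00002"))
  # 0-1 dialect: 0.89 excluded at 0.9
  ed2 <- data.frame(protein_a = "P00001", protein_b = "P00002", score = 0.89)
  expect_equal(igraph::ecount(ppi_subgraph(ed2, pool, 0.9)), 0L)
  # duplicate unordered pair keeps max score
  ed3 <- data.frame(protein_a = c("P00001", "P00002"),
                    protein_b = c("P00002", "P00001"), score = c(0.95, 0.91))
  net3 <- ppi_subgraph(ed3, pool, 0.9)
  expect_equal(igraph::ecount(net3), 1L)
  expect_equal(network_edges(net3)$score, 0.95)
  prov <- attr(net3, "provenance")
  expect_identical(prov$interacting, 2L)
  expect_error(ppi_subgraph(ed[0, ], pool), "empty")
})

test_that("giant_component picks the largest component deterministically and is idempotent", {
  nodes <- data.frame(name = c(letters[1:5], LETTERS[1:3]), layer = "protein")
  edges <- data.frame(from = c("a", "b", "c", "d", "A", "B"),
                      to   = c("b", "c", "d", "e", "B", "C"))
  net <- layered_network(nodes, edges, allow_intralayer = "protein")
  gc1 <- giant_component(net)
  expect_setequal(network_nodes(gc1)$name, letters[1:5])
  expect_setequal(attr(gc1, "removed"), LETTERS[1:3])
  # idempotence
  gc2 <- giant_component(gc1)
  expect_setequal(network_nodes(gc2)$name, network_nodes(gc1)$name)
  # connected graph returns itself
  expect_equal(igraph::vcount(giant_component(gc1)), igraph::vcount(gc1))
  # tie on nodes broken by edge count
  nodes2 <- data.frame(name = c("a", "b", "c", "x", "y", "z"), layer = "protein")
  edges2 <- data.frame(from = c("a", "b", "c", "x", "y"),
                       to   = c("b", "c", "a", "y", "z"))
  gct <- giant_component(layered_network(nodes2, edges2,
                                         allow_intralayer = "protein"))
  expect_setequal(network_nodes(gct)$name, c("a", "b", "c"))
  expect_error(giant_component(layered_network(
    data.frame(name = character(0), layer = character(0)))), "empty")
})

test_that("build_tripartite keeps only middle-incident edges with provenance", {
  left <- data.frame(compound_id = c("c1", "c2"), protein_id = c("P1", "P9"),
                     votes = c(3L, 1L))
  right <- data.frame(drug_id = "d1", protein_id = "P1")
  net <- build_tripartite("P1", left, right)
  nl <- network_nodes(net)
  expect_setequal(nl$name, c("c1", "P1", "d1"))
  ed <- network_edges(net)
  expect_setequal(ed$side, c("compound", "drug"))
  expect_identical(ed$votes[ed$side == "compound"], 3L)
  expect_warning(build_tripartite("P1", left, NULL), "degenerate")
})

test_that("GraphML round-trip preserves nodes, layers and edge attributes", {
  nodes <- data.frame(name = c("c1", "P1", "P2"),
                      layer = c("compound", "protein", "protein"))
  edges <- data.frame(from = c("c1", "P1"), to = c("P1", "P2"),
                      votes = c(3L, NA), score = c(NA, 0.97))
  net <- layered_network(nodes, edges, allow_intralayer = "protein")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f)
  expect_setequal(igraph::V(back)$name, nodes$name)
  expect_identical(
    network_nodes(back)[order(network_nodes(back)$name), ]$layer,
    nodes[order(nodes$name), ]$layer)
  eb <- network_edges(back)
  eo <- network_edges(net)
  ord <- function(d) d[order(d$from, d$to), c("from", "to", "votes", "score")]
  expect_equal(ord(eb), ord(eo), ignore_attr = TRUE)
})
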