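pnet <- function(edges) {
  nodes <- data.frame(name = unique(c(edges$from, edges$to)), layer = "protein")
  layered_network(nodes, edges, allow_intralayer = "protein")
}

test_that("centralities match hand-derived and brute-force values", {
  # path A-B-C: only B is intermediate
  ce <- centralities(pnet(data.frame(from = c("A", "B"), to = c("B", "C"))))
  expect_equal(ce$betweenness_Cb[ce$node_id == "B"], 1)
  expect_equal(ce$betweenness_Cb[ce$node_id != "B"], c(0, 0))
  # 4-cycle: each node 1/6
  c4 <- pnet(data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a")))
  expect_equal(centralities(c4)$betweenness_Cb, rep(1 / 6, 4))
  # n < 3 warns and reports 0
  tiny <- pnet(data.frame(from = "a", to = "b"))
  expect_warning(ct <- centralities(tiny), "fewer than 3")
  expect_equal(ct$betweenness_Cb, c(0, 0))
})

test_that("betweenness equals the brute-force shortest-path enumerator", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    nodes <- sprintf("n%02d", 1:n)
    pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(pairs)) < 0.35
    if (sum(sel) < 3) sel[1:3] <- TRUE
    edges <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2])
    net <- pnet(edges)
    got <- centralities(net)
    want <- oracle_betweenness(edges, network_nodes(net)$name)
    expect_equal(got$betweenness_Cb, unname(want[got$node_id]),
                 tolerance = 1e-10, info = paste("rep", rep))
  }
})

test_that("fit_powerlaw is OLS on log-log raw counts", {
  # noiseless planted data
  pf <- fit_powerlaw(data.frame(k = 1:10, n_k = 100 * (1:10)^-2))
  expect_equal(pf$exponent_gamma, 2, tolerance = 1e-9)
  expect_equal(pf$coefficient_a, 100, tolerance = 1e-6)
  # constant histogram -> zero exponent
  pf0 <- fit_powerlaw(data.frame(k = 1:8, n_k = 7))
  expect_equal(pf0$exponent_gamma, 0, tolerance = 1e-12)
  # single support point -> error
  expect_error(fit_powerlaw(data.frame(k = 3, n_k = 5)), "at least 2")
  # multinomial-resampled histogram recovers gamma within 0.1
  set.seed(19)
  k <- 1:15
  probs <- k^-1.6 / sum(k^-1.6)
  counts <- as.integer(stats::rmultinom(1, 5000, probs))
  pf2 <- fit_powerlaw(data.frame(k = k, n_k = counts)[counts > 0, ])
  expect_equal(pf2$exponent_gamma, 1.6, tolerance = 0.1)
})

test_that("mcode recovers a planted clique and respects its contract", {
  # 6-clique bridged to a sparse 20-node background
  cl <- t(combn(sprintf("K%d", 1:6), 2))
  set.seed(3)
  bg_from <- sprintf("B%02d", sample(20, 30, replace = TRUE))
  bg_to <- sprintf("B%02d", sample(20, 30, replace = TRUE))
  keep <- bg_from != bg_to
  edges <- rbind(data.frame(from = cl[, 1], to = cl[, 2]),
                 data.frame(from = bg_from[keep], to = bg_to[keep]),
                 data.frame(from = "K1", to = "B01"))
  net <- pnet(edges)
  mods <- mcode(net)
  expect_gte(length(mods), 1L)
  expect_identical(mods[[1]]$members, sprintf("K%d", 1:6))
  # modules are disjoint and each survives its haircut condition
  all_members <- unlist(lapply(mods, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
  for (m in mods) {
    sub <- igraph::induced_subgraph(net, m$members)
    expect_true(all(igraph::degree(sub) >= 2), info = m$module_id)
    expect_true(igraph::is_connected(sub))
  }
  # edgeless graph -> no modules
  empty <- layered_network(data.frame(name = c("x", "y"), layer = "protein"))
  expect_identical(mcode(empty), list())
  # determinism
  expect_identical(mcode(net), mcode(net))
})

test_that("degree histogram + centralities are consistent", {
  set.seed(29)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  igraph::V(g)$layer <- "protein"
  class(g) <- c("layered_network", class(g))
  ce <- centralities(g)
  expect_identical(ce$degree_Cd, unname(as.integer(igraph::degree(g))))
  h <- degree_histogram(g)
  expect_identical(sum(h$n_k), sum(igraph::degree(g) > 0))
})
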