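# Generator tests run at reduced scale; the full-scale stated world is
# exercised once by the acceptance suite.

small_bundle <- function(seed = 101) {
  gen_bundle(seed = seed, n_herb = 6L, n_pc = 80L, n_drug = 100L, n_aed = 8L,
             n_protein = 200L, n_pool = 80L, n_pathway = 3L,
             near_dup_rate = 0.05, exact_dup_rate = 0.3)
}

test_that("generation is deterministic under a fixed seed", {
  b1 <- gen_compounds(n_pc = 30, n_drug = 30, seed = 5,
                      near_dup_rate = 0.1, exact_dup_rate = 0.2)
  b2 <- gen_compounds(n_pc = 30, n_drug = 30, seed = 5,
                      near_dup_rate = 0.1, exact_dup_rate = 0.2)
  expect_identical(b1, b2)
  b3 <- gen_compounds(n_pc = 30, n_drug = 30, seed = 6,
                      near_dup_rate = 0.1, exact_dup_rate = 0.2)
  expect_false(identical(b1$compounds$smiles, b3$compounds$smiles))
})

test_that("planted near- and exact duplicates satisfy their defining relations", {
  b <- gen_compounds(n_pc = 60, n_drug = 80, seed = 9,
                     near_dup_rate = 0.1, exact_dup_rate = 0.25)
  comp <- b$compounds
  smiles <- stats::setNames(comp$smiles, comp$compound_id)
  nd <- b$sidecar$planted_near_duplicates
  expect_gt(length(nd), 0)
  for (p in nd) {
    tc <- tanimoto(fingerprint(smiles[p$pc]), fingerprint(smiles[p$drug]))
    expect_gt(tc, 0.85); expect_lt(tc, 1)
    expect_equal(tc, p$tc)
    expect_false(smiles[p$pc] == smiles[p$drug])
  }
  for (e in b$sidecar$planted_exact_duplicates) {
    expect_identical(unname(smiles[e$dup]), unname(smiles[e$of]))
  }
  # near_dup_rate = 0 -> no planted pairs
  b0 <- gen_compounds(n_pc = 20, n_drug = 20, seed = 2, near_dup_rate = 0,
                      exact_dup_rate = 0)
  expect_length(b0$sidecar$planted_near_duplicates, 0)
  expect_identical(b0$sidecar$n_unique_pc, 20)
})

test_that("ADMET generator plants an exact pass set", {
  ids <- sprintf("PC%03d", 1:50)
  g <- gen_admet(ids, pass_fraction = 0.4, seed = 3)
  v <- screen_dpcs(g$admet)
  expect_setequal(v$compound_id[v$passed %in% TRUE], g$sidecar$planted_pass_set)
  expect_identical(length(g$sidecar$planted_pass_set), 20L)
  # every failing record violates exactly the planted rules
  for (id in names(g$sidecar$planted_violations)) {
    got <- sort(strsplit(v$violated_rules[v$compound_id == id], ";")[[1]])
    expect_identical(got, g$sidecar$planted_violations[[id]], info = id)
  }
  # extremes
  expect_true(all(screen_dpcs(gen_admet(ids, 1, seed = 4)$admet)$passed))
  expect_false(any(screen_dpcs(gen_admet(ids, 0, seed = 4)$admet)$passed))
})

test_that("prediction generator straddles thresholds and matches binomial expectation", {
  g <- gen_predictions(sprintf("c%03d", 1:150), sprintf("P%05d", 1:500),
                       mean_targets = 12, per_source_hit_prob = 0.5,
                       overlap_boost = 0, seed = 21)
  p <- g$predictions
  # below-threshold rows present by construction
  expect_gt(sum(p$source == "bindingdb" & p$score < 0.85), 0)
  expect_gt(sum(p$source == "stitch" & p$score < 0.4), 0)
  expect_gt(sum(p$source == "swisstarget" & p$rank > 15), 0)
  # vote histogram ~ Binomial(3, 0.5) conditional on >= 1 vote, within 3 sigma
  votes <- g$sidecar$planted_votes$votes
  n <- length(votes)
  for (v in 1:3) {
    pv <- choose(3, v) * 0.5^3 / (1 - 0.5^3)
    expect_lt(abs(sum(votes == v) - n * pv), 3 * sqrt(n * pv * (1 - pv)) + 1,
              label = sprintf("votes == %d count", v))
  }
})

test_that("PPI generator plants recoverable cliques over controlled background", {
  nodes <- sprintf("P%05d", 1:120)
  g <- gen_ppi(nodes, module_sizes = c(6L, 5L), p_background = 0.01, seed = 8)
  pool <- gene_pool(nodes)
  net <- ppi_subgraph(g$edges, pool, 0)  # keep everything
  mods <- mcode(net)
  planted <- lapply(g$sidecar$planted_modules, sort)
  got <- lapply(mods, `[[`, "members")
  for (pm in planted) {
    expect_true(any(vapply(got, function(m) all(pm %in% m), logical(1))),
                info = paste(pm, collapse = ","))
  }
  # p_background = 0: components are exactly the cliques plus isolates
  g0 <- gen_ppi(nodes, module_sizes = c(6L, 5L), p_background = 0, seed = 8)
  net0 <- ppi_subgraph(g0$edges, pool, 0)
  comp <- igraph::components(net0)
  expect_setequal(comp$csize, c(6, 5))
  # clique edges all score >= 0.9
  expect_true(all(g0$edges$score >= 0.9))
})

test_that("the full bundle is internally consistent", {
  b <- small_bundle()
  # herb associations reference unique phytochemicals only
  expect_true(all(b$herb_pc$pc_id %in% b$sidecar$unique_pc))
  expect_true(all(table(b$herb_pc$pc_id) >= 1))
  # ADMET covers exactly the unique phytochemicals
  expect_setequal(b$admet$compound_id, b$sidecar$unique_pc)
  # planted neumods pass the screen and have wired predictions
  v <- screen_dpcs(b$admet)
  for (pc in b$sidecar$planted_neumods) {
    expect_true(v$passed[v$compound_id == pc], info = pc)
    expect_true(pc %in% b$predictions$compound_id)
  }
  # bundle round-trips through the plain-text writers
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_identical(b2$compounds$smiles, b$compounds$smiles)
  expect_identical(nrow(b2$predictions), nrow(b$predictions))
  expect_identical(b2$gene_pool_ids, b$gene_pool_ids)
})
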