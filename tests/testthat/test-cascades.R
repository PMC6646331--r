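cp <- function(cid, pid, votes = 1L) {
  data.frame(compound_id = cid, protein_id = pid, votes = votes,
             stringsAsFactors = FALSE)
}

test_that("select_nm_proteins intersects pathways with the approved list", {
  targets <- cp(c("c1", "c1", "c2"), c("P00001", "P00002", "P00003"))
  pw <- data.frame(pathway_id = c("hsa1", "hsa1", "hsa2"),
                   protein_id = c("P00001", "P00002", "P00009"))
  nm <- select_nm_proteins(targets, pw, approved_targets = c("P00002", "P00009"))
  expect_identical(nm$pre_intersection, c("P00001", "P00002"))
  expect_identical(nm$proteins, "P00002")
  # empty approved list -> empty NM set
  nm0 <- select_nm_proteins(targets, pw, character(0))
  expect_length(nm0$proteins, 0)
  expect_error(select_nm_proteins(targets, pw[0, ], "P00001"), "empty")
})

test_that("build_datasets produces D, D1, D2 with containment", {
  targets <- cp(c("c1", "c2", "c3"), c("P00001", "P00002", "P00009"))
  dt <- data.frame(drug_id = c("d1", "d2", "d3"),
                   protein_id = c("P00001", "P00002", "P00099"))
  pw <- data.frame(pathway_id = "hsa1", protein_id = c("P00001", "P00002"))
  nm <- select_nm_proteins(targets, pw, approved_targets = c("P00001", "P00002"))
  ds <- build_datasets(nm, targets, dt)
  expect_setequal(ds$D, c("d1", "d2"))      # d3's target is no DPC target
  expect_setequal(ds$D1, c("c1", "c2"))
  expect_setequal(ds$D2, c("d1", "d2"))
  expect_true(all(ds$D2 %in% ds$D))
  # empty NM set -> empty D1/D2
  nm_empty <- select_nm_proteins(targets, pw, character(0))
  ds0 <- build_datasets(nm_empty, targets, dt)
  expect_length(ds0$D1, 0); expect_length(ds0$D2, 0)
  # removing an NM protein never adds members
  nm1 <- nm; nm1$proteins <- "P00001"
  ds1 <- build_datasets(nm1, targets, dt)
  expect_true(all(ds1$D1 %in% ds$D1) && all(ds1$D2 %in% ds$D2))
})

mk_sim <- function(vals, rows, cols) {
  m <- matrix(vals, nrow = length(rows), dimnames = list(rows, cols))
  structure(m, class = c("similarity_matrix", class(m)))
}

test_that("the drug-similarity screen applies both dual-criterion conditions", {
  rows <- c("pc1", "pc2", "pc3")
  cols <- c("d1", "d2")
  sim <- mk_sim(c(0.90, 0.85, 1.00,
                  0.10, 0.20, 0.95), rows, cols)
  smiles <- c(pc1 = "CCO", pc2 = "CCN", pc3 = "CCS", d1 = "CCCC", d2 = "CCS")
  hits <- neumods(sim, smiles, rows, cols)
  # pc1: TC 0.90 with d1 -> hit; pc2: best is exactly 0.85 -> no (strict)
  # pc3: TC 1.0 with d1 excluded, 0.95 with d2 but identical SMILES -> no
  expect_identical(hits$dpc_id, "pc1")
  expect_match(hits$qualifying_drugs, "^d1:0.9000$")
  # per-DPC reading blocks pc1 if ANY drug is identical
  sim2 <- mk_sim(c(0.90, 1.00), "pc1", c("d1", "d2"))
  smiles2 <- c(pc1 = "CCO", d1 = "CCCC", d2 = "CCO")
  expect_identical(nrow(neumods(sim2, smiles2, "pc1", c("d1", "d2"),
                                criteria = "per_dpc")), 0L)
  expect_identical(nrow(neumods(sim2, smiles2, "pc1", c("d1", "d2"),
                                criteria = "per_pair")), 1L)
  # missing D1 row is an error naming the compound
  expect_error(neumods(sim, smiles, c(rows, "pcX"), cols), "pcX")
})

test_that("the hit set shrinks monotonically as the TC threshold rises", {
  set.seed(41)
  rows <- sprintf("pc%02d", 1:12)
  cols <- sprintf("d%02d", 1:20)
  sim <- mk_sim(runif(240, 0.5, 0.99), rows, cols)
  smiles <- stats::setNames(paste0("C", seq_len(32)), c(rows, cols))
  prev <- NULL
  for (thr in c(0.6, 0.7, 0.8, 0.9, 0.95)) {
    hits <- neumods(sim, smiles, rows, cols, tc_min = thr)$dpc_id
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
  }
})

test_that("aed_overlap intersects vote-filtered target sets and flags full coverage", {
  dpc <- rbind(cp("c1", "P00001", 3L), cp("c1", "P00002", 2L),
               cp("c2", "P00001", 1L), cp("c3", "P00003", 2L))
  aed <- rbind(cp("a1", "P00001", 2L), cp("a1", "P00002", 3L),
               cp("a2", "P00009", 2L))
  ov <- aed_overlap(dpc, aed, min_votes = 2L)
  expect_setequal(ov$shared_proteins, c("P00001", "P00002"))
  # c1 covers a1's full filtered target set
  expect_identical(ov$multi_target$covering_dpcs[ov$multi_target$aed_id == "a1"],
                   "c1")
  ed <- network_edges(ov$network)
  expect_identical(nrow(ed), 4L)  # c1-P1, c1-P2, a1-P1, a1-P2
  # disjoint target sets
  ov0 <- aed_overlap(cp("c", "P00001", 3L), cp("a", "P00009", 3L))
  expect_length(ov0$shared_proteins, 0)
  expect_equal(igraph::vcount(ov0$network), 0L)
  # containment: min_votes=1 result contains min_votes=2 result
  ov1 <- aed_overlap(dpc, aed, min_votes = 1L)
  expect_true(all(ov$shared_proteins %in% ov1$shared_proteins))
})

test_that("module_regulators back-maps compounds with vote attributes", {
  nodes <- data.frame(name = c("P00001", "P00002", "P00003"), layer = "protein")
  edges <- data.frame(from = c("P00001", "P00002"), to = c("P00002", "P00003"))
  ppi <- layered_network(nodes, edges, allow_intralayer = "protein")
  mod <- list(members = c("P00001", "P00002", "P00003"))
  dpc_pt <- rbind(cp("c1", "P00001", 3L), cp("c1", "P00003", 2L),
                  cp("c2", "P00002", 1L))
  mr <- module_regulators(mod, ppi, dpc_pt)
  expect_setequal(mr$regulators, c("c1", "c2"))
  expect_identical(mr$multi_targeting, "c1")
  ed <- network_edges(mr$network)
  expect_identical(sum(is.na(ed$votes)), 2L)   # the two PPI edges
  expect_identical(sort(ed$votes[!is.na(ed$votes)]), c(1L, 2L, 3L))
  # module with no regulators: subgraph alone
  mr0 <- module_regulators(mod, ppi, dpc_pt[0, ])
  expect_length(mr0$regulators, 0)
  expect_equal(igraph::vcount(mr0$network), 3L)
})
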