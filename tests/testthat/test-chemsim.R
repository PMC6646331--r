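test_that("canonicalization maps identical molecules to one form and is idempotent", {
  expect_identical(as.character(canonicalize("OCC")),
                   as.character(canonicalize("CCO")))
  c1 <- as.character(canonicalize("CCO"))
  expect_identical(as.character(canonicalize(c1)), c1)
  # equivalent writings of one molecule
  pairs <- list(c("CN(C)C", "N(C)(C)C"),
                c("c1ccccc1O", "Oc1ccccc1"),
                c("CC(C)C(=O)O", "OC(=O)C(C)C"),
                c("C1=CC=CC=C1", "C=1C=CC=CC1"),
                c("c1ccc2ccccc2c1", "c1cc2ccccc2cc1"))
  for (p in pairs) {
    expect_identical(as.character(canonicalize(p[1])),
                     as.character(canonicalize(p[2])), info = p[1])
  }
  # random small molecules: canonical form survives a re-canonicalization
  set.seed(11)
  for (i in 1:25) {
    s <- random_small_smiles(sample(3:10, 1))
    cs <- as.character(canonicalize(s))
    expect_identical(as.character(canonicalize(cs)), cs, info = s)
  }
})

test_that("unparsable SMILES raise a structured error naming the position", {
  err <- expect_error(canonicalize("C("), class = "smiles_parse_error")
  expect_match(conditionMessage(err), "position 2")
  expect_error(canonicalize("C1CC"), class = "smiles_parse_error")
  expect_error(canonicalize("CC)"), class = "smiles_parse_error")
  expect_error(canonicalize("CQ"), class = "smiles_parse_error")
  expect_error(canonicalize(""), class = "smiles_parse_error")
})

test_that("fingerprint follows the documented fragment contract", {
  # methane: single plain-C fragment is excluded
  expect_length(fingerprint("C")$bits, 0)
  expect_length(fingerprint("O")$bits, 0)  # single plain O excluded too
  expect_gt(length(fingerprint("S")$bits), 0)  # S single atom kept
  # identical canonical SMILES => identical bits
  f1 <- fingerprint("CCO"); f2 <- fingerprint("OCC")
  expect_identical(f1$bits, f2$bits)
  expect_lte(length(f1$bits), f1$fragment_count)
})

test_that("fingerprint fragment sets equal the exhaustive enumeration oracle", {
  mols <- c("c1ccccc1", "CCO", "CC(C)C(=O)O", "C1CC2CCC1CC2",
            "N#CCC(=O)O", "CC(=O)[O-]", "c1ccc2ccccc2c1")
  set.seed(23)
  mols <- c(mols, replicate(15, random_small_smiles(sample(4:12, 1))))
  for (s in mols) {
    got <- sort(phytonet:::.path_fragments(parse_smiles(s)))
    expect_identical(got, oracle_fragments(s), info = s)
  }
})

test_that("tanimoto satisfies its algebraic identities", {
  a <- fingerprint("CCOCC")
  expect_identical(tanimoto(a, a), 1)
  # disjoint fingerprints
  fa <- random_fingerprint(); fa$bits <- c(0L, 1L, 2L)
  fb <- fa; fb$bits <- c(10L, 11L)
  expect_identical(tanimoto(fa, fb), 0)
  # direct substitution |A|=10, |B|=8, |A^B|=6
  fa$bits <- 0:9; fb$bits <- c(0:5, 20L, 21L)
  expect_equal(tanimoto(fa, fb), 0.5)
  # both-empty convention
  fe <- fa; fe$bits <- integer(0)
  expect_warning(tc <- tanimoto(fe, fe), "empty")
  expect_identical(tc, 0)
  # n_bits mismatch is a configuration error
  fw <- random_fingerprint(n_bits = 32L)
  expect_error(tanimoto(fa, fw), "n_bits")
})

test_that("tanimoto is symmetric and bounded over random fingerprints", {
  set.seed(5)
  for (i in 1:50) {
    a <- random_fingerprint(); b <- random_fingerprint()
    tab <- suppressWarnings(tanimoto(a, b))
    tba <- suppressWarnings(tanimoto(b, a))
    expect_identical(tab, tba)
    expect_gte(tab, 0); expect_lte(tab, 1)
    if (tab == 1) expect_identical(a$bits, b$bits)
    if (identical(a$bits, b$bits) && length(a$bits) > 0) expect_identical(tab, 1)
  }
})

test_that("similarity_matrix equals brute-force pairwise values", {
  df <- data.frame(compound_id = c("A", "B", "C"),
                   smiles = c("CCO", "CCN", "c1ccccc1"),
                   stringsAsFactors = FALSE)
  m <- similarity_matrix(df)
  fps <- lapply(df$smiles, fingerprint)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(unclass(m)[i, j], suppressWarnings(tanimoto(fps[[i]], fps[[j]])),
                 info = paste(i, j))
  }
  expect_equal(unname(diag(unclass(m))), c(1, 1, 1))
  # 1x1 case
  m1 <- similarity_matrix(df[1, ])
  expect_equal(unname(unclass(m1)[1, 1]), 1)
  # unparsable compounds excluded and reported
  df2 <- rbind(df, data.frame(compound_id = "BAD", smiles = "C("))
  m2 <- similarity_matrix(df2)
  expect_identical(rownames(m2), c("A", "B", "C"))
  expect_identical(attr(m2, "excluded")$compound_id, c("BAD", "BAD"))
  # empty input warns
  expect_warning(similarity_matrix(df[0, ]), "empty")
})

test_that("compound clustering produces correct Newick trees", {
  # two compounds: single merge at d = 1 - TC, branch lengths d/2
  df <- data.frame(compound_id = c("A", "B"), smiles = c("CCO", "CCN"))
  tr <- cluster_compounds(df)
  tc <- unclass(similarity_matrix(df))["A", "B"]
  d <- (1 - tc) / 2
  expect_identical(tr$newick, sprintf("(A:%.6g,B:%.6g);", d, d))
  expect_setequal(tr$leaf_ids, c("A", "B"))
  # duplicate structures merge at height 0 first
  df3 <- data.frame(compound_id = c("X", "Y", "Z"),
                    smiles = c("CCOC", "CCOC", "SCCCS"))
  tr3 <- cluster_compounds(df3)
  expect_match(tr3$newick, "\\(X:0,Y:0\\)")
  # 4 compounds: topology matches a brute-force single-linkage run
  df4 <- data.frame(compound_id = c("A", "B", "C", "D"),
                    smiles = c("CCCCO", "CCCCN", "c1ccccc1", "c1ccccc1C"))
  sim <- similarity_matrix(df4)
  tr4 <- cluster_compounds(sim)
  # oracle: closest pair first
  d4 <- 1 - unclass(sim); diag(d4) <- Inf
  first_pair <- sort(rownames(d4)[which(d4 == min(d4), arr.ind = TRUE)[1, ]])
  expect_match(tr4$newick, paste0("\\(", first_pair[1], ":[0-9.e-]+,",
                                  first_pair[2], ":[0-9.e-]+\\)"))
  expect_error(cluster_compounds(df[1, , drop = FALSE]), "at least 2")
})
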