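# Seeded synthetic-data generator.  Emits the eight input tables of the
# pipeline (herb-phytochemical associations, compound libraries with SMILES,
# ADMET annotations, three target-prediction tables, a disease gene pool
# with ID mapping, pathway membership, an approved drug-target list, and a
# weighted PPI edge list) together with a ground-truth sidecar that records
# every planted fact, so each pipeline stage can be checked exactly without
# re-running the generator.  One top-level seed fans out to per-table
# sub-seeds, so regenerating one table does not perturb the others.

.sub_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k * 7919) %%
               2147483647)
}

# Random chain-with-branches molecule as a SMILES string.  Hetero-atom-rich
# chains give many distinct path fragments, which makes Tanimoto similarity
# controllable by single-atom edits.
.rand_smiles <- function(n_atoms, alphabet = c("C", "C", "C", "N", "O", "S")) {
  atoms <- sample(alphabet, n_atoms, replace = TRUE)
  out <- atoms[1]
  for (i in 2:n_atoms) {
    bond <- if (atoms[i] == "C" && atoms[i - 1] == "C" &&
                stats::runif(1) < 0.15) "=" else ""
    if (stats::runif(1) < 0.12 && i < n_atoms) {
      out <- paste0(out, "(", sample(c("C", "O", "N"), 1), ")")
    }
    out <- paste0(out, bond, atoms[i])
  }
  out
}

# single-atom substitution at the chain terminus (keeps most fragments)
.mutate_terminal <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  last_atom <- max(which(chars %in% c("C", "N", "O", "S")))
  repl <- sample(setdiff(c("C", "N", "O", "S"), chars[last_atom]), 1)
  chars[last_atom] <- repl
  paste(chars, collapse = "")
}

#' Generate synthetic compound libraries with planted duplicates
#'
#' Phytochemicals (`PC###`) and drugs (`DB#####`) as random hetero-atom
#' chains.  `exact_dup_rate` of the phytochemicals are exact copies of
#' earlier ones (same canonical SMILES, new id) -- the raw-to-unique
#' deduplication structure.  `near_dup_rate` of the phytochemicals are
#' single-atom edits of randomly chosen drugs, constructed and post-hoc
#' verified to satisfy `0.85 < TC < 1`; the verified pairs and their TC
#' values are recorded in the sidecar.
#'
#' @param n_pc raw phytochemical count (default 1993, deduplicating to 867).
#' @param n_drug drug count (default 2337).
#' @param n_aed how many drugs are tagged as anti-epileptic drugs (default 40).
#' @param near_dup_rate,exact_dup_rate rates in `[0, 1]`.
#' @param seed integer seed.
#' @param n_atoms_range heavy-atom count range for generated molecules.
#' @return list: `compounds` (data.frame `compound_id`, `smiles`, `name`,
#'   `role`), `sidecar` (list with `planted_near_duplicates`,
#'   `planted_exact_duplicates`, `n_unique_pc`, parameters).
#' @export
gen_compounds <- function(n_pc = 1993L, n_drug = 2337L, n_aed = 40L,
                          near_dup_rate = 0.006, exact_dup_rate = 0.565,
                          seed = 1L, n_atoms_range = c(16L, 28L)) {
  stopifnot(n_pc >= 1L, n_drug >= 1L,
            near_dup_rate >= 0, near_dup_rate <= 1,
            exact_dup_rate >= 0, exact_dup_rate <= 1)
  set.seed(.sub_seed(seed, 1L))
  n_unique <- max(1L, round(n_pc * (1 - exact_dup_rate)))
  n_near <- round(n_unique * near_dup_rate)

  drug_ids <- sprintf("DB%05d", seq_len(n_drug))
  drug_smiles <- character(n_drug)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n_drug)) {
    repeat {
      s <- .rand_smiles(sample(n_atoms_range[1]:n_atoms_range[2], 1))
      cs <- canonicalize(s)
      if (is.null(seen[[cs]])) { assign(cs, TRUE, envir = seen); break }
    }
    drug_smiles[i] <- cs
  }

  pc_ids <- sprintf("PC%03d", seq_len(n_pc))
  pc_smiles <- character(n_pc)
  near <- list()
  # unique structures first; the first n_near are near-duplicates of drugs
  for (i in seq_len(n_unique)) {
    if (i <= n_near) {
      ok <- FALSE
      for (try in 1:100) {
        base_idx <- sample(n_drug, 1)
        base <- drug_smiles[base_idx]
        cand <- tryCatch(canonicalize(.mutate_terminal(base)),
                         error = function(e) NULL)
        if (is.null(cand)) next
        tc <- suppressWarnings(tanimoto(fingerprint(cand), fingerprint(base)))
        if (tc > 0.85 && tc < 1 && cand != base && is.null(seen[[cand]])) {
          pc_smiles[i] <- cand
          assign(cand, TRUE, envir = seen)
          near[[length(near) + 1L]] <- list(pc = pc_ids[i],
                                            drug = drug_ids[base_idx],
                                            tc = tc)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not construct a verified near-duplicate pair")
    } else {
      repeat {
        s <- .rand_smiles(sample(n_atoms_range[1]:n_atoms_range[2], 1))
        cs <- canonicalize(s)
        if (is.null(seen[[cs]])) { assign(cs, TRUE, envir = seen); break }
      }
      pc_smiles[i] <- cs
    }
  }
  exact <- list()
  if (n_pc > n_unique) {
    for (i in (n_unique + 1L):n_pc) {
      src <- sample(n_unique, 1)
      pc_smiles[i] <- pc_smiles[src]
      exact[[length(exact) + 1L]] <- list(dup = pc_ids[i], of = pc_ids[src])
    }
  }
  aed_idx <- sample(n_drug, min(n_aed, n_drug))
  role <- rep("drug", n_drug); role[aed_idx] <- "aed"
  compounds <- data.frame(
    compound_id = c(pc_ids, drug_ids),
    smiles = c(pc_smiles, drug_smiles),
    name = c(paste0("phytochemical-", seq_len(n_pc)),
             paste0("drug-", seq_len(n_drug))),
    role = c(rep("phytochemical", n_pc), role),
    stringsAsFactors = FALSE)
  list(compounds = compounds,
       sidecar = list(planted_near_duplicates = near,
                      planted_exact_duplicates = exact,
                      n_unique_pc = n_unique,
                      params = list(n_pc = n_pc, n_drug = n_drug,
                                    n_aed = n_aed,
                                    near_dup_rate = near_dup_rate,
                                    exact_dup_rate = exact_dup_rate,
                                    seed = seed)))
}

#' Generate synthetic ADMET annotations with an exact planted pass set
#'
#' Exactly `floor(pass_fraction * n)` records satisfy the full drug-likeness
#' screen; every failing record violates at least one named rule, recorded in
#' the sidecar.
#'
#' @param compound_ids identifiers to annotate.
#' @param pass_fraction fraction passing (default 349/867).
#' @param seed integer seed.
#' @return list `admet` (data.frame of `AdmetRecord` columns), `sidecar`
#'   (`planted_pass_set`, `planted_violations`).
#' @export
gen_admet <- function(compound_ids, pass_fraction = 349 / 867, seed = 1L) {
  set.seed(.sub_seed(seed, 2L))
  n <- length(compound_ids)
  n_pass <- floor(pass_fraction * n)
  pass <- rep(FALSE, n)
  if (n_pass > 0) pass[sample(n, n_pass)] <- TRUE
  df <- data.frame(
    compound_id = compound_ids,
    mw = stats::runif(n, 80, 480),
    hbd = sample(0:4, n, replace = TRUE),
    hba = sample(0:9, n, replace = TRUE),
    logp = stats::runif(n, -2, 4.8),
    caco2 = stats::runif(n, 0.95, 1.8),
    intestinal_absorption = stats::runif(n, 35, 100),
    hepatotoxic = FALSE, ames_toxic = FALSE,
    stringsAsFactors = FALSE)
  rules <- c("MW", "HBD", "HBA", "LogP", "Caco2", "Absorption",
             "Hepatotoxicity", "Ames")
  violations <- list()
  for (i in which(!pass)) {
    viol <- sample(rules, sample(1:2, 1))
    for (v in viol) {
      switch(v,
        MW = { df$mw[i] <- stats::runif(1, 500, 900) },
        HBD = { df$hbd[i] <- sample(5:9, 1) },
        HBA = { df$hba[i] <- sample(10:15, 1) },
        LogP = { df$logp[i] <- stats::runif(1, 5, 9) },
        Caco2 = { df$caco2[i] <- stats::runif(1, 0, 0.9) },
        Absorption = { df$intestinal_absorption[i] <- stats::runif(1, 0, 30) },
        Hepatotoxicity = { df$hepatotoxic[i] <- TRUE },
        Ames = { df$ames_toxic[i] <- TRUE })
    }
    violations[[df$compound_id[i]]] <- sort(viol)
  }
  list(admet = df,
       sidecar = list(planted_pass_set = compound_ids[pass],
                      planted_violations = violations,
                      params = list(pass_fraction = pass_fraction, seed = seed)))
}

#' Generate three synthetic target-prediction tables with planted votes
#'
#' Each compound receives `rpois(mean_targets)` candidate protein targets.
#' For each pair a vote pattern over the three sources is drawn: with
#' probability `overlap_boost` all three sources assert it, otherwise each
#' source asserts independently with `per_source_hit_prob`.  Asserting
#' sources emit an above-threshold row; in addition, below-threshold decoy
#' rows are emitted at `decoy_rate`, so both sides of every cutoff are
#' represented.  The sidecar records the planted vote count per pair.
#'
#' @param compound_ids compounds to predict targets for.
#' @param protein_ids protein accession universe.
#' @param mean_targets Poisson mean of candidate targets per compound.
#' @param per_source_hit_prob per-source assertion probability.
#' @param overlap_boost probability that a pair is asserted by all 3 sources.
#' @param decoy_rate probability of a below-threshold decoy row per
#'   non-asserting source.
#' @param seed integer seed.
#' @return list `predictions` (data.frame `compound_id`, `protein_id`,
#'   `source`, `score`, `rank`), `sidecar` (`planted_votes` data.frame).
#' @export
gen_predictions <- function(compound_ids, protein_ids, mean_targets = 15,
                            per_source_hit_prob = 0.5, overlap_boost = 0.05,
                            decoy_rate = 0.2, seed = 1L) {
  set.seed(.sub_seed(seed, 3L))
  rows <- list()
  votes <- list()
  for (cid in compound_ids) {
    k <- min(stats::rpois(1, mean_targets), length(protein_ids))
    if (k == 0L) next
    prots <- sample(protein_ids, k)
    # rank pool for swisstarget: asserting rows get ranks 1..15 in order
    st_rank <- 0L
    for (pid in prots) {
      if (stats::runif(1) < overlap_boost) {
        pattern <- c(TRUE, TRUE, TRUE)
      } else {
        pattern <- stats::runif(3) < per_source_hit_prob
      }
      names(pattern) <- .PRED_SOURCES
      v <- sum(pattern)
      if (v > 0L) {
        votes[[length(votes) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, votes = v,
          stringsAsFactors = FALSE)
      }
      if (pattern["bindingdb"]) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "bindingdb",
          score = stats::runif(1, 0.85, 1), rank = NA_integer_,
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < decoy_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "bindingdb",
          score = stats::runif(1, 0, 0.849), rank = NA_integer_,
          stringsAsFactors = FALSE)
      }
      if (pattern["stitch"]) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "stitch",
          score = stats::runif(1, 0.4, 1), rank = NA_integer_,
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < decoy_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "stitch",
          score = stats::runif(1, 0, 0.399), rank = NA_integer_,
          stringsAsFactors = FALSE)
      }
      if (pattern["swisstarget"]) {
        st_rank <- st_rank + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "swisstarget",
          score = NA_real_, rank = min(st_rank, 15L),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < decoy_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cid, protein_id = pid, source = "swisstarget",
          score = NA_real_, rank = sample(16:50, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(0), protein_id = character(0),
               source = character(0), score = numeric(0), rank = integer(0))
  planted <- if (length(votes)) do.call(rbind, votes) else
    data.frame(compound_id = character(0), protein_id = character(0),
               votes = integer(0))
  list(predictions = predictions,
       sidecar = list(planted_votes = planted,
                      params = list(mean_targets = mean_targets,
                                    per_source_hit_prob = per_source_hit_prob,
                                    overlap_boost = overlap_boost,
                                    decoy_rate = decoy_rate, seed = seed)))
}

#' Generate a synthetic weighted PPI edge list with planted cliques
#'
#' Planted cliques of `module_sizes` on disjoint node subsets (all clique
#' edges scored >= 0.9) over an Erdos-Renyi background at `p_background`
#' with mixed scores, emulating a STRING-style export.
#'
#' @param node_ids protein accession vector.
#' @param module_sizes planted clique sizes (disjoint member sets).
#' @param p_background background edge probability.
#' @param seed integer seed.
#' @return list `edges` (data.frame `protein_a`, `protein_b`, `score`),
#'   `sidecar` (`planted_modules` list of member vectors).
#' @export
gen_ppi <- function(node_ids, module_sizes = c(8L, 7L, 6L),
                    p_background = 0.004, seed = 1L) {
  set.seed(.sub_seed(seed, 4L))
  n <- length(node_ids)
  stopifnot(sum(module_sizes) <= n)
  shuffled <- sample(node_ids)
  modules <- list()
  off <- 0L
  ea <- character(0); eb <- character(0); sc <- numeric(0)
  for (ms in module_sizes) {
    memb <- sort(shuffled[(off + 1L):(off + ms)])
    off <- off + ms
    prs <- utils::combn(memb, 2)
    ea <- c(ea, prs[1, ]); eb <- c(eb, prs[2, ])
    sc <- c(sc, stats::runif(ncol(prs), 0.9, 1))
    modules[[length(modules) + 1L]] <- memb
  }
  # background: sample pairs
  n_bg <- stats::rbinom(1, as.integer(n * (n - 1) / 2), p_background)
  if (n_bg > 0) {
    i <- sample(n, n_bg, replace = TRUE)
    j <- sample(n, n_bg, replace = TRUE)
    ok <- i != j
    a <- pmin(node_ids[i[ok]], node_ids[j[ok]])
    b <- pmax(node_ids[i[ok]], node_ids[j[ok]])
    ea <- c(ea, a); eb <- c(eb, b)
    sc <- c(sc, stats::runif(length(a), 0.4, 1))
  }
  key <- paste(ea, eb)
  keep <- !duplicated(key)
  list(edges = data.frame(protein_a = ea[keep], protein_b = eb[keep],
                          score = sc[keep], stringsAsFactors = FALSE),
       sidecar = list(planted_modules = modules,
                      params = list(module_sizes = module_sizes,
                                    p_background = p_background, seed = seed)))
}

#' Generate the full synthetic input bundle
#'
#' Produces all eight pipeline inputs at the scale of the study this package
#' emulates (63 herbs, 1,993 raw / 867 unique phytochemicals, 2,337 drugs of
#' which 40 are AEDs, a 1,179-protein disease gene pool, 10 nervous-system
#' pathways, a drug-target list, target predictions from three sources, and
#' a weighted PPI), plus a ground-truth sidecar.  The planted
#' drug-near-duplicate phytochemicals are wired end-to-end: their ADMET
#' records pass, they target an NM-protein via an above-threshold
#' prediction, and the base drug targets the same protein, so the
#' drug-similarity cascade must recover exactly them.
#'
#' @param seed integer seed.
#' @param n_herb,n_pc,n_drug,n_aed,n_protein,n_pool,n_pathway scale knobs.
#' @param ... forwarded to [gen_compounds()] (`near_dup_rate`,
#'   `exact_dup_rate`, `n_atoms_range`), e.g. to shrink molecules in tests.
#' @return a `synthetic_bundle`: list of the eight tables
#'   (`herb_pc`, `compounds`, `admet`, `predictions`, `gene_pool_ids`,
#'   `id_mapping`, `pathways`, `drug_targets`, `ppi`) plus `sidecar`.
#' @export
gen_bundle <- function(seed = 1L, n_herb = 63L, n_pc = 1993L, n_drug = 2337L,
                       n_aed = 40L, n_protein = 3000L, n_pool = 1179L,
                       n_pathway = 10L, ...) {
  comp <- gen_compounds(n_pc = n_pc, n_drug = n_drug, n_aed = n_aed,
                        seed = seed, ...)
  compounds <- comp$compounds
  pc_ids <- compounds$compound_id[compounds$role == "phytochemical"]
  drug_ids <- compounds$compound_id[compounds$role %in% c("drug", "aed")]
  aed_ids <- compounds$compound_id[compounds$role == "aed"]

  # unique phytochemicals by canonical structure (generator emits canonical
  # SMILES already); first id per structure is the representative
  pc_tab <- compounds[compounds$role == "phytochemical", ]
  unique_pc <- pc_tab$compound_id[!duplicated(pc_tab$smiles)]

  set.seed(.sub_seed(seed, 5L))
  herb_ids <- sprintf("EP%02d", seq_len(n_herb))
  hp <- list()
  for (h in herb_ids) {
    k <- max(1L, min(stats::rpois(1, 25), length(unique_pc)))
    hp[[h]] <- data.frame(herb_id = h,
                          pc_id = sample(unique_pc, k),
                          stringsAsFactors = FALSE)
  }
  herb_pc <- do.call(rbind, hp)
  orphan <- setdiff(unique_pc, herb_pc$pc_id)
  if (length(orphan) > 0L) {
    herb_pc <- rbind(herb_pc,
                     data.frame(herb_id = sample(herb_ids, length(orphan),
                                                 replace = TRUE),
                                pc_id = orphan, stringsAsFactors = FALSE))
  }
  rownames(herb_pc) <- NULL

  admet <- gen_admet(unique_pc, seed = seed)
  # planted near-duplicate phytochemicals must pass the screen
  near_pcs <- vapply(comp$sidecar$planted_near_duplicates,
                     function(x) x$pc, character(1))
  if (length(near_pcs) > 0L) {
    fix <- match(near_pcs, admet$admet$compound_id)
    fix <- fix[!is.na(fix)]
    admet$admet$mw[fix] <- 300; admet$admet$hbd[fix] <- 2
    admet$admet$hba[fix] <- 4; admet$admet$logp[fix] <- 2
    admet$admet$caco2[fix] <- 1.2
    admet$admet$intestinal_absorption[fix] <- 80
    admet$admet$hepatotoxic[fix] <- FALSE; admet$admet$ames_toxic[fix] <- FALSE
    admet$sidecar$planted_pass_set <-
      sort(union(admet$sidecar$planted_pass_set, near_pcs))
    admet$sidecar$planted_violations[near_pcs] <- NULL
  }

  protein_ids <- sprintf("P%05d", seq_len(n_protein))
  pred <- gen_predictions(c(unique_pc, aed_ids), protein_ids, seed = seed)

  set.seed(.sub_seed(seed, 6L))
  pool_acc <- sample(protein_ids, n_pool)
  # half the pool is given as gene symbols through the mapping table
  sym_idx <- sample(n_pool, n_pool %/% 2)
  symbols <- sprintf("GENE%04d", seq_along(sym_idx))
  id_mapping <- data.frame(symbol = symbols, accession = pool_acc[sym_idx],
                           stringsAsFactors = FALSE)
  gene_pool_ids <- pool_acc
  gene_pool_ids[sym_idx] <- symbols

  pathway_ids <- sprintf("hsa%04d", 2700 + seq_len(n_pathway))
  pw <- list()
  for (p in pathway_ids) {
    k <- max(3L, stats::rpois(1, 30))
    pw[[p]] <- data.frame(pathway_id = p,
                          protein_id = sample(protein_ids, min(k, n_protein)),
                          stringsAsFactors = FALSE)
  }
  pathways <- do.call(rbind, pw)
  rownames(pathways) <- NULL

  # drug-target list: each drug targets a few proteins
  n_dt <- length(drug_ids)
  dt <- data.frame(
    drug_id = rep(drug_ids, times = pmax(1L, stats::rpois(n_dt, 2))),
    stringsAsFactors = FALSE)
  dt$protein_id <- sample(protein_ids, nrow(dt), replace = TRUE)
  dt <- dt[!duplicated(dt), ]

  # wire the planted near-duplicate cascade end-to-end
  planted_neumods <- character(0)
  if (length(near_pcs) > 0L) {
    extra_pred <- list(); extra_dt <- list(); extra_pw <- list()
    for (nd in comp$sidecar$planted_near_duplicates) {
      prot <- sample(protein_ids, 1)
      # the phytochemical targets prot with a high-confidence prediction
      extra_pred[[length(extra_pred) + 1L]] <- data.frame(
        compound_id = nd$pc, protein_id = prot, source = "bindingdb",
        score = 0.95, rank = NA_integer_, stringsAsFactors = FALSE)
      # prot is in a nervous-system pathway and in the approved target list
      extra_pw[[length(extra_pw) + 1L]] <- data.frame(
        pathway_id = sample(pathway_ids, 1), protein_id = prot,
        stringsAsFactors = FALSE)
      extra_dt[[length(extra_dt) + 1L]] <- data.frame(
        drug_id = nd$drug, protein_id = prot, stringsAsFactors = FALSE)
      planted_neumods <- c(planted_neumods, nd$pc)
    }
    pred$predictions <- rbind(pred$predictions, do.call(rbind, extra_pred))
    pred$sidecar$planted_votes <- rbind(
      pred$sidecar$planted_votes,
      do.call(rbind, lapply(extra_pred, function(e)
        data.frame(compound_id = e$compound_id, protein_id = e$protein_id,
                   votes = 1L, stringsAsFactors = FALSE))))
    pv <- pred$sidecar$planted_votes
    pv <- stats::aggregate(votes ~ compound_id + protein_id, pv,
                           function(v) min(3L, sum(v)))
    pred$sidecar$planted_votes <- pv
    pathways <- rbind(pathways, do.call(rbind, extra_pw))
    pathways <- pathways[!duplicated(pathways), ]
    dt <- rbind(dt, do.call(rbind, extra_dt))
    dt <- dt[!duplicated(dt), ]
  }
  rownames(dt) <- NULL

  ppi <- gen_ppi(pool_acc, seed = seed)

  structure(list(
    herb_pc = herb_pc,
    compounds = compounds,
    admet = admet$admet,
    predictions = pred$predictions,
    gene_pool_ids = gene_pool_ids,
    id_mapping = id_mapping,
    pathways = pathways,
    drug_targets = dt,
    ppi = ppi$edges,
    sidecar = list(
      compounds = comp$sidecar,
      admet = admet$sidecar,
      predictions = pred$sidecar,
      ppi = ppi$sidecar,
      planted_neumods = sort(unique(planted_neumods)),
      unique_pc = unique_pc,
      seed = seed)
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle (and its sidecar) to a directory
#'
#' Tables are written in the same plain-text formats the real readers
#' consume (.smi, TSV); the sidecar is JSON.
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(bundle$herb_pc, "herb_pc.tsv")
  write_smi(bundle$compounds, file.path(dir, "compounds.smi"))
  w(bundle$compounds, "compounds.tsv")
  w(bundle$admet, "admet.tsv")
  w(bundle$predictions, "predictions.tsv")
  writeLines(bundle$gene_pool_ids, file.path(dir, "gene_pool.txt"))
  w(bundle$id_mapping, "id_mapping.tsv")
  w(bundle$pathways, "pathways.tsv")
  w(bundle$drug_targets, "drug_targets.tsv")
  w(bundle$ppi, "ppi.tsv")
  jsonlite::write_json(bundle$sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
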