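# End-to-end orchestration: dedup -> drug-likeness screen -> target
# consensus -> layered networks -> network statistics -> selection cascades,
# emitting a machine-readable ledger of counts at every stage.

#' Default run configuration
#'
#' Every threshold defaults to the screening protocol's printed value.
#' @return named list: prediction thresholds, screen thresholds, STRING
#'   `ppi_min_score` (0.9), `min_votes` for the AED overlap (2), the
#'   drug-similarity bound `tc_min` (0.85), MCODE parameters, fingerprint
#'   `n_bits` (1024), and `canonical_input` (set `TRUE` when compound SMILES
#'   are already canonical, e.g. straight from the generator).
#' @export
default_run_config <- function() {
  list(prediction = default_prediction_thresholds(),
       screen = default_screen_thresholds(),
       ppi_min_score = 0.9,
       min_votes = 2L,
       tc_min = 0.85,
       mcode = default_mcode_params(),
       n_bits = 1024L,
       canonical_input = FALSE)
}

#' Run the full screening pipeline on an input bundle
#'
#' Executes, in order: phytochemical deduplication by canonical SMILES,
#' drug-likeness + ADMET screening, per-source threshold filtering and
#' consensus voting, layered-network construction (herb-compound,
#' compound-protein, pool-restricted compound-protein, high-confidence PPI
#' and its giant component), network statistics (centralities, power-law
#' degree fit, MCODE modules), and the selection cascades (NM-proteins,
#' D/D1/D2, drug-similarity screen, AED overlap, module regulators).
#'
#' @param bundle a `synthetic_bundle` from [gen_bundle()] or an equivalent
#'   list of tables (see [read_bundle()]).
#' @param config as [default_run_config()].
#' @param outdir optional directory; when given, stage outputs and the
#'   ledger are written there.
#' @return a `pipeline_result`: list of stage outputs plus `ledger` (named
#'   count list) and `status` (per-stage `"ok"` / `"empty-input"` /
#'   `"error"`).
#' @export
run_pipeline <- function(bundle, config = default_run_config(), outdir = NULL) {
  config <- utils::modifyList(default_run_config(), config)
  status <- list()
  ledger <- list()

  # --- dedup --------------------------------------------------------------
  comp <- bundle$compounds
  if (!config$canonical_input) {
    canon_cache <- new.env(parent = emptyenv())
    comp$canonical <- vapply(comp$smiles, function(s) {
      if (!is.null(canon_cache[[s]])) return(canon_cache[[s]])
      v <- tryCatch(as.character(canonicalize(s)),
                    error = function(e) NA_character_)
      canon_cache[[s]] <- v
      v
    }, character(1), USE.NAMES = FALSE)
  } else {
    comp$canonical <- comp$smiles
  }
  unresolved <- comp$compound_id[is.na(comp$canonical)]
  comp <- comp[!is.na(comp$canonical), ]
  pc <- comp[comp$role == "phytochemical", ]
  unique_pc <- pc[!duplicated(pc$canonical), ]
  ledger$raw_phytochemicals <- nrow(pc)
  ledger$unique_phytochemicals <- nrow(unique_pc)
  ledger$structurally_unresolved <- length(unresolved)
  status$dedup <- "ok"

  smiles_lookup <- stats::setNames(comp$canonical, comp$compound_id)

  # --- drug-likeness screen ----------------------------------------------
  admet <- bundle$admet[bundle$admet$compound_id %in% unique_pc$compound_id, ]
  verdicts <- screen_dpcs(admet, config$screen)
  dpc_ids <- verdicts$compound_id[verdicts$passed %in% TRUE]
  ledger$drugable_phytochemicals <- length(dpc_ids)
  status$screen <- "ok"

  # --- target consensus ---------------------------------------------------
  filtered <- ingest_predictions(bundle$predictions, config$prediction,
                                 mapping = bundle$id_mapping)
  aed_ids <- comp$compound_id[comp$role == "aed"]
  dpc_pred <- filtered[filtered$compound_id %in% dpc_ids, ]
  aed_pred <- filtered[filtered$compound_id %in% aed_ids, ]
  dpc_pairs <- consensus_pairs(dpc_pred)
  aed_pairs <- consensus_pairs(aed_pred)
  ledger$dpc_pt_pairs <- nrow(dpc_pairs)
  ledger$dpc_pt_proteins <- length(unique(dpc_pairs$protein_id))
  ledger$high_confidence_dpc_pt_pairs <- sum(dpc_pairs$votes == 3L)
  ledger$aed_pt_pairs <- nrow(aed_pairs)
  ledger$high_confidence_aed_pt_pairs <- sum(aed_pairs$votes >= config$min_votes)
  status$consensus <- "ok"

  # --- networks -----------------------------------------------------------
  hpc <- build_bipartite(bundle$herb_pc, "herb", "compound")
  ledger$herb_pc_nodes <- igraph::vcount(hpc)
  ledger$herb_pc_edges <- igraph::ecount(hpc)

  dpc_pt_net <- if (nrow(dpc_pairs) > 0L) {
    build_bipartite(dpc_pairs[, c("compound_id", "protein_id", "votes",
                                  "sources")], "compound", "protein")
  } else NULL

  pool <- NULL; dpc_pte_net <- NULL; ep_ppi <- NULL; ppi_sub <- NULL
  if (length(bundle$gene_pool_ids) == 0L) {
    status$networks <- "empty-input"
  } else {
    pool <- gene_pool(bundle$gene_pool_ids, bundle$id_mapping)
    ledger$gene_pool_size <- length(pool$ids)
    if (!is.null(dpc_pt_net)) {
      dpc_pte_net <- filter_to_pool(dpc_pt_net, pool)
      nl <- network_nodes(dpc_pte_net)
      ledger$dpc_pte_edges <- igraph::ecount(dpc_pte_net)
      ledger$dpc_pte_compounds <- sum(nl$layer == "compound")
      ledger$dpc_pte_proteins <- sum(nl$layer == "protein")
    }
    ppi_sub <- ppi_subgraph(bundle$ppi, pool, config$ppi_min_score)
    prov <- attr(ppi_sub, "provenance")
    ledger$ppi_mapped <- prov$mapped_in_ppi
    ledger$ppi_interacting <- prov$interacting
    ledger$ppi_edges <- igraph::ecount(ppi_sub)
    ep_ppi <- giant_component(ppi_sub)
    ledger$ep_ppi_nodes <- igraph::vcount(ep_ppi)
    ledger$ep_ppi_edges <- igraph::ecount(ep_ppi)
    status$networks <- "ok"
  }

  # --- statistics ---------------------------------------------------------
  cent <- NULL; plfit <- NULL; modules <- list()
  if (is.null(ep_ppi)) {
    status$stats <- "empty-input"
  } else {
    cent <- centralities(ep_ppi)
    plfit <- tryCatch(fit_powerlaw(degree_histogram(ep_ppi)),
                      error = function(e) NULL)
    if (!is.null(plfit)) {
      ledger$powerlaw_gamma <- plfit$exponent_gamma
      ledger$powerlaw_a <- plfit$coefficient_a
    }
    modules <- mcode(ep_ppi, config$mcode)
    ledger$mcode_modules <- length(modules)
    status$stats <- "ok"
  }

  # --- cascades -----------------------------------------------------------
  nm <- NULL; ds <- NULL; nm_hits <- NULL; aed <- NULL; modreg <- NULL
  sim_d1_d <- NULL
  approved <- unique(normalize_protein_ids(bundle$drug_targets$protein_id))
  ledger$approved_targets <- length(approved)
  if (nrow(dpc_pairs) == 0L) {
    status$cascades <- "empty-input"
  } else {
    nm <- select_nm_proteins(dpc_pairs, bundle$pathways, approved)
    ledger$nm_proteins_pre <- length(nm$pre_intersection)
    ledger$nm_proteins <- length(nm$proteins)
    ds <- build_datasets(nm, dpc_pairs, bundle$drug_targets)
    ledger$d_dataset <- length(ds$D)
    ledger$d1_dataset <- length(ds$D1)
    ledger$d2_dataset <- length(ds$D2)
    if (length(ds$D1) > 0L && length(ds$D) > 0L) {
      rows_df <- data.frame(compound_id = ds$D1,
                            smiles = smiles_lookup[ds$D1],
                            stringsAsFactors = FALSE)
      cols_df <- data.frame(compound_id = ds$D,
                            smiles = smiles_lookup[ds$D],
                            stringsAsFactors = FALSE)
      sim_d1_d <- similarity_matrix(rows_df, cols_df, n_bits = config$n_bits)
      nm_hits <- neumods(sim_d1_d, smiles_lookup, ds$D1, ds$D,
                         dpc_targets = dpc_pairs, nm = nm,
                         tc_min = config$tc_min)
      ledger$neumods <- nrow(nm_hits)
      nm_link <- unlist(strsplit(nm_hits$nm_proteins_targeted, ";", fixed = TRUE))
      ledger$neumods_nm_proteins <- length(unique(nm_link[nzchar(nm_link)]))
    }
    aed <- aed_overlap(dpc_pairs, aed_pairs, config$min_votes)
    ledger$aed_shared_proteins <- length(aed$shared_proteins)
    ledger$aed_tripartite_edges <- unname(aed$counts["tripartite_edges"])
    if (length(modules) > 0L && !is.null(ep_ppi)) {
      modreg <- module_regulators(modules[[1]], ep_ppi, dpc_pairs)
      ledger$module1_regulators <- length(modreg$regulators)
      ledger$module1_multi_targeting <- length(modreg$multi_targeting)
    }
    status$cascades <- "ok"
  }

  res <- structure(list(
    unique_pc = unique_pc, verdicts = verdicts, dpc_ids = dpc_ids,
    dpc_pairs = dpc_pairs, aed_pairs = aed_pairs,
    hpc = hpc, dpc_pt_net = dpc_pt_net, dpc_pte_net = dpc_pte_net,
    ppi_sub = ppi_sub, ep_ppi = ep_ppi,
    centralities = cent, powerlaw = plfit, modules = modules,
    nm = nm, datasets = ds, sim_d1_d = sim_d1_d, neumod_hits = nm_hits,
    aed_overlap = aed, module_regulators = modreg,
    ledger = ledger, status = status, config = config
  ), class = "pipeline_result")

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result; ledger:\n")
  for (nm in names(x$ledger)) {
    cat(sprintf("  %-32s %s\n", nm, format(x$ledger[[nm]])))
  }
  invisible(x)
}

#' Write pipeline stage outputs and the ledger to a directory
#' @param res a `pipeline_result`.
#' @param outdir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(res$verdicts, "screen_verdicts.tsv")
  write_consensus_tsv(res$dpc_pairs, file.path(outdir, "dpc_pt_pairs.tsv"))
  write_consensus_tsv(res$aed_pairs, file.path(outdir, "aed_pt_pairs.tsv"))
  write_sif(res$hpc, file.path(outdir, "herb_pc.sif"))
  if (!is.null(res$ep_ppi)) {
    write_graphml(res$ep_ppi, file.path(outdir, "ep_ppi.graphml"))
    write_provenance(res$ep_ppi, file.path(outdir, "ep_ppi_provenance.json"))
  }
  if (!is.null(res$centralities)) w(res$centralities, "centralities.tsv")
  if (length(res$modules) > 0L) {
    write_modules_tsv(res$modules, file.path(outdir, "mcode_modules.tsv"))
  }
  if (!is.null(res$neumod_hits)) w(res$neumod_hits, "neumod_hits.tsv")
  jsonlite::write_json(
    list(ledger = res$ledger, status = res$status,
         config = res$config[setdiff(names(res$config), "mcode")],
         mcode_params = res$config$mcode),
    file.path(outdir, "ledger.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' Read an input bundle from a directory written by [write_bundle()]
#' @param dir bundle directory.
#' @return a bundle list usable with [run_pipeline()].
#' @export
read_bundle <- function(dir) {
  r <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
  bundle <- list(
    herb_pc = r("herb_pc.tsv"),
    compounds = r("compounds.tsv"),
    admet = read_admet_tsv(file.path(dir, "admet.tsv")),
    predictions = r("predictions.tsv"),
    gene_pool_ids = readLines(file.path(dir, "gene_pool.txt")),
    id_mapping = r("id_mapping.tsv"),
    pathways = r("pathways.tsv"),
    drug_targets = r("drug_targets.tsv"),
    ppi = r("ppi.tsv"))
  sc <- file.path(dir, "sidecar.json")
  if (file.exists(sc)) bundle$sidecar <- jsonlite::read_json(sc)
  bundle
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `run-all` (run the
#' pipeline on a bundle directory).  Global flags: `--seed`, `--outdir`,
#' plus `--bundle` for `run-all` and scale flags for `simulate`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
phytonet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: phytonet <simulate|run-all> [--seed N] [--outdir DIR]",
    "  simulate: [--n-pc N] [--n-drug N] [--small]",
    "  run-all:  --bundle DIR [--canonical-input]", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    args[i[1] + 1L]
  }
  has <- function(flag) flag %in% args
  seed <- as.integer(opt("--seed", "1"))
  outdir <- opt("--outdir", "phytonet-out")
  if (cmd == "simulate") {
    if (has("--small")) {
      bundle <- gen_bundle(seed = seed, n_herb = 8L, n_pc = 120L,
                           n_drug = 150L, n_aed = 10L, n_protein = 300L,
                           n_pool = 120L, n_pathway = 4L)
    } else {
      bundle <- gen_bundle(seed = seed,
                           n_pc = as.integer(opt("--n-pc", "1993")),
                           n_drug = as.integer(opt("--n-drug", "2337")))
    }
    write_bundle(bundle, outdir)
    message("bundle written to ", outdir)
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    bdir <- opt("--bundle")
    if (is.null(bdir)) { message(usage); return(invisible(1L)) }
    bundle <- read_bundle(bdir)
    cfg <- default_run_config()
    cfg$canonical_input <- has("--canonical-input")
    res <- run_pipeline(bundle, cfg, outdir = outdir)
    message("ledger written to ", file.path(outdir, "ledger.json"))
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
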