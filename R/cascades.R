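# The selection cascades layered on top of the similarity and network
# machinery: neuromodulatory-protein (NM-protein) screening, the D/D1/D2
# dataset construction, the dual-criterion drug-similarity screen for
# candidate neuromodulators, the AED poly-pharmacology overlap, and
# module-regulator back-mapping.

#' Select NM-proteins
#'
#' NM-proteins are the protein targets of screened compounds that (a) belong
#' to the configured nervous-system pathways and (b) appear in the approved
#' drug-target list.  The pre-intersection set (pathway members only) is also
#' reported.
#'
#' @param dpc_targets consensus data.frame (`compound_id`, `protein_id`, ...).
#' @param pathway_members data.frame `pathway_id`, `protein_id`.
#' @param approved_targets character vector of approved-target accessions.
#' @param pathway_ids pathways to use (default: all in `pathway_members`).
#' @return an `nm_protein_set`: list `proteins`, `pre_intersection`,
#'   `source_pathways`.
#' @export
select_nm_proteins <- function(dpc_targets, pathway_members, approved_targets,
                               pathway_ids = NULL) {
  if (nrow(pathway_members) == 0L) stop("empty pathway membership table")
  if (is.null(pathway_ids)) pathway_ids <- unique(pathway_members$pathway_id)
  members <- unique(normalize_protein_ids(
    pathway_members$protein_id[pathway_members$pathway_id %in% pathway_ids]))
  targeted <- unique(normalize_protein_ids(dpc_targets$protein_id))
  pre <- sort(intersect(targeted, members))
  nm <- sort(intersect(pre, normalize_protein_ids(approved_targets)))
  structure(list(proteins = nm, pre_intersection = pre,
                 source_pathways = sort(unique(pathway_ids))),
            class = "nm_protein_set")
}

#' Build the D / D1 / D2 screening datasets
#'
#' `D`: drugs targeting at least one protein target of the screened
#' compounds; `D1`: compounds targeting an NM-protein; `D2`: drugs targeting
#' an NM-protein (`D2` is a subset of `D` whenever NM-proteins are compound
#' targets, which the construction guarantees).
#'
#' @param nm an [select_nm_proteins()] result.
#' @param dpc_targets consensus data.frame (`compound_id`, `protein_id`).
#' @param drug_targets data.frame `drug_id`, `protein_id`.
#' @return a `screen_datasets`: list of character vectors `D`, `D1`, `D2`
#'   and a `counts` vector.
#' @export
build_datasets <- function(nm, dpc_targets, drug_targets) {
  stopifnot(inherits(nm, "nm_protein_set"))
  dt <- data.frame(drug_id = drug_targets$drug_id,
                   protein_id = normalize_protein_ids(drug_targets$protein_id),
                   stringsAsFactors = FALSE)
  pc <- data.frame(compound_id = dpc_targets$compound_id,
                   protein_id = normalize_protein_ids(dpc_targets$protein_id),
                   stringsAsFactors = FALSE)
  dpc_prot <- unique(pc$protein_id)
  D <- sort(unique(dt$drug_id[dt$protein_id %in% dpc_prot]))
  D1 <- sort(unique(pc$compound_id[pc$protein_id %in% nm$proteins]))
  D2 <- sort(unique(dt$drug_id[dt$protein_id %in% nm$proteins]))
  structure(list(D = D, D1 = D1, D2 = D2,
                 counts = c(D = length(D), D1 = length(D1), D2 = length(D2))),
            class = "screen_datasets")
}

#' Screen for drug-similar neuromodulator candidates
#'
#' A compound in `D1` is a hit iff some drug in `D` satisfies the dual
#' criterion `tc_min < TC < 1` with a different canonical SMILES.  With
#' `criteria = "per_pair"` (default, the stricter reading) both conditions
#' must hold for the same compound-drug pair; with `"per_dpc"` a compound
#' qualifies if it has any drug with `TC > tc_min` and no drug with `TC = 1`
#' or identical SMILES.
#'
#' @param sim a `similarity_matrix` with the D1 compounds among its rows and
#'   the D drugs among its columns.
#' @param smiles named character vector: canonical SMILES by compound/drug id.
#' @param d1,d identifier vectors (the D1 and D datasets).
#' @param dpc_targets optional consensus table used to annotate which
#'   NM-proteins each hit targets.
#' @param nm optional `nm_protein_set` for the same annotation.
#' @param tc_min lower TC bound, strict (default 0.85).
#' @param criteria `"per_pair"` or `"per_dpc"`.
#' @return data.frame (one row per hit, sorted by compound id):
#'   `dpc_id`, `qualifying_drugs` (semicolon list `drug:TC`), `max_tc`,
#'   `nm_proteins_targeted`.
#' @export
neumods <- function(sim, smiles, d1, d, dpc_targets = NULL, nm = NULL,
                    tc_min = 0.85, criteria = c("per_pair", "per_dpc")) {
  criteria <- match.arg(criteria)
  missing_rows <- setdiff(d1, rownames(sim))
  if (length(missing_rows) > 0L) {
    stop("D1 compound(s) missing from similarity matrix rows: ",
         paste(utils::head(missing_rows, 5), collapse = ", "))
  }
  d <- intersect(d, colnames(sim))
  hits <- list()
  for (pc in sort(d1)) {
    tcs <- sim[pc, d]
    same_smiles <- !is.na(smiles[d]) & !is.na(smiles[pc]) &
      smiles[d] == smiles[pc]
    if (criteria == "per_pair") {
      qual <- tcs > tc_min & tcs < 1 & !same_smiles
    } else {
      any_high <- any(tcs > tc_min)
      blocked <- any(tcs == 1 | same_smiles)
      qual <- if (any_high && !blocked) tcs > tc_min else rep(FALSE, length(tcs))
    }
    if (!any(qual)) next
    qd <- d[qual]
    qtc <- tcs[qual]
    ord <- order(-qtc, qd)
    nm_prot <- ""
    if (!is.null(dpc_targets) && !is.null(nm)) {
      prot <- unique(normalize_protein_ids(
        dpc_targets$protein_id[dpc_targets$compound_id == pc]))
      nm_prot <- paste(sort(intersect(prot, nm$proteins)), collapse = ";")
    }
    hits[[length(hits) + 1L]] <- data.frame(
      dpc_id = pc,
      qualifying_drugs = paste(sprintf("%s:%.4f", qd[ord], qtc[ord]),
                               collapse = ";"),
      max_tc = max(qtc),
      nm_proteins_targeted = nm_prot,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) {
    return(data.frame(dpc_id = character(0), qualifying_drugs = character(0),
                      max_tc = numeric(0), nm_proteins_targeted = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' AED poly-pharmacology overlap
#'
#' Restricts both compound-protein and AED-protein consensus tables to pairs
#' with at least `min_votes` supporting sources, intersects their protein
#' target sets, and assembles the tripartite compound / shared-protein / AED
#' network.  Compounds covering the complete (filtered) target set of an AED
#' are flagged in the `multi_target` report.
#'
#' @param dpc_pairs,aed_pairs vote-annotated consensus data.frames.
#' @param min_votes vote threshold applied to both sides (default 2).
#' @return list: `shared_proteins`, `network` (tripartite
#'   `layered_network`), `multi_target` (data.frame `aed_id`, `n_targets`,
#'   `covering_dpcs`), `counts`.
#' @export
aed_overlap <- function(dpc_pairs, aed_pairs, min_votes = 2L) {
  dp <- dpc_pairs[dpc_pairs$votes >= min_votes, , drop = FALSE]
  ap <- aed_pairs[aed_pairs$votes >= min_votes, , drop = FALSE]
  shared <- sort(intersect(unique(dp$protein_id), unique(ap$protein_id)))
  if (length(shared) == 0L) {
    empty <- layered_network(data.frame(name = character(0),
                                        layer = character(0)))
    return(list(shared_proteins = character(0), network = empty,
                multi_target = data.frame(aed_id = character(0),
                                          n_targets = integer(0),
                                          covering_dpcs = character(0),
                                          stringsAsFactors = FALSE),
                counts = c(dpc_qualifying = nrow(dp),
                           aed_qualifying = nrow(ap),
                           shared_proteins = 0L,
                           tripartite_edges = 0L)))
  }
  left <- data.frame(compound_id = dp$compound_id, protein_id = dp$protein_id,
                     votes = dp$votes, stringsAsFactors = FALSE)
  right <- data.frame(drug_id = ap$compound_id, protein_id = ap$protein_id,
                      votes = ap$votes, stringsAsFactors = FALSE)
  net <- build_tripartite(shared, left, right)
  # per-AED full (filtered) target coverage by single compounds
  aed_targets <- split(ap$protein_id, ap$compound_id)
  dpc_targets <- split(dp$protein_id, dp$compound_id)
  mt <- lapply(names(aed_targets), function(a) {
    tset <- unique(aed_targets[[a]])
    covering <- names(dpc_targets)[vapply(dpc_targets, function(ts)
      all(tset %in% ts), logical(1))]
    data.frame(aed_id = a, n_targets = length(tset),
               covering_dpcs = paste(sort(covering), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  mt <- do.call(rbind, mt)
  list(shared_proteins = shared, network = net, multi_target = mt,
       counts = c(dpc_qualifying = nrow(dp), aed_qualifying = nrow(ap),
                  shared_proteins = length(shared),
                  tripartite_edges = igraph::ecount(net)))
}

#' Back-map regulator compounds onto a PPI module
#'
#' Builds the induced PPI subgraph of a module's members plus every
#' compound-protein edge incident to them (vote attributes retained).
#' Compounds targeting at least two module members are flagged as
#' multi-targeting.
#'
#' @param module an `mcode_module` (or list with a `members` vector).
#' @param ppi_net the PPI `layered_network` the module came from.
#' @param dpc_pt compound-protein consensus data.frame (`compound_id`,
#'   `protein_id`, `votes`).
#' @return list: `network` (`layered_network` with `protein` and `compound`
#'   layers), `regulators` (compound ids), `multi_targeting` (compound ids
#'   with >= 2 module-member targets).
#' @export
module_regulators <- function(module, ppi_net, dpc_pt) {
  members <- module$members
  stopifnot(length(members) > 0L)
  idx <- match(members, igraph::V(ppi_net)$name)
  if (anyNA(idx)) stop("module member(s) absent from the PPI network")
  sub <- igraph::induced_subgraph(ppi_net, idx)
  ppi_edges <- igraph::as_data_frame(sub, what = "edges")
  reg <- dpc_pt[dpc_pt$protein_id %in% members, , drop = FALSE]
  comp <- sort(unique(reg$compound_id))
  nodes <- data.frame(name = c(members, comp),
                      layer = c(rep("protein", length(members)),
                                rep("compound", length(comp))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c(ppi_edges$from, reg$compound_id),
                      to = c(ppi_edges$to, reg$protein_id),
                      votes = c(rep(NA_integer_, nrow(ppi_edges)),
                                as.integer(reg$votes)),
                      stringsAsFactors = FALSE)
  net <- layered_network(nodes, edges, allow_intralayer = "protein")
  tgt_per_comp <- vapply(split(reg$protein_id, reg$compound_id),
                         function(p) length(unique(p)), integer(1))
  list(network = net,
       regulators = comp,
       multi_targeting = sort(names(tgt_per_comp)[tgt_per_comp >= 2L]))
}
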