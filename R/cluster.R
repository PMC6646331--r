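# Agglomerative clustering of compounds on Tanimoto distance (1 - TC), with
# the deterministic tie-break the rest of the pipeline relies on: among pairs
# at equal merge distance, the pair whose smallest member id sorts first (then
# the other id) merges first.  stats::hclust is not used because its tie
# handling is order-dependent.

#' Hierarchically cluster compounds into a Newick tree
#'
#' Agglomerative clustering on distance `1 - TC`.  Branch lengths are derived
#' from merge heights so the tree is ultrametric: a pair merging at distance
#' `d` gets two branches of length `d/2`.  Compounds whose SMILES cannot be
#' fingerprinted are excluded and listed in the result.
#'
#' @param compounds data.frame with columns `compound_id`, `smiles`; or a
#'   precomputed `similarity_matrix` with identical row and column ids.
#' @param linkage one of `"single"`, `"complete"`, `"average"`.
#' @param n_bits fingerprint width used when `compounds` is a data.frame.
#' @return a `compound_tree`: list with `newick` (string), `leaf_ids`,
#'   `excluded` (character vector of unclusterable compound ids),
#'   `distance_metric = "1 - TC"`, `linkage`.
#' @export
cluster_compounds <- function(compounds, linkage = c("single", "complete", "average"),
                              n_bits = 1024L) {
  linkage <- match.arg(linkage)
  excluded <- character(0)
  if (inherits(compounds, "similarity_matrix")) {
    stopifnot(identical(rownames(compounds), colnames(compounds)))
    sim <- compounds
    excluded <- attr(compounds, "excluded")$compound_id
  } else {
    sim <- similarity_matrix(compounds, compounds, n_bits = n_bits)
    excluded <- attr(sim, "excluded")$compound_id
  }
  ids <- rownames(sim)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 clusterable compounds, got ", n)
  d <- 1 - unclass(sim)

  # active clusters: list of member index vectors; height of each cluster
  members <- as.list(seq_len(n))
  minid <- ids                       # lexicographically smallest member id
  elev <- rep(0, n)                  # node elevation = height / 2
  nwk <- ids                         # newick fragment per active cluster
  dist_cl <- d                       # cluster-cluster distance matrix
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    # find minimal distance pair with deterministic tie-break
    best <- NULL
    for (ai in seq_along(idx)) {
      for (bi in seq_len(ai - 1L)) {
        i <- idx[ai]; j <- idx[bi]
        dij <- dist_cl[i, j]
        lo <- if (minid[i] <= minid[j]) i else j
        hi <- if (lo == i) j else i
        key <- list(dij, minid[lo], minid[hi])
        if (is.null(best) ||
            dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[[2]] < best$key2 ||
              (key[[2]] == best$key2 && key[[3]] < best$key3)))) {
          best <- list(d = dij, i = lo, j = hi, key2 = key[[2]], key3 = key[[3]])
        }
      }
    }
    i <- best$i; j <- best$j; h <- best$d
    new_elev <- h / 2
    bl_i <- max(new_elev - elev[i], 0)
    bl_j <- max(new_elev - elev[j], 0)
    nwk_new <- sprintf("(%s:%.6g,%s:%.6g)", nwk[i], bl_i, nwk[j], bl_j)
    # update distances (Lance-Williams)
    ni <- length(members[[i]]); nj <- length(members[[j]])
    for (k in which(active)) {
      if (k == i || k == j) next
      dik <- dist_cl[i, k]; djk <- dist_cl[j, k]
      dnew <- switch(linkage,
        single   = min(dik, djk),
        complete = max(dik, djk),
        average  = (ni * dik + nj * djk) / (ni + nj))
      dist_cl[i, k] <- dnew; dist_cl[k, i] <- dnew
    }
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
    elev[i] <- new_elev
    nwk[i] <- nwk_new
    active[j] <- FALSE
  }
  root <- which(active)
  structure(list(newick = paste0(nwk[root], ";"),
                 leaf_ids = ids,
                 excluded = excluded,
                 distance_metric = "1 - TC",
                 linkage = linkage),
            class = "compound_tree")
}

#' Write a compound tree to a Newick file
#' @param tree a `compound_tree`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
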