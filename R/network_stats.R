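# Centrality reports, power-law degree-distribution fits, and a native
# implementation of the MCODE dense-module detector (vertex weighting by
# highest-k-core density of the closed neighborhood, seeded complex growth,
# haircut/fluff post-processing).

#' Degree and normalized betweenness centralities
#'
#' Betweenness is exact over all shortest paths with fractional credit for
#' ties, normalized by `2 / ((n-1)(n-2))` so values lie in `[0, 1]`.  On
#' disconnected graphs it is computed per component but normalized globally
#' (flagged in the `disconnected` attribute).  Graphs with fewer than 3 nodes
#' get `Cb = 0` with a warning.
#'
#' @param net a `layered_network` or igraph.
#' @return data.frame `node_id`, `degree_Cd`, `betweenness_Cb`.
#' @export
centralities <- function(net) {
  n <- igraph::vcount(net)
  deg <- igraph::degree(net, loops = FALSE)
  if (n < 3L) {
    warning("fewer than 3 nodes; betweenness reported as 0", call. = FALSE)
    cb <- rep(0, n)
  } else {
    cb <- igraph::betweenness(net, directed = FALSE, normalized = FALSE) *
      2 / ((n - 1) * (n - 2))
  }
  out <- data.frame(node_id = igraph::V(net)$name, degree_Cd = as.integer(deg),
                    betweenness_Cb = unname(cb), stringsAsFactors = FALSE)
  attr(out, "disconnected") <- !igraph::is_connected(net)
  out
}

#' Degree histogram of a network
#' @param net a `layered_network` or igraph.
#' @return data.frame `k`, `n_k` over observed degrees with `n_k > 0`.
#' @export
degree_histogram <- function(net) {
  deg <- igraph::degree(net, loops = FALSE)
  tab <- table(deg[deg > 0])
  data.frame(k = as.integer(names(tab)), n_k = as.integer(tab))
}

#' Fit a power law to a degree histogram
#'
#' Ordinary least squares on `(log10 k, log10 n_k)` over degrees with
#' `n_k > 0` (raw counts, not cumulative, not log-binned), the convention of
#' log-log degree-distribution plots.  Model: `n_k = a * k^-gamma`.
#'
#' @param hist data.frame with columns `k`, `n_k`.
#' @return a `powerlaw_fit`: list `coefficient_a`, `exponent_gamma`,
#'   `r_squared`.
#' @export
fit_powerlaw <- function(hist) {
  stopifnot(all(c("k", "n_k") %in% names(hist)))
  h <- hist[hist$n_k > 0 & hist$k > 0, , drop = FALSE]
  if (length(unique(h$k)) < 2L) {
    stop("power-law fit needs at least 2 distinct degrees with positive count")
  }
  fit <- stats::lm(log10(n_k) ~ log10(k), data = h)
  co <- stats::coef(fit)
  structure(list(coefficient_a = unname(10^co[1]),
                 exponent_gamma = unname(-co[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: y = %.4g * x^-%.4g  (r^2 = %.4f)\n",
              x$coefficient_a, x$exponent_gamma, x$r_squared))
  invisible(x)
}

#' Default MCODE parameters
#'
#' The canonical plugin defaults: degree cutoff 2, node score cutoff 0.2,
#' k-core 2, max depth 100, haircut on, fluff off.
#' @return named list of parameters.
#' @export
default_mcode_params <- function() {
  list(degree_cutoff = 2L, node_score_cutoff = 0.2, k_core = 2L,
       max_depth = 100L, haircut = TRUE, fluff = FALSE,
       fluff_density_cutoff = 0.1)
}

# weight of one vertex: k of the highest k-core of its closed neighborhood
# times that core's density ("core-clustering coefficient")
.mcode_weights <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  w <- numeric(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_v <- which(core == kmax)
    m <- igraph::ecount(igraph::induced_subgraph(sub, core_v))
    nn <- length(core_v)
    dens <- if (nn > 1L) 2 * m / (nn * (nn - 1)) else 0
    w[v] <- kmax * dens
  }
  w
}

#' MCODE dense-module detection
#'
#' Native implementation of the three MCODE stages: (1) vertex weighting --
#' the highest k-core of each vertex's closed neighborhood scored by
#' `k * density`; (2) seeded complex growth from the highest-weighted unseen
#' vertex, admitting neighbors with weight at least
#' `(1 - node_score_cutoff) * seed weight`, breadth-first up to `max_depth`;
#' (3) post-processing -- complexes without a `k_core`-core are discarded,
#' `haircut` iteratively removes members with fewer than 2 within-module
#' connections, `fluff` optionally adds neighbor shells above a density
#' cutoff.  Each node belongs to at most one module; ties are broken by node
#' id, so the result is deterministic.
#'
#' @param net a `layered_network` or igraph (undirected, simple).
#' @param params as [default_mcode_params()].
#' @return list of `module` records (`module_id`, `members`, `seed`,
#'   `mcode_score`, `params_used`), ordered by score descending.
#' @export
mcode <- function(net, params = default_mcode_params()) {
  p <- utils::modifyList(default_mcode_params(), params)
  g <- igraph::simplify(igraph::as_undirected(net, mode = "collapse"))
  n <- igraph::vcount(g)
  if (n == 0L || igraph::ecount(g) == 0L) return(list())
  names_v <- igraph::V(g)$name
  w <- .mcode_weights(g, p$degree_cutoff)
  if (all(w <= 0)) return(list())
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  assigned <- logical(n)
  seed_used <- logical(n)

  # seeds in decreasing weight, ties by node name
  seed_order <- order(-w, names_v)
  modules <- list()
  for (s in seed_order) {
    if (w[s] <= 0 || assigned[s] || seed_used[s]) next
    seed_used[s] <- TRUE
    thresh <- w[s] * (1 - p$node_score_cutoff)
    members <- s
    inmod <- logical(n); inmod[s] <- TRUE
    frontier <- s; depth <- 0L
    while (length(frontier) > 0L && depth < p$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (inmod[u] || assigned[u]) next
          if (w[u] >= thresh) {
            inmod[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < p$k_core) next
    memb_names <- igraph::V(sub)$name
    if (p$haircut) {
      repeat {
        degs <- igraph::degree(sub)
        drop <- degs < 2
        if (!any(drop)) break
        sub <- igraph::induced_subgraph(sub, which(!drop))
        if (igraph::vcount(sub) == 0L) break
      }
      memb_names <- igraph::V(sub)$name
    }
    if (length(memb_names) < 2L) next
    if (p$fluff) {
      shell <- setdiff(unique(unlist(lapply(match(memb_names, names_v),
                                            function(v) as.integer(adj[[v]])))),
                       match(memb_names, names_v))
      for (u in shell) {
        if (assigned[u]) next
        nbu <- c(u, as.integer(adj[[u]]))
        subu <- igraph::induced_subgraph(g, nbu)
        nn <- igraph::vcount(subu)
        dens <- if (nn > 1) 2 * igraph::ecount(subu) / (nn * (nn - 1)) else 0
        if (dens > p$fluff_density_cutoff) memb_names <- c(memb_names, names_v[u])
      }
      memb_names <- unique(memb_names)
    }
    idx <- match(memb_names, names_v)
    assigned[idx] <- TRUE
    msub <- igraph::induced_subgraph(g, idx)
    nn <- igraph::vcount(msub)
    dens <- if (nn > 1) 2 * igraph::ecount(msub) / (nn * (nn - 1)) else 0
    modules[[length(modules) + 1L]] <- list(
      members = sort(memb_names), seed = names_v[s],
      mcode_score = dens * nn)
  }
  if (length(modules) == 0L) return(list())
  ord <- order(-vapply(modules, `[[`, numeric(1), "mcode_score"),
               vapply(modules, function(m) m$members[1], character(1)))
  modules <- modules[ord]
  for (i in seq_along(modules)) {
    modules[[i]]$module_id <- i
    modules[[i]]$params_used <- p
    class(modules[[i]]) <- "mcode_module"
  }
  modules
}

#' Write MCODE modules as TSV (`module_id`, `score`, `seed`, `members`)
#' @param modules output of [mcode()].
#' @param path output file.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- data.frame(
    module_id = vapply(modules, `[[`, integer(1), "module_id"),
    mcode_score = vapply(modules, `[[`, numeric(1), "mcode_score"),
    seed = vapply(modules, `[[`, character(1), "seed"),
    members = vapply(modules, function(m) paste(m$members, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
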