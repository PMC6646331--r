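# Layered (bipartite / tripartite / PPI) networks backed by igraph.  Every
# node carries a `layer` tag; edges carry provenance attributes (votes,
# scores).  Intra-layer edges are forbidden except where explicitly allowed
# (PPI layers).

#' Construct a layered network
#'
#' @param nodes data.frame with columns `name`, `layer`.
#' @param edges data.frame with columns `from`, `to` plus any attribute
#'   columns.
#' @param allow_intralayer layer names within which edges are allowed
#'   (e.g. `"protein"` for PPI edges).
#' @return a `layered_network` (igraph with vertex attribute `layer`).
#' @export
layered_network <- function(nodes, edges = NULL, allow_intralayer = character(0)) {
  stopifnot(all(c("name", "layer") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  miss <- setdiff(unique(c(edges$from, edges$to)), nodes$name)
  if (length(miss) > 0L) {
    stop("edge endpoint(s) not in any declared layer: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  lay <- stats::setNames(nodes$layer, nodes$name)
  intra <- lay[edges$from] == lay[edges$to]
  bad <- intra & !(lay[edges$from] %in% allow_intralayer)
  if (any(bad)) {
    stop(sum(bad), " intra-layer edge(s) in layer(s) ",
         paste(unique(lay[edges$from][bad]), collapse = ", "),
         " not allowed")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  class(g) <- c("layered_network", class(g))
  g
}

#' @export
print.layered_network <- function(x, ...) {
  tab <- table(igraph::V(x)$layer)
  cat("layered_network:", igraph::vcount(x), "nodes,", igraph::ecount(x),
      "edges\n  layers:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Node / edge accessors for layered networks
#' @param net a `layered_network`.
#' @return `network_nodes`: data.frame `name`, `layer`; `network_edges`:
#'   data.frame `from`, `to` plus attribute columns.
#' @export
network_nodes <- function(net) {
  data.frame(name = igraph::V(net)$name, layer = igraph::V(net)$layer,
             stringsAsFactors = FALSE)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  igraph::as_data_frame(net, what = "edges")
}

#' Build a bipartite layered network from an association list
#'
#' @param assoc data.frame whose first two columns are the left and right
#'   identifiers; extra columns become edge attributes.
#' @param left_type,right_type layer tags (e.g. `"herb"`, `"compound"`).
#' @return a `layered_network`.
#' @export
build_bipartite <- function(assoc, left_type, right_type) {
  if (nrow(assoc) == 0L) {
    warning("empty association list; returning empty network", call. = FALSE)
    return(layered_network(data.frame(name = character(0), layer = character(0))))
  }
  assoc <- assoc[!duplicated(assoc[, 1:2]), , drop = FALSE]
  left <- unique(assoc[[1]])
  right <- unique(assoc[[2]])
  if (length(common <- intersect(left, right)) > 0L) {
    stop("identifier(s) appear on both sides of a bipartite build: ",
         paste(utils::head(common, 5), collapse = ", "))
  }
  nodes <- data.frame(name = c(left, right),
                      layer = c(rep(left_type, length(left)),
                                rep(right_type, length(right))),
                      stringsAsFactors = FALSE)
  edges <- assoc
  names(edges)[1:2] <- c("from", "to")
  layered_network(nodes, edges)
}

#' Build an epilepsy-style gene pool
#'
#' @param ids character vector of gene symbols or accessions.
#' @param mapping optional data.frame (`symbol`, `accession`) used to convert
#'   symbols; entries that stay unmapped (no accession-shaped id and not in
#'   the table) are reported via the `unmapped` attribute with a warning.
#' @return a `gene_pool`: list with `ids` (normalized accession set) and
#'   `mapping`.
#' @export
gene_pool <- function(ids, mapping = NULL) {
  stopifnot(length(ids) > 0L)
  norm <- normalize_protein_ids(ids, mapping)
  unmapped <- character(0)
  if (!is.null(mapping)) {
    known <- toupper(c(mapping$accession, mapping$symbol))
    looks_acc <- grepl("^[A-Z][0-9][A-Z0-9]{3,8}[0-9]$", norm)
    unmapped <- unique(norm[!looks_acc & !(toupper(ids) %in% known)])
    if (length(unmapped) > 0L) {
      warning(length(unmapped), " pool entr(ies) could not be mapped to accessions",
              call. = FALSE)
    }
  }
  structure(list(ids = unique(norm), mapping = mapping, unmapped = unmapped),
            class = "gene_pool")
}

#' Restrict a compound-protein network to a gene pool
#'
#' Keeps edges whose protein endpoint is in the pool, then drops isolated
#' nodes.  Edge attributes (votes, sources) are preserved.
#'
#' @param net a compound-protein `layered_network`.
#' @param pool a [gene_pool()].
#' @param protein_layer name of the protein layer (default `"protein"`).
#' @return the filtered `layered_network`.
#' @export
filter_to_pool <- function(net, pool, protein_layer = "protein") {
  stopifnot(inherits(pool, "gene_pool"))
  prot <- igraph::V(net)$name[igraph::V(net)$layer == protein_layer]
  keep_prot <- prot[prot %in% pool$ids]
  ed <- network_edges(net)
  keep <- (ed$from %in% keep_prot) | (ed$to %in% keep_prot)
  sub <- igraph::subgraph_from_edges(net, igraph::E(net)[keep],
                                     delete.vertices = TRUE)
  class(sub) <- c("layered_network", class(sub))
  sub
}

#' High-confidence PPI subgraph induced on a gene pool
#'
#' Scores greater than 1 anywhere in the input are interpreted as STRING
#' milli-scores and the whole column is divided by 1000 before thresholding.
#' Self-loops are dropped; duplicate unordered pairs keep the maximum score.
#'
#' @param edges data.frame `protein_a`, `protein_b`, `score`.
#' @param pool a [gene_pool()].
#' @param min_score confidence threshold after normalization (default 0.9).
#' @return a `layered_network` of layer `"protein"`; attribute `provenance`
#'   records pool size, mapped, interacting and isolated counts.
#' @export
ppi_subgraph <- function(edges, pool, min_score = 0.9) {
  stopifnot(inherits(pool, "gene_pool"))
  if (nrow(edges) == 0L) stop("empty PPI edge list")
  score <- edges$score
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  a <- normalize_protein_ids(edges$protein_a)
  b <- normalize_protein_ids(edges$protein_b)
  self <- a == b
  if (any(self)) message(sum(self), " self-loop(s) dropped from PPI edges")
  keep <- !self & !is.na(score) & score >= min_score
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep]); s2 <- score[keep]
  key <- paste(a2, b2)
  s2 <- vapply(split(s2, key), max, numeric(1))
  parts <- strsplit(names(s2), " ", fixed = TRUE)
  a3 <- vapply(parts, `[`, character(1), 1L)
  b3 <- vapply(parts, `[`, character(1), 2L)
  # proteins of the pool present anywhere in the thresholded network
  mapped <- intersect(pool$ids, unique(c(a3, b3)))
  inpool <- a3 %in% pool$ids & b3 %in% pool$ids
  a4 <- a3[inpool]; b4 <- b3[inpool]; s4 <- unname(s2[inpool])
  interacting <- unique(c(a4, b4))
  nodes <- data.frame(name = sort(interacting),
                      layer = rep("protein", length(interacting)),
                      stringsAsFactors = FALSE)
  net <- layered_network(nodes,
                         data.frame(from = a4, to = b4, score = s4,
                                    stringsAsFactors = FALSE),
                         allow_intralayer = "protein")
  attr(net, "provenance") <- list(
    pool_size = length(pool$ids),
    mapped_in_ppi = length(mapped),
    interacting = length(interacting),
    isolated = length(setdiff(mapped, interacting)),
    min_score = min_score)
  net
}

#' Giant (largest connected) component
#'
#' Ties on node count are broken by edge count, then by smallest
#' lexicographic node id.  Idempotent.  The `removed` attribute lists nodes
#' outside the giant component.
#'
#' @param net a `layered_network`.
#' @return the giant component as a `layered_network`.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty graph has no giant component")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ec <- vapply(best, function(ci) {
      sub <- igraph::induced_subgraph(net, which(comp$membership == ci))
      igraph::ecount(sub)
    }, numeric(1))
    best <- best[ec == max(ec)]
    if (length(best) > 1L) {
      mins <- vapply(best, function(ci)
        min(igraph::V(net)$name[comp$membership == ci]), character(1))
      best <- best[which.min(mins)]
    }
  }
  keep <- which(comp$membership == best[1])
  sub <- igraph::induced_subgraph(net, keep)
  class(sub) <- c("layered_network", class(sub))
  attr(sub, "removed") <- setdiff(igraph::V(net)$name, igraph::V(sub)$name)
  attr(sub, "provenance") <- attr(net, "provenance")
  sub
}

#' Assemble a tripartite network around a middle protein layer
#'
#' Keeps left (compound-protein) and right (drug-protein) edges incident to
#' the middle-layer proteins; edge provenance is kept in a `side` attribute
#' plus whatever attribute columns the inputs carry.
#'
#' @param middle character vector of protein accessions (middle layer).
#' @param left data.frame `compound_id`, `protein_id` + attributes.
#' @param right data.frame `drug_id`, `protein_id` + attributes.
#' @return a `layered_network` with layers `compound`, `protein`, `drug`.
#' @export
build_tripartite <- function(middle, left, right = NULL) {
  stopifnot(length(middle) > 0L)
  if (is.null(right) || nrow(right) == 0L) {
    warning("no drug-side edges; building a degenerate bipartite network",
            call. = FALSE)
    right <- data.frame(drug_id = character(0), protein_id = character(0),
                        stringsAsFactors = FALSE)
  }
  l <- left[left$protein_id %in% middle, , drop = FALSE]
  r <- right[right$protein_id %in% middle, , drop = FALSE]
  prot <- sort(unique(c(l$protein_id, r$protein_id)))
  nodes <- data.frame(
    name = c(unique(l$compound_id), prot, unique(r$drug_id)),
    layer = c(rep("compound", length(unique(l$compound_id))),
              rep("protein", length(prot)),
              rep("drug", length(unique(r$drug_id)))),
    stringsAsFactors = FALSE)
  le <- data.frame(from = l$compound_id, to = l$protein_id,
                   side = rep("compound", nrow(l)),
                   l[, setdiff(names(l), c("compound_id", "protein_id")),
                     drop = FALSE], stringsAsFactors = FALSE)
  re <- data.frame(from = r$drug_id, to = r$protein_id,
                   side = rep("drug", nrow(r)),
                   r[, setdiff(names(r), c("drug_id", "protein_id")),
                     drop = FALSE], stringsAsFactors = FALSE)
  cols <- union(names(le), names(re))
  for (cn in setdiff(cols, names(le))) le[[cn]] <- rep(NA, nrow(le))
  for (cn in setdiff(cols, names(re))) re[[cn]] <- rep(NA, nrow(re))
  layered_network(nodes, rbind(le[, cols], re[, cols]))
}

# --- interchange ------------------------------------------------------------

#' Write a layered network in SIF format (`A<TAB>interacts<TAB>B`)
#' @param net a `layered_network`.
#' @param path output file.
#' @param relation relation label (default `"interacts"`).
#' @export
write_sif <- function(net, path, relation = "interacts") {
  ed <- network_edges(net)
  utils::write.table(data.frame(ed$from, relation, ed$to),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' GraphML round-trip for layered networks
#'
#' Node names, layer tags and all edge attributes survive a write/read
#' round trip exactly.
#' @param net a `layered_network`.
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  # GraphML has no NA: integers/logicals are written as doubles (NA -> NaN)
  # and character NAs as a sentinel token, with the original types recorded
  # in a graph attribute so read_graphml can restore them exactly.
  types <- list(vertex = list(), edge = list())
  for (a in igraph::vertex_attr_names(net)) {
    v <- igraph::vertex_attr(net, a)
    types$vertex[[a]] <- class(v)[1]
    if (is.integer(v) || is.logical(v)) {
      net <- igraph::set_vertex_attr(net, a, value = as.double(v))
    } else if (is.character(v) && anyNA(v)) {
      v[is.na(v)] <- "__NA__"
      net <- igraph::set_vertex_attr(net, a, value = v)
    }
  }
  for (a in igraph::edge_attr_names(net)) {
    v <- igraph::edge_attr(net, a)
    types$edge[[a]] <- class(v)[1]
    if (is.integer(v) || is.logical(v)) {
      net <- igraph::set_edge_attr(net, a, value = as.double(v))
    } else if (is.character(v) && anyNA(v)) {
      v[is.na(v)] <- "__NA__"
      net <- igraph::set_edge_attr(net, a, value = v)
    }
  }
  net <- igraph::set_graph_attr(net, "attr_types",
                                jsonlite::toJSON(types, auto_unbox = TRUE))
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

.restore_attr <- function(v, type) {
  if (type %in% c("integer", "logical", "numeric")) {
    v[is.nan(v)] <- NA
    v <- switch(type, integer = as.integer(v), logical = as.logical(v), v)
  } else if (type == "character") {
    v[v == "__NA__"] <- NA_character_
  }
  v
}

#' @rdname write_graphml
#' @return `read_graphml`: the restored `layered_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # igraph stores the vertex name under `id` on graphml write
  if (!("name" %in% igraph::vertex_attr_names(g)) &&
      "id" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  if ("id" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "id")
  }
  if ("attr_types" %in% igraph::graph_attr_names(g)) {
    types <- jsonlite::fromJSON(igraph::graph_attr(g, "attr_types"))
    for (a in intersect(names(types$vertex), igraph::vertex_attr_names(g))) {
      g <- igraph::set_vertex_attr(
        g, a, value = .restore_attr(igraph::vertex_attr(g, a), types$vertex[[a]]))
    }
    for (a in intersect(names(types$edge), igraph::edge_attr_names(g))) {
      g <- igraph::set_edge_attr(
        g, a, value = .restore_attr(igraph::edge_attr(g, a), types$edge[[a]]))
    }
    g <- igraph::delete_graph_attr(g, "attr_types")
  }
  class(g) <- c("layered_network", class(g))
  g
}

#' Write a provenance report as JSON
#' @param net a `layered_network` carrying a `provenance` attribute.
#' @param path output file.
#' @export
write_provenance <- function(net, path) {
  prov <- attr(net, "provenance")
  if (is.null(prov)) prov <- list()
  prov$nodes <- igraph::vcount(net)
  prov$edges <- igraph::ecount(net)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
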