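# Independent brute-force oracles.  These deliberately avoid the package's
# production code paths: the path enumerator grows vertex sequences by plain
# list extension (no DFS bookkeeping), and the betweenness oracle enumerates
# every shortest path explicitly.

# --- exhaustive path enumeration over a parsed molecule ---------------------

# Returns the set of canonical fragment strings for all linear paths of
# 1..max_len heavy atoms, with the single-atom plain-C/N/O exclusion.
oracle_fragments <- function(smiles, max_len = 7L) {
  mol <- phytonet::parse_smiles(smiles)
  heavy <- which(mol$atoms$element != "H")
  atoms <- mol$atoms
  bonds <- mol$bonds[mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy, ,
                     drop = FALSE]
  code <- function(i) paste0(atoms$element[i],
                             if (atoms$aromatic[i]) "'" else "",
                             if (atoms$charge[i] != 0L)
                               sprintf("%+d", atoms$charge[i]) else "")
  bond_between <- function(i, j) {
    hit <- (bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i)
    bonds$order[hit][1]
  }
  nbrs <- function(i) {
    c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
  }
  frags <- character(0)
  for (i in heavy) {
    if (!(atoms$element[i] %in% c("C", "N", "O") && atoms$charge[i] == 0L)) {
      frags <- c(frags, code(i))
    }
  }
  # grow all simple vertex sequences, one length at a time
  paths <- lapply(heavy, function(i) i)
  for (len in 2:max_len) {
    nxt <- list()
    for (p in paths) {
      last <- p[length(p)]
      for (j in nbrs(last)) {
        if (!(j %in% p)) nxt[[length(nxt) + 1L]] <- c(p, j)
      }
    }
    if (length(nxt) == 0L) break
    for (p in nxt) {
      toks <- character(2L * length(p) - 1L)
      toks[seq(1, by = 2, length.out = length(p))] <- vapply(p, code, "")
      toks[seq(2, by = 2, length.out = length(p) - 1L)] <-
        vapply(seq_len(length(p) - 1L),
               function(k) bond_between(p[k], p[k + 1L]), "")
      f <- paste(toks, collapse = "")
      r <- paste(rev(toks), collapse = "")
      frags <- c(frags, min(f, r))
    }
    paths <- nxt
  }
  sort(unique(frags))
}

# --- brute-force betweenness ------------------------------------------------

# Exact normalized betweenness by explicit enumeration of all shortest paths
# between every unordered pair (fractional credit for ties).
oracle_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  names(adj) <- nodes
  all_shortest <- function(s, t) {
    # BFS layer by layer collecting all shortest paths
    paths <- list(s)
    found <- list()
    repeat {
      if (length(paths) == 0L) return(found)
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        if (last == t) found[[length(found) + 1L]] <- p
      }
      if (length(found) > 0L) return(found)
      seen_depth <- unique(unlist(paths))
      for (p in paths) {
        for (u in adj[[p[length(p)]]]) {
          if (!(u %in% p)) nxt[[length(nxt) + 1L]] <- c(p, u)
        }
      }
      # prune: keep only paths whose endpoint is at BFS distance == length
      if (length(nxt) == 0L) return(found)
      paths <- nxt
      if (length(paths[[1]]) > n) return(found)
    }
  }
  cb <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sp <- all_shortest(nodes[i], nodes[j])
      if (length(sp) == 0L) next
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        for (v in inner) cb[v] <- cb[v] + 1 / length(sp)
      }
    }
  }
  if (n >= 3) cb * 2 / ((n - 1) * (n - 2)) else cb * 0
}

# small random molecule for property tests (same grammar as the generator,
# but built here so oracle tests do not depend on generator internals)
random_small_smiles <- function(n_atoms) {
  atoms <- sample(c("C", "C", "N", "O", "S"), n_atoms, replace = TRUE)
  out <- atoms[1]
  if (n_atoms > 1) for (i in 2:n_atoms) {
    bond <- if (runif(1) < 0.2 && atoms[i] != "O" && atoms[i - 1] != "O") "=" else ""
    out <- paste0(out, bond, atoms[i])
  }
  out
}

random_fingerprint <- function(n_bits = 64L, density = 0.2) {
  bits <- which(runif(n_bits) < density) - 1L
  structure(list(compound_id = NA_character_, bits = bits,
                 n_bits = as.integer(n_bits), fragment_count = length(bits)),
            class = "path_fingerprint")
}
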