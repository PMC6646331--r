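# Organic-subset elements that may be written without brackets, and their
# aromatic (lowercase) forms.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

smiles_parse_error <- function(msg, pos) {
  stop(structure(
    class = c("smiles_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error at position %d: %s", pos, msg),
         call = NULL, position = pos)
  ))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, bracket atoms with explicit hydrogen count and charge, single,
#' double, triple and aromatic bonds, branches, and ring-bond closures
#' (`1`-`9` and `%nn`). Stereo markers (`/ \ @`) are accepted and ignored;
#' no aromaticity perception or kekulization is performed, so the aromatic
#' flags are taken exactly as written.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a `molgraph` object: a list with `atoms` (data.frame with columns
#'   `element`, `aromatic`, `charge`, `hcount` -- `NA` meaning implicit) and
#'   `bonds` (data.frame with columns `a1`, `a2`, `order`; order is one of
#'   `"1"`, `"2"`, `"3"`, `"a"`).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    smiles_parse_error("input must be a single non-empty string", 0L)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hcount <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- character(0)

  add_atom <- function(el, arom, chg = 0L, hc = NA_integer_) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hcount[length(hcount) + 1L] <<- hc
    length(element)
  }
  add_bond <- function(a1, a2, ord) {
    b_a1[length(b_a1) + 1L] <<- a1
    b_a2[length(b_a2) + 1L] <<- a2
    b_ord[length(b_ord) + 1L] <<- ord
  }

  prev <- 0L                 # atom the next atom bonds to (0 = none)
  stack <- integer(0)        # branch stack
  pending_bond <- NA_character_
  ring_open <- list()        # ring digit -> list(atom, bond, pos)
  i <- 1L

  bond_for <- function(a1, a2) {
    if (!is.na(pending_bond)) return(pending_bond)
    if (aromatic[a1] && aromatic[a2]) "a" else "1"
  }
  attach_atom <- function(idx) {
    if (prev > 0L) add_bond(prev, idx, bond_for(prev, idx))
    pending_bond <<- NA_character_
    prev <<- idx
  }
  ring_closure <- function(key, pos) {
    if (prev == 0L) smiles_parse_error("ring bond before any atom", pos)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ord <- pending_bond
      if (is.na(ord)) ord <- op$bond
      if (is.na(ord)) {
        ord <- if (aromatic[op$atom] && aromatic[prev]) "a" else "1"
      }
      if (op$atom == prev) smiles_parse_error("ring bond to self", pos)
      add_bond(op$atom, prev, ord)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond, pos = pos)
    }
    pending_bond <<- NA_character_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smiles_parse_error("unclosed bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+{1,3}|-{1,3}|[+-][0-9]+)?)$",
        body))[[1]]
      if (length(m) == 0L || !nzchar(m[3])) {
        smiles_parse_error(sprintf("cannot parse bracket atom '[%s]'", body), i)
      }
      sym <- m[3]
      arom <- sym %in% .AROMATIC_OK
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      hstr <- m[4]
      hc <- 0L
      hm <- regmatches(hstr, regexec("H([0-9]*)", hstr))[[1]]
      if (length(hm) > 0L) hc <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      chg <- 0L
      cs <- m[5]
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(substring(cs, 2)) *
            (if (substr(cs, 1, 1) == "+") 1L else -1L)
        } else {
          chg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      attach_atom(add_atom(el, arom, chg, hc))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        attach_atom(add_atom(two, FALSE))
        i <- i + 2L
      } else smiles_parse_error(sprintf("unknown element '%s'", two), i)
    } else if (ch %in% .ORGANIC_SUBSET) {
      attach_atom(add_atom(ch, FALSE))
      i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      el <- paste0(toupper(substr(ch, 1, 1)), substring(ch, 2))
      attach_atom(add_atom(el, TRUE))
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) smiles_parse_error("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_parse_error("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "a")
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "1"   # stereo bonds treated as single
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_closure(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
        smiles_parse_error("'%' must be followed by two digits", i)
      }
      ring_closure(paste0("%", chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == ".") {
      smiles_parse_error("disconnected structures ('.') are not supported", i)
    } else {
      smiles_parse_error(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(stack) > 0L) smiles_parse_error("unclosed branch '('", n)
  if (length(ring_open) > 0L) {
    smiles_parse_error(sprintf("unclosed ring bond '%s'", names(ring_open)[1]),
                       ring_open[[1]]$pos)
  }
  if (length(element) == 0L) smiles_parse_error("no atoms", 1L)

  structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, hcount = hcount,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b_a1, a2 = b_a2, order = b_ord,
                       stringsAsFactors = FALSE)
  ), class = "molgraph")
}

# adjacency list: for atom i, data.frame(nb, order)
.mol_adj <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nb = integer(0), ord = character(0))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
    adj[[i]]$nb <- c(adj[[i]]$nb, j); adj[[i]]$ord <- c(adj[[i]]$ord, o)
    adj[[j]]$nb <- c(adj[[j]]$nb, i); adj[[j]]$ord <- c(adj[[j]]$ord, o)
  }
  adj
}

# --- canonical ranking ------------------------------------------------------

# Iterative neighborhood refinement of atom ranks (Morgan-style).  Returns an
# integer rank per atom; equal ranks = indistinguishable at fixpoint.
.refine_ranks <- function(mol, adj, ranks) {
  n <- nrow(mol$atoms)
  repeat {
    keys <- vapply(seq_len(n), function(i) {
      nbk <- sort(paste0(adj[[i]]$ord, ":", sprintf("%06d", ranks[adj[[i]]$nb])))
      paste(sprintf("%06d", ranks[i]), paste(nbk, collapse = "|"))
    }, character(1))
    new_ranks <- match(keys, sort(unique(keys)))
    if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
    ranks <- new_ranks
  }
}

.initial_ranks <- function(mol, adj) {
  n <- nrow(mol$atoms)
  deg <- vapply(adj, function(a) length(a$nb), integer(1))
  keys <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
                ifelse(is.na(mol$atoms$hcount), -1L, mol$atoms$hcount), deg)
  match(keys, sort(unique(keys)))
}

# Canonical SMILES via individualization-refinement: whenever refinement
# leaves a tied cell, branch on each member and keep the lexicographically
# smallest emitted string.  Exponential only for highly symmetric graphs,
# which symmetry also collapses quickly after one individualization.
.canon_string <- function(mol, adj, ranks) {
  ranks <- .refine_ranks(mol, adj, ranks)
  n <- nrow(mol$atoms)
  if (length(unique(ranks)) == n) return(.write_smiles(mol, adj, ranks))
  tab <- table(ranks)
  cell_rank <- as.integer(names(tab)[tab > 1L][1])
  members <- which(ranks == cell_rank)
  best <- NULL
  for (a in members) {
    r2 <- ranks * 2L
    r2[a] <- r2[a] - 1L
    s <- .canon_string(mol, adj, match(r2, sort(unique(r2))))
    if (is.null(best) || s < best) best <- s
  }
  best
}

# Emit SMILES following canonical ranks: DFS from the lowest-ranked atom,
# neighbors visited in increasing rank order; ring-closure digits assigned
# in order of opening.
.write_smiles <- function(mol, adj, ranks) {
  n <- nrow(mol$atoms)
  visited <- logical(n)
  ring_digit <- 0L
  ring_label <- list()  # "i-j" -> digit
  atoms <- mol$atoms

  edge_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

  # pre-walk to find tree/back edges from the same traversal order
  back_edges <- character(0)
  order_nb <- function(i) adj[[i]]$nb[order(ranks[adj[[i]]$nb])]

  atom_token <- function(i) {
    el <- atoms$element[i]
    sym <- if (atoms$aromatic[i]) tolower(el) else el
    needs_bracket <- atoms$charge[i] != 0L || !is.na(atoms$hcount[i]) ||
      !(el %in% .ORGANIC_SUBSET) ||
      (atoms$aromatic[i] && !(tolower(el) %in% .AROMATIC_OK))
    if (!needs_bracket) return(sym)
    hc <- atoms$hcount[i]
    hstr <- if (is.na(hc) || hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
    chg <- atoms$charge[i]
    cstr <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-" else
      sprintf("%+d", chg)
    paste0("[", sym, hstr, cstr, "]")
  }
  bond_token <- function(ord, i, j) {
    if (ord == "2") return("=")
    if (ord == "3") return("#")
    if (ord == "a") {
      if (atoms$aromatic[i] && atoms$aromatic[j]) return("") else return(":")
    }
    if (atoms$aromatic[i] && atoms$aromatic[j]) return("-")  # explicit single
    ""
  }

  # Two-pass scheme: pass 1 discovers DFS back edges (ring bonds), pass 2
  # emits the string with ring digits written at both endpoints.
  back <- character(0)
  walk <- function(i, from) {
    visited[i] <<- TRUE
    for (j in order_nb(i)) {
      if (!is.na(from) && j == from) next
      if (visited[j]) {
        ek <- edge_key(i, j)
        if (!(ek %in% back)) back <<- c(back, ek)
      } else walk(j, i)
    }
  }
  start <- which.min(ranks)
  walk(start, NA)

  # assign digits in discovery order of the SECOND pass opening; emit with
  # closure bookkeeping: a ring edge emits its digit at both endpoints.
  visited[] <- FALSE
  ring_label <- list(); ring_digit <- 0L
  pending_open <- list()  # edge -> digit, waiting to close
  emit2 <- function(i, from) {
    visited[i] <<- TRUE
    out <- atom_token(i)
    nbs <- order_nb(i)
    ords <- adj[[i]]$ord[match(nbs, adj[[i]]$nb)]
    children <- integer(0); child_ord <- character(0)
    ring_here <- ""
    for (k in seq_along(nbs)) {
      j <- nbs[k]
      if (!is.na(from) && j == from) next
      ek <- edge_key(i, j)
      if (ek %in% back) {
        if (is.null(ring_label[[ek]])) {
          ring_digit <<- ring_digit + 1L
          ring_label[[ek]] <<- ring_digit
        }
        lab <- ring_label[[ek]]
        digit <- if (lab > 9L) paste0("%", sprintf("%02d", lab)) else as.character(lab)
        ring_here <- paste0(ring_here, bond_token(ords[k], i, j), digit)
      } else if (!visited[j]) {
        children <- c(children, j); child_ord <- c(child_ord, ords[k])
      }
    }
    out <- paste0(out, ring_here)
    if (length(children) > 0L) {
      for (k in seq_along(children)) {
        j <- children[k]
        seg <- paste0(bond_token(child_ord[k], i, j), emit2(j, i))
        if (k < length(children)) seg <- paste0("(", seg, ")")
        out <- paste0(out, seg)
      }
    }
    out
  }
  emit2(start, NA)
}

#' Canonicalize a SMILES string
#'
#' Produces a deterministic canonical form: chemically identical inputs (the
#' same molecular graph, with aromatic flags as written) map to identical
#' output strings, and the transformation is idempotent.  Canonical atom
#' ordering comes from iterative neighborhood refinement with full
#' individualization branching on ties, taking the lexicographically
#' smallest emitted string.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string, with attribute `algorithm` recording
#'   the canonical-form algorithm identifier.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  mol <- parse_smiles(smiles)
  adj <- .mol_adj(mol)
  out <- .canon_string(mol, adj, .initial_ranks(mol, adj))
  attr(out, "algorithm") <- "phytonet-morgan-ir-1"
  out
}
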