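# Path-based (FP2-style) fingerprints: every linear path of 1-7 heavy atoms
# is encoded (elements, aromatic flags and bond orders), single-atom C/N/O
# fragments are excluded, and each fragment is hashed into a fixed-width bit
# set.  The hash is a plain polynomial rolling hash so that bit assignment is
# stable across R sessions and platforms.

.HASH_MOD <- 2^25  # keeps (h * 31 + byte) < 2^53, exact in doubles

.hash_fragment <- function(frag, n_bits) {
  bytes <- utf8ToInt(frag)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% .HASH_MOD
  as.integer(h %% n_bits)
}

# atom token used inside fragments: element, aromatic marker, charge if any
.atom_code <- function(atoms, i) {
  paste0(atoms$element[i],
         ifelse(atoms$aromatic[i], "'", ""),
         ifelse(atoms$charge[i] == 0L, "",
                sprintf("%+d", atoms$charge[i])))
}

# Enumerate the distinct linear fragments (canonical min of the two reading
# directions) of 1..max_len heavy atoms.  Hydrogen atoms are dropped first.
.path_fragments <- function(mol, max_len = 7L) {
  heavy <- which(mol$atoms$element != "H")
  if (length(heavy) == 0L) return(character(0))
  keep <- mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy
  mol2 <- list(atoms = mol$atoms[heavy, , drop = FALSE],
               bonds = mol$bonds[keep, , drop = FALSE])
  remap <- match(seq_len(nrow(mol$atoms)), heavy)
  mol2$bonds$a1 <- remap[mol2$bonds$a1]
  mol2$bonds$a2 <- remap[mol2$bonds$a2]
  atoms <- mol2$atoms
  adj <- .mol_adj(mol2)
  n <- nrow(atoms)
  codes <- vapply(seq_len(n), function(i) .atom_code(atoms, i), character(1))

  frags <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(s) assign(s, TRUE, envir = frags)

  # single atoms: exclude plain C/N/O (the FP2 convention)
  for (i in seq_len(n)) {
    if (atoms$element[i] %in% c("C", "N", "O") && atoms$charge[i] == 0L) next
    add(codes[i])
  }

  in_path <- logical(n)
  fwd <- character(max_len * 2L - 1L)   # token sequence of the current path
  dfs <- function(i, depth) {
    in_path[i] <<- TRUE
    fwd[2L * depth - 1L] <<- codes[i]
    if (depth > 1L) {
      f <- paste(fwd[seq_len(2L * depth - 1L)], collapse = "")
      r <- paste(rev(fwd[seq_len(2L * depth - 1L)]), collapse = "")
      add(if (f < r) f else r)
    }
    if (depth < max_len) {
      nbs <- adj[[i]]$nb
      ords <- adj[[i]]$ord
      for (k in seq_along(nbs)) {
        j <- nbs[k]
        if (in_path[j]) next
        fwd[2L * depth] <<- ords[k]
        dfs(j, depth + 1L)
      }
    }
    in_path[i] <<- FALSE
  }
  for (i in seq_len(n)) dfs(i, 1L)
  ls(frags)
}

#' Compute a path fingerprint for a compound
#'
#' Enumerates all linear paths of 1 to `max_len` heavy atoms (elements,
#' aromatic flags and bond orders encoded; single-atom fragments that are
#' plain carbon, nitrogen or oxygen are excluded, following the FP2
#' convention) and hashes each distinct fragment to one bit of an
#' `n_bits`-wide bit set.
#'
#' @param smiles SMILES string of the compound (canonical or not; the
#'   fingerprint depends only on the molecular graph).
#' @param compound_id identifier carried on the result.
#' @param n_bits width of the bit set (default 1024).
#' @param max_len maximum fragment length in atoms (default 7).
#' @return a `path_fingerprint`: list with `compound_id`, `bits` (sorted
#'   0-based integer vector), `n_bits`, `fragment_count`.
#' @export
fingerprint <- function(smiles, compound_id = NA_character_, n_bits = 1024L,
                        max_len = 7L) {
  mol <- parse_smiles(smiles)
  frags <- .path_fragments(mol, max_len = max_len)
  if (length(frags) == 0L && !any(mol$atoms$element != "H")) {
    warning(sprintf("compound %s has no heavy atoms; empty fingerprint",
                    compound_id), call. = FALSE)
  }
  bits <- sort(unique(vapply(frags, .hash_fragment, integer(1),
                             n_bits = n_bits, USE.NAMES = FALSE)))
  structure(list(compound_id = compound_id, bits = bits,
                 n_bits = as.integer(n_bits),
                 fragment_count = length(frags)),
            class = "path_fingerprint")
}

#' Tanimoto coefficient of two path fingerprints
#'
#' `TC = |A intersect B| / (|A| + |B| - |A intersect B|)` over the bit sets.
#' When both fingerprints are empty the ratio is 0/0; it is defined here as 0
#' (with a warning), so fragment-free species never appear spuriously
#' identical.
#'
#' @param a,b `path_fingerprint` objects with equal `n_bits`.
#' @return a number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "path_fingerprint"), inherits(b, "path_fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint configuration mismatch: n_bits ", a$n_bits, " vs ",
         b$n_bits)
  }
  na <- length(a$bits); nb <- length(b$bits)
  if (na == 0L && nb == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0", call. = FALSE)
    return(0)
  }
  ni <- length(intersect(a$bits, b$bits))
  ni / (na + nb - ni)
}

#' All-pairs Tanimoto similarity matrix
#'
#' Fingerprints every compound (rows and columns may be different libraries),
#' then computes the dense Tanimoto matrix via bit-matrix cross products.
#' Compounds whose SMILES fail to parse are excluded and reported in the
#' `excluded` attribute.
#'
#' @param rows,cols data.frames with columns `compound_id` and `smiles`.
#' @param n_bits fingerprint width.
#' @return a `similarity_matrix`: numeric matrix with compound ids as
#'   dimnames, attributes `excluded` (data.frame of failures) and `n_bits`.
#' @export
similarity_matrix <- function(rows, cols = rows, n_bits = 1024L) {
  fp_of <- function(df) {
    ok <- logical(nrow(df)); fps <- vector("list", nrow(df))
    err <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      fps[[i]] <- tryCatch({
        f <- suppressWarnings(fingerprint(df$smiles[i], df$compound_id[i],
                                          n_bits = n_bits))
        ok[i] <- TRUE
        f
      }, error = function(e) {
        err[i] <<- conditionMessage(e)
        NULL
      })
    }
    list(fps = fps[ok], ids = df$compound_id[ok],
         excluded = data.frame(compound_id = df$compound_id[!ok],
                               reason = err[!ok], stringsAsFactors = FALSE))
  }
  r <- fp_of(rows)
  same <- identical(rows, cols)
  c_ <- if (same) r else fp_of(cols)
  if (length(r$ids) == 0L || length(c_$ids) == 0L) {
    warning("empty row or column compound set; returning empty matrix",
            call. = FALSE)
    m <- matrix(numeric(0), nrow = length(r$ids), ncol = length(c_$ids),
                dimnames = list(r$ids, c_$ids))
    return(structure(m, excluded = rbind(r$excluded, c_$excluded),
                     n_bits = as.integer(n_bits), class = c("similarity_matrix", class(m))))
  }
  bitmat <- function(fps, ids) {
    m <- matrix(0L, nrow = length(fps), ncol = n_bits, dimnames = list(ids, NULL))
    for (i in seq_along(fps)) if (length(fps[[i]]$bits)) m[i, fps[[i]]$bits + 1L] <- 1L
    m
  }
  A <- bitmat(r$fps, r$ids)
  B <- if (same) A else bitmat(c_$fps, c_$ids)
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  denom <- outer(ra, rb, "+") - inter
  tc <- ifelse(denom == 0, 0, inter / denom)
  structure(tc, excluded = rbind(r$excluded, c_$excluded),
            n_bits = as.integer(n_bits),
            class = c("similarity_matrix", class(tc)))
}

#' Write a similarity matrix as TSV
#'
#' Row ids in the first column, column ids in the header.
#' @param sim a `similarity_matrix`.
#' @param path output file.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(compound_id = rownames(sim), as.data.frame(unclass(sim)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound library in .smi format
#'
#' One record per line: `<smiles>\t<id>\t<name>`.
#' @param path input file.
#' @return data.frame with columns `smiles`, `compound_id`, `name`.
#' @export
read_smi <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("smiles", "compound_id", "name"))
  df[, c("smiles", "compound_id", "name")]
}

#' Write a compound library in .smi format
#' @param df data.frame with columns `smiles`, `compound_id`, `name`.
#' @param path output file.
#' @export
write_smi <- function(df, path) {
  utils::write.table(df[, c("smiles", "compound_id", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
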