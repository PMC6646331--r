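# Multi-predictor target consensus: three heterogeneous prediction sources
# (BindingDB-style interaction scores, STITCH-style confidence scores,
# SwissTargetPrediction-style ranked lists) filtered at per-source thresholds
# and merged into vote-tiered compound-protein pairs.

.PRED_SOURCES <- c("bindingdb", "stitch", "swisstarget")

#' Default per-source prediction thresholds
#'
#' BindingDB interaction score >= 0.85, STITCH confidence >= 0.4 (both
#' inclusive), SwissTarget rank <= 15 ("top-15").
#' @return named list `bindingdb_min`, `stitch_min`, `swisstarget_rank_max`.
#' @export
default_prediction_thresholds <- function() {
  list(bindingdb_min = 0.85, stitch_min = 0.4, swisstarget_rank_max = 15L)
}

#' Normalize protein identifiers
#'
#' Upper-cases accessions and strips isoform suffixes (`"-1"`).  If a
#' symbol-to-accession `mapping` (data.frame with columns `symbol`,
#' `accession`) is supplied, symbols found in it are converted first.
#'
#' @param ids character vector of accessions or gene symbols.
#' @param mapping optional mapping table.
#' @return character vector of normalized accessions; unmappable symbols are
#'   returned upper-cased as-is.
#' @export
normalize_protein_ids <- function(ids, mapping = NULL) {
  ids <- toupper(trimws(ids))
  if (!is.null(mapping)) {
    m <- match(ids, toupper(mapping$symbol))
    hit <- !is.na(m)
    ids[hit] <- toupper(mapping$accession[m[hit]])
  }
  sub("-[0-9]+$", "", ids)
}

#' Filter raw target predictions at per-source thresholds
#'
#' Keeps `bindingdb` rows with `score >= bindingdb_min`, `stitch` rows with
#' `score >= stitch_min`, and `swisstarget` rows with `rank <=
#' swisstarget_rank_max`.  Rows with negative scores are rejected with a
#' message; an unknown `source` tag is an error.
#'
#' @param predictions data.frame with columns `compound_id`, `protein_id`,
#'   `source`, `score` (NA allowed for swisstarget), `rank` (NA allowed for
#'   score-based sources).
#' @param thresholds as [default_prediction_thresholds()].
#' @param mapping optional symbol-to-accession table passed to
#'   [normalize_protein_ids()].
#' @return the filtered data.frame (same columns, protein ids normalized).
#' @export
ingest_predictions <- function(predictions,
                               thresholds = default_prediction_thresholds(),
                               mapping = NULL) {
  thresholds <- utils::modifyList(default_prediction_thresholds(), thresholds)
  stopifnot(all(c("compound_id", "protein_id", "source") %in% names(predictions)))
  bad <- setdiff(unique(predictions$source), .PRED_SOURCES)
  if (length(bad) > 0L) {
    stop("unknown prediction source tag(s): ", paste(bad, collapse = ", "))
  }
  if (!"score" %in% names(predictions)) predictions$score <- NA_real_
  if (!"rank" %in% names(predictions)) predictions$rank <- NA_integer_
  neg <- !is.na(predictions$score) & predictions$score < 0
  if (any(neg)) {
    message(sum(neg), " prediction row(s) with negative score rejected")
    predictions <- predictions[!neg, , drop = FALSE]
  }
  predictions$protein_id <- normalize_protein_ids(predictions$protein_id, mapping)
  keep <- rep(FALSE, nrow(predictions))
  s <- predictions$source
  keep[s == "bindingdb"] <- !is.na(predictions$score[s == "bindingdb"]) &
    predictions$score[s == "bindingdb"] >= thresholds$bindingdb_min
  keep[s == "stitch"] <- !is.na(predictions$score[s == "stitch"]) &
    predictions$score[s == "stitch"] >= thresholds$stitch_min
  keep[s == "swisstarget"] <- !is.na(predictions$rank[s == "swisstarget"]) &
    predictions$rank[s == "swisstarget"] <= thresholds$swisstarget_rank_max
  predictions[keep, , drop = FALSE]
}

#' Merge filtered predictions into vote-tiered consensus pairs
#'
#' One row per distinct (compound, protein) pair; `votes` is the number of
#' distinct sources asserting the pair (1-3).  Sorted by votes descending,
#' then compound id, then protein id.
#'
#' @param filtered output of [ingest_predictions()].
#' @return data.frame `compound_id`, `protein_id`, `votes`, `sources`
#'   (comma-joined sorted source names).
#' @export
consensus_pairs <- function(filtered) {
  if (nrow(filtered) == 0L) {
    return(data.frame(compound_id = character(0), protein_id = character(0),
                      votes = integer(0), sources = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(filtered$compound_id, filtered$protein_id, sep = "\r")
  src <- split(filtered$source, key)
  srcs <- vapply(src, function(s) paste(sort(unique(s)), collapse = ","),
                 character(1))
  votes <- vapply(src, function(s) length(unique(s)), integer(1))
  parts <- strsplit(names(src), "\r", fixed = TRUE)
  out <- data.frame(compound_id = vapply(parts, `[`, character(1), 1L),
                    protein_id = vapply(parts, `[`, character(1), 2L),
                    votes = unname(votes), sources = unname(srcs),
                    stringsAsFactors = FALSE)
  out[order(-out$votes, out$compound_id, out$protein_id), , drop = FALSE]
}

#' Write consensus pairs as TSV
#' @param pairs output of [consensus_pairs()].
#' @param path output file.
#' @export
write_consensus_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
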