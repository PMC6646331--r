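# Drug-likeness screening: Lipinski's rule of five plus ADMET cutoffs
# (Caco-2 permeability, intestinal absorption, hepatotoxicity, Ames).  All
# inequalities are strict, exactly as the screening protocol words them
# ("less than 500 Dalton", "> 0.9", "> 30%"); the common "one Lipinski
# violation allowed" relaxation is deliberately not applied.

#' Default drug-likeness screening thresholds
#'
#' @return named list: `mw_max` (500 Da), `hbd_max` (5), `hba_max` (10),
#'   `logp_max` (5) -- all compared strictly `<`; `caco2_min` (0.9, log Papp,
#'   strict `>`), `absorption_min` (30 percent, strict `>`).
#' @export
default_screen_thresholds <- function() {
  list(mw_max = 500, hbd_max = 5, hba_max = 10, logp_max = 5,
       caco2_min = 0.9, absorption_min = 30)
}

.LIPINSKI_FIELDS <- c("mw", "hbd", "hba", "logp")
.ADMET_FIELDS <- c("caco2", "intestinal_absorption", "hepatotoxic", "ames_toxic")

#' Lipinski's rule-of-five verdicts
#'
#' A compound passes iff `hba < 10`, `hbd < 5`, `mw < 500` and `logp < 5`
#' (all strict).  Records with any missing descriptor are marked unevaluable
#' (`passed = NA`) rather than silently dropped.
#'
#' @param records data.frame with columns `compound_id`, `mw`, `hbd`, `hba`,
#'   `logp` (extra columns ignored).
#' @param thresholds as [default_screen_thresholds()].
#' @return data.frame with `compound_id`, `passed` (logical, `NA` if
#'   unevaluable) and `violated_rules` (semicolon-joined rule names, empty
#'   when passed).
#' @export
lipinski <- function(records, thresholds = default_screen_thresholds()) {
  thresholds <- utils::modifyList(default_screen_thresholds(), thresholds)
  stopifnot(all(c("compound_id", .LIPINSKI_FIELDS) %in% names(records)))
  out <- data.frame(compound_id = records$compound_id,
                    passed = NA, violated_rules = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    miss <- .LIPINSKI_FIELDS[vapply(.LIPINSKI_FIELDS,
                                    function(f) is.na(r[[f]]), logical(1))]
    if (length(miss) > 0L) {
      out$passed[i] <- NA
      out$violated_rules[i] <- paste0("unevaluable:", paste(miss, collapse = ","))
      next
    }
    v <- character(0)
    if (!(r$mw < thresholds$mw_max)) v <- c(v, "MW")
    if (!(r$hbd < thresholds$hbd_max)) v <- c(v, "HBD")
    if (!(r$hba < thresholds$hba_max)) v <- c(v, "HBA")
    if (!(r$logp < thresholds$logp_max)) v <- c(v, "LogP")
    out$passed[i] <- length(v) == 0L
    out$violated_rules[i] <- paste(v, collapse = ";")
  }
  out
}

#' Full drug-likeness + ADMET screen (the DPC screen)
#'
#' A compound passes iff it passes [lipinski()] AND `caco2 > 0.9` AND
#' `intestinal_absorption > 30` AND `hepatotoxic` is `FALSE` AND `ames_toxic`
#' is `FALSE`.  Input order is preserved.
#'
#' @param records data.frame with `compound_id`, the four Lipinski columns
#'   and `caco2`, `intestinal_absorption`, `hepatotoxic`, `ames_toxic`.
#' @param thresholds as [default_screen_thresholds()].
#' @return data.frame `compound_id`, `passed`, `violated_rules`; attribute
#'   `summary` holds pass/fail/unevaluable counts.
#' @export
screen_dpcs <- function(records, thresholds = default_screen_thresholds()) {
  thresholds <- utils::modifyList(default_screen_thresholds(), thresholds)
  stopifnot(all(c("compound_id", .LIPINSKI_FIELDS, .ADMET_FIELDS) %in%
                  names(records)))
  if (anyDuplicated(records$compound_id)) {
    stop("duplicate compound_id in ADMET table: ",
         paste(unique(records$compound_id[duplicated(records$compound_id)]),
               collapse = ", "))
  }
  out <- lipinski(records, thresholds)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    miss <- .ADMET_FIELDS[vapply(.ADMET_FIELDS,
                                 function(f) is.na(r[[f]]), logical(1))]
    if (length(miss) > 0L) {
      out$passed[i] <- NA
      out$violated_rules[i] <- paste(
        c(out$violated_rules[i][nzchar(out$violated_rules[i])],
          paste0("unevaluable:", paste(miss, collapse = ","))), collapse = ";")
      next
    }
    if (is.na(out$passed[i])) next  # already unevaluable from Lipinski
    v <- character(0)
    if (!(r$caco2 > thresholds$caco2_min)) v <- c(v, "Caco2")
    if (!(r$intestinal_absorption > thresholds$absorption_min)) v <- c(v, "Absorption")
    if (isTRUE(as.logical(r$hepatotoxic))) v <- c(v, "Hepatotoxicity")
    if (isTRUE(as.logical(r$ames_toxic))) v <- c(v, "Ames")
    if (length(v) > 0L) {
      out$passed[i] <- FALSE
      out$violated_rules[i] <- paste(
        c(out$violated_rules[i][nzchar(out$violated_rules[i])], v),
        collapse = ";")
    }
  }
  attr(out, "summary") <- c(passed = sum(out$passed %in% TRUE),
                            failed = sum(out$passed %in% FALSE),
                            unevaluable = sum(is.na(out$passed)))
  out
}

#' Read / write ADMET annotation tables (TSV)
#' @param path file path.
#' @return data.frame with the `AdmetRecord` columns.
#' @export
read_admet_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$hepatotoxic <- as.logical(df$hepatotoxic)
  df$ames_toxic <- as.logical(df$ames_toxic)
  df
}

#' @rdname read_admet_tsv
#' @param df ADMET data.frame.
#' @export
write_admet_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
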