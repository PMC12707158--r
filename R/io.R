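#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comment lines are skipped; surrounding whitespace is
#' trimmed.
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write rank-annotation scores as TSV
#'
#' Columns: `gene`, `omnibus_score`, then one column of per-source
#' percentiles per knowledge source.
#'
#' @param ra A `rank_annotation` from [omnibus_scores()].
#' @param path Output path.
#' @export
write_rank_annotation <- function(ra, path) {
  stopifnot(inherits(ra, "rank_annotation"))
  utils::write.table(as.data.frame(ra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read rank-annotation scores written by [write_rank_annotation()]
#'
#' @param path TSV path.
#' @return Named numeric vector of omnibus scores.
#' @export
read_rank_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$omnibus_score, df$gene)
}

#' Write leave-one-out validation results as JSON
#'
#' Serializes the ROC-style curves, the AUC above the diagonal and the
#' per-gene leave-one-out percentiles of a [loocv_roc()] result.
#'
#' @param roc A `roc_result`.
#' @param path Output JSON path.
#' @export
write_roc_json <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  jsonlite::write_json(
    list(per_source_curves = roc$per_source_curves,
         omnibus_curve = roc$omnibus_curve,
         auc_above_diagonal = roc$auc_above_diagonal,
         per_source_auc_above = as.list(roc$per_source_auc_above),
         loo_percentiles = as.list(roc$loo_percentiles)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
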