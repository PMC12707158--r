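#' Summarize rank-annotation scores for a gene subset
#'
#' Computes the median, quartiles and interquartile range (IQR) of the
#' scores of a gene subset, and flags low outliers by the boxplot rule: a
#' gene is a low outlier when its score falls below `Q1 - 1.5 * IQR`.
#' Quartiles use linear interpolation between order statistics (positions
#' `(n - 1) * p`; `stats::quantile` type 7). Only low outliers are
#' reported: the rule is one-sided because the question is which members
#' of a high-scoring set score unexpectedly poorly.
#'
#' @param scores Named numeric vector of scores (percent).
#' @param subset Character vector of genes to summarize; must be non-empty
#'   and present in `scores`. Defaults to all genes.
#' @param label Label for the gene set.
#' @return An object of class `score_summary`: list with `gene_set_label`,
#'   `n`, `median`, `q1`, `q3`, `iqr` and `low_outliers` (data.frame of
#'   gene and score).
#' @examples
#' summarize_scores(c(DVL3 = 96.8, MED13L = 85.1, PUF60 = 79.9,
#'                    MEIS2 = 61.9))$median  # 82.5
#' @export
summarize_scores <- function(scores, subset = names(scores),
                             label = "gene set") {
  if (is.null(names(scores))) stop_("`scores` must be a named vector")
  subset <- unique(as.character(subset))
  if (!length(subset)) stop_("`subset` must be non-empty")
  missing <- setdiff(subset, names(scores))
  if (length(missing)) {
    stop_("subset gene(s) absent from scores: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  vals <- scores[subset]
  q <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  iqr <- q[3L] - q[1L]
  cutoff <- q[1L] - 1.5 * iqr
  low <- vals < cutoff
  ord <- order(vals[low])
  structure(list(
    gene_set_label = label,
    n = length(vals),
    median = q[2L],
    q1 = q[1L],
    q3 = q[3L],
    iqr = iqr,
    low_outliers = data.frame(gene = names(vals[low])[ord],
                              score = unname(vals[low])[ord],
                              stringsAsFactors = FALSE)
  ), class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat("<score_summary> '", x$gene_set_label, "' (n = ", x$n, ")\n", sep = "")
  cat("  median ", round_half_up(x$median), "%  [Q1 ", round_half_up(x$q1),
      "%, Q3 ", round_half_up(x$q3), "%; IQR ", round_half_up(x$iqr),
      "%]\n", sep = "")
  if (nrow(x$low_outliers)) {
    cat("  low outliers (score < Q1 - 1.5 IQR):\n")
    for (i in seq_len(nrow(x$low_outliers))) {
      cat("    ", x$low_outliers$gene[i], " (",
          round_half_up(x$low_outliers$score[i]), "%)\n", sep = "")
    }
  } else {
    cat("  no low outliers\n")
  }
  invisible(x)
}
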