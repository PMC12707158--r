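#' Cohort diagnostic-efficacy summary
#'
#' Diagnostic efficacy of clinical exome sequencing is the fraction of
#' cohort individuals with a definitive or probable diagnosis, using each
#' individual's diagnosis of highest certainty. The diagnosis-level count
#' (`n_dx_diagnoses`) counts definitive/probable diagnosis records, so an
#' individual with several diagnoses contributes each of them once; an
#' autosomal-recessive diagnosis backed by two variants in one gene is a
#' single (gene-level) diagnosis.
#'
#' Percentages are carried at full precision (`*_exact` fields) and
#' additionally rounded half-up to one decimal for presentation (`*_pct`
#' fields); comparisons should use the exact fractions.
#'
#' @param best Named character vector, individual -> best certainty (from
#'   [best_per_individual()]). Individuals absent from it count as
#'   undiagnosed.
#' @param diagnoses Optional diagnoses data.frame ([classify_cohort()])
#'   used for the diagnosis-level count; when omitted, the count equals the
#'   number of diagnosed individuals.
#' @param n_individuals Total cohort size (denominator); must be at least
#'   the number of individuals in `best`.
#' @return An object of class `cohort_summary`.
#' @examples
#' best <- c(rep("definitive", 24), rep("probable", 7), rep("provisional", 40))
#' names(best) <- sprintf("I%03d", seq_along(best))
#' summarize_cohort(best, n_individuals = 131)
#' @export
summarize_cohort <- function(best, diagnoses = NULL, n_individuals) {
  check_certainty_value(best, "`best`")
  if (n_individuals < length(best)) {
    stop_("n_individuals (", n_individuals,
          ") is smaller than the number of individuals with classified ",
          "findings (", length(best), ")")
  }
  n_def <- sum(best == "definitive")
  n_prob <- sum(best == "probable")
  n_prov <- sum(best == "provisional")
  n_dx_ind <- n_def + n_prob
  n_dx_dx <- if (is.null(diagnoses)) {
    n_dx_ind
  } else {
    check_certainty_value(diagnoses$certainty, "`diagnoses`")
    sum(diagnoses$certainty %in% c("definitive", "probable"))
  }
  if (n_dx_dx < n_dx_ind) {
    stop_("fewer definitive/probable diagnosis records (", n_dx_dx,
          ") than diagnosed individuals (", n_dx_ind, ")")
  }
  pct <- function(k) 100 * k / n_individuals
  structure(list(
    n_individuals = n_individuals,
    n_definitive = n_def,
    n_probable = n_prob,
    n_provisional = n_prov,
    n_dx_individuals = n_dx_ind,
    n_dx_diagnoses = n_dx_dx,
    efficacy_exact = pct(n_dx_ind),
    definitive_exact = pct(n_def),
    probable_exact = pct(n_prob),
    provisional_exact = pct(n_prov),
    efficacy_pct = round_half_up(pct(n_dx_ind)),
    definitive_pct = round_half_up(pct(n_def)),
    probable_pct = round_half_up(pct(n_prob)),
    provisional_pct = round_half_up(pct(n_prov))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_individuals, " individuals\n", sep = "")
  cat("  definitive  ", x$n_definitive, " (", x$definitive_pct, "%)\n",
      sep = "")
  cat("  probable    ", x$n_probable, " (", x$probable_pct, "%)\n", sep = "")
  cat("  provisional ", x$n_provisional, " (", x$provisional_pct, "%)\n",
      sep = "")
  cat("  diagnostic efficacy ", x$efficacy_pct, "% (", x$n_dx_individuals,
      "/", x$n_individuals, "; exact ",
      format(x$efficacy_exact, digits = 5), "%)\n", sep = "")
  cat("  definitive/probable diagnoses: ", x$n_dx_diagnoses, " across ",
      x$n_dx_individuals, " individuals\n", sep = "")
  invisible(x)
}

#' Gene-panel coverage of cohort diagnoses
#'
#' For each panel (a named gene set), counts how many definitive/probable
#' diagnoses involve a panel gene (diagnosis-level coverage) and how many
#' of the distinct diagnosed genes the panel contains (unique-gene-level
#' coverage). Rows of `diagnoses` with other certainties are ignored. The
#' cross-panel minimum/maximum coverage range is attached as attributes
#' `dx_range` and `gene_range` (exact percentages).
#'
#' @param diagnoses Diagnoses data.frame with `gene` and `certainty`
#'   columns; only definitive/probable rows are counted.
#' @param panels Named list of character vectors (panel gene sets), or a
#'   path to a JSON file of the form `{"panel name": ["GENE1", ...]}`.
#' @return A data.frame of class `panel_coverage`: one row per panel with
#'   `panel`, `dx_covered`, `dx_total`, `dx_pct_exact`, `genes_covered`,
#'   `genes_total`, `gene_pct_exact`.
#' @export
panel_coverage <- function(diagnoses, panels) {
  if (is.character(panels) && length(panels) == 1L) {
    panels <- lapply(jsonlite::read_json(panels), unlist)
  }
  if (!length(panels)) stop_("at least one panel is required")
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    stop_("panels must be named")
  }
  dx <- diagnoses[diagnoses$certainty %in% c("definitive", "probable"), ,
                  drop = FALSE]
  if (!nrow(dx)) stop_("no definitive or probable diagnoses to cover")
  dx_total <- nrow(dx)
  genes <- unique(dx$gene)
  out <- do.call(rbind, lapply(names(panels), function(p) {
    set <- unique(as.character(panels[[p]]))
    data.frame(panel = p,
               dx_covered = sum(dx$gene %in% set),
               dx_total = dx_total,
               dx_pct_exact = 100 * sum(dx$gene %in% set) / dx_total,
               genes_covered = sum(genes %in% set),
               genes_total = length(genes),
               gene_pct_exact = 100 * sum(genes %in% set) / length(genes),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "dx_range") <- range(out$dx_pct_exact)
  attr(out, "gene_range") <- range(out$gene_pct_exact)
  class(out) <- c("panel_coverage", "data.frame")
  out
}

#' @export
print.panel_coverage <- function(x, ...) {
  df <- as.data.frame(x)
  df$dx_pct_exact <- round_half_up(df$dx_pct_exact)
  df$gene_pct_exact <- round_half_up(df$gene_pct_exact)
  names(df)[names(df) == "dx_pct_exact"] <- "dx_pct"
  names(df)[names(df) == "gene_pct_exact"] <- "gene_pct"
  print(df)
  dr <- round_half_up(attr(x, "dx_range"))
  gr <- round_half_up(attr(x, "gene_range"))
  cat("diagnosis-level coverage range: ", dr[1L], "%-", dr[2L], "%\n",
      sep = "")
  cat("unique-gene coverage range:     ", gr[1L], "%-", gr[2L], "%\n",
      sep = "")
  invisible(x)
}

#' Write a cohort summary (plus optional panel coverage) as JSON
#'
#' @param summary A `cohort_summary`.
#' @param path Output path.
#' @param coverage Optional `panel_coverage` table to embed.
#' @export
write_cohort_summary <- function(summary, path, coverage = NULL) {
  payload <- unclass(summary)
  payload$note <- paste("percentages *_pct are rounded half-up to 1 decimal;",
                        "*_exact fields carry the exact fractions")
  if (!is.null(coverage)) {
    payload$panel_coverage <- as.data.frame(coverage)
    payload$panel_dx_range <- attr(coverage, "dx_range")
    payload$panel_gene_range <- attr(coverage, "gene_range")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
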