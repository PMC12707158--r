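#' Registry of genes already known to cause the phenotype
#'
#' Phenotypic-expansion candidates must be novel: genes already established
#' as causes of the phenotype are screened out before evidence evaluation.
#' The default registry is the union of the 53-gene TOF training set and
#' the additional established TOF genes observed in the cohort
#' ([tof_training_genes], [tof_established_genes]).
#'
#' @param extra Additional known gene symbols to include.
#' @param include_default Include the default TOF gene lists?
#' @return Sorted character vector of gene symbols.
#' @export
known_gene_registry <- function(extra = character(), include_default = TRUE) {
  base <- if (include_default) {
    union(tof_training_genes, tof_established_genes)
  } else {
    character()
  }
  sort(union(base, as.character(extra)))
}

#' Identify phenotypic-expansion candidate genes
#'
#' Candidate genes are those harboring variants associated with at least
#' one definitive or probable diagnosis and not already known to cause the
#' phenotype (i.e. absent from the registry). Provisional-only genes do not
#' qualify.
#'
#' @param diagnoses Diagnoses data.frame ([classify_cohort()]).
#' @param registry Character vector of known phenotype genes
#'   ([known_gene_registry()]).
#' @return Sorted character vector of candidate gene symbols.
#' @export
identify_candidates <- function(diagnoses, registry = known_gene_registry()) {
  check_certainty_value(diagnoses$certainty, "`diagnoses`")
  dx <- diagnoses[diagnoses$certainty %in% c("definitive", "probable"), ,
                  drop = FALSE]
  sort(setdiff(unique(dx$gene), registry))
}

#' Evaluate phenotypic-expansion evidence for candidate genes
#'
#' Applies the three-line evidence review to each candidate gene: (1) is
#' the gene's rank-annotation score positive (> 50%) or high (>= 85%)?
#' (2) have cases linking the gene, or its syndrome, to the phenotype been
#' published? (3) has CHD been observed in mouse models of the homolog?
#' The decision rule declares an expansion `supported` when the score is
#' positive (above `score_threshold`) **and** literature cases exist; mouse
#' evidence is recorded as supportive annotation but is not required (two
#' of the four published supported genes lack it).
#'
#' All arguments are vectorized over genes.
#'
#' @param gene Candidate gene symbols.
#' @param rank_score Rank-annotation scores in `[0, 100]` (percent).
#' @param literature_cases Logical: published cases of the phenotype for
#'   the gene or its associated syndrome.
#' @param mouse_chd Logical: CHD observed in mouse models of the homolog.
#' @param diagnosis_certainty Optional certainty bin(s) of the underlying
#'   diagnoses (`"definitive"`/`"probable"`), carried through to output.
#' @param score_threshold Score required by the decision rule (default 50,
#'   i.e. "positive"); the `high` band boundary stays at 85.
#' @param require_literature Must literature cases exist for support?
#' @return Data.frame of class `expansion_evidence`: `gene`, `rank_score`,
#'   `score_band` (`high`/`positive`/`non-positive`), `literature_cases`,
#'   `mouse_chd`, `diagnosis_certainty`, `verdict`
#'   (`supported`/`not_supported`).
#' @examples
#' ev <- tof_candidate_evidence()
#' evaluate_expansion(ev$gene, ev$rank_score, ev$literature_cases,
#'                    ev$mouse_chd, ev$diagnosis_certainty)
#' @export
evaluate_expansion <- function(gene, rank_score, literature_cases,
                               mouse_chd = FALSE,
                               diagnosis_certainty = NA_character_,
                               score_threshold = 50,
                               require_literature = TRUE) {
  n <- length(gene)
  rank_score <- rep_len(as.numeric(rank_score), n)
  literature_cases <- rep_len(as.logical(literature_cases), n)
  mouse_chd <- rep_len(as.logical(mouse_chd), n)
  diagnosis_certainty <- rep_len(as.character(diagnosis_certainty), n)
  bad <- !is.finite(rank_score) | rank_score < 0 | rank_score > 100
  if (any(bad)) {
    stop_("rank_score outside [0, 100] for gene(s): ",
          paste(gene[bad], collapse = ", "))
  }
  band <- ifelse(rank_score >= 85, "high",
                 ifelse(rank_score > 50, "positive", "non-positive"))
  supported <- rank_score > score_threshold &
    (!require_literature | literature_cases)
  out <- data.frame(
    gene = gene,
    rank_score = rank_score,
    score_band = band,
    literature_cases = literature_cases,
    mouse_chd = mouse_chd,
    diagnosis_certainty = diagnosis_certainty,
    verdict = ifelse(supported, "supported", "not_supported"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("expansion_evidence", "data.frame")
  out
}

#' Evaluate expansion evidence from tables
#'
#' Convenience wrapper joining an evidence table (gene, literature_cases,
#' mouse_chd) to a score vector and optional diagnoses, then calling
#' [evaluate_expansion()].
#'
#' @param evidence Data.frame with columns `gene`, `literature_cases`,
#'   `mouse_chd` (or a path to such a TSV).
#' @param scores Named numeric vector of rank-annotation scores covering
#'   every evidence gene.
#' @param diagnoses Optional diagnoses data.frame; each gene's highest
#'   definitive/probable certainty is attached.
#' @inheritParams evaluate_expansion
#' @return See [evaluate_expansion()].
#' @export
evaluate_expansion_table <- function(evidence, scores, diagnoses = NULL,
                                     score_threshold = 50,
                                     require_literature = TRUE) {
  if (is.character(evidence) && length(evidence) == 1L) {
    evidence <- utils::read.delim(evidence, stringsAsFactors = FALSE)
    evidence$literature_cases <- as.logical(evidence$literature_cases)
    evidence$mouse_chd <- as.logical(evidence$mouse_chd)
  }
  missing <- setdiff(evidence$gene, names(scores))
  if (length(missing)) {
    stop_("no rank score for evidence gene(s): ",
          paste(missing, collapse = ", "))
  }
  certainty <- rep(NA_character_, nrow(evidence))
  if (!is.null(diagnoses)) {
    dx <- diagnoses[diagnoses$certainty %in% c("definitive", "probable"), ,
                    drop = FALSE]
    if (nrow(dx)) {
      byg <- tapply(certainty_rank(dx$certainty), dx$gene, min)
      hit <- match(evidence$gene, names(byg))
      certainty[!is.na(hit)] <- certainty_levels[byg[hit[!is.na(hit)]]]
    }
  }
  evaluate_expansion(evidence$gene, scores[evidence$gene],
                     evidence$literature_cases, evidence$mouse_chd,
                     certainty, score_threshold, require_literature)
}
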