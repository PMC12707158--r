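#' @name certainty_rules
#' @title Diagnostic-certainty rule table
#'
#' @description
#' Reported variant findings are binned into `definitive`, `probable` or
#' `provisional` diagnoses (or `none`) per individual-gene pair. Likely
#' benign and benign findings are ignored throughout, and every rule
#' requires phenotypic data suggestive of the gene's associated disorder.
#'
#' For genes with autosomal dominant (AD) or X-linked (XL) conditions the
#' strongest single finding decides: pathogenic (P) gives a definitive
#' diagnosis, likely pathogenic (LP) probable, and a variant of uncertain
#' significance (VUS) provisional.
#'
#' For autosomal recessive (AR) conditions a compound-heterozygous pair in
#' trans decides: P+P, P+LP or LP+LP give a definitive diagnosis, P+VUS a
#' probable diagnosis and LP+VUS a provisional diagnosis. A qualifying pair
#' whose phase is unknown is demoted one bin (definitive to probable,
#' probable to provisional; provisional stays provisional). Pairs in cis
#' are not compound heterozygotes and yield no diagnosis, as do single
#' heterozygous findings in AR genes and VUS+VUS pairs.
#'
#' The base table is configurable, except the P+VUS-in-trans (probable) and
#' LP+VUS-in-trans (provisional) AR rules, which are fixed: attempts to
#' override them are ignored with a warning.
#'
#' @param ad Named character vector mapping single-finding ACMG class to
#'   certainty for AD/XL conditions.
#' @param ar_pairs Named character vector mapping unordered AR class pairs
#'   (keys like `"P+LP"`, stronger class first) to the certainty of an
#'   in-trans pair.
#' @param demote_unknown_phase Demote phase-unknown AR pairs one bin?
#' @return An object of class `certainty_rules`.
#' @examples
#' rules <- certainty_rules()
#' classify_findings(data.frame(
#'   individual_id = "I1", gene = "CFC1",
#'   acmg_class = c("P", "VUS"), inheritance_mode = "AR",
#'   phase = "in_trans", phenotype_suggestive = TRUE))
NULL

certainty_levels <- c("definitive", "probable", "provisional", "none")

acmg_classes <- c("P", "LP", "VUS", "LB", "B")
inheritance_modes <- c("AD", "AR", "XL")
phase_values <- c("in_trans", "in_cis", "unknown", "n/a")

# fixed, non-overridable AR additions
ar_fixed_pairs <- c("P+VUS" = "probable", "LP+VUS" = "provisional")

certainty_rank <- function(x) match(x, certainty_levels)

# one bin lower, floored at provisional; none stays none
demote_certainty <- function(x) {
  ifelse(x == "none", "none",
         certainty_levels[pmin(certainty_rank(x) + 1L, 3L)])
}

check_certainty_value <- function(x, where) {
  bad <- setdiff(x, certainty_levels)
  if (length(bad)) {
    stop_("invalid certainty value(s) in ", where, ": ",
          paste(bad, collapse = ", "))
  }
}

#' @rdname certainty_rules
#' @export
certainty_rules <- function(ad = c(P = "definitive", LP = "probable",
                                   VUS = "provisional"),
                            ar_pairs = c("P+P" = "definitive",
                                         "P+LP" = "definitive",
                                         "LP+LP" = "definitive",
                                         "VUS+VUS" = "none"),
                            demote_unknown_phase = TRUE) {
  ad <- unlist(ad)
  ar_pairs <- unlist(ar_pairs)
  check_certainty_value(ad, "`ad`")
  check_certainty_value(ar_pairs, "`ar_pairs`")
  clash <- intersect(names(ar_pairs), names(ar_fixed_pairs))
  overridden <- clash[ar_pairs[clash] != ar_fixed_pairs[clash]]
  if (length(overridden)) {
    warning("the AR rules ", paste(overridden, collapse = ", "),
            " are fixed and cannot be overridden; ignoring supplied values",
            call. = FALSE)
  }
  ar_pairs <- ar_pairs[setdiff(names(ar_pairs), names(ar_fixed_pairs))]
  full_ar <- c(ar_pairs, ar_fixed_pairs)
  structure(list(ad = ad, ar_pairs = full_ar,
                 demote_unknown_phase = isTRUE(demote_unknown_phase)),
            class = "certainty_rules")
}

#' @rdname certainty_rules
#' @param path Path to a YAML rule file with optional top-level keys `ad`,
#'   `ar_pairs` and `demote_unknown_phase` mirroring the arguments.
#' @export
read_certainty_rules <- function(path) {
  y <- yaml::read_yaml(path)
  default <- formals(certainty_rules)
  certainty_rules(
    ad = y$ad %||% eval(default$ad),
    ar_pairs = y$ar_pairs %||% eval(default$ar_pairs),
    demote_unknown_phase = y$demote_unknown_phase %||% TRUE
  )
}

#' @export
print.certainty_rules <- function(x, ...) {
  cat("<certainty_rules>\n  AD/XL single finding: ",
      paste(names(x$ad), x$ad, sep = " -> ", collapse = ", "), "\n", sep = "")
  cat("  AR in-trans pair:     ",
      paste(names(x$ar_pairs), x$ar_pairs, sep = " -> ", collapse = ", "),
      "\n", sep = "")
  cat("  phase-unknown AR pairs demoted one bin: ",
      x$demote_unknown_phase, "\n", sep = "")
  invisible(x)
}

validate_findings <- function(findings, where = "findings") {
  req <- c("individual_id", "gene", "acmg_class", "inheritance_mode",
           "phase", "phenotype_suggestive")
  missing <- setdiff(req, names(findings))
  if (length(missing)) {
    stop_(where, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!findings$acmg_class %in% acmg_classes)
  if (length(bad)) {
    stop_("unknown acmg_class '", findings$acmg_class[bad[1L]],
          "' in ", where, " row ", bad[1L])
  }
  bad <- which(!findings$inheritance_mode %in% inheritance_modes)
  if (length(bad)) {
    stop_("unknown inheritance_mode '", findings$inheritance_mode[bad[1L]],
          "' in ", where, " row ", bad[1L])
  }
  bad <- which(!findings$phase %in% phase_values)
  if (length(bad)) {
    stop_("unknown phase '", findings$phase[bad[1L]], "' in ", where,
          " row ", bad[1L])
  }
  invisible(findings)
}

ar_pair_key <- function(c1, c2) {
  ord <- match(c(c1, c2), acmg_classes)
  paste(acmg_classes[sort(ord)], collapse = "+")
}

# classify the findings of a single (individual, gene) pair
classify_pair_findings <- function(fnd, rules) {
  kept <- fnd[!fnd$acmg_class %in% c("LB", "B"), , drop = FALSE]
  if (!nrow(kept)) {
    return(list(certainty = "none", rule = "no_reportable_finding"))
  }
  mode <- unique(kept$inheritance_mode)
  if (length(mode) > 1L) {
    stop_("conflicting inheritance_mode for individual '",
          kept$individual_id[1L], "', gene '", kept$gene[1L], "'")
  }
  suggestive <- any(kept$phenotype_suggestive)
  if (!suggestive) {
    return(list(certainty = "none", rule = "not_phenotype_suggestive"))
  }
  if (mode %in% c("AD", "XL")) {
    best <- acmg_classes[min(match(kept$acmg_class, acmg_classes))]
    certainty <- unname(rules$ad[best]) %||% "none"
    if (is.na(certainty)) certainty <- "none"
    return(list(certainty = certainty, rule = paste0(mode, ":", best)))
  }
  # AR: evaluate every pair of findings, keep the best outcome
  n <- nrow(kept)
  if (n < 2L) {
    return(list(certainty = "none", rule = "AR:single_heterozygote"))
  }
  best <- list(certainty = "none", rule = "AR:no_qualifying_pair")
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ph <- c(kept$phase[i], kept$phase[j])
      pair_phase <- if (any(ph == "in_cis")) "in_cis"
                    else if (all(ph == "in_trans")) "in_trans"
                    else "unknown"
      if (pair_phase == "in_cis") next
      key <- ar_pair_key(kept$acmg_class[i], kept$acmg_class[j])
      certainty <- unname(rules$ar_pairs[key])
      if (is.null(certainty) || is.na(certainty)) certainty <- "none"
      rule <- paste0("AR:", key, ":", pair_phase)
      if (pair_phase == "unknown" && rules$demote_unknown_phase) {
        certainty <- demote_certainty(certainty)
        rule <- paste0(rule, ":demoted")
      }
      if (certainty_rank(certainty) < certainty_rank(best$certainty)) {
        best <- list(certainty = certainty, rule = rule)
      }
    }
  }
  best
}

#' Classify the findings of one individual-gene pair
#'
#' @param findings Data.frame of findings sharing one `individual_id` and
#'   one `gene`, with columns `individual_id`, `gene`, `acmg_class`
#'   (P/LP/VUS/LB/B), `inheritance_mode` (AD/AR/XL), `phase`
#'   (in_trans/in_cis/unknown/n/a) and `phenotype_suggestive` (logical).
#' @param rules A [certainty_rules()] table.
#' @return One-row data.frame: `individual_id`, `gene`, `certainty`,
#'   `triggering_rule`.
#' @seealso [classify_cohort()] for whole-cohort tables.
#' @export
classify_findings <- function(findings, rules = certainty_rules()) {
  validate_findings(findings)
  if (length(unique(findings$individual_id)) != 1L ||
      length(unique(findings$gene)) != 1L) {
    stop_("`findings` must share a single individual and gene; ",
          "use classify_cohort() for full tables")
  }
  res <- classify_pair_findings(findings, rules)
  data.frame(individual_id = findings$individual_id[1L],
             gene = findings$gene[1L],
             certainty = res$certainty,
             triggering_rule = res$rule,
             stringsAsFactors = FALSE)
}

#' Classify every individual-gene pair of a cohort table
#'
#' Applies the certainty rule table to each (individual, gene) group of a
#' cohort findings table. Classification is deterministic and independent
#' of row order.
#'
#' @param cohort Cohort findings data.frame (schema as in
#'   [classify_findings()]).
#' @param rules A [certainty_rules()] table.
#' @return Data.frame of diagnoses, one row per individual-gene pair:
#'   `individual_id`, `gene`, `certainty`, `triggering_rule`, sorted by
#'   individual then gene.
#' @export
classify_cohort <- function(cohort, rules = certainty_rules()) {
  validate_findings(cohort, "cohort")
  if (!nrow(cohort)) {
    return(data.frame(individual_id = character(), gene = character(),
                      certainty = character(), triggering_rule = character(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(cohort$individual_id, cohort$gene, drop = TRUE)
  parts <- split(cohort, key)
  out <- do.call(rbind, lapply(parts, classify_findings, rules = rules))
  out <- out[order(out$individual_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Highest diagnostic certainty per individual
#'
#' Individuals can hold several diagnoses; diagnostic-efficacy accounting
#' uses each individual's diagnosis of highest certainty (ordering
#' definitive > probable > provisional > none).
#'
#' @param diagnoses Data.frame with `individual_id` and `certainty` columns
#'   (as produced by [classify_cohort()]).
#' @param individuals Optional character vector of individual IDs to report
#'   on; IDs with no diagnosis map to `"none"`. Defaults to the individuals
#'   present in `diagnoses`.
#' @return Named character vector: individual ID -> best certainty.
#' @export
best_per_individual <- function(diagnoses, individuals = NULL) {
  check_certainty_value(diagnoses$certainty, "`diagnoses`")
  ids <- individuals %||% unique(diagnoses$individual_id)
  if (!length(ids)) return(stats::setNames(character(), character()))
  best <- stats::setNames(rep("none", length(ids)), ids)
  if (nrow(diagnoses)) {
    agg <- tapply(certainty_rank(diagnoses$certainty),
                  diagnoses$individual_id, min)
    agg <- agg[names(agg) %in% ids]
    best[names(agg)] <- certainty_levels[agg]
  }
  best
}

#' Read / write cohort findings and diagnoses tables
#'
#' Tab-separated with a header row; columns as in [classify_findings()]
#' (cohort) and [classify_cohort()] (diagnoses).
#'
#' @param path File path.
#' @param cohort,diagnoses Data.frames to write.
#' @return `read_cohort` returns the validated findings data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$phenotype_suggestive <- as.logical(x$phenotype_suggestive)
  validate_findings(x, path)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_diagnoses <- function(diagnoses, path) {
  utils::write.table(diagnoses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
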