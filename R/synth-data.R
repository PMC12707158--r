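#' Configuration for synthetic knowledge-source simulation
#'
#' Describes a synthetic genome of `n_genes` genes annotated by `n_sources`
#' independent knowledge sources of `n_features` quantitative features
#' each. Features are independent Gaussian noise with standard deviation
#' `noise_sd`; in each source a fixed fraction (`enriched_frac`, default
#' 20%) of the features carries planted disease-gene signal: the mean of
#' those features is shifted upward by `enrichment` for every training
#' gene. `enrichment = 0` makes training genes exchangeable with the rest
#' of the genome (a null simulation).
#'
#' By default the genome consists of the training genes followed by filler
#' symbols `G000001, G000002, ...`; a full custom genome (e.g. real RefSeq
#' symbols) can be supplied via `genes`, in which case every training gene
#' must be present in it.
#'
#' @param n_genes Genome size (positive integer).
#' @param training_genes Character vector of training gene symbols.
#' @param n_sources Number of knowledge sources K.
#' @param n_features Features per source.
#' @param enrichment Additive mean shift (in noise SD units when
#'   `noise_sd = 1`) planted on enriched features of training genes;
#'   must be >= 0.
#' @param noise_sd Standard deviation of the Gaussian feature noise (> 0).
#' @param seed Integer seed; identical configurations reproduce identical
#'   simulations bit for bit.
#' @param genes Optional full genome symbol vector (length `n_genes`).
#' @param enriched_frac Fraction of features per source carrying signal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes, training_genes, n_sources = 3L,
                       n_features = 50L, enrichment = 3, noise_sd = 1,
                       seed = 1L, genes = NULL, enriched_frac = 0.2) {
  stopifnot(n_genes >= 2, n_sources >= 1, n_features >= 2,
            enrichment >= 0, noise_sd > 0,
            enriched_frac > 0, enriched_frac <= 1)
  training_genes <- unique(as.character(training_genes))
  if (!length(training_genes)) stop_("training_genes must be non-empty")
  if (is.null(genes)) {
    if (length(training_genes) > n_genes) {
      stop_("more training genes than genes in the genome")
    }
    filler <- sprintf("G%06d", seq_len(n_genes))
    genes <- c(training_genes,
               utils::head(setdiff(filler, training_genes),
                           n_genes - length(training_genes)))
  } else {
    genes <- as.character(genes)
    if (length(genes) != n_genes) {
      stop_("`genes` must have length n_genes (", n_genes, ")")
    }
    if (anyDuplicated(genes)) stop_("`genes` contains duplicates")
    missing <- setdiff(training_genes, genes)
    if (length(missing)) {
      stop_("training gene(s) not in genome: ",
            paste(missing, collapse = ", "))
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_sources = as.integer(n_sources),
                 n_features = as.integer(n_features),
                 training_genes = training_genes,
                 enrichment = enrichment,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 genes = genes,
                 enriched_frac = enriched_frac),
            class = "sim_config")
}

#' Simulate knowledge sources with planted disease-gene signal
#'
#' Generates `config$n_sources` gene-by-feature matrices according to the
#' model described in [sim_config()]. Each source draws from its own seed
#' substream derived from `config$seed`, so sources are independent yet the
#' whole ensemble is reproducible. Gene order is identical across sources.
#'
#' @param config A [sim_config()].
#' @return List of [feature_source()] objects named `source_1`,
#'   `source_2`, ...
#' @examples
#' cfg <- sim_config(n_genes = 200, training_genes = sprintf("T%02d", 1:10),
#'                   seed = 42)
#' srcs <- simulate_sources(cfg)
#' ra <- omnibus_scores(srcs, training_set(cfg$training_genes, "sim"))
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  p <- config$n_features
  train_rows <- match(config$training_genes, config$genes)
  n_signal <- max(1L, floor(p * config$enriched_frac))
  lapply(seq_len(config$n_sources), function(k) {
    with_seed(seed_stream(config$seed, k), {
      m <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
      # planted signal: additive mean shift on a fixed block of features
      m[train_rows, seq_len(n_signal)] <-
        m[train_rows, seq_len(n_signal)] + config$enrichment
      colnames(m) <- sprintf("f%03d", seq_len(p))
      rownames(m) <- config$genes
      feature_source(m, name = sprintf("source_%d", k))
    })
  })
}

#' Write / read knowledge sources as TSV
#'
#' One TSV per source (`<name>.tsv` in `dir`): header row, gene symbol in
#' the first column (`gene`), one column per feature. `write_sim_manifest`
#' records the generating configuration as JSON next to the sources.
#'
#' @param sources List of [feature_source()] objects.
#' @param dir Directory (created if needed).
#' @return `read_feature_sources` returns a list of `feature_source`
#'   objects, ordered by file name.
#' @export
write_feature_sources <- function(sources, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in sources) {
    df <- data.frame(gene = s$genes, s$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(s$name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_feature_sources
#' @export
read_feature_sources <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop_("no .tsv source files in ", dir)
  lapply(files, function(f) {
    df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    feature_source(as.matrix(df[, -1L, drop = FALSE]),
                   name = sub("\\.tsv$", "", basename(f)),
                   genes = df[[1L]])
  })
}

#' @rdname write_feature_sources
#' @param config A [sim_config()] or [cohort_spec()].
#' @param path Output JSON path.
#' @export
write_sim_manifest <- function(config, path) {
  payload <- unclass(config)
  payload$class <- class(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Specification of a synthetic cohort's diagnostic composition
#'
#' Describes a cohort of `n_individuals` in which exactly `n_definitive`,
#' `n_probable` and `n_provisional` individuals reach each certainty bin
#' (by their highest-certainty diagnosis) once the generated findings are
#' classified with the default [certainty_rules()]. Generation is
#' constructive — findings are built backwards from the rule table — so
#' the requested composition is met exactly, not approximately.
#'
#' `multi_diagnosis` grants extra diagnoses to selected individuals: a list
#' of `c(index, n_extra)` pairs, where `index` (1-based) must refer to a
#' definitive or probable individual (indices `1..n_definitive` are the
#' definitive individuals, the next `n_probable` the probable ones). Each
#' extra diagnosis lands in a distinct gene at the same certainty as the
#' individual's primary diagnosis, so bin composition is unchanged while
#' the number of definitive/probable diagnosis *records* grows.
#'
#' `gene_overlap` controls gene sharing across definitive/probable
#' diagnoses of distinct individuals: multiplicities `c(3, 2)` (the
#' default) make one gene carry 3 diagnoses and another 2, so 33 diagnoses
#' involve 30 unique genes — the kind of composition real TOF+ cohorts
#' show. Overlap is skipped when there are too few diagnoses to honor it.
#'
#' @param n_individuals Cohort size.
#' @param n_definitive,n_probable,n_provisional Individuals per bin; their
#'   sum must not exceed `n_individuals`.
#' @param multi_diagnosis List of `c(index, n_extra)` integer pairs
#'   (`n_extra >= 1`).
#' @param seed Integer seed.
#' @param gene_overlap Integer multiplicities of shared genes among
#'   definitive/probable diagnoses (use `integer(0)` for all-distinct
#'   genes).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, n_definitive = 0L, n_probable = 0L,
                        n_provisional = 0L, multi_diagnosis = list(),
                        seed = 1L, gene_overlap = c(3L, 2L)) {
  stopifnot(n_individuals >= 1, n_definitive >= 0, n_probable >= 0,
            n_provisional >= 0)
  if (n_definitive + n_probable + n_provisional > n_individuals) {
    stop_("requested bin counts exceed the number of individuals")
  }
  if (!is.list(multi_diagnosis)) stop_("multi_diagnosis must be a list")
  n_dx <- n_definitive + n_probable
  for (md in multi_diagnosis) {
    if (length(md) != 2L || any(md < 1) || md[1L] != round(md[1L])) {
      stop_("multi_diagnosis entries must be c(index, n_extra) with both >= 1")
    }
    if (md[1L] > n_dx) {
      stop_("multi_diagnosis index ", md[1L], " does not refer to a ",
            "definitive or probable individual (only ", n_dx, " exist); ",
            "extra diagnoses for lower-certainty individuals would change ",
            "the requested composition")
    }
  }
  idx <- vapply(multi_diagnosis, `[`, numeric(1), 1L)
  if (anyDuplicated(idx)) stop_("duplicate individual index in multi_diagnosis")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_definitive = as.integer(n_definitive),
                 n_probable = as.integer(n_probable),
                 n_provisional = as.integer(n_provisional),
                 multi_diagnosis = multi_diagnosis,
                 seed = as.integer(seed),
                 gene_overlap = as.integer(gene_overlap)),
            class = "cohort_spec")
}

# finding-row templates per certainty bin; each classifies to its bin
# under the default rule table
cohort_mechanisms <- list(
  definitive = list(
    list(classes = "P", mode = "AD", phase = "n/a"),
    list(classes = c("P", "P"), mode = "AR", phase = "in_trans"),
    list(classes = c("P", "LP"), mode = "AR", phase = "in_trans"),
    list(classes = c("LP", "LP"), mode = "AR", phase = "in_trans"),
    list(classes = "P", mode = "XL", phase = "n/a")
  ),
  probable = list(
    list(classes = "LP", mode = "AD", phase = "n/a"),
    list(classes = c("P", "VUS"), mode = "AR", phase = "in_trans"),
    list(classes = c("P", "P"), mode = "AR", phase = "unknown")
  ),
  provisional = list(
    list(classes = "VUS", mode = "AD", phase = "n/a"),
    list(classes = c("LP", "VUS"), mode = "AR", phase = "in_trans"),
    list(classes = c("P", "VUS"), mode = "AR", phase = "unknown")
  )
)

finding_rows <- function(id, gene, mech, suggestive = TRUE) {
  data.frame(individual_id = id, gene = gene,
             acmg_class = mech$classes,
             inheritance_mode = mech$mode,
             phase = mech$phase,
             phenotype_suggestive = suggestive,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort findings table with exact certainty composition
#'
#' Builds one finding row per reported variant (two for compound
#' heterozygotes) such that classifying the table with the default
#' [certainty_rules()] reproduces the composition requested in the
#' [cohort_spec()] exactly. Diagnostic mechanisms (e.g. a single de facto
#' dominant pathogenic variant versus an autosomal-recessive in-trans pair)
#' are drawn at random per diagnosis from the templates compatible with the
#' requested bin. A seeded subset of undiagnosed individuals receives
#' non-qualifying findings (a non-suggestive VUS, or a likely benign
#' variant) so the `none` path is exercised; the rest contribute no rows.
#'
#' @param spec A [cohort_spec()].
#' @return Data.frame of findings with columns `individual_id`, `gene`,
#'   `acmg_class`, `inheritance_mode`, `phase`, `phenotype_suggestive`;
#'   the generating spec is attached as attribute `"spec"`.
#' @examples
#' spec <- cohort_spec(131, 24, 7, 40, multi_diagnosis = list(c(1, 2)),
#'                     seed = 7)
#' cohort <- simulate_cohort(spec)
#' dx <- classify_cohort(cohort)
#' table(best_per_individual(dx, unique(cohort$individual_id)))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed_stream(spec$seed, 101L), {
    n <- spec$n_individuals
    ids <- sprintf("I%04d", seq_len(n))
    bins <- rep(c("definitive", "probable", "provisional", "none"),
                c(spec$n_definitive, spec$n_probable, spec$n_provisional,
                  n - spec$n_definitive - spec$n_probable -
                    spec$n_provisional))

    # enumerate definitive/probable diagnoses: primaries first, then extras
    dx_bins <- character()
    dx_owner <- integer()
    for (i in which(bins %in% c("definitive", "probable"))) {
      dx_bins <- c(dx_bins, bins[i])
      dx_owner <- c(dx_owner, i)
    }
    for (md in spec$multi_diagnosis) {
      i <- as.integer(md[1L])
      dx_bins <- c(dx_bins, rep(bins[i], as.integer(md[2L])))
      dx_owner <- c(dx_owner, rep(i, as.integer(md[2L])))
    }

    # gene assignment: shared genes go to primaries of distinct
    # individuals; everything else gets a fresh symbol
    n_dx <- length(dx_bins)
    gene_pool <- sprintf("GENE%04d", seq_len(n_dx + n))
    next_gene <- 0L
    take_gene <- function() {
      next_gene <<- next_gene + 1L
      gene_pool[next_gene]
    }
    dx_gene <- character(n_dx)
    n_primary <- sum(bins %in% c("definitive", "probable"))
    overlap <- spec$gene_overlap
    if (length(overlap) && sum(overlap) <= n_primary && all(overlap >= 2L)) {
      pos <- 1L
      for (m in overlap) {
        g <- take_gene()
        dx_gene[pos:(pos + m - 1L)] <- g
        pos <- pos + m
      }
    }
    for (j in seq_len(n_dx)) {
      if (dx_gene[j] == "") dx_gene[j] <- take_gene()
    }

    rows <- vector("list", 0L)
    for (j in seq_len(n_dx)) {
      mechs <- cohort_mechanisms[[dx_bins[j]]]
      mech <- mechs[[sample.int(length(mechs), 1L)]]
      rows[[length(rows) + 1L]] <-
        finding_rows(ids[dx_owner[j]], dx_gene[j], mech)
    }
    for (i in which(bins == "provisional")) {
      mechs <- cohort_mechanisms$provisional
      mech <- mechs[[sample.int(length(mechs), 1L)]]
      rows[[length(rows) + 1L]] <- finding_rows(ids[i], take_gene(), mech)
    }
    for (i in which(bins == "none")) {
      u <- stats::runif(1)
      if (u < 0.25) {        # non-suggestive VUS: reportable but no overlap
        rows[[length(rows) + 1L]] <- finding_rows(
          ids[i], take_gene(),
          list(classes = "VUS", mode = "AD", phase = "n/a"),
          suggestive = FALSE)
      } else if (u < 0.4) {  # likely benign finding: ignored by the rules
        rows[[length(rows) + 1L]] <- finding_rows(
          ids[i], take_gene(),
          list(classes = "LB", mode = "AD", phase = "n/a"),
          suggestive = TRUE)
      }                      # else: nothing reported
    }
    out <- if (length(rows)) {
      do.call(rbind, rows)
    } else {
      finding_rows("x", "x", list(classes = "P", mode = "AD",
                                  phase = "n/a"))[0L, ]
    }
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    attr(out, "individuals") <- ids
    out
  })
}
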