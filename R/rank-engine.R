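#' Construct a knowledge-source feature matrix
#'
#' A feature source is one genome-scale annotation resource expressed as a
#' numeric gene-by-feature matrix: one row per gene, one column per
#' quantitative annotation feature. Gene prioritization scores each gene's
#' feature vector against the centroid of a training gene set within each
#' source (see [score_source()]).
#'
#' @param matrix Numeric matrix, one row per gene, at least 2 feature
#'   columns.
#' @param name Label for the source.
#' @param genes Character vector of unique gene symbols, one per row;
#'   defaults to `rownames(matrix)`.
#' @return An object of class `feature_source`.
#' @export
feature_source <- function(matrix, name = "source", genes = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop_("feature matrix must be numeric")
  if (ncol(matrix) < 2L) stop_("a feature source needs at least 2 features")
  if (is.null(genes)) stop_("gene symbols are required (rownames or `genes`)")
  genes <- as.character(genes)
  if (length(genes) != nrow(matrix)) {
    stop_("length of `genes` (", length(genes), ") != rows of matrix (",
          nrow(matrix), ")")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop_("duplicate gene symbols in source '", name, "': ",
          paste(utils::head(dup, 5L), collapse = ", "))
  }
  rownames(matrix) <- genes
  structure(list(name = name, genes = genes, matrix = matrix),
            class = "feature_source")
}

#' @export
print.feature_source <- function(x, ...) {
  cat("<feature_source> '", x$name, "': ", length(x$genes), " genes x ",
      ncol(x$matrix), " features\n", sep = "")
  invisible(x)
}

#' Define a phenotype-specific training gene set
#'
#' @param genes Character vector of gene symbols with an established causal
#'   relationship to the phenotype.
#' @param phenotype_label Name of the phenotype (e.g. `"TOF"`).
#' @return An object of class `training_set`.
#' @export
training_set <- function(genes, phenotype_label = "phenotype") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop_("training set must be non-empty")
  structure(list(phenotype_label = phenotype_label, genes = genes),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> '", x$phenotype_label, "': ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

as_training_set <- function(x) {
  if (inherits(x, "training_set")) x else training_set(x)
}

# Per-feature z-scoring within a source; zero-variance features carry no
# similarity information and are dropped (with a warning naming the source).
standardize_features <- function(mat, source_name = "source") {
  mu <- colMeans(mat)
  sdev <- apply(mat, 2L, stats::sd)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s) in source '",
            source_name, "'", call. = FALSE)
    mat <- mat[, !zero, drop = FALSE]
    mu <- mu[!zero]
    sdev <- sdev[!zero]
  }
  if (ncol(mat) < 2L) {
    stop_("source '", source_name,
          "' has fewer than 2 informative features after dropping ",
          "zero-variance columns")
  }
  sweep(sweep(mat, 2L, mu, "-"), 2L, sdev, "/")
}

# Cosine similarity of every row of Z to the centroid of rows `idx`.
# Rows (or a centroid) with zero norm have undefined direction; their
# similarity is 0 (orthogonal-by-convention).
cosine_to_centroid <- function(Z, idx, row_norms = sqrt(rowSums(Z^2))) {
  centroid <- colMeans(Z[idx, , drop = FALSE])
  cnorm <- sqrt(sum(centroid^2))
  if (cnorm == 0) return(stats::setNames(rep(0, nrow(Z)), rownames(Z)))
  sims <- as.vector(Z %*% centroid) / (row_norms * cnorm)
  sims[row_norms == 0] <- 0
  stats::setNames(sims, rownames(Z))
}

#' Score all genes of one knowledge source against a training set
#'
#' Each gene's feature vector is standardized per feature (z-score within
#' the source) and its similarity to the centroid of the standardized
#' training-gene vectors is measured as the cosine of the angle between
#' them. Scores are raw similarities in `[-1, 1]`, later converted to
#' percentile ranks by [percentile_ranks()].
#'
#' @param source A [feature_source()].
#' @param training A [training_set()] (or character vector of symbols); all
#'   members must be present in the source.
#' @param exclude Optional single training gene to hold out of the centroid
#'   (used by leave-one-out validation).
#' @return Named numeric vector of similarities, one per gene.
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(sprintf("G%02d", 1:10), NULL))
#' src <- feature_source(m, "toy")
#' head(score_source(src, c("G01", "G02", "G03")))
#' @export
score_source <- function(source, training, exclude = NULL) {
  stopifnot(inherits(source, "feature_source"))
  training <- as_training_set(training)
  missing <- setdiff(training$genes, source$genes)
  if (length(missing)) {
    stop_("training gene(s) absent from source '", source$name, "': ",
          paste(missing, collapse = ", "))
  }
  train <- training$genes
  if (!is.null(exclude)) {
    if (!exclude %in% train) {
      stop_("`exclude` ('", exclude, "') is not a training gene")
    }
    train <- setdiff(train, exclude)
    if (!length(train)) stop_("training set empty after exclusion")
  }
  Z <- standardize_features(source$matrix, source$name)
  cosine_to_centroid(Z, match(train, source$genes))
}

#' Midrank percentile scores
#'
#' Converts raw similarity values into percentile ranks on a 0-100 percent
#' scale using midranks: `score(g) = 100 * (midrank(g) - 0.5) / N`, where
#' tied values share their average rank. By construction the genome-wide
#' median is 50 (exactly, when `N` is even or all values are distinct) and
#' scores are symmetric about it.
#'
#' @param raw Named numeric vector of raw scores (at least 2 genes).
#' @return Named numeric vector of percentiles in `[0, 100]`.
#' @examples
#' percentile_ranks(c(a = 1, b = 2, c = 3, d = 4, e = 5)) # 10 30 50 70 90
#' @export
percentile_ranks <- function(raw) {
  if (length(raw) < 2L) stop_("percentile ranks need at least 2 genes")
  if (anyNA(raw)) stop_("raw scores contain NA")
  100 * (rank(raw, ties.method = "average") - 0.5) / length(raw)
}

check_same_universe <- function(sources) {
  ref <- sources[[1L]]$genes
  for (s in sources[-1L]) {
    if (!setequal(s$genes, ref)) {
      only_ref <- setdiff(ref, s$genes)
      only_s <- setdiff(s$genes, ref)
      stop_("gene universes differ between sources '", sources[[1L]]$name,
            "' and '", s$name, "'; only in first: {",
            paste(utils::head(only_ref, 5L), collapse = ", "),
            "}, only in second: {",
            paste(utils::head(only_s, 5L), collapse = ", "), "}")
    }
  }
  ref
}

#' Omnibus rank-annotation scores across knowledge sources
#'
#' Computes per-source similarities ([score_source()]), converts each
#' source's similarities to percentile ranks, averages the percentiles
#' gene-wise across sources, and re-percentiles the average so the final
#' omnibus score is again a 0-100 percent rank with genome-wide median 50.
#' Rank aggregation makes sources with incommensurate raw scales
#' comparable; re-percentiling restores the median-50-by-definition
#' property of a single source.
#'
#' Training genes are scored like every other gene (they are only excluded
#' from the centroid during leave-one-out validation, see [loocv_roc()]).
#'
#' @param sources List of [feature_source()] objects over an identical gene
#'   universe.
#' @param training A [training_set()] or character vector.
#' @return An object of class `rank_annotation` with elements `scores`
#'   (named omnibus percentiles), `per_source_scores` (gene x source matrix
#'   of per-source percentiles) and `training_set`.
#' @export
omnibus_scores <- function(sources, training) {
  if (inherits(sources, "feature_source")) sources <- list(sources)
  if (!length(sources)) stop_("at least one feature source is required")
  training <- as_training_set(training)
  genes <- check_same_universe(sources)
  per_source <- vapply(sources, function(s) {
    percentile_ranks(score_source(s, training))[genes]
  }, numeric(length(genes)))
  colnames(per_source) <- vapply(sources, `[[`, "", "name")
  rownames(per_source) <- genes
  omnibus <- percentile_ranks(rowMeans(per_source))
  structure(list(scores = omnibus, per_source_scores = per_source,
                 training_set = training),
            class = "rank_annotation")
}

#' @export
print.rank_annotation <- function(x, ...) {
  cat("<rank_annotation> '", x$training_set$phenotype_label, "': ",
      length(x$scores), " genes, ", ncol(x$per_source_scores),
      " source(s)\n", sep = "")
  cat("  genome median ", format(stats::median(x$scores), digits = 4),
      "%; training-gene median ",
      format(stats::median(x$scores[intersect(x$training_set$genes,
                                              names(x$scores))]),
             digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rank_annotation <- function(x, ...) {
  data.frame(gene = names(x$scores), omnibus_score = unname(x$scores),
             x$per_source_scores, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# ROC-style curve from a threshold sweep over percentile scores.
# x = fraction of all genes called positive at the threshold,
# y = fraction of positive (held-out training) genes recovered.
# Thresholds are the distinct positive scores plus {0, 100}, swept from
# high to low; the curve starts at (0, 0) and ends at (1, 1).
roc_curve <- function(scores_all, scores_pos) {
  thr <- sort(unique(c(0, 100, scores_pos)), decreasing = TRUE)
  x <- vapply(thr, function(t) mean(scores_all >= t), numeric(1))
  y <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  if (x[1L] != 0 || y[1L] != 0) {
    x <- c(0, x)
    y <- c(0, y)
  }
  data.frame(x = x, y = y)
}

trapezoid_auc <- function(curve) {
  sum(diff(curve$x) * (utils::head(curve$y, -1L) + utils::tail(curve$y, -1L)) / 2)
}

#' Leave-one-out cross-validation with ROC-style curves
#'
#' Validates a rank-annotation scoring run: each training gene in turn is
#' held out of every source's centroid, the omnibus score is recomputed,
#' and the held-out gene's recovered percentile is recorded. ROC-style
#' curves then sweep a percentile threshold from 100 down to 0; at each
#' threshold `x` is the fraction of all genes called positive (training
#' genes enter at their held-out percentile, all other genes at their
#' full-model percentile) and `y` is the fraction of training genes
#' recovered. The area under the curve minus the chance-level area
#' (`auc_above_diagonal`, in `[-0.5, 0.5]`) summarizes how much better
#' than random the ranking recovers the training genes; per-source curves
#' are reported alongside the omnibus curve.
#'
#' @param sources List of [feature_source()] objects (identical gene
#'   universe).
#' @param training A [training_set()] of at least 3 genes.
#' @return An object of class `roc_result` with elements
#'   `per_source_curves`, `omnibus_curve`, `auc_above_diagonal`,
#'   `per_source_auc_above`, and `loo_percentiles` (named vector, one per
#'   training gene).
#' @export
loocv_roc <- function(sources, training) {
  if (inherits(sources, "feature_source")) sources <- list(sources)
  training <- as_training_set(training)
  if (length(training$genes) < 3L) {
    stop_("leave-one-out validation needs a training set of at least 3 genes")
  }
  genes <- check_same_universe(sources)
  missing <- setdiff(training$genes, genes)
  if (length(missing)) {
    stop_("training gene(s) absent from sources: ",
          paste(missing, collapse = ", "))
  }
  train <- training$genes
  src_names <- vapply(sources, `[[`, "", "name")

  # standardize once per source; LOO runs reuse the matrices
  prepped <- lapply(sources, function(s) {
    Z <- standardize_features(s$matrix[genes, , drop = FALSE], s$name)
    list(Z = Z, norms = sqrt(rowSums(Z^2)))
  })
  train_idx <- match(train, genes)

  per_source_pct <- function(excl_i) {
    idx <- if (is.null(excl_i)) train_idx else setdiff(train_idx, excl_i)
    vapply(prepped, function(p) {
      percentile_ranks(cosine_to_centroid(p$Z, idx, p$norms))
    }, numeric(length(genes)))
  }

  full_pct <- per_source_pct(NULL)           # genes x sources
  full_omnibus <- percentile_ranks(rowMeans(full_pct))

  loo_omni <- stats::setNames(numeric(length(train)), train)
  loo_src <- matrix(NA_real_, length(train), length(sources),
                    dimnames = list(train, src_names))
  for (t in train) {
    ti <- match(t, genes)
    pct <- per_source_pct(ti)
    loo_src[t, ] <- pct[ti, ]
    loo_omni[t] <- percentile_ranks(rowMeans(pct))[ti]
  }

  combined <- full_omnibus
  combined[train] <- loo_omni
  omnibus_curve <- roc_curve(combined, loo_omni)

  per_source_curves <- stats::setNames(vector("list", length(sources)),
                                       src_names)
  per_source_auc <- stats::setNames(numeric(length(sources)), src_names)
  for (k in seq_along(sources)) {
    comb_k <- full_pct[, k]
    comb_k[train] <- loo_src[, k]
    per_source_curves[[k]] <- roc_curve(comb_k, loo_src[, k])
    per_source_auc[k] <- trapezoid_auc(per_source_curves[[k]]) - 0.5
  }

  structure(list(per_source_curves = per_source_curves,
                 omnibus_curve = omnibus_curve,
                 auc_above_diagonal = trapezoid_auc(omnibus_curve) - 0.5,
                 per_source_auc_above = per_source_auc,
                 loo_percentiles = loo_omni),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", length(x$loo_percentiles), " held-out genes, ",
      length(x$per_source_curves), " source(s)\n", sep = "")
  cat("  omnibus AUC above diagonal: ",
      format(x$auc_above_diagonal, digits = 4), "\n", sep = "")
  cat("  median leave-one-out percentile: ",
      format(stats::median(x$loo_percentiles), digits = 4), "%\n", sep = "")
  invisible(x)
}

#' Plot leave-one-out ROC-style curves
#'
#' @param x A `roc_result` from [loocv_roc()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$omnibus_curve$x, x$omnibus_curve$y, type = "l", lwd = 2,
                 xlab = "fraction of genome called positive",
                 ylab = "fraction of training genes recovered",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  for (k in seq_along(x$per_source_curves)) {
    graphics::lines(x$per_source_curves[[k]]$x, x$per_source_curves[[k]]$y,
                    col = k + 1L)
  }
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
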