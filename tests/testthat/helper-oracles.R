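# Independent brute-force oracles, deliberately written with plain loops
# and sorting so they share no code path with the package implementation.

# cosine of each gene's standardized vector to the training centroid
brute_cosine_scores <- function(mat, train, exclude = NULL) {
  Z <- mat
  for (j in seq_len(ncol(mat))) {
    Z[, j] <- (mat[, j] - mean(mat[, j])) / sd(mat[, j])
  }
  use <- setdiff(train, exclude)
  centroid <- rep(0, ncol(Z))
  for (g in use) centroid <- centroid + Z[g, ] / length(use)
  out <- numeric(nrow(Z))
  names(out) <- rownames(Z)
  for (i in seq_len(nrow(Z))) {
    num <- sum(Z[i, ] * centroid)
    den <- sqrt(sum(Z[i, ]^2)) * sqrt(sum(centroid^2))
    out[i] <- if (den == 0) 0 else num / den
  }
  out
}

# midrank percentile via sorted positions
brute_percentiles <- function(x) {
  s <- sort(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    pos <- which(s == x[i])
    out[i] <- 100 * (mean(pos) - 0.5) / length(x)
  }
  names(out) <- names(x)
  out
}

# quantile by linear interpolation at position (n - 1) * p
brute_quantile <- function(x, p) {
  s <- unname(sort(x))
  n <- length(s)
  sapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo + 1 >= n) return(s[n])
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  })
}

brute_trapezoid <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1)) {
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  a
}

# small deterministic feature matrix with named genes
toy_matrix <- function(n_genes = 8, n_feat = 4, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_feat), n_genes, n_feat)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  m
}

# one-row finding constructor for rule tests
finding <- function(acmg, mode = "AD", phase = "n/a", suggestive = TRUE,
                    id = "I1", gene = "GENE1") {
  data.frame(individual_id = id, gene = gene, acmg_class = acmg,
             inheritance_mode = mode, phase = phase,
             phenotype_suggestive = suggestive, stringsAsFactors = FALSE)
}

ar_pair <- function(c1, c2, phase = "in_trans", suggestive = TRUE,
                    id = "I1", gene = "GENE1") {
  rbind(finding(c1, "AR", phase, suggestive, id, gene),
        finding(c2, "AR", phase, suggestive, id, gene))
}
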