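make_best <- function(n_def, n_prob, n_prov) {
  setNames(rep(c("definitive", "probable", "provisional"),
               c(n_def, n_prob, n_prov)),
           sprintf("I%03d", seq_len(n_def + n_prob + n_prov)))
}

test_that("diagnostic efficacy arithmetic matches the printed cohort figures", {
  best <- make_best(24, 7, 40)
  s <- summarize_cohort(best, n_individuals = 131)
  expect_equal(s$n_dx_individuals, 31)
  expect_equal(s$efficacy_exact, 100 * 31 / 131)
  expect_equal(s$efficacy_pct, 23.7)
  expect_equal(s$definitive_pct, 18.3)
  expect_equal(s$probable_pct, 5.3)
  expect_equal(s$provisional_pct, 30.5)
  # definitive + probable reproduce the efficacy within rounding slack
  expect_lt(abs(s$definitive_pct + s$probable_pct - s$efficacy_pct), 0.1 + 1e-9)
})

test_that("diagnosis-level counts include multiple diagnoses per individual", {
  best <- make_best(24, 7, 40)
  dx <- data.frame(
    individual_id = c(names(best)[best != "provisional"],
                      rep("I001", 2)),            # I001 holds 3 diagnoses
    gene = paste0("G", 1:33),
    certainty = c(best[best != "provisional"], "definitive", "definitive"),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(best, dx, 131)
  expect_equal(s$n_dx_diagnoses, 33)
  expect_equal(s$n_dx_individuals, 31)
})

test_that("degenerate cohorts summarize cleanly", {
  s0 <- summarize_cohort(setNames(character(), character()),
                         n_individuals = 10)
  expect_equal(s0$efficacy_pct, 0)
  s5 <- summarize_cohort(make_best(5, 0, 0), n_individuals = 5)
  expect_equal(s5$efficacy_pct, 100)
  expect_error(summarize_cohort(make_best(3, 0, 0), n_individuals = 2),
               "smaller")
})

test_that("panel coverage reproduces the printed coverage ranges", {
  # 33 definitive/probable diagnoses over 30 unique genes (one gene thrice,
  # one twice)
  genes <- c(rep("SHARED3", 3), rep("SHARED2", 2), paste0("G", 1:28))
  dx <- data.frame(individual_id = paste0("I", seq_along(genes)),
                   gene = genes,
                   certainty = rep(c("definitive", "probable"), c(24, 9)),
                   stringsAsFactors = FALSE)
  panels <- list(
    narrow = c("SHARED3", "SHARED2", paste0("G", 1:4)),   # 9 dx, 6 genes
    broad = c("SHARED3", "SHARED2", paste0("G", 1:16))    # 21 dx, 18 genes
  )
  pc <- panel_coverage(dx, panels)
  expect_equal(pc$dx_covered, c(9, 21))
  expect_equal(pc$genes_covered, c(6, 18))
  expect_equal(attr(pc, "dx_range"), 100 * c(9, 21) / 33)
  expect_equal(attr(pc, "gene_range"), 100 * c(6, 18) / 30)
  # brute-force membership count
  for (p in names(panels)) {
    expect_equal(pc$dx_covered[pc$panel == p],
                 sum(dx$gene %in% panels[[p]]))
  }
  # an all-genome panel covers everything
  full <- panel_coverage(dx, list(all = unique(dx$gene)))
  expect_equal(full$dx_pct_exact, 100)
  expect_equal(full$gene_pct_exact, 100)
})

test_that("adding a gene to a panel never decreases coverage", {
  set.seed(71)
  dx <- data.frame(individual_id = paste0("I", 1:20),
                   gene = sample(paste0("G", 1:12), 20, replace = TRUE),
                   certainty = "definitive", stringsAsFactors = FALSE)
  panel <- paste0("G", 1:3)
  prev <- panel_coverage(dx, list(p = panel))
  for (g in paste0("G", 4:12)) {
    panel <- c(panel, g)
    cur <- panel_coverage(dx, list(p = panel))
    expect_gte(cur$dx_pct_exact, prev$dx_pct_exact)
    expect_gte(cur$gene_pct_exact, prev$gene_pct_exact)
    prev <- cur
  }
})

test_that("provisional diagnoses and empty panel sets are handled", {
  dx <- data.frame(individual_id = "I1", gene = "G1",
                   certainty = "provisional", stringsAsFactors = FALSE)
  expect_error(panel_coverage(dx, list(p = "G1")), "no definitive")
  dx$certainty <- "definitive"
  expect_error(panel_coverage(dx, list()), "at least one panel")
  expect_error(panel_coverage(dx, list("G1")), "named")
})

test_that("panel definitions load from JSON", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(list(p1 = c("G1", "G2"), p2 = "G3"), path)
  dx <- data.frame(individual_id = c("I1", "I2"), gene = c("G1", "G3"),
                   certainty = "definitive", stringsAsFactors = FALSE)
  pc <- panel_coverage(dx, path)
  expect_equal(pc$dx_covered, c(1, 1))
})
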