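test_that("zero enrichment makes training genes exchangeable", {
  cfg <- sim_config(n_genes = 800, training_genes = sprintf("T%02d", 1:20),
                    n_sources = 2, enrichment = 0, seed = 19)
  for (src in simulate_sources(cfg)) {
    tr <- src$genes %in% cfg$training_genes
    m_tr <- mean(src$matrix[tr, ])
    m_bg <- mean(src$matrix[!tr, ])
    se <- sqrt(sd(src$matrix[tr, ])^2 / sum(tr) /
                 ncol(src$matrix) +
               sd(src$matrix[!tr, ])^2 / sum(!tr) / ncol(src$matrix))
    expect_lt(abs(m_tr - m_bg), 3 * se)
  }
})

test_that("planted enrichment separates training genes in every source", {
  cfg <- sim_config(n_genes = 1000, training_genes = sprintf("T%02d", 1:20),
                    n_sources = 3, enrichment = 3, noise_sd = 1, seed = 13)
  for (src in simulate_sources(cfg)) {
    sims <- score_source(src, cfg$training_genes)
    tr <- names(sims) %in% cfg$training_genes
    expect_gt(min(sims[tr]), quantile(sims[!tr], 0.95))
  }
})

test_that("identical configurations reproduce byte-identical TSV output", {
  cfg <- sim_config(n_genes = 60, training_genes = c("TBX1", "JAG1"),
                    n_sources = 2, n_features = 8, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_feature_sources(simulate_sources(cfg), d1)
  write_feature_sources(simulate_sources(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # and the round trip through TSV preserves the matrices
  back <- read_feature_sources(d1)
  orig <- simulate_sources(cfg)
  expect_equal(back[[1]]$matrix, orig[[1]]$matrix, tolerance = 1e-9)
  expect_equal(back[[1]]$genes, orig[[1]]$genes)
})

test_that("custom genomes must contain every training gene", {
  expect_error(
    sim_config(n_genes = 5, training_genes = c("TBX1", "NOPE"),
               genes = c("TBX1", "A", "B", "C", "D")),
    "NOPE")
  expect_error(sim_config(n_genes = 3, training_genes = paste0("T", 1:5)),
               "more training genes")
})

test_that("classifying a simulated cohort returns the requested composition exactly", {
  set.seed(73)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    nd <- sample(0:3, 1)
    np <- sample(0:3, 1)
    npr <- sample(0:3, 1)
    if (nd + np + npr > n) next
    spec <- cohort_spec(n, nd, np, npr, seed = i)
    cohort <- simulate_cohort(spec)
    best <- best_per_individual(classify_cohort(cohort),
                                attr(cohort, "individuals"))
    expect_equal(unname(c(sum(best == "definitive"), sum(best == "probable"),
                          sum(best == "provisional"))),
                 c(nd, np, npr),
                 label = sprintf("spec(%d,%d,%d,%d) seed %d", n, nd, np, npr, i))
  }
})

test_that("multi-diagnosis individuals gain extra diagnoses without changing bins", {
  spec <- cohort_spec(131, 24, 7, 40, multi_diagnosis = list(c(1, 2)),
                      seed = 7)
  cohort <- simulate_cohort(spec)
  dx <- classify_cohort(cohort)
  best <- best_per_individual(dx, attr(cohort, "individuals"))
  expect_equal(sum(best == "definitive"), 24)
  expect_equal(sum(best == "probable"), 7)
  expect_equal(sum(best == "provisional"), 40)
  dp <- dx[dx$certainty %in% c("definitive", "probable"), ]
  expect_equal(nrow(dp), 33)
  expect_equal(length(unique(dp$individual_id)), 31)
  expect_equal(sum(dp$individual_id == "I0001"), 3)
  # default gene overlap emulates 33 diagnoses across 30 unique genes
  expect_equal(length(unique(dp$gene)), 30)
})

test_that("degenerate and infeasible cohort specs behave", {
  empty <- simulate_cohort(cohort_spec(10, seed = 2))
  if (nrow(empty)) {
    best <- best_per_individual(classify_cohort(empty))
    expect_true(all(best == "none"))
  }
  all_def <- simulate_cohort(cohort_spec(5, 5, gene_overlap = integer()))
  best <- best_per_individual(classify_cohort(all_def),
                              attr(all_def, "individuals"))
  expect_true(all(best == "definitive"))
  s <- summarize_cohort(best, n_individuals = 5)
  expect_equal(s$efficacy_pct, 100)

  expect_error(cohort_spec(10, 6, 5, 0), "exceed")
  expect_error(cohort_spec(10, 2, 0, 3, multi_diagnosis = list(c(5, 1))),
               "definitive or probable")
  expect_error(cohort_spec(10, 2, 0, 0, multi_diagnosis = list(c(1, 0))),
               ">= 1")
})

test_that("manifests record the generating configuration", {
  cfg <- sim_config(n_genes = 10, training_genes = "TBX1", seed = 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_sim_manifest(cfg, path)
  m <- jsonlite::read_json(path)
  expect_equal(m$n_genes, 10)
  expect_equal(m$seed, 4)
  expect_equal(m$class, "sim_config")
})
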