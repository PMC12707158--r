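test_that("the compound-heterozygous P+VUS in trans rule gives a probable diagnosis", {
  dx <- classify_findings(ar_pair("P", "VUS"))
  expect_equal(dx$certainty, "probable")
  expect_match(dx$triggering_rule, "AR:P\\+VUS:in_trans")
})

test_that("the compound-heterozygous LP+VUS in trans rule gives a provisional diagnosis", {
  dx <- classify_findings(ar_pair("LP", "VUS"))
  expect_equal(dx$certainty, "provisional")
  expect_match(dx$triggering_rule, "AR:LP\\+VUS:in_trans")
})

test_that("the two fixed AR rules survive attempted overrides", {
  expect_warning(
    rules <- certainty_rules(ar_pairs = c("P+VUS" = "definitive",
                                          "P+P" = "definitive")),
    "fixed")
  expect_equal(classify_findings(ar_pair("P", "VUS"), rules)$certainty,
               "probable")
  expect_equal(classify_findings(ar_pair("LP", "VUS"), rules)$certainty,
               "provisional")
})

test_that("single-finding rules for dominant and X-linked conditions", {
  expect_equal(classify_findings(finding("P", "AD"))$certainty, "definitive")
  expect_equal(classify_findings(finding("LP", "AD"))$certainty, "probable")
  expect_equal(classify_findings(finding("VUS", "AD"))$certainty,
               "provisional")
  expect_equal(classify_findings(finding("P", "XL"))$certainty, "definitive")
  # without phenotype overlap nothing qualifies
  expect_equal(classify_findings(finding("P", "AD",
                                         suggestive = FALSE))$certainty,
               "none")
  # benign-tier findings are ignored entirely
  expect_equal(classify_findings(finding("LB", "AD"))$certainty, "none")
})

test_that("AR pair table, phase demotion and non-qualifying configurations", {
  expect_equal(classify_findings(ar_pair("P", "P"))$certainty, "definitive")
  expect_equal(classify_findings(ar_pair("P", "LP"))$certainty, "definitive")
  expect_equal(classify_findings(ar_pair("LP", "LP"))$certainty, "definitive")

  # unknown phase demotes one bin, floored at provisional
  expect_equal(classify_findings(ar_pair("P", "P", "unknown"))$certainty,
               "probable")
  expect_equal(classify_findings(ar_pair("P", "VUS", "unknown"))$certainty,
               "provisional")
  expect_equal(classify_findings(ar_pair("LP", "VUS", "unknown"))$certainty,
               "provisional")

  # in cis pairs are not compound heterozygotes
  expect_equal(classify_findings(ar_pair("P", "P", "in_cis"))$certainty,
               "none")
  # a single heterozygote in an AR gene is a carrier
  expect_equal(classify_findings(finding("P", "AR"))$certainty, "none")
  expect_equal(classify_findings(ar_pair("VUS", "VUS"))$certainty, "none")
})

test_that("classification is independent of row order", {
  set.seed(67)
  spec <- cohort_spec(40, 8, 5, 6, seed = 3)
  cohort <- simulate_cohort(spec)
  dx <- classify_cohort(cohort)
  for (i in 1:3) {
    shuffled <- cohort[sample(nrow(cohort)), , drop = FALSE]
    expect_equal(classify_cohort(shuffled), dx)
  }
})

test_that("upgrading any finding one ACMG tier never lowers certainty", {
  upgrade <- c(VUS = "LP", LP = "P")
  rank_of <- function(x) match(x, c("definitive", "probable",
                                    "provisional", "none"))
  cases <- c(
    lapply(c("P", "LP", "VUS"), function(cl) finding(cl, "AD")),
    lapply(list(c("P", "P"), c("P", "LP"), c("P", "VUS"), c("LP", "LP"),
                c("LP", "VUS"), c("VUS", "VUS")), function(p) {
      ar_pair(p[1], p[2])
    }),
    lapply(list(c("P", "VUS"), c("LP", "VUS")), function(p) {
      ar_pair(p[1], p[2], phase = "unknown")
    })
  )
  for (fnd in cases) {
    before <- classify_findings(fnd)$certainty
    for (i in seq_len(nrow(fnd))) {
      up <- upgrade[fnd$acmg_class[i]]
      if (is.na(up)) next
      fnd2 <- fnd
      fnd2$acmg_class[i] <- up
      after <- classify_findings(fnd2)$certainty
      expect_lte(rank_of(after), rank_of(before))
    }
  }
})

test_that("invalid vocabulary is rejected with the offending row", {
  bad <- finding("P", "AD")
  bad$acmg_class <- "PATHO"
  expect_error(classify_cohort(bad), "unknown acmg_class 'PATHO'.*row 1")
  bad <- finding("P", "AD")
  bad$inheritance_mode <- "mito"
  expect_error(classify_cohort(bad), "unknown inheritance_mode")
  bad <- finding("P", "AD")
  bad$phase <- "cis"
  expect_error(classify_cohort(bad), "unknown phase")
})

test_that("best_per_individual takes the maximum certainty and keeps records", {
  dx <- data.frame(
    individual_id = c("A", "A", "A", "B", "B", "B", "C"),
    gene = paste0("G", 1:7),
    certainty = c("definitive", "provisional", "provisional",
                  "definitive", "definitive", "definitive", "none"),
    triggering_rule = "t", stringsAsFactors = FALSE)
  best <- best_per_individual(dx)
  expect_equal(best[["A"]], "definitive")
  # three definitive diagnoses count once at the individual level but all
  # records remain available for diagnosis-level accounting
  expect_equal(best[["B"]], "definitive")
  expect_equal(sum(dx$certainty == "definitive" & dx$individual_id == "B"), 3)
  expect_equal(best[["C"]], "none")
  expect_equal(best_per_individual(dx, individuals = c("A", "Z"))[["Z"]],
               "none")
  expect_length(best_per_individual(dx[0, ]), 0)
})

test_that("rules round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("ad:", "  P: definitive", "  LP: probable",
               "  VUS: provisional", "demote_unknown_phase: false"), path)
  rules <- read_certainty_rules(path)
  expect_false(rules$demote_unknown_phase)
  expect_equal(classify_findings(ar_pair("P", "P", "unknown"),
                                 rules)$certainty, "definitive")
})
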