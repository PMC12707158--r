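# rankdx

Phenotype-specific gene rank-annotation scores, leave-one-out validation,
and clinical exome diagnostic-yield accounting.

## The problem

Clinical exome sequencing (cES) cohorts assembled around one phenotype —
the package was developed around non-isolated tetralogy of Fallot (TOF+) —
raise four recurring analysis questions:

1. **Which genes look like the known disease genes?** Given a training set
   of genes with an established causal role, score every gene in the genome
   for similarity to that set across several annotation knowledge sources.
2. **Does the ranking actually discriminate?** Validate it with
   leave-one-out cross-validation and ROC-style curves.
3. **What did sequencing diagnose?** Bin each individual's reported
   variants into definitive / probable / provisional diagnoses under an
   explicit rule table, then compute diagnostic efficacy and how much of it
   a commercial gene panel would have captured.
4. **Which novel genes deserve a phenotypic expansion?** Integrate the rank
   score with literature and mouse-model evidence under a declared decision
   rule.

`rankdx` implements all four stages as composable R functions, plus a
synthetic-data module that generates knowledge sources with planted
disease-gene signal and cohorts with exact diagnostic-certainty
composition, so the whole pipeline runs end to end with no external data.

## The method in brief

For knowledge source *k* with feature matrix *X<sub>k</sub>* (genes x
features, z-scored per feature), each gene *g* receives a similarity

> s<sub>k</sub>(g) = cos( z<sub>k</sub>(g), c<sub>k</sub> ),

where *c<sub>k</sub>* is the centroid of the standardized training-gene
vectors. Per-source similarities are converted to midrank percentiles,
averaged gene-wise across sources, and re-percentiled, giving the omnibus
**rank annotation score** in 0–100% with genome-wide median 50% by
construction. In leave-one-out cross-validation each training gene *t* is
removed from every centroid, re-scored, and its recovered percentile
recorded; sweeping a percentile threshold yields an ROC-style curve whose
**area above the diagonal** (0 = chance, 0.5 = perfect) summarizes
discrimination.

Diagnostic certainty follows a rule table over ACMG variant classes: for
dominant/X-linked conditions the strongest suggestive finding decides
(P → definitive, LP → probable, VUS → provisional); for autosomal recessive
conditions an in-trans pair decides (P+P/P+LP/LP+LP → definitive,
P+VUS → probable, LP+VUS → provisional), with phase-unknown pairs demoted
one bin. Efficacy is the fraction of individuals whose best diagnosis is
definitive or probable. A phenotypic expansion is *supported* when the
candidate gene's rank score is positive (> 50%) **and** published cases
link the gene or its syndrome to the phenotype; mouse CHD evidence is
recorded as supportive annotation.

## Worked example

```r
library(rankdx)

## 1. rank-annotation scores on synthetic knowledge sources
cfg  <- sim_config(n_genes = 1000, training_genes = sprintf("T%02d", 1:20),
                   n_sources = 3, enrichment = 3, seed = 11)
srcs <- simulate_sources(cfg)
ts   <- training_set(cfg$training_genes, "synthetic phenotype")
omnibus_scores(srcs, ts)
#> <rank_annotation> 'synthetic phenotype': 1000 genes, 3 source(s)
#>   genome median 50.03%; training-gene median 99.03%

loocv_roc(srcs, ts)
#> <roc_result> 20 held-out genes, 3 source(s)
#>   omnibus AUC above diagonal: 0.49
#>   median leave-one-out percentile: 98.47%

## 2. cohort diagnostic yield
spec   <- cohort_spec(131, 24, 7, 40, multi_diagnosis = list(c(1, 2)), seed = 7)
cohort <- simulate_cohort(spec)
dx     <- classify_cohort(cohort)
best   <- best_per_individual(dx, attr(cohort, "individuals"))
summarize_cohort(best, dx, 131)
#> <cohort_summary> 131 individuals
#>   definitive  24 (18.3%)
#>   probable    7 (5.3%)
#>   provisional 40 (30.5%)
#>   diagnostic efficacy 23.7% (31/131; exact 23.664%)
#>   definitive/probable diagnoses: 33 across 31 individuals

## 3. phenotypic-expansion evidence for the four published candidates
ev <- tof_candidate_evidence()
summarize_scores(setNames(ev$rank_score, ev$gene), label = "expansion candidates")
#> <score_summary> 'expansion candidates' (n = 4)
#>   median 82.5%  [Q1 75.4%, Q3 88%; IQR 12.6%]
#>   no low outliers
evaluate_expansion(ev$gene, ev$rank_score, ev$literature_cases,
                   ev$mouse_chd, ev$diagnosis_certainty)$verdict
#> [1] "supported" "supported" "supported" "supported"
```

The genome median of 50% is a structural property of the percentile
scoring; the training-gene median near 99% and the strongly positive AUC
show the planted signal being recovered; the cohort summary reproduces the
certainty composition the generator was asked for; and all four candidate
genes (median score 82.5%) pass the expansion decision rule.

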