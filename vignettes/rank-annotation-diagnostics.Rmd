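---
title: "Rank-annotation scoring, diagnostic certainty, and phenotypic expansions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-annotation scoring, diagnostic certainty, and phenotypic expansions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankdx)
```

## Scope

`rankdx` chains four analyses that together audit a clinical exome
sequencing (cES) cohort assembled around one phenotype: genome-wide
rank-annotation scoring of candidate genes against a training set,
leave-one-out validation of that scoring, rule-based binning of reported
variants into diagnostic-certainty categories with the derived cohort
metrics, and a rule-based evidence integrator for phenotypic-expansion
candidates. This vignette records the model behind each stage, the
parameters that matter, and the decisions taken where the design was
genuinely open.

## The scoring model

Each knowledge source is a numeric gene-by-feature matrix: one annotation
resource (pathway membership strengths, expression profiles, phenotype
semantic similarities, ...) reduced to quantitative features. The scoring
model makes three assumptions:

1. features are comparable after per-feature standardization (z-score
   within the source);
2. genes causing the phenotype cluster in the standardized feature space,
   so the centroid of the training genes is a useful prototype;
3. the direction of a gene's feature vector is informative, its magnitude
   is not — similarity is the **cosine** between the standardized gene
   vector and the training centroid.

Cosine-to-centroid was chosen because it is scale-free, deterministic, has
no tuning parameters, and directly encodes "similarity to a set of
training genes". Zero-variance features carry no information and are
dropped with a warning; a gene vector (or centroid) of zero norm has
undefined direction and is assigned similarity 0.

Raw similarities are never compared across sources. Instead each source's
similarities become midrank percentiles,

$$\mathrm{score}(g) = 100 \cdot \frac{\mathrm{midrank}(g) - 0.5}{N},$$

which are averaged gene-wise across the $K$ sources and re-percentiled.
Rank aggregation makes sources with incommensurate raw scales
exchangeable, and re-percentiling restores the defining property of the
final score: 0–100% range with genome-wide median 50% (exact when $N$ is
even or all aggregated values are distinct; ties can displace the median
by at most $100/N$). Midranks are used everywhere so tied genes share one
value. Training genes are scored like every other gene — reported scores
for training genes are in-sample by design — and are excluded from the
centroid only during leave-one-out validation.

## Leave-one-out validation and the ROC construction

Each training gene $t$ is removed from every source's centroid, all genes
are re-scored, and $t$'s recovered omnibus percentile is recorded. The
ROC-style curve sweeps a percentile threshold from 100 down to 0; at each
threshold,

* $x$ = fraction of all genome genes called positive (training genes enter
  the genome-wide score vector at their held-out percentile, every other
  gene at its full-model percentile), and
* $y$ = fraction of training genes whose held-out percentile clears the
  threshold.

The threshold grid is the set of distinct held-out percentiles plus
$\{0, 100\}$, and the area is trapezoidal. Replacing training genes'
scores with their held-out values makes the curve a proper operating
characteristic: with perfect separation ($|T|$ training genes occupying
the top of the ranking) the area above the diagonal approaches
$0.5 - |T|/2N$, and under the null it is 0 in expectation. The per-source
curves use the same construction within one source.

Two statistical facts matter when interpreting null simulations. First,
the held-out percentiles of different training genes are positively
correlated (they share $|T|-1$ of $|T|$ centroid members), so the
area-above-diagonal of a single null run scatters considerably more than
an independence calculation suggests (empirically sd ≈ 0.07 for 20
training genes in a 1000-gene genome). Calibration checks therefore
aggregate across seeds — the package's null test requires the *median*
over 20 independent simulations to satisfy |AUC above diagonal| < 0.1 and
the median held-out percentile to lie in [35, 65]. Second, percentile
scores make the genome fraction called positive essentially linear in the
threshold, so curve geometry is driven by the held-out percentiles alone.

## Score statistics

`summarize_scores()` reports median and quartiles of a gene subset's
scores using linear interpolation between order statistics (quantile
positions $(n-1)p$; `stats::quantile` type 7). No interpolation
convention was dictated by the problem; type 7 is R's default and is
declared here so results are reproducible — Tukey hinges would flag
marginally different outliers on borderline data. The outlier rule is the
one-sided boxplot rule: a gene is a **low outlier** when its score falls
below $Q_1 - 1.5\,\mathrm{IQR}$. Only low outliers are reported because
the scientific question is which members of a putatively high-scoring set
score unexpectedly poorly. Presentation output rounds percentages half-up
to one decimal; all stored values keep full precision.

## Diagnostic-certainty rules

Findings are classified per (individual, gene) pair from five-tier ACMG
classes (P, LP, VUS, LB, B); LB/B findings are ignored, and every rule
requires phenotypic data suggestive of the gene's disorder. The default
table:

| configuration | certainty |
|---|---|
| AD/XL, P | definitive |
| AD/XL, LP | probable |
| AD/XL, VUS | provisional |
| AR in trans: P+P, P+LP, LP+LP | definitive |
| AR in trans: P+VUS | probable *(fixed)* |
| AR in trans: LP+VUS | provisional *(fixed)* |
| AR qualifying pair, phase unknown | one bin lower (floor provisional) |
| AR in cis pair, AR single heterozygote, AR VUS+VUS | none |

The base table is configurable (in code or via a YAML file read by
`read_certainty_rules()`), with two exceptions: the P+VUS and LP+VUS
in-trans rules are fixed and attempts to override them are ignored with a
warning — they are the two rules this framework exists to encode. Three
behaviors were design choices: (i) phase-unknown demotion by one bin is a
conservative middle ground between trusting unphased pairs and discarding
them; (ii) unlisted AR configurations (VUS+VUS, single heterozygotes)
classify as `none`, which also preserves the monotonicity property that
upgrading any single finding one ACMG tier never lowers the certainty;
(iii) with more than two AR findings, every non-cis pair is evaluated and
the best outcome kept. De novo status, mosaicism and imprinting are not
modeled.

Cohort efficacy uses each individual's *highest*-certainty diagnosis
(definitive > probable > provisional > none): efficacy = (definitive +
probable individuals) / cohort size. Diagnosis-level counts keep every
definitive/probable record, so an individual with three diagnoses
contributes three; an AR diagnosis backed by two variants in one gene is
one gene-level diagnosis. Percentages are reported both as exact fractions
and rounded half-up to one decimal; the exact fraction is the ground truth
(a fraction like 31/131 = 23.664% prints as 23.7% under this convention,
while naive truncation would print 23.6% — both roundings have appeared in
print for the same fraction, which is why both values are carried).

Panel coverage counts a definitive/probable diagnosis as covered when its
gene belongs to the panel's gene set, at two levels: diagnosis-level
(records) and unique-gene-level (deduplicated genes); the cross-panel
min–max range is attached to the result. Panels are user-supplied gene
lists; none are bundled.

## The phenotypic-expansion rule

Candidate genes are those with at least one definitive or probable
diagnosis that are absent from the known-gene registry (default: the
53-gene training set plus the established genes observed in the cohort,
`known_gene_registry()`). Each candidate is evaluated on three lines of
evidence: the rank-annotation score (banded *high* ≥ 85%, *positive* >
50%, *non-positive* otherwise), previously published cases linking the
gene or its syndrome to the phenotype, and CHD in mouse models of the
homolog. What counts as enough evidence for an expansion is, in practice,
a narrative judgment; this package fixes it as an explicit rule,

> supported ⇔ score > 50% **and** literature cases exist,

with mouse evidence recorded as supportive annotation only — two of the
four genes with well-established TOF expansions (MED13L, PUF60) lack
mouse CHD evidence, so requiring it would reject accepted expansions. An
open question is whether a high score alone (≥ 85%) should suffice
without literature support; the default says no, and both the threshold
and the literature requirement are arguments (`score_threshold`,
`require_literature`) so the rule is overridable.

## The synthetic-data generator

The generator exists because the real knowledge sources and the raw
cohort are not redistributable; it emulates their *structure* so every
downstream stage is exercised.

**Knowledge sources.** `sim_config()` defaults: `n_sources = 3` sources of
`n_features = 50` independent Gaussian features (`noise_sd = 1`), with a
fixed 20% block of each source's features shifted upward by
`enrichment = 3` noise-SD units for training genes. This is the simplest
model with tunable separability: `enrichment = 0` makes training genes
exchangeable (a null), and `enrichment = 3` produces clear but imperfect
separation — held-out training genes land around the 98th–99th percentile,
comparable to the score range reported for strong disease genes. The
source count mirrors "several" knowledge sources; the feature count is a
placeholder, not an estimate of any original resource. Each source draws
from its own substream of the global seed, so identical configurations are
bit-for-bit reproducible and components can be regenerated independently.

**What the generator does not emulate:** correlated features, non-Gaussian
annotation semantics (ontology terms, sparse memberships), heterogeneous
source quality, and genes with missing annotations. Passing tests
therefore demonstrate the pipeline's correctness and calibration under a
clean signal-plus-noise model, not performance on real annotation data.

**Cohorts.** `simulate_cohort()` works *backwards from the rule table*
(constructive, not rejection sampling): each requested
definitive/probable/provisional individual receives findings drawn from
mechanism templates that classify to exactly that bin — e.g. a probable
individual gets either a single suggestive LP in a dominant gene, an AR
P+VUS pair in trans, or an AR P+P pair of unknown phase. This guarantees
the requested composition exactly. Multi-diagnosis individuals (1-based
indices into the definitive/probable block) receive extra distinct-gene
diagnoses at their primary certainty, growing the diagnosis count without
moving any individual between bins. The `gene_overlap = c(3, 2)` default
shares one gene across three diagnoses and another across two, emulating a
cohort where 33 definitive/probable diagnoses involve 30 unique genes — a
composition needed to study unique-gene panel coverage. A seeded fraction
of undiagnosed individuals receives non-qualifying findings (non-suggestive
VUS, or a likely benign variant) so the `none` path is exercised.

## Numerical choices and degenerate inputs

* Ties: midranks everywhere; full-tie inputs score 50.
* Zero-variance features: dropped with a warning; a source left with fewer
  than two informative features is an error.
* Zero-norm standardized vectors: similarity 0.
* Gene universes must be identical across sources; the error lists the
  symmetric difference.
* Training sets: non-empty for scoring, at least 3 genes for leave-one-out
  validation; an exclusion that empties the training set is an error.
* Presentation rounding is half-up at one decimal, applied only at print
  time; tests and stored values use exact fractions.

## Problem sizes used in the test suite

The packaged tests run the planted-signal study at 1000 genes x 3 sources
x 50 features with 20 training genes, the null calibration over 20 seeds
at the same size, and cohort round-trips over 100 random small
compositions — sizes at which every statistical property checked is stable
while the whole suite completes in well under a minute.

## Known limitations

* Proprietary gene-prioritization systems do not publish their annotation
  sources, similarity metrics or aggregation schemes; this package
  implements the *procedure* — train on a gene set, rank all genes within
  each source, aggregate, validate by leave-one-out — with a declared,
  reproducible metric, and does not reproduce any specific system's
  per-gene scores (the TOF candidate scores in `tof_candidate_evidence()`
  are inputs to the evidence rule, not outputs of this package).
* ACMG classification itself is out of scope: classes are inputs.
* Copy-number variants are not modeled; the expansion evaluator handles
  sequence-variant genes only.
* The certainty rule table beyond the two fixed AR rules is a declared
  default, intended to be overridden where a cohort's source criteria
  differ.
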