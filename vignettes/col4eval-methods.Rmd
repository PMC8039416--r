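---
title: "Methods: evaluating in silico predictions for type IV collagen variants"
author: "col4eval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating in silico predictions for type IV collagen variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(col4eval)
```

# The problem

Rare missense variants in *COL4A3*, *COL4A4* and *COL4A5* — the genes
encoding the α3/α4/α5 chains of the glomerular basement membrane's
type IV collagen heterotrimer — are a frequent and vexing output of
diagnostic sequencing in kidney disease. Computational pathogenicity
predictors are cheap to consult but of uncertain reliability on this
gene family. `col4eval` implements an evaluation framework with two
arms: a *computational* arm that scores how a 12-program consensus
agrees with clinical labels in disease databases, and a *functional*
arm that compares the same predictions against a split-luciferase
readout of collagen heterotrimer secretion.

# Rarity filtering

A variant is categorized as rare when its minor allele frequency (MAF)
in the ethnically matched population is at or below 0.005. The
threshold reflects the low prevalence of FSGS (on the order of a few
per million) and the mixed recessive/dominant/X-linked inheritance of
type IV collagen disease: a causal allele may legitimately be carried
by unaffected individuals, so the cutoff sits well above a strict
singleton criterion but far below common variation.

Three choices are configurable in `filterConfig()`:

* `maf_threshold` (default 0.005) — the frequency cutoff, a unitless
  allele frequency in (0, 0.5).
* `comparison` — `inclusive` (≤, default) or `strict` (<). The two
  conventions appear interchangeably in practice; we default to the
  inclusive reading and expose the switch. None of the packaged
  analyses change under either mode because the synthetic frequency
  spectra deliberately avoid mass exactly at the boundary.
* `population_policy` — which frequency the rule sees:
  `carrier_matched` (default) uses the carrier's ancestry-matched
  gnomAD population and falls back, with a logged message, to the
  across-population maximum when the carrier ancestry is unknown;
  `global_max` always uses the maximum (the conservative choice — a
  variant must be rare everywhere); `global` uses a pooled `af_global`
  column when present. The fallback policy is our design decision: the
  matched-population rule is normative, but an unmatched carrier has
  to be handled somehow, and the across-population maximum can only
  make the rule harder to pass, never easier.

A variant observed in no population is rare under every policy,
comparison and threshold — absence of evidence of commonness is
treated as rarity, which is the only coherent reading for
never-catalogued variants.

Variant labels downstream of filtering follow a reported-case rule
(`designateLabel()`): a rare missense variant already reported in
other kidney-disease cases is designated pathogenic; any other rare
missense variant is a variant of uncertain significance (VUS).

# The 12-tool consensus

Each predictor votes once. Numeric tools vote deleterious when their
score lies on the damaging side of their own recommended cutoff;
categorical tools (LRT, MutationTaster) vote through a damaging token
set. The registry (`defaultToolRegistry()`) stores orientation,
cutoff, boundary inclusivity and the categorical maps; it is an
editable TSV so a user can adjust a cutoff or extend the panel without
touching code. The shipped cutoffs come from each tool's own
documentation (e.g. SIFT damaging below 0.05, PROVEAN at or below
−2.5, M-CAP above 0.025); the two PolyPhen-2 classifiers (HDIV and
HVAR) vote independently, counting "possibly" plus "probably damaging"
as deleterious.

Two semantics matter more than the cutoffs themselves:

* **Boundary ties** default to non-damaging (`cutoff_inclusive =
  FALSE`) except where a tool documents an inclusive rule (PROVEAN,
  FATHMM, PolyPhen-2). This is the strict reading of "less than".
* **Missing outputs** vote neither way and the denominator stays 12.
  A tool that fails to produce a score is a classification failure,
  not a tolerated vote; consequently a variant missing three or more
  tools can never reach the 10-of-12 bar. This mirrors how a
  non-output is penalized in single-tool evaluation, where it counts
  against both sensitivity and specificity.

The aggregate rule — predicted pathogenic iff at least *k* = 10 of 12
tools vote deleterious — is deliberately majority-plus: it encodes the
observation that near-unanimity, not bare majority, is what database
concordance analyses reward. `k` is a parameter (1–12) everywhere.

Orientation is metadata only: raw scores are never negated or
rescaled in storage, so ROC analysis and cross-tool correlation see
each tool's native scale (and opposite orientations legitimately show
up as negative Spearman coefficients).

# Concordance and single-tool evaluation

For each (database, gene, label) stratum, concordance is the fraction
of variants whose consensus call matches the clinical label; benign
concordance demands an explicit not-predicted-pathogenic call, so a
mostly-missing panel is discordant for benign variants too. Strata
with no variants are omitted rather than reported as 0/0. Reports are
written with the `k/n (p%)` presentation (numerator, denominator,
whole-percent) so fractions remain auditable after rounding; the exact
fraction is preserved in the machine-readable column.

# ROC recalibration

`rocCurve()` sweeps every distinct observed score as a candidate
threshold, classifying a variant as damaging when its score is
*strictly* on the damaging side of the threshold, plus one extreme
threshold so the curve reaches (1, 1). Consequences of this
construction:

* AUC computed by trapezoid over the swept points equals the
  Mann-Whitney U statistic normalized by n₊ × n₋ (ties counting ½) —
  the test suite asserts this identity against `wilcox.test` on random
  panels, and against `pROC` as a second, independent implementation.
* The Youden-optimal threshold (max TPR − FPR; ties broken by smaller
  FPR, then by the stricter threshold) lands just past the last
  pathogenic score in a separable sample — i.e. at the most permissive
  value that still excludes the benign mass — which is the natural
  reported "recalibrated cutoff".
* Missing scores are excluded from the curve and counted; a
  single-class input raises an explicit "ROC undefined" error rather
  than returning a degenerate curve.

Youden's J operationalizes "maximize the true-positive rate while
minimizing the false-positive rate"; it is the standard single-number
reading of that informal criterion, and the tie-break rules make the
optimum deterministic. `compareCutoffs()` classifies the optimum
against the recommendation under the tool's orientation: on synthetic
panels with benign score mass inside the recommended damaging region,
the optimum comes out `optimal_stricter`, the qualitative behavior
expected when recommended cutoffs admit false positives.

# Cross-predictor correlation

`spearmanMatrix()` rank-correlates raw scores pairwise-complete.
Categorical tools need an ordering, which their documentation provides
(for MutationTaster, polymorphism < neutral < disease causing <
disease causing automatic); that ordering is stored in the registry.
Cells with fewer than three complete pairs are undefined (`NA`), and
the diagonal is 1 whenever a tool has at least two observed scores.
No multiple-testing control is applied anywhere in the package — all
reported quantities are raw fractions and coefficients.

# Split-luciferase analysis

The assay co-expresses tagged α3/α4/α5 constructs; reconstituted
luminescence in cells measures intracellular heterotrimer formation
and in the medium measures secreted trimer. Per mutant, replicate
readings (triplicate by design) are averaged arithmetically — one
summarized point per mutant, matching the one-point-per-mutant scatter
convention. On the scatter of X = intracellular vs Y = secreted RLU, a
mutant under the Y = X − `band_offset` line is called a significant
secretory defect; `band_offset` defaults to 50 RLU on the supplied
scale. The band rule is scale-covariant (scaling all RLU and the band
by the same constant changes nothing) and monotone (widening the band
never creates a defect). Because the meaningful absolute scale is
instrument-dependent, an optional pre-step rescales a dataset so WT
intracellular = 100 with the band interpreted on that scale; it is off
by default, since the default band is defined on the raw plotted
scale. A dataset whose WT falls below its own band is rejected as
miscalibrated rather than silently analyzed.

N-terminal tagged constructs are authoritative for congruence.
Heterotrimer assembly initiates at the C-terminal NC1 domain, so
C-tagged reporters can luminesce before folding completes and
underreport defects; C-terminal calls are computed and compared
(`compareTerminals()`) but excluded from `functionalCongruence()`,
which reports, per (gene, label class), the fraction of
predicted-deleterious variants that also show a defect. An empty
denominator yields an undefined (NA) congruence, never 0%.

# The synthetic-data generators

The package ships no cohort or database exports; all inputs are
generated. Three generators cover the three input kinds, and their
defaults *are* the study conditions the packaged manifests describe:

* `generateScorePanels()` draws class-conditional scores per tool —
  truncated normals on each tool's native range for numeric tools,
  class-conditional token frequencies for categorical ones — with
  independent per-tool missingness (2% by default). The damaging and
  tolerated components sit well inside their respective sides of each
  cutoff (e.g. SIFT damaging ≈ N(0.01, 0.015), tolerated ≈
  N(0.4, 0.2)): separations chosen once to represent the
  strongly-bimodal score profiles these tools produce on confidently
  classified collagen variants.
* `generateFixture()` is count-exact: for each manifest stratum,
  exactly the target number of variants receive ≥10 damaging-side
  scores and the rest at most 9 (unpredicted vote tallies are drawn
  label-dependently: near-miss 6–9 for pathogenic strata, 0–5 for
  benign). The generator re-runs the consensus classifier on its own
  output and refuses to emit a fixture that deviates from its
  manifest, so downstream counts are reproduced exactly under any
  seed.
* `generateRlu()` plants defects geometrically: a defective mutant's
  secreted mean sits `defect_drop` = 200 RLU below its intracellular
  mean — far beyond band (50) plus replicate noise (sd 10, n = 3) — a
  non-defective mutant sits within ±15 RLU of the Y = X line, and WT
  sits on it at 500 RLU. The generated dataset is self-verified
  against its plan before being returned. In the C-terminal datasets,
  defects are planted for only 4 of the 9 pathogenic mutants,
  reproducing the qualitative N/C discordance; the exact C-terminal
  count is a free choice of the fixture, as only the N-terminal calls
  enter congruence.

Allele-frequency spectra mix a point mass at "never observed" (30%)
with a log-uniform spectrum, placed at ≤0.004 for rare variants and
0.006–0.05 for common ones so that both comparison modes and all
population policies agree on every fixture variant.

What the generators do **not** emulate: real inter-tool score
correlation (tools are drawn independently given the latent class, so
the synthetic Spearman matrix is not a model of the empirical one),
real score distributions (truncated normals are a convenience family),
database label noise, and sequence-level structure. Passing tests
therefore demonstrate that the *machinery* — filtering rules,
consensus arithmetic, concordance bookkeeping, ROC identities, band
geometry — is correct on data with known ground truth; they do not
re-measure the behavior of the 12 programs on real collagen variants,
which requires real score tables as input.

# Numerical and degenerate-input choices

* Boundary scores at a cutoff follow the registry's inclusivity flag;
  synthetic draws avoid exact-boundary mass (continuous components).
* The ROC sweep uses a strict inequality, making the optimum the most
  permissive threshold that attains the maximal J after tie-breaks.
* Empty tables propagate as empty results (filter, classify,
  concordance); single-class ROC input and WT-defective RLU datasets
  raise errors rather than degenerate output.
* Report percentages are whole-percent rounded for display with exact
  fractions retained alongside.
* Problem sizes in the test suite: the vote-space oracle enumerates
  all 4,096 deleterious/tolerated vectors; the Mann-Whitney identity
  runs on 200 random panels; threshold recovery uses 10,000 scores per
  class against the closed-form density crossing (declared tolerance
  0.03 on a score scale of 1); generator sensitivity/specificity
  checks use 10,000 variants per class.

# Known limitations

* The shipped registry cutoffs are tool-documentation defaults; an
  analysis bound to a specific dbNSFP release should load its own
  registry TSV.
* Concordance carries no confidence intervals, by design — strata are
  reported as raw count fractions.
* The band rule is binary; a graded defect severity (a VUS may sit
  only slightly under the band) is not modeled.
* The functional arm addresses secretion only; disease mechanisms
  leaving heterotrimer secretion intact are outside the assay's reach.
* Database-derived labels are themselves partly informed by in silico
  evidence, so concordance against them can overestimate sensitivity;
  the functional arm exists precisely to provide an orthogonal check.
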