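---
title: "Methods: evolving and validating dichotomous qPCR gene signatures"
author: "gpsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving and validating dichotomous qPCR gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsig)
library(SummarizedExperiment)
```

# The problem

One in four patients with lymph node-negative, invasive colorectal carcinoma
recurs after curative surgery, and guideline-based clinicopathologic risk
factors (T4 stage, grade 3–4, lymphovascular or perineural invasion,
obstruction/perforation, fewer than 12 nodes examined, compromised margins)
are coarse: they flag many patients who would never recur. A small
tumor-derived expression signature measured by RT-PCR on archival FFPE
tissue can, in principle, dichotomize these patients into high- and low-risk
groups for 36-month recurrence.

`gpsig` implements the full computational path of such a study as a tested,
reusable pipeline: qPCR quality screening and normalization,
genetic-programming (GP) induction of small algebraic classifier rules,
candidate analysis and finalization, and the external-validation statistics
battery. Because studies of this kind typically deposit no patient-level
data, the package also ships a synthetic-cohort generator so that every
stage — and the pipeline end to end — can be exercised and property-tested.

# Normalization model

Expression is measured as cycle thresholds (Ct): the PCR cycle at which
fluorescence crosses a fixed threshold, a log2-scale quantity where one
cycle less means twice the transcript. Duplicate measurements are averaged
on the Ct scale, their congruence summarized per sample by the squared
Pearson correlation across genes. Five housekeeping genes (B2M, GUSB,
POLR2L, PSMB6, UBC) anchor the per-sample normalization constant, and each
target gene's linear expression is

$$E_{s,g} = 100 \times 2^{\,\overline{Ct}^{HK}_s - Ct_{s,g}}$$

so a gene expressed at the housekeeping mean scores 100, and every one-cycle
decrease doubles the value. Samples must pass five acceptance criteria
(all bounds inclusive): RNA concentration ≥ 10 ng/µL, 260/280 ratio ≥ 1.8,
housekeeping mean Ct ≤ 32.0, every individual Ct ≤ 35, replicate r² ≥ 0.90;
additionally, a requisite gene with no amplification in either replicate
rejects the sample. Failed amplification is represented as a missing value,
never as a sentinel Ct. The replicate-r² criterion is applied per sample
across genes (the replicate pairs of one assay card); whether the original
assays applied it per card or per gene is not documented, and this
convention is a deliberate design choice, recorded here rather than claimed
as fact.

# Rule grammar and evaluation

A classifier rule is an expression tree over gene symbols and numeric
constants built from a fixed grammar: `add`, `sub`, `mul`, protected
division (x/0 ≡ 1, the standard GP convention), `min`, `max`, `neg`, the
4-ary comparison `if_less_then_else(a, b, x, y)`, and `and`/`or`/`not`
(operands true iff > 0, results encoded 1/0 so every tree yields a real
score). Two hard constraints are enforced at construction, during
evolution, and at parse time: at most `max_genes` distinct genes (the
published constraint is ≤ 7) and a depth cap. Node results are clamped to
±10¹² and NaN maps to 0, making evaluation total and finite on any input.

The rule's score is dichotomized at a *slice point*: scores strictly below
versus at-or-above the threshold, with `high_risk_side` naming the
high-risk side. The boundary is inclusive on the at-or-above side,
mirroring the published cut (< −4.4777 vs ≥ −4.4777). No gradation within
either group is exposed — by design the classifier is dichotomous. Which
side of the published slice point denotes high risk was never printed, so
the risk side is data, not convention: it is fixed during finalization as
the side with the higher observed recurrence proportion. Rules serialize to
versioned JSON documents; parsing re-validates the grammar.

# Genetic-programming search

`evolveRules()` performs independent GP runs grouped into *sets*, one set
per maximum-gene-count value; the default configuration — 4 sets × 300 runs
with 4-fold cross-validated fitness — realizes the published campaign shape
(4 folds × 300 runs × 4 sets = 4800 fold-level runs, 1200 best-of-run
candidates). Fitness is the mean held-out AUC of the raw rule score over
stratified cross-validation folds; the slice point plays no part in
fitness. AUC is computed from ranks with ties counted one-half
(Mann–Whitney). The search itself uses conventional GP machinery, since
the original proprietary platform's hyperparameters were never published:
ramped
half-and-half initialization, tournament selection (size 3), subtree
crossover, subtree and Gaussian constant mutation, and one-individual
elitism. Offspring violating the gene or depth constraint are retried a few
times and then replaced by a parent copy, so no individual ever violates
the grammar. Per-run seeds are derived from the campaign seed, making runs
order-independent and the campaign reproducible.

The original study notes that gene-use frequency also influenced fitness,
without stating a mechanism; here fitness is AUC-only and frequency
analysis is performed post hoc (`geneUseFrequency()`), which keeps the
fitness function well-defined. Whether candidate pools should be best-of-run
rules or whole final populations is likewise unstated; this implementation
collects best-of-run rules.

# Finalization

Candidates are compared on a reserved test set (`selectBestRule()`:
argmax of test AUC, ties broken by fewer genes, then shallower trees, then
earlier runs), and the frozen winner's slice point is then refined on the
combined training + test set (`refineSlicePoint()`). The refinement
objective is Youden's J = sensitivity + specificity − 1, maximized over all
midpoints between adjacent distinct scores and both risk orientations, with
ties resolved toward the score median. The published account says only that
the slice point was "refined"; Youden's J is the standard dichotomization
criterion and an accuracy objective is available as an alternative.

# Validation statistics

* **Diagnostics** (`confusionMetrics()`): sensitivity, specificity, PPV,
  NPV with exact Clopper–Pearson intervals from beta quantiles. These
  reproduce the published external-validation numbers exactly from the
  printed contingency counts (62/92 and 87/172 → 0.67/0.51/0.42/0.74; the
  95% CI on 62/92 → 0.57–0.77).
* **Paired comparison** (`comparePairedClassifiers()`): among recurrent
  patients the proportions called high-risk by each classifier, among
  nonrecurrent the proportions called low-risk, each with an exact
  two-sided McNemar test on discordant pairs (doubled smaller tail, capped
  at 1).
* **Survival** (`kmCurve()`, `logrankTest()`, `coxFit()`): product-limit
  curves, the log-rank test, and Cox proportional-hazards regression with
  Efron tie handling (monthly follow-up times make ties likely; Breslow is
  available). Missing covariates are handled complete-case per model with
  the n used reported, matching the per-variable patient counts convention
  of clinical tables. `univariateScreen()` fits each baseline variable
  jointly with the dichotomous test result; `backwardElimination()`
  repeatedly removes the highest-p non-forced variable (Wald test per
  variable) until all remaining baseline variables fall below α = 0.05,
  with the molecular test forced to stay. `compareHazardModels()` puts two
  classifiers in one model and Wald-tests the difference of their
  coefficients using the joint covariance.
* **Design** (`sampleSizeTwoProportions()`): the two-proportion normal
  approximation with unpooled variance; the published calculation named
  only the software used, so the formula implemented here is stated
  explicitly rather than claimed identical.
* **Guideline baseline** (`nccnClassify()`): stage I → low risk
  (surveillance); stage II → high risk with ≥ 1 risk factor present, low
  risk with all factors confirmed absent, not evaluable otherwise.
  Not-evaluable patients are excluded from comparisons, reproducing the
  evaluable-subset logic of the original comparison (241 of 264).

# The synthetic-cohort generator

`generateCohort()` emulates the statistical structure the pipeline assumes:

* duplicate Ct values for 5 housekeeping + 225 target genes, with per-gene
  baselines (SD 1.2 cycles), per-sample biological variation (SD 1.0), a
  per-sample global loading shift (SD 0.7, removed by normalization), and
  independent replicate noise (SD 0.15, giving replicate r² ≈ 0.98). True
  Cts are clamped to the assay's usable range (5–34 cycles), so a clean
  panel passes all acceptance criteria;
* an optional *planted rule* whose score on the noise-free expression
  drives the outcome. Genes referenced by the planted rule share a common
  baseline Ct so that each carries comparable weight in the score —
  otherwise a random expression-scale mismatch can make one gene of a
  "2-gene ground truth" carry essentially no signal, leaving the ground
  truth unidentifiable for any method;
* recurrence at ~35% prevalence through one of two outcome links. The
  default `"logistic"` link draws recurrence Bernoulli with probability
  logistic in the standardized score (slope 8 by default, giving a strong
  but noisy signal: label-vs-score AUC ≈ 0.96; the intercept is solved
  numerically to hit the prevalence). The `"threshold"` link instead draws
  exponential event times with group-specific rates — high- vs low-risk by
  the planted slice point — so the group hazard ratio equals the configured
  value exactly and recurrence is the event falling inside the 36-month
  horizon (the baseline rate is solved to hit the prevalence). Hazard-ratio
  recovery experiments use the threshold link; rule-recovery experiments
  the logistic link;
* recurrence-free survival with administrative censoring at 36 months
  (nonrecurrent patients censored at 36), matching the binary 36-month
  endpoint;
* clinicopathologic covariates (T class, grade, nodes examined, LVI, PNI,
  obstruction/perforation, site, age, sex, race) with marginals typical of
  a node-negative colorectal validation cohort, independent of outcome by
  default so that adjusted and unadjusted effects are distinguishable in
  tests. PNI is missing in ~53% of patients (and LVI/obstruction in small
  fractions) to exercise complete-case handling;
* optional injected QC failures, each violating exactly one named
  criterion, with the mode recorded.

What the generator does *not* emulate: FFPE degradation chemistry, plate
geometry or position effects, correlated gene-gene expression structure
(genes are independent given the sample effects), outcome-covariate
confounding (unless wired in by the user), and enrollment-style eligibility
filters. Tests passing on these cohorts therefore demonstrate the
correctness of the computational machinery — normalization arithmetic,
search, selection, statistics — not the clinical performance of any real
signature.

# Numerical choices

* Protected division returns 1.0 on zero denominators; node results are
  clamped to ±10¹² with NaN → 0.
* Stratified splits use half-up rounding of the per-stratum group size, so
  ratio-0.5 groups differ by at most one; a 74-patient cohort with 32
  recurrent/42 nonrecurrent splits 37/37 with 16 recurrent on each side.
* Cox fits run Newton–Raphson (survival package) with tight tolerances
  (eps 1e-10) and up to 100 iterations; monotone-likelihood warnings are
  surfaced as flags rather than silently ignored.
* The exact binomial interval uses the closed beta-quantile form with the
  conventional k = 0 / k = n endpoints.
* Slice-point ties (equal J) resolve toward the score median — the most
  central of the equally good cuts.
* All random processes take explicit integer seeds; per-run/per-stage seeds
  are derived arithmetically and stay below 2³¹.

# Problem sizes used in the test suite

The published cohort data were never deposited, so the suite validates by
parameter recovery at sizes a single CPU handles comfortably: planted-rule
recovery on cohorts of n = 300 (split 140/100/60 into training/test/
validation, campaign of 2 sets × 4 runs, population 200, 35 generations,
10 seeds); Cox hazard-ratio recovery at n = 2000; log-rank type-I error
over 500 null replicates of n = 1000; oracle agreement checks (AUC against
brute-force pair counting, Youden refinement against a dense threshold
grid, Cox against direct partial-likelihood maximization) on hundreds of
random small instances.

# Known limitations

* The published 5-gene rule's algebraic form was shown only as a figure and
  is deliberately not reconstructed; `publishedRuleConstants()` carries its
  printed constants (genes, slice point, score range) for format-level
  checks only.
* Published hazard ratios (1.80, 1.63, 1.76), log-rank p values, the
  regression tables and the gene-use frequency table depend on the
  undeposited patient-level data and are treated as non-reproducible;
  the package substitutes seeded recovery experiments.
* GP search is stochastic; a given small campaign can converge on a
  surrogate gene whose profile mimics a planted gene's contribution.
  Recovery rates are therefore assessed across seeds, not per seed.
* The backward-elimination p values are Wald-based; no likelihood-ratio
  variant is provided.
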