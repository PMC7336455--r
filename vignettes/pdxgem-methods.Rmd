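---
title: "Modeling drug response from PDX panels: methods and design notes"
author: "pdxgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug response from PDX panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxgem)
```

# The problem

Patient-derived xenografts (PDXs) are the one preclinical system in which a
drug's effect on a human tumor can be measured directly — as the percent
change in tumor volume,

$$ \text{activity} = 100 \times \frac{V_\text{post} - V_\text{pre}}{V_\text{pre}}, $$

with negative values meaning shrinkage (a sensitive model) and values at or
above zero meaning growth (a resistant one; the boundary case of exactly
zero counts as growth, because shrinkage must be strict). Pairing that
activity with the models' pretreatment expression profiles gives a small
supervised learning problem: find genes whose expression predicts the
drug's effect, and turn them into a score that transfers to cancer
patients.

The catch is that engraftment changes tumors. A gene that predicts response
in mice through some co-regulated program is useless in patients if that
program's wiring does not survive the transfer between systems. The
package's central statistic — the concordance co-expression coefficient
(CCEC) — filters candidate biomarkers by whether their co-expression
neighborhood is preserved between the PDX panel and a pretreatment patient
cohort, before any predictive model is trained.

# Pipeline stages

## 1. Drug-sensitivity biomarker discovery

`discoverBiomarkers()` screens every feature against activity:

* **t-test branch** (default when both the shrunken and grown groups have
  at least `minGroupSize = 2` models): a two-sided unpaired t-test of
  expression between the two groups. Pooled-variance Student's t is the
  default — at panel sizes of 6–16 there is little information to estimate
  separate variances — with Welch available via `varEqual = FALSE`. The
  statistic is oriented as (mean grown − mean shrunken), so positive
  values mean higher expression in resistant tumors.
* **correlation branch** (when a group is smaller than `minGroupSize`,
  including the all-grown case): Spearman correlation (average ranks,
  two-sided t approximation with n−2 df) of expression with the continuous
  activity; Pearson by option. Spearman is the default because rank
  correlation is the natural choice at these sample sizes with heavy-tailed
  volume changes.

Multiplicity is controlled by Benjamini–Hochberg at `fdr = 0.05`. Small
panels often yield nothing at that level; the stage then falls back to the
nominal p < 0.05 rule and records `alpha_mode = "nominal"`. Features with
no variance are flagged `degenerate` and never selected.

A note on the branch threshold: the size rule is "fewer than
`minGroupSize` models in a group", with default 2, so a 2-vs-4 panel is
still analyzed by t-test while a 0-vs-13 panel falls through to
correlation. A "near-zero variance of activity" side condition is
deliberately not part of the rule: it has no natural scale, and the group
size already captures the failure mode that matters.

## 2. Concordant co-expression analysis (CCEA)

For the $n$ selected candidates, two $n \times n$ correlation matrices are
built across samples: $U$ on the PDX panel and $V$ on the patient reference
cohort (Pearson by default). For candidate $g$, write $u = U_{\cdot g}$ and
$v = V_{\cdot g}$ for the off-diagonal columns (length $m = n-1$). The
CCEC is

$$ c(g) = \frac{2\sum_{k\neq g}(U_{kg}-\bar U_{.g})(V_{kg}-\bar V_{.g})}
  {\sum_{k\neq g}(U_{kg}-\bar U_{.g})^2 + \sum_{k\neq g}(V_{kg}-\bar V_{.g})^2
   + (n-1)(\bar U_{.g}-\bar V_{.g})^2}, $$

which is exactly Lin's concordance correlation coefficient between $u$ and
$v$ with population moments over the $m$ entries (note the $(n-1)$, not
$(n-2)$, in the third term — the tests pin this equivalence to 1e-12
against an independently coded moment-form oracle). $c(g) = 1$ iff the
neighborhood is perfectly preserved; unlike a plain Pearson correlation of
$u$ and $v$, the CCEC also punishes location and scale shifts, so
$|c(g)| \le |r(u,v)|$ always.

**Significance.** The reference implementation of Lin's coefficient
reports confidence intervals, not tests, so the package adopts a
Fisher-type construction under $H_0\!: c = 0$: $Z = \operatorname{atanh}(c)$
with standard error $1/\sqrt{m-2}$ against a normal reference, two-sided.
A feature-label permutation null (`pMethod = "permutation"`) is available
as a calibration cross-check; the two broadly agree on simulated data.
P-values are BH-adjusted and candidates with q < `fdr` **and**
`ccec > minCcec` are the CCE biomarkers. `minCcec = 0` (significance-only)
is the default; raising it to e.g. 0.3 is a config knob that yields a
sparser, more strongly concordant signature — selection is nested in both
`fdr` and `minCcec`, so stricter settings always give subsets.

**Degeneracies worth knowing about.** A constant feature in either cohort
gets $c = 0$, p = 1, flagged, never selected. More subtly, if the
candidate set is co-expression-*homogeneous* — every candidate in one
tight module — then each $u$ vector is nearly constant and the CCEC tends
to 0 even when the module is genuinely shared: the statistic needs
contrast (correlated and uncorrelated partners) to certify concordance.
In practice candidate sets from nominal-level discovery contain enough
null features to provide that contrast; the pipeline-level fallbacks below
handle the rest. At least 4 candidates are required (the p-value needs
$m \ge 3$ paired entries).

## 3. Model training and scoring

`trainGem()` standardizes each feature to mean 0 / sd 1 (divisor n−1)
across the PDX panel, fits a random-forest regression of activity on
expression (500 trees, `mtry = max(p/3, 1)`, a mandatory seed), drops
features with non-positive permutation importance (%IncMSE on out-of-bag
samples — less biased than impurity importance, which remains available),
and refits once on the survivors. No recursive elimination: one
filter-then-refit pass. Both the in-sample refit correlation and the
out-of-bag correlation with observed activity are stored, since either can
be meant by a "training correlation" and they can differ substantially at
n ≈ 13.

`predictScores()` standardizes the *scoring cohort within itself* before
applying the forest. This is a deliberate choice: a training-recipe
transfer (applying PDX means/sds) is not invariant to platform and
cohort-level location/scale shifts, while within-cohort z-scoring is, and
cross-platform shifts are the rule for these data. Scores therefore live
on the training activity scale: lower score = predicted shrinkage =
expected responder. Model features missing from a cohort (or constant in
it) are imputed at the standardized mean 0 with a warning, up to a 20%
ceiling, above which scoring errors out.

## 4. Evaluation

For binary endpoints (pCR vs RD and the like): a two-sided two-sample
t-test of scores between response groups, and the rank (Mann–Whitney) AUC
with ties at half credit, oriented by `responderLow = TRUE` so that an AUC
above 0.5 means responders score lower. The optional CI is a seeded
stratified bootstrap (2,000 resamples by default, resampling within each
response class). For survival endpoints: scores are stratified by median
split (ties at the median go to "low", deterministically) or empirical
tertiles; strata are compared by Kaplan–Meier medians, the log-rank test,
and an ordered trend test implemented as the log-rank linear-trend
contrast with stratum scores 1, 2, 3 (for two strata it reduces to the
ordinary log-rank test). Multivariable Cox modeling is a thin pass-through
to the survival package (`coxScoreAssociation()`).

## Orchestration

`runPipeline()` drives all stages from one configuration (in-memory or
YAML), writes every artifact as it is produced, and emits a manifest with
input digests, per-stage feature counts, seeds, and versions. The counts
nest by construction: screened ⊇ discovered ⊇ CCE-selected ⊇ final model.
All randomness descends from the single root seed (forest: seed + 101,
bootstrap: seed + 303), and a rerun with identical inputs is byte-identical.

Two pragmatic fallbacks live at the pipeline level (never inside the stage
functions, which keep their strict contracts): if FDR discovery returns
fewer than `minModelFeatures = 4` features, selection widens to nominal
p < 0.05; if FDR CCEA selects fewer than 4, it relaxes to nominal CCEA and
then, if still too sparse, skips the filter entirely. The mode actually
applied is recorded in the manifest (`alpha_mode`, `ccea_mode`). A
`ccea: skip: true` config runs the ablation variant (train on all
discovered biomarkers), which is how the value of the concordance filter
is itself measured.

# The synthetic-data generator

There is no public desk-scale dataset with paired PDX activity, patient
co-expression, and patient outcomes, so the package ships a generator
(`simulateStudy()`) that makes every assumption of the pipeline literally
true and tunable:

* **Co-expression**: sensitivity features form equicorrelated modules
  (loading $\sqrt\rho$ on a module factor, within-module correlation
  `blockCorrelation`). The first `nConcordant` features' modules exist in
  *both* systems; the remaining sensitivity features form PDX-only modules
  that are iid in patient cohorts — the engraftment-rewiring phenomenon
  the CCEC is designed to detect. Null features are iid everywhere.
  Per-feature baselines (uniform on 5–12, shared across cohorts) mimic
  log-scale array intensities.
* **Activity**: a linear combination of the sensitivity features' (signed,
  module-aligned) expression scaled by `effectSize`, plus Gaussian noise
  (`noiseSd`), in percent units. With `effectSize = 0` the design is an
  exact global null.
* **Patient outcomes**: the validation cohort's latent response applies
  the same linear rule restricted to the concordant features (pure noise
  when `nConcordant = 0`). The binary endpoint thresholds at the latent
  median (balanced classes; responders are the low/shrinkage half); the
  survival endpoint is exponential with hazard rising in the latent
  response ($0.08\,e^{0.8 z}$ per month), censored at 60 months.

Defaults (1,000 features, 50 sensitivity / 30 concordant, panel of 13
PDXs, reference and validation cohorts of 100, $\rho = 0.7$,
`moduleSize = 50`) mirror the regimes these studies actually occupy: small
panels, a minority of discoveries surviving the concordance filter, and
training correlations near 0.97. Everything is reproducible from the
config seed (Mersenne–Twister, recorded in the config).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: microarray technical artifacts, batch and
platform effects beyond structure scrambling, non-Gaussian expression,
probeset-level redundancy, non-linear genotype–response relationships, and
informative censoring. The generator validates the machinery, not the
biology.

# Numerical and design choices, in brief

* Duplicate feature ids on load collapse to the highest-mean row
  (warning); missing cells are mean-imputed up to 20% per feature, beyond
  which the feature is dropped (warning). Inputs are assumed normalized,
  log-scale; nothing is renormalized across samples.
* Feature matching across datasets is exact-string only.
* Expression writes use 17 significant digits, so write→read round-trips
  doubles exactly; score files likewise, which is what makes rerun
  byte-identity a meaningful contract.
* Degenerate statistics are never silently dropped: zero-variance features
  carry flags and p = 1 (or p = 0 for exact separation) through the
  tables.
* The CCEC returns 0 for the 0/0 case (both correlation vectors constant
  with equal means) and flags it.
* Ties: average ranks in Spearman and in the AUC; ties at the median go to
  the "low" stratum.
* Test sizes in the acceptance suite: 1,000 random pairs for the oracle
  equivalence, 200 global-null replicates, 20 recovery seeds, 10 ablation
  seeds with 200 validation patients — sizes at which the Monte-Carlo error
  of each summary is well inside the margin it is compared against, while
  the whole suite runs in well under a minute.

# Known limitations

* The CCEC significance test is an asymptotic stand-in chosen for
  determinism; the permutation option exists precisely because the
  statistic's exact null depends on the correlation structure of the
  candidate set.
* Homogeneous candidate sets (single tight module) defeat the CCEC, as
  discussed above; the pipeline's fallback chain makes the tool degrade
  gracefully rather than abort, at the cost of a weaker filter in that
  regime.
* Whether the forest should be refit after the importance filter, and
  which training correlation (in-sample vs out-of-bag) to headline, are
  genuinely open conventions; the package refits and reports both.
* No cross-platform identifier mapping, no normalization, no enrichment
  analysis: those belong to upstream/downstream tools.
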