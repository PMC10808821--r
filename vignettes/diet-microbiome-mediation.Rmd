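---
title: "Diet scores, the gut microbiome, and mediated adiposity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet scores, the gut microbiome, and mediated adiposity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amediate)
```

## The scientific question

Adherence to a Mediterranean-style dietary pattern is associated with lower
abdominal adiposity and lower systemic inflammation, and diet also shapes the
gut microbial community. `amediate` implements the analysis chain needed to
ask how much of a diet–outcome association is transmitted *through* the
microbiome: score diet adherence, identify taxa associated with both diet and
outcome, and decompose each diet–outcome association into an indirect
(through-taxon) part and a direct remainder.

The three inputs are participant covariates with outcomes (subcutaneous and
visceral abdominal adipose tissue volumes in litres, C-reactive protein in
mg/L), dietary intakes in g/d, and a samples-by-taxa table of 16S relative
abundances on the percent scale at one taxonomic rank.

## The aMed score

The Alternate Mediterranean Diet score sums nine binary components.
Vegetables, legumes, fruit, nuts, whole grains, fish, and the
monounsaturated:saturated fat ratio each score one point when intake is
strictly above the sex-specific cohort median; red and processed meat scores
one point when intake is strictly below its median; alcohol scores one point
inside a moderate window of 5–25 g/d. Totals run 0–9, higher meaning greater
adherence. Participants with implausible energy intakes (below 800 or above
6000 kcal/d) are excluded before medians are computed, and the exclusion
bounds themselves survive (the exclusion is strict, a literal reading of the
rule).

Three conventions here were genuinely open and are package design choices:

* **Strict inequalities.** Intake exactly at the median scores 0 in both
  directions. Ties are measure-zero for continuous FFQ-derived intakes, so
  this choice is essentially free, but it is applied consistently.
* **Closed alcohol window.** The 5 and 25 g/d endpoints both score the
  point. The window endpoints' inclusivity is not determined by the score's
  verbal definition; the closed interval is the package's reading and is
  configurable (`alcohol_window`).
* **Sex strata are male/female.** Menopausal status enters the models as a
  covariate level (male, premenopausal female, postmenopausal female) but
  does not split the median strata.

Tertiles of the total score are assigned within sex by ranking and cutting at
the empirical 1/3 and 2/3 quantile positions; scores tied at a boundary all
take the lower tertile. With heavily tied integer scores this produces
unequal tertile sizes — deterministically and independently of participant
order — which is the realistic behaviour for a 0–9 integer score.

When adiposity and CRP are observed on different subsamples (a common design:
imaging at one follow-up, bloods at another), medians, tertiles and all
models are recomputed within each outcome's subsample.

## Core measurable microbiota and community summaries

Per-taxon association screens are restricted to the *core measurable
microbiota*. The default filter drops a taxon when its relative abundance is
below 0.01% in at least 10% of samples. This literal rule is stricter than
the more common converse convention (keep a taxon observed at ≥ 0.01% in
≥ 10% of samples); both are implemented behind `rule =` in
`filter_core_microbiota()`, with the literal reading as default. The
discrepancy is documented rather than resolved: on realistic tables the two
rules differ only for taxa hovering at the threshold.

Shannon diversity and Bray–Curtis dissimilarity are computed on the
*unfiltered* table — the filter exists to stabilise per-taxon screens, not to
redefine the community — via vegan, with principal-coordinates analysis
(classical MDS) of the Bray–Curtis matrix. Negative PCoA eigenvalues are
truncated with a warning reporting the truncated mass; axis signs are fixed
so each axis's largest-magnitude coordinate is positive, making ordinations
reproducible across platforms.

## Covariate-adjusted models

"ANCOVA" here is ordinary least squares with categorical and continuous
covariates. All models adjust for sex/menopausal status, age, smoking status,
physical activity (MET/wk), supplement, hormone-therapy and corticosteroid
use, and energy intake; adiposity outcomes add height (m) and CRP adds BMI
(kg/m²). Two fits are made per tertile exposure: tertile entered
categorically for covariate-adjusted level means (evaluated at covariate
means and observed category proportions), and tertile entered numerically
(1/2/3) for the linear-trend coefficient and P-trend. Covariates that are
constant in an analysis subsample (e.g. an all-zero rare-medication flag in a
small stratum) are dropped with a note rather than producing a singular
design.

CRP is right-skewed: values below the assay limit of detection (0.9 mg/L by
default) are imputed as LOD/√2, the vector is natural-log transformed,
adjusted means are exponentiated back to geometric means, and trend
coefficients are reported as percent change, 100·(exp(β) − 1).

Taxa screens treat each taxon's abundance as the outcome of a diet-exposure
model (matching how abundance-by-tertile tables are usually presented), on
the raw percent scale; whether to log-transform abundances first is left as a
sensitivity option since per-tertile means are typically reported raw.
Benjamini–Hochberg q-values are computed across the taxa family only, with
significance at q < 0.25 — a deliberately liberal screening threshold, since
the screen feeds a mediation stage rather than a confirmatory claim. A taxon
becomes a mediation candidate for an outcome when it passes the diet screen
(q < 0.25) and its own association with that outcome has p < 0.05.

## The mediation decomposition

For a triple (exposure X, mediator M, outcome Y) with covariates W, two OLS
fits with the *same* covariate set:

* M ~ X + W gives the a-path;
* Y ~ X + M + W gives the b-path (mediator→outcome, exposure-adjusted) and
  the direct effect c′.

The indirect association is a·b, the total is a·b + c′, and the proportion
mediated is the signed ratio indirect/total in percent. In a linear,
interaction-free model with identical covariates in both fits, a·b + c′
equals the exposure coefficient from Y ~ X + W exactly — the
product-of-coefficients and difference-of-coefficients estimators coincide —
and the package tests enforce this identity to 1e-8 on every fit.

Design choices:

* **Continuous exposure.** The mediation exposure is the 0–9 aMed total (or
  a 0/1 component exposure) rather than the tertile label: a path model on an
  ordinal trend is most natural continuous, and the proportion mediated is
  invariant to affine recoding of the exposure anyway.
* **Signed proportions.** Proportions below 0% or above 100% (inconsistent
  mediation/suppression) are reported as-is with an `outside_range` flag,
  never truncated; a total association below tolerance yields `NA` with an
  `undefined` flag rather than a near-infinite ratio.
* **Percentile bootstrap CI.** Participants are resampled (default 1000
  draws, seeded), the proportion recomputed per draw, and the 2.5/97.5
  percentiles reported. The bootstrap is the default because the proportion
  is a ratio whose normal-theory variance is unreliable near small totals;
  resamples whose total falls below tolerance are dropped and counted.
* **Combined mediator.** Candidate taxa for an outcome are standardized and
  combined by the first principal component of their correlation matrix
  (sign fixed so the largest-magnitude loading is positive); the PCA score
  then enters the same mediation machinery, with the component's variance
  explained reported alongside.

## The synthetic cohort generator

No individual-level cohort of this kind is publicly deposited, so the
package ships a generator whose cohorts have the exact statistical structure
the analysis assumes, with known ground truth:

* **Covariates** are drawn from ranges typical of a middle-aged European
  community cohort: age uniform on 25–83 y, 41% female (72% of females
  postmenopausal), smoking 50/38/12% never/former/current, activity
  lognormal around 105 MET/wk, supplement use 40%, and sex-specific heights.
* **Intakes** are lognormal with means and SDs typical of such a cohort
  (e.g. vegetables 201 ± 93 g/d, red meat 107 ± 69 g/d, energy 2295 ± 679
  kcal/d), all driven by a single latent diet-quality factor: favorable
  components load +0.45 on it, red meat −0.45, alcohol and energy 0 (the
  alcohol point is non-monotone in intake, so a linear loading would be
  wrong). A configurable fraction of participants (default 1%) receives
  implausible energy values to exercise the exclusion stage.
* **The exposure is the recomputed score.** The mediation ground truth is
  defined against the aMed total computed *post hoc* from the generated
  intakes (standardized), not against the latent factor — because the
  analysis's exposure is the derived score, the truth must be too.
* **Mediators and taxa.** Each designated mediator taxon follows
  M = a·X + ε with ε ~ N(0, `noise_sd_mediator`); its relative abundance is
  an affine map of M (base share × (1 + 0.25·M), floored at 5% of base).
  Non-mediator taxa are logistic-normal (log-scale SD 0.6) around a
  geometrically decaying base profile and are rescaled so every sample
  closes at exactly 100%. Making the mediator's abundance affine in M (and
  closing the composition through the *other* taxa) keeps the pipeline's
  observed mediator an essentially exact linear image of the structural one,
  so the estimable proportion equals the configured truth; a fully
  logistic-normal mediator would attenuate the recoverable proportion
  through closure noise.
* **Outcomes.** A shared structural term c·X + Σ bⱼMⱼ plus small sex and age
  effects and N(0, `noise_sd_outcome`) noise is drawn independently per
  outcome and mapped affinely to realistic scales (SAT around 6.9 L, VAT
  around 4.1 L); CRP is generated on the log scale (so the percent-change
  back-transform is exact in expectation) with roughly 15% of values falling
  below the 0.9 mg/L LOD. The proportion mediated is invariant to affine
  maps of exposure, mediator and outcome, so the ground truth for mediator j
  is aⱼbⱼ/(c + Σₖ aₖbₖ), reducing to a·b/(a·b + c) for a single mediator.

What the generator does *not* emulate: 16S read counts, sequencing error,
rarefaction, zero-inflation beyond what the logistic-normal tail produces,
non-linear diet–taxon dose response, and exposure–mediator interaction.
Passing recovery tests therefore show the estimator is correct *for the
linear, interaction-free data-generating process it assumes* — they cannot
certify behaviour on real compositions with structural zeros.

## Numerical and testing choices

All randomness flows through explicit seeds (`with_seed` restores global RNG
state); reruns with identical seed and configuration produce byte-identical
report files. Validation failures raise classed conditions naming the
offending columns or samples. The test suite checks the scoring rules
against hand-scored participants, every standard transform against its
closed form, OLS/BH/PCoA against hand-rolled normal-equation, brute-force
and dense-eigendecomposition oracles, and parameter recovery at n = 600 over
20 seeds for true proportions of 0, 10, 20 and 50% (the mean estimate sits
within ±5 percentage points of truth in all four cases; recovery SD grows as
the direct effect shrinks, reaching ~9 points at a true proportion of 50%).
The bootstrap coverage check runs at reduced scale (n = 300, 200 draws, 20
replicates) to keep the suite fast; problem sizes throughout the tests
(n = 120–600) were chosen as the smallest at which the stochastic checks are
stable.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_participants = 620, seed = 7)
cohort <- generate_cohort(cfg)     # truth: 20% mediated via Family05
res <- run_pipeline(cohort, config = pipeline_config(boot = 200, seed = 7),
                    out_dir = "reports")
print(res)
```

The printed result lists, per outcome, the adjusted tertile trend, the taxa
passing the diet screen, the selected mediator candidates, and each
candidate's proportion mediated — for the configuration above, the true
mediator is flagged for all three outcomes with estimates near the 20%
truth.

## Known limitations

* The mediation model is linear and interaction-free by design; natural
  direct/indirect effects under exposure–mediator interaction are out of
  scope.
* Cross-sectional mediation cannot establish causal direction; the
  decomposition quantifies association routing, not causation.
* Raw-scale abundance modelling ignores compositional constraints; the
  log-transform sensitivity switch mitigates but does not remove this.
* The proportion mediated is unstable when the total association is small;
  the `undefined` flag and bootstrap CIs surface, but do not cure, this.
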