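---
title: "Symptom networks from sparse panels: methods and design choices"
author: "panelDTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks from sparse panels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelDTW)
```

## The problem

Depressive and anxiety disorders overlap heavily in symptoms and comorbidity,
and their individual symptoms need not move in lockstep: one symptom may lead
or lag another across years. Cohort panels that assess symptom questionnaires
only every few years (here: 30 IDS depression items and 21 BAI anxiety items
scored 0–3, 11 short-form PSWQ worry items scored 0–4, at up to five
assessments spread over nine years) are too sparse for vector-autoregressive
or cross-lagged models. Dynamic time warping (DTW) sidesteps their
stationarity and linearity assumptions: it scores each item *pair* within
each participant by the minimum cost of aligning the two short score
trajectories, allowing limited temporal shifts. Items with similar dynamics
get small distances; aggregating the per-participant distance matrices gives
a group-level symptom network and a scalar *network density* per participant,
which can then be related to diagnosis and to the stability of disease states
over follow-up.

## The warping engine

For two equal-length series $a, b$ (a participant's standardized scores of
two items over their $T \in \{4, 5\}$ complete waves) the local cost matrix
is $c_{ij} = |a_i - b_j|$. The accumulated cost follows the canonical
**symmetric2** step pattern,

$$D(i,j) = \min\big\{ D(i-1,j) + c_{ij},\; D(i-1,j-1) + 2c_{ij},\;
D(i,j-1) + c_{ij} \big\}, \qquad D(1,1) = 2c_{11},$$

restricted to the **Sakoe–Chiba band** $|i-j| \le 1$: scores may be matched
to at most one assessment earlier or later. With assessments two to three
years apart, a wider band could align observations many years apart, so the
band is expressed in assessment indices, not years; wave times are carried
as metadata only. The reported distance is $D(T,T)/(T_a + T_b)$. Because the
symmetric2 weights along any admissible path sum to $T_a + T_b$, this
normalization makes distances directly comparable between 4-wave and 5-wave
participants — both are used at their native length, never padded — and the
whole construction is symmetric in $a$ and $b$.

Design points worth making explicit:

* **Local cost metric.** Absolute difference of the two scalar z-scores, the
  univariate default in the DTW literature; squared difference is available
  via `metric = "squared"` but is not the default.
* **Ties.** Equal-cost predecessors are resolved diagonal-first, then
  vertical, then horizontal. This fixes the reported path; the distance is
  unaffected.
* **Correctness.** The dynamic program is checked against an independent
  brute-force enumeration of all band-admissible monotone paths
  (`bruteForceDTW`), feasible because $T \le 5$; the compiled all-pairs
  kernel is in turn checked against the pure-R reference implementation.

## From scores to distances

Scores are **group-level standardized** per item (pooled over all retained
participants and their complete waves, sample-SD denominator) after the
inclusion rule is applied: a wave counts only if all 62 items are observed,
and participants need at least four complete waves. Incomplete waves are
dropped wholly, never imputed. Items with zero pooled variance are mapped to
$z = 0$ and flagged rather than dropped, so every participant always yields
the same $(62^2 - 62)/2 = 1891$ pair distances. Raw per-participant item
means are recorded *before* standardization; they become adjustment
covariates downstream, because an item pair that simply stays near zero
produces a deceptively small distance.

## Networks, edges, density

**Edge filter.** An edge is drawn between two items when their mean distance
across participants is significantly *smaller* than that of all remaining
pairs (one-sided, default $\alpha = 10^{-4}$, uncorrected — Bonferroni and
Benjamini–Hochberg are options). Two test modes exist: a Welch t-test of the
focal pair's distances against all remaining distances, and the default
*adjusted* mode — a linear model of distance on the focal-pair indicator
with participant intercepts absorbed and a quadratic polynomial in the
pair's mean raw score as covariate. The quadratic term matters: near the
response floor the distance-versus-score-level relation is curved, and with
a linear term alone the null significant-edge rate runs about ten percent
above its nominal level in calibration simulations, while the quadratic
adjustment restores it. Because every participant contributes every pair (a balanced
panel), the absorbed-intercept (within) estimator coincides with the
fixed-effect contrast of a random-intercept mixed model; all 1,891 models
share their nuisance projections, so the whole family is computed in closed
form via Frisch–Waugh in milliseconds, where per-pair mixed-model fits would
be prohibitive. An explicit `engine = "lmer"` path exists and is
cross-checked in the tests, as is the exact equality of the closed form with
`lm(distance ~ focal + covariate + factor(participant))`. The ambiguous
phrase "adjusted for the average score of each item and each participant
separately" admits a second covariate coding — item-membership main effects
— which is implemented as `edgeAdjust = "item_indicators"`; the pair-mean
coding is the default and the choice is recorded in the output attributes.

**Centrality** of an item is the inverted mean distance to its connected
(significant) neighbours; isolated items are flagged and placed at the
bottom of the inverted scale. A z-standardized centrality is returned for
ranked bar plots.

**Density** is the inverse of the mean of all 1,891 distances per
participant. "Inverse" is implemented as the linear inversion
$\mathrm{shift} - \bar d$ (default shift 2) with the reciprocal
$1/\bar d$ as an option: group contrasts and the quadratic regression below
are invariant to the affine choice, the reciprocal is not, and the tests pin
this invariance down. Group densities are adjusted for mean symptom severity
(default: grand mean of all standardized items; per-instrument sum scores
optional), age, sex and education. With one density record per participant
the random-intercept model reduces to an ordinary linear model; adjusted
means and pairwise contrasts come from `emmeans`.

**Fixed layout.** The whole-group network fixes a seeded
Fruchterman–Reingold node placement and the edge-effect range; subgroup
networks inherit both bit-identically, so only edge width carries
association strength in subgroup plots.

## Disease-state stability

The stability score counts, over the five diagnostic assessments (the
baseline interview covering lifetime-before-inclusion, plus four follow-up
intervals), how often an anxiety and/or depressive diagnosis was present:
0–5, a count, deliberately insensitive to the order of assessments. Score 0
defines the controls; 0–1 is read as stable health, 2–3 as unstable, 4–5 as
stable disease. The density–stability analysis follows the literal two-step
procedure: residualize density on severity, age, sex and education, then
regress the residuals on the score with linear and quadratic terms (a joint
single model is available via `twoStep = FALSE`; the two differ slightly and
the two-step form is the default because it is the procedure being
replicated). A negative quadratic coefficient indicates an inverted U:
density peaks at unstable mid-range scores.

## The synthetic cohort generator

Real panels of this kind are access-restricted, so the generator is a
first-class module: it fixes the generating conditions under which every claim in
the test suite is evaluated.

* **Structure.** Four subgroups with sizes 72 / 32 / 53 / 173 (a large
  depression-anxiety cohort's 360 / 158 / 265 / 866, scaled by one fifth), five waves at years
  0/2/4/6/9, the 62-item catalog. Roughly a quarter of participants miss one
  follow-up wave, yielding genuine 4-wave cases.
* **Dynamics.** A shared per-participant symptom state and five latent
  factors (sleep, mood, somatic arousal, cognitive anxiety, worry) evolve as
  stationary AR(1) processes across waves ($\phi = 0.5$ and $0.4$). Each
  factor is coupled to the shared state with subgroup-specific strength
  $\rho$ (defaults 0.05 / 0.55 / 0.60 / 0.85 for controls / AD / MDD /
  comorbid): stronger coupling means items co-move more, shrinking DTW
  distances and raising density. PSWQ items carry loading 1.25 versus 1.0
  elsewhere, so worry items cluster most tightly.
* **Scores.** Item value = loading × factor + item noise (SD 0.8) + subgroup
  severity offset (0 / 0.20 / 0.25 / 0.50), with a baseline boost of 0.35
  producing the initial post-baseline drop; affinely mapped onto each item's
  Likert range, rounded and clipped. Fixed-threshold discretization (rather
  than probit sampling) keeps generation fast and fully deterministic under
  its seed.
* **Diagnoses.** Per-disorder Markov chains over assessments (persist /
  relapse defaults 0.6/0.3 for single disorders, 0.8/0.5 comorbid) with the
  baseline flag encoding lifetime diagnosis; subgroup membership and flags
  are generated consistently (controls never flagged, single-disorder groups
  never carry the other diagnosis).
* **Covariates.** Age $\sim N(41.5, 13.2^2)$ truncated to 18–65, 66.4%
  female, education 3.3/55.4/41.3% — marginals typical of such cohorts.
* **Scenarios.** `independentItemsConfig()` (every item its own factor,
  zero coupling) is the null for type-I-error calibration;
  `clusterScenarioConfig()` plants one coupled cluster whose first item, the
  hub, has reduced item noise (0.4) — tracking the factor most faithfully
  while keeping its marginal score distribution comparable — so the true
  network and its most central node are known; `makeStabilityScenario()`
  draws stability scores from a realistic 0–5 marginal and sets each
  participant's coupling from a target density-by-score profile (default an
  inverted U peaking at score 3).

Severity offsets deserve a note. Strongly floor-limited controls (almost all
zeros) produce *artificially small* DTW distances — flat series align
perfectly — which is precisely why the edge test adjusts for raw item means.
A linear severity adjustment cannot fully remove this nonlinear
discretization artifact at the density level, so the default control offset
keeps floor effects moderate; with a strong floor the artifact can dominate
the coupling signal, which is a real caveat for low-severity groups in data
of this kind, not just in simulation. For the same reason the "flat" null of
the stability scenario sets the severity-by-score slope to zero: with a
severity gradient but flat coupling, residual discretization curvature leaks
into the quadratic term even though coupling is constant.

What the generator does **not** emulate: item-specific content (appetite
versus suicidality behave identically up to their factor), measurement-model
misfit, informative dropout, treatment effects, or calibrated prevalences.
Passing recovery tests therefore demonstrates that the pipeline recovers the
statistical structure it assumes, not that the substantive findings
generalize.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 null cohorts of 300
participants × 20 items for calibration (significant-edge fraction compared
with the 99% binomial band around the nominal level); 15 clustered cohorts
of n = 500 for power, false-positive and hub-recovery checks; 50 subgroup
cohorts (n = 330) for the density ordering; 100 stability scenarios of
n = 800 for the quadratic shape. These sizes give stable Monte-Carlo
estimates while a full run stays in the minutes range on one CPU; the DTW
kernel is compiled C++ (a 62-item participant costs ~0.2 ms). Degenerate
inputs are handled explicitly rather than silently: zero-variance items map
to z = 0 with a warning, constant distance tables yield p = 1 and a
`zeroVariance` flag, groups with fewer than two participants are dropped
from density models with a warning, collinear covariates abort with the
offending column named, and fewer than three distinct stability scores
refuse a quadratic fit.

## Known limitations

* With 4–5 points per series, DTW distances are coarse; the band of one
  assessment is the only warping freedom, and no guidance exists on optimal
  band width for multi-year gaps.
* The edge test treats pair distances within a participant as exchangeable
  after absorbing the participant mean and the raw-score covariate; shared
  items induce residual dependence between pairs, which the calibration
  check bounds empirically but which is not modeled.
* Network density depends on the item set: adding a tightly clustering
  instrument (like the worry items here) raises density mechanically.
* The linear severity adjustment leaves nonlinear floor-effect artifacts in
  extreme low-severity groups, as discussed above.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  simulate = cohortConfig(nPerGroup = c(control = 20, AD = 10,
                                        MDD = 15, comorbid = 40)),
  alpha = 1e-4, groupBy = "diagnosis", seed = 11)
res <- runPipeline(cfg, outDir = "panelDTW_run")
res$network                 # whole-group SymptomNetwork
res$density$estimate        # adjusted density per subgroup
res$density$quadratic       # density ~ stability (linear + quadratic)
```
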