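# panelDTW

Symptom networks from **sparse longitudinal panels** via dynamic time
warping (DTW).

Depressive and anxiety disorders overlap in symptoms and comorbidity, and
individual symptoms need not covary simultaneously — one can lead or lag
another across years. In cohort panels where questionnaires (30 IDS
depression items and 21 BAI anxiety items scored 0–3, 11 short-PSWQ worry
items scored 0–4) are assessed only 4–5 times over ~9 years, standard
time-series network models are not identifiable. `panelDTW` instead scores
each of the (62² − 62)/2 = 1,891 item pairs *within each participant* by a
shape-based warping distance, aggregates these per-participant distance
matrices into group-level symptom networks, and relates covariate-adjusted
**network density** to diagnostic subgroup (controls, anxiety-only,
depression-only, comorbid) and to a 0–5 **disease-state stability score**.

The core distance is symmetric2 DTW under a Sakoe–Chiba band of one
assessment:

$$D(i,j) = \min\{D(i-1,j) + c_{ij},\ D(i-1,j-1) + 2c_{ij},\ D(i,j-1) + c_{ij}\},
\quad D(1,1) = 2c_{11},\quad |i-j| \le 1,$$

with $c_{ij} = |a_i - b_j|$ on group-standardized scores and final
normalization by $T_a + T_b$, so 4-wave and 5-wave participants are on one
scale. Edges are kept when a pair's mean distance is significantly smaller
than that of all remaining pairs (default α = 1e-4), adjusted for raw
item-score levels and participant effects; density is the inverse of the
mean pairwise distance, adjusted for severity, age, sex and education; the
density–stability relation is fit with linear + quadratic terms on
covariate residuals. A seeded synthetic-cohort generator with known
latent-factor ground truth (a first-class module) makes every stage
testable: type-I-error calibration, edge-detection power, hub centrality,
density ordering and quadratic-shape recovery.

## Worked example

```r
library(panelDTW)

sim <- simulateCohort(cohortConfig(), seed = 42)   # 330 participants, 62 items
sp  <- standardize(sim$panel)
sim$panel
#> class: SymptomPanel
#> items: 62  assessments: 1558
#> participants: 330  (excluded: 0 )
#> complete waves per participant: 92 x 4, 238 x 5

d <- cohortDistances(sp)          # 330 x 1891 pair distances, long format
e <- testEdges(d, alpha = 1e-4)   # focal pair vs all remaining pairs
sum(e$significant)
#> [1] 460

head(itemCentrality(e)[order(-itemCentrality(e)$centrality), ], 3)
#>    item centrality zCentrality nNeighbors
#>  PSWQ06   1.609638    2.367384         10
#>  PSWQ03   1.608460    2.309047         10
#>  PSWQ05   1.606083    2.191387         10
```

The worry (PSWQ) items emerge as the most central — they load most tightly
on one latent factor in the generator, so their trajectories covary most.

```r
dens <- invertDistance(participantMeanDistances(sp))
cov  <- merge(covariates(sim$panel), meanSeverity(sp), by = "participant")
prof <- stabilityScore(sim$panel)
networkDensity(dens, setNames(as.character(prof$subgroup),
                              prof$participant), cov)
#> Adjusted network density by group:
#>     group adjustedDensity       se  df   n
#>   AD_only           1.377 0.014704 322  32
#>  comorbid           1.466 0.006605 322 173
#>   control           1.344 0.010078 322  72
#>  MDD_only           1.403 0.011469 322  53
```

Adjusted density recovers the generating order: controls lowest, the
comorbid group highest (its pairwise contrasts against all other groups are
significant). On the inverted-U stability scenario, the quadratic term is
recovered as negative — density peaks at unstable mid-range scores:

```r
scn  <- makeStabilityScenario(n = 800, seed = 7)
sp2  <- standardize(scn$panel)
dens <- invertDistance(participantMeanDistances(sp2))
cov2 <- merge(covariates(scn$panel), meanSeverity(sp2), by = "participant")
densityVsStability(dens, data.frame(participant = scn$truth$participant,
                                    score = scn$truth$score), cov2)
#> Density ~ stability score (linear + quadratic):
#>   beta linear    =   0.0615 (p = 1.17e-24)
#>   beta quadratic =  -0.0117 (p = 4.16e-22)
```

`runPipeline(pipelineConfig(simulate = cohortConfig(), seed = 1), outDir)`
executes the whole chain (load/simulate → standardize → distances → edges,
centrality, fixed-layout networks → adjusted densities → stability
regression) and writes tables, GraphML/JSON network exports and a manifest
with file checksums.

## Package layout

* `R/` — S4 containers (`SymptomPanel`, `StandardizedPanel` extending
  `SummarizedExperiment`; `SymptomNetwork`), the DTW engine, distance
  pipeline, edge/centrality/density statistics, stability analysis, the
  cohort generator and the pipeline driver.
* `src/` — compiled all-pairs DTW kernel (Rcpp).
* `vignettes/dtw-symptom-networks.Rmd` — model, assumptions, parameter
  choices, generator design and limitations.
* `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
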