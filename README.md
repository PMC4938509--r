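# beescape

Pollinator communities, pollen limitation and the economic value of insect
pollination in highbush blueberry field studies.

Commercial highbush blueberry (*Vaccinium corymbosum*) depends on insect
pollination, and growers in different regions rely on very different
pollinator communities — from heavily stocked honey bees beside
species-poor wild-bee faunas to diverse communities of wild bees. Field
studies of this system combine four kinds of evidence: timed
flower-visitor counts along in-field transects, netted specimens
identified to species, cluster-level pollination experiments (pollinator
exclusion vs open pollination vs hand-supplemented pollen), and tabulated
land cover around each field. `beescape` turns that whole design into a
tested, reproducible pipeline for R: data validation, diversity
estimation, community ordination, visitor-abundance modelling, pollen
limitation analysis, and a yield-and-valuation model — plus a synthetic
generator with known ground truth so every stage can be verified without
field data.

## What it computes

* **Diversity** — observed richness, classic Chao-1
  (`S_obs + f1²/(2 f2)`, with the `f2 = 0` fallback), Shannon–Wiener H
  (nats), sample-based rarefaction with permutation envelopes, and
  between-region tests (Welch t, Mann–Whitney).
* **Composition** — Bray–Curtis dissimilarity, non-metric
  multidimensional scaling (Kruskal stress-1, restarts from a
  classical-scaling start), environmental vector fitting with permutation
  p-values, PERMANOVA (`p = (1 + #{F* ≥ F}) / (1 + n_perm)`).
* **Abundance models** — NB2 negative-binomial GLMMs of visitor-group
  counts with date and time-block random intercepts, collinearity
  screening, land-use radius selection, all-subsets candidate sets,
  `AICc = −2 logL + 2k + 2k(k+1)/(n−k−1)`, Akaike weights, and full model
  averaging with unconditional SEs.
* **Pollination** — fruit set, cluster→bush→field treatment summaries,
  pollinator contribution (open − excluded) and pollination deficit
  (hand − open), Kruskal–Wallis and exact Mann–Whitney contrasts with
  compact letters, and the seed-effect vs weight-effect ANCOVA.
* **Economics** — berries/ha from yield components, then per field
  (weights in grams, yields in kg/ha)

  ```
  Yield = B · W_o / 1000
  Y_p   = (B · W_o − B · (FS_e / FS_o) · W_e) / 1000      # yield due to pollination
  Y_d   = (B · (FS_s / FS_o) · W_s − B · W_o) / 1000      # unrealized yield
  ```

  valued at farm-gate prices, with region means ± SE and the proportion of
  maximum yield currently achieved, `Yield / (Yield + Y_d)`.

## Worked example

```r
library(beescape)

sim <- simulateStudy(simulationConfig(), seed = 2013)
sim$study
#> StudyBundle: 34 fields ( BC: 17, MI: 17 )
#>   surveys:  340 timed counts
#>   specimens: 80 species, 999 individuals
#>   clusters: 4080 treatment clusters; berries: 4430
#>   landscape: 612 cover-class areas

ds <- diversityStats(sim$study)
subset(ds, unit == "region")[, c("id", "S_obs", "f1", "f2",
                                 "chao1_rounded", "shannon")]
#>  id S_obs f1 f2 chao1_rounded  shannon
#>  BC    11  0  0            11 2.095048
#>  MI    69 10  9            75 3.657072

eco <- runPipeline(sim$study, stages = "economics", seed = 2013)$economics
#>  region yield    Yp   Yd prop_max crop_value prop_increase
#>      BC 13280  5703 4844     0.73      43824          0.36
#>      MI 14380 10518  772     0.95      40840          0.05
```

Reading: the species-poor BC community pools to an estimated 11 species
(no singletons — the fauna is saturated) against ~75 in MI. In BC, open
pollination yields about 13.3 t/ha worth ~$43.8k/ha, of which ~5.7 t/ha is
attributable to insect pollination; hand supplementation shows a further
4.8 t/ha unrealized, i.e. fields achieve ~73% of their pollination-limited
maximum and could raise crop value ~36% with full pollination. MI fields
are close to saturation (95%). These synthetic defaults are calibrated to
the published regional magnitudes, so a correct pipeline reproduces this
contrast.

Other stages: `runPipeline(study, stages = c("diversity", "composition",
"glmm", "pollination"))`, or call the pieces directly (`chao1()`,
`brayCurtis()`, `nmdsOrdination()`, `permanovaTest()`, `fitNbGlmm()`,
`rankAndAverage()`, `summarizeTreatments()`, `economicSummary()`, ...).
A thin CLI lives in `inst/scripts/pollpipe` (`pollpipe simulate`,
`pollpipe run`). Studies on disk are seven plain CSV tables read with
`readStudy()` and written with `writeStudy()`.

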