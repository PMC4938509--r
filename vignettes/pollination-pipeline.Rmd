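---
title: "Methods: pollinator communities, pollen limitation and the value of pollination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollinator communities, pollen limitation and the value of pollination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beescape)
```

# The study system and the data model

beescape analyses two-region field studies of insect pollination in
commercial highbush blueberry (*Vaccinium corymbosum*). The design it
expects — and that its generator emulates — is 17 fields per region
(British Columbia, a species-poor, bumble-bee-dominated system with heavy
honey-bee stocking, and Michigan, a species-rich system), each field
carrying four transects at 0, 25, 50 and 100 m from a semi-natural border.
Every field is visited 2 (BC) or 3 (MI) times; each visit yields one
10-minute timed count of flower visitors per transect in four groups
(honey bees, bumble bees, other bees, other flower visitors) and netted
specimens identified to species (honey bees excluded by design). On every
bush of a transect, three flower clusters receive one pollination
treatment each: pollinator exclusion (bagged through bloom), open
pollination, or open plus hand-applied supplemental pollen. Land cover
around each field is tabulated as class areas within 300, 1000 and 2000 m
radii; the pipeline consumes these tables, never imagery.

All tables live in a validated S4 container, `StudyBundle`. Validity
enforces the design invariants (unique field ids, referential integrity,
known factor levels, 10-minute durations, `n_fruit <= n_flowers`, a
honey-bee-free specimen matrix), so every downstream stage can assume a
clean study. Units are fixed at ingestion: grams for berry and cluster
weights, square metres for areas, metres for distances, kg/ha for yields,
dollars per kg for prices. Dates are ISO-8601; time of day enters as a
three-level block (morning, midday, afternoon), a deliberately coarse
categorical so it can serve as a random-effect grouping.

# Diversity

Per field (transects and visits pooled) and per region (fields pooled) the
pipeline reports observed richness, singletons and doubletons, the classic
Chao-1 lower bound

$$\hat S = S_{obs} + \frac{f_1^2}{2 f_2},$$

with the fallback $S_{obs} + f_1(f_1-1)/2$ when $f_2 = 0$, and
Shannon–Wiener $H = -\sum p_i \ln p_i$ in nats. The natural log is the
convention in the community-ecology literature this estimator family comes
from; the uncorrected Chao-1 is used because the bias-corrected variant is
a different estimator and the choice matters exactly when $f_2 = 0$. Both
choices are frozen here; the bias-corrected variant is deliberately out of
scope rather than switchable, to keep reported richness comparable across
runs.

Regional accumulation curves are sample-based (site-order) rarefaction:
mean and SD of cumulative richness over 999 random site orderings
(seeded), envelope mean ± 2 SD. An exhaustive mode enumerates all
orderings for up to 7 sites and is used in tests against the analytic
expectation. Regions are compared with a Welch t on per-field observed
richness and two-sided Mann–Whitney tests on Chao-1 and $H$ (exact when
group sizes allow and ties are absent).

# Composition

Bray–Curtis dissimilarity $d(x,y) = \sum|x_i-y_i| / \sum(x_i+y_i)$ is
computed on per-field pooled counts, untransformed by default — square-root
and Wisconsin options exist because no transformation is canonical for
these data. NMDS (global model, Kruskal stress-1, monotone regression via
vegan's engine) runs from a classical-scaling start plus random restarts,
keeps the best solution, and returns a centred, principal-axis-rotated
configuration. Environmental vectors (the semi-natural proportion at each
radius) are fitted by least squares on the ordination axes with a
permutation p-value. PERMANOVA partitions the squared dissimilarities
(Gower-centred identity $SS_T = \sum_{i<j} d_{ij}^2/n$) between regions;
p-values use free permutation of rows, upper tail,
$p = (1 + \#\{F^{perm} \ge F\})/(1 + n_{perm})$, so $p \ge 1/(n_{perm}+1)$
always. The PERMANOVA, vector fitting, Bray–Curtis and rarefaction are
implemented in-package and cross-checked in the test suite against vegan
(`adonis2`, `envfit`, `vegdist`, `specaccum`) as independent oracles.

# Visitor-abundance models

Counts per transect-visit are modelled with NB2 negative-binomial GLMMs
(log link; Laplace-approximated marginal likelihood via glmmTMB) with
normal random intercepts for sample date and time block. Candidate fixed
effects: distance (categorical, 0 m reference), the semi-natural
proportion at one radius, row orientation, other visitor groups, and — for
the honey-bee response only — hive stocking rate, which stays in the
candidate list regardless of the collinearity screen. Pairs of candidates
with $|r| \ge 0.6$ (dummy-coded for categoricals; threshold configurable,
as the source convention reports screening without a numeric bound) are
never co-included. The land-use radius is chosen by preliminary
single-predictor AICc. The candidate set is all admissible subsets plus
the null (random-effects-only) model; a distance-by-land-use interaction
model is added only where both mains are present.

Ranking uses
$AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)$ with $n$ = transect-visits (136
in a BC-design region, 204 in MI) and $k$ = fixed effects + NB dispersion
+ one variance per random term (`attr(logLik, "df")`). Akaike weights are
computed over all converged fits; models within 2 AICc units of the best
are flagged as substantially supported. Coefficients are full model
averages: a term absent from a model contributes estimate 0 with zero
variance; the unconditional SE is the revised Burnham–Anderson form
$\sqrt{\sum_i w_i\,(\mathrm{var}_i + (\hat\beta_i - \bar\beta)^2)}$, with
$z = |\bar\beta|/SE$ and two-sided normal p. Non-convergent fits are
logged and dropped, never imputed; AICc ties break by smaller $k$, then
label.

# Pollination treatments

Fruit set is fruit over flowers per cluster. Aggregation is strictly
cluster → bush → field, each level an unweighted mean of the one below, so
bushes with unequal cluster numbers carry equal weight; the order is
idempotent when levels are singletons. Mean berry weight prefers focal
berries (three individually weighed, seed-counted berries per cluster on
four subsampled bushes per transect) and falls back to cluster weight over
fruit count; seed counts come from focal berries only and are missing —
never zero — where no berries were subsampled.

The pollinator contribution is open − excluded and the pollination deficit
is hand − open, per field, for fruit set, berry weight and seeds; negative
values are sampling noise and are retained at field level. Contrasts use
Kruskal–Wallis with tie correction, then pairwise two-sided Mann–Whitney
(exact when the smaller group has ≤ 8 values and no ties; normal
approximation with continuity and tie correction otherwise), summarised by
a Tukey-style compact letter display of the pairwise decisions at
$\alpha = 0.05$. Pairwise-Mann–Whitney-plus-letters is an unusual hybrid;
it is retained as the primary path because it is the procedure this study
family reports, and a Dunn-style Holm-adjusted variant sits behind
`adjust = "holm"` for users who prefer a conventional correction. A
Shapiro–Wilk screen may be reported but never reroutes the analysis: the
contrasts are rank-based regardless.

The seed–weight ANCOVA relates the per-field weight effect to the seed
effect with `weight ~ seeds * region`; the interaction F tests slope
homogeneity, and the additive model supplies the common slope and
per-region intercepts. An exactly collinear configuration is reported as
interaction F = 0, not a 0/0 artefact. Note one caveat: per-field seed
effects are themselves estimated from a dozen berries, and this
error-in-x attenuates the fitted slope below the generating berry-level
slope — visible in the synthetic runs and expected in field data too.

# Economics

With $B$ berries/ha (the product of bushes/ha — derived from bush and row
spacing when not given directly — canes/bush, clusters/cane,
berries/cluster), fruit sets $FS$ and berry weights $W$ (g) per treatment
(e excluded, o open, s hand-supplemented):

$$\mathrm{Yield} = B\,W_o/1000, \qquad
  Y_p = (B\,W_o - B\,(FS_e/FS_o)\,W_e)/1000, \qquad
  Y_d = (B\,(FS_s/FS_o)\,W_s - B\,W_o)/1000$$

in kg/ha (the grams-to-kilograms factor is made explicit here; the source
equations leave it implicit). $\mathrm{Yield} + Y_d$ equals the
hand-supplemented yield exactly, an identity the tests assert. Valuation
multiplies by the field's farm-gate price: crop value, pollination value
($Y_p \cdot p$), potential increase ($Y_d \cdot p$), proportion of maximum
yield achieved $\mathrm{Yield}/(\mathrm{Yield}+Y_d)$, and proportional
increase. Region summaries are means ± SE over fields, computed
per-field-first (region means of per-field products, not products of
region means — both differ and the per-field path is the primary output).
Negative $Y_p$ or $Y_d$ stay raw in per-field tables and are floored at
zero only in the region summary, with a count of floored fields so the
information loss is visible.

# The synthetic generator

`simulateStudy()` draws a complete study under the design above with known
ground truth, so every stage has a test surface with a right answer. What
it emulates, and what it does not:

* **Landscape.** Semi-natural proportions per radius from a Gaussian
  copula: cross-radius correlation ~0 in BC, 0.8 in MI; BC means low
  (0.08–0.20), MI high (0.45–0.55). Proportions expand into cover-class
  areas over $\pi r^2$. No spatial autocorrelation between neighbouring
  fields.
* **Visitation.** NB2 counts on a log link with date and time-block random
  intercepts (SD 0.3 and 0.15), dispersion $\theta = 1.5$. Default
  coefficients are order-of-magnitude analogues of published
  model-averaged estimates for this system (e.g. wild-bee land-use slopes
  4–5 at the region's operative radius, BC at 2000 m and MI at 300 m; MI
  honey-bee intercept ~2.5; distance declines for MI wild bees; a positive
  perpendicular-row effect), not fitted values — the source reports
  coefficients, not raw count distributions, so $\theta$ and the
  intercepts are assumptions and are documented as such.
* **Communities.** Species weights from a Fisher log-series per region —
  BC: pool 11, $x = 0.5$ (few, dominant species); MI: pool 72, $x = 0.95$
  (many, mostly rare) — sampled multinomially at ~24–36 netted specimens
  per field. These pools put the pooled Chao-1 estimates near the
  published 11 (BC) and 71 (MI) and give MI a realistic singleton tail.
* **Treatments.** Fruit set binomial per cluster; mature seeds Poisson per
  berry; berry weight $= 1.44 + 0.04 \cdot \mathrm{seeds} + N(0, 0.15)$ g,
  floored at 0.01 g. The hand treatment is the open treatment shifted by a
  per-region deficit (BC: +0.08 fruit set, +11 seeds; MI: +0.03, +1), so a
  zero deficit makes hand and open exchangeable by construction. The
  defaults were set from the published summary magnitudes — a ~22% berry
  weight and ~79% seed gain under supplementation in BC, little gain in
  MI, open yields of 12–14 t/ha, proportions of maximum yield near 0.74
  (BC) and 0.94 (MI) — and reproduce those magnitudes in expectation. One
  published feature the weight law does not reproduce: a positive
  intercept (~0.48 g) in the seed-effect-vs-weight-effect regression,
  i.e. weight gains at zero seed gain (parthenocarpy-like); here the
  difference-scale intercept is ~0 by construction.
* **Yield components.** Bush spacing 1.2 m, rows 3.0 m, ~15 canes/bush,
  ~25 clusters/cane, ~6.5 berries/cluster — typical mature Bluecrop
  numbers chosen to land open yields in the 12–17 t/ha range.

One master seed drives every sub-generator through derived sub-stream
seeds, so a partial re-run of any sub-generator reproduces exactly.
Because fields within a region share treatment parameters, between-field
variation in deficits is pure sampling noise — real fields differ
systematically, so field-data CIs will be wider than synthetic ones.
Passing ground-truth-recovery tests shows the estimators are consistent
under the generating model, not that the model is true of any farm.

# Numerical choices and problem sizes

Permutation defaults are 999 (diversity envelopes, envfit, PERMANOVA),
seeded and derived per stage; NMDS uses 100 restarts by default (20 in the
pipeline driver, where it follows a classical-scaling start and in
practice converges immediately on these small matrices), tolerance 1e-6,
500 iterations. Exact Mann–Whitney switches to the normal approximation
above a smaller-group size of 8. Degenerate inputs are defined, not
accidental: all-tied contrasts report $\chi^2 = 0$, $p = 1$, one letter;
all-zero abundance vectors, zero total areas, constant env variables and
constant ANCOVA covariates raise typed errors; `aicc` returns Inf with a
warning when $n \le k+1$.

The test suite and the worked examples run the generator at reduced sizes
(4 fields/region, 2 bushes/transect) where full fidelity is not the point,
and at the full 17-field design for ground-truth recovery (100 NB-GLMM
replicates, 20 treatment replicates) and the Monte-Carlo Chao-1 check
(20 replicates); these sizes give the Monte-Carlo checks comfortable
margins while keeping a default run in minutes on one CPU.

# Known limitations

* The published per-field results (U statistics, PERMANOVA F = 11.9, GLMM
  coefficient tables) are not recomputable without the undeposited raw
  data; they serve as plausibility magnitudes for the generator, and the
  quantitative anchors are instead the arithmetic identities the published
  region tables do determine (valuation rows, AICc from printed
  logLik/df/n).
* The printed model-selection df convention exceeds fixed effects +
  dispersion + two RE variances by one for every reproducible row; `aicc()`
  therefore takes $k$ as given, and in-package fits count parameters from
  the fitted object.
* The default cover-class vocabulary is a reconstruction of the classes
  named in the source methods, not the full 26-class legend (unpublished);
  unmapped classes error and must be supplied via `extra` or a YAML
  override rather than defaulting silently.
* No spatially explicit foraging, phenology, zero-inflation,
  observation-level random effects, or within-region heterogeneity in
  treatment parameters.
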