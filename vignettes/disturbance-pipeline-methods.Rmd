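---
title: "Methods: synthetic forest-disturbance landscapes and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic forest-disturbance landscapes and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`disturbscape` re-implements, as a tested and reusable pipeline, a global
analysis of recent severe forest-canopy disturbance: raster patch-pattern
metrics per landscape, Gaussian-mixture clustering of landscapes into
disturbance-activity groups, permutation tests associating clusters with
disturbance agents, tree genera and species traits, an inside/outside
protected-area contrast, and a pixel-level logistic mixed model of climatic
and topographic disturbance drivers. Real inputs (global loss-year rasters,
elevation models, reanalysis climate, trait databases, expert
questionnaires) are out of scope; a synthetic-landscape generator with
fully known generative truth stands in for all of them, which is what makes
every stage of the pipeline testable against ground truth.

# Data model

A landscape is a set of congruent planar 30 m grids (`ds_grid`): a forest
mask, a protected-area mask, a DEM, and an integer disturbance grid holding
the first disturbance year per pixel (0 = never; a pixel records at most
one loss year, matching single-loss-year satellite products). Climate is a
per-landscape annual table of mean temperature (°C) and precipitation sum
(mm). Context tables list each landscape's two most important disturbance
agents (ranked), tree-species basal-area shares, and a species trait table
(maximum height m, wood density g cm⁻³, conifer flag). Rasters are read and
written as ESRI ASCII grids — a plain-text, dependency-free, lossless
format for these integer and float bands; no projection metadata is carried
because the whole pipeline works on planar grids.

# Patch metrics

Disturbances are aggregated over the whole study period and patches are
delineated under an **eight-neighbour rule** (diagonal contact merges).
Perimeter counts every cell edge adjoining background or the grid boundary
(30 m per edge); cell area is 0.09 ha. The four metrics are

* **pland** — percent of the stratum's forest area disturbed;
* **edge density** — total patch perimeter / forest area (m/ha);
* **AWMPS** — area-weighted mean patch size, $\sum a_i^2 / \sum a_i$ (ha);
* **AWM-PAR** — area-weighted mean perimeter–area ratio, which reduces to
  total perimeter / total disturbed area (m/ha); its ceiling at 30 m
  resolution is a single cell, $120/0.09 = 1333.3$.

Note the exact per-landscape identity
$\text{ED} = \text{AWM-PAR} \times \text{pland} / 100$: the four metrics
carry three degrees of freedom. This matters for clustering (below).
Stratified (inside/outside) metrics clip disturbances to the stratum mask
before labelling, so a straddling patch contributes clipped pieces to both
strata with conserved total area; each stratum's ED and pland use that
stratum's own forest area. Zero-disturbance strata return pland = ED = 0
and flagged-missing (`NA`) patch metrics rather than silent `NaN`s.

# Protected-area buffer

The "outside" stratum is a buffer around the protected area whose width
equals the diagonal of the protected area's minimum bounding rectangle
(measured across the outer edges of extreme cells, so a single cell spans
30 m × 30 m), making the comparison region scale with landscape size. The
buffer is computed on the raster with an exact Euclidean distance transform
(cell centre to cell centre) rather than vector geometry, which keeps a
single data model and exact congruence with the disturbance grids. Only the
focal protected mask is excluded from its own buffer.

# Mixture clustering

Landscapes are clustered on the 4-metric vector. Because the metrics span
orders of magnitude, the default preprocessing takes natural logs of pland,
edge density and AWMPS (offset by half the smallest nonzero value when
zeros occur) and z-scores all features; AWM-PAR stays on its natural scale.
The transform is recorded in the output, invertible, and configurable —
cluster summaries are reported on both the feature and the raw scale.

The mixture is fitted by EM with k-means++-style seeding, multiple
restarts (20 in the pipeline; selection is sensitive to search depth on
these data), and a covariance ridge $\delta I$ added in every M-step
(default $\delta = 10^{-6}$ × mean feature variance; the pipeline uses
$\delta = 0.02$ on the z-scored features, i.e. a ~14%-of-SD noise floor —
see below). A restart whose component loses nearly all responsibility mass
is discarded as a degenerate optimum. The per-iteration log-likelihood
trace of every restart is retained so the EM monotonicity guarantee is
asserted, not assumed. Model choice maximises
$\mathrm{BIC} = 2\ell - p\log n$ over the number of components and four
covariance families:

| family | covariance | parameters (K components, d features) |
|---|---|---|
| `spherical` | one shared $\sigma^2 I$ | $Kd + K - 1 + 1$ |
| `diagonal` | per-component diagonal | $Kd + K - 1 + Kd$ |
| `full_equal` | one shared unrestricted $\Sigma$ | $Kd + K - 1 + d(d+1)/2$ |
| `full` | per-component unrestricted | $Kd + K - 1 + Kd(d+1)/2$ |

The `full_equal` family was added after the three-family set proved
inadequate on exactly these data: the metric identity above makes the
log-features lie on a thin, slightly curved sheet, which the per-component
`full` family models by splitting clusters along the sheet (curvature
chasing), while `spherical`/`diagonal` cannot represent the strong
collinearity at all. A single shared unrestricted covariance models three
parallel elongated clusters parsimoniously — it is the equal-shape model of
the standard mixture-model toolbox. All four families compete in the BIC
table and the winner is recorded in every run.

The pipeline's ridge of 0.02 on z-scored features plays the same role as
the covariance prior familiar from standard mixture software: without it,
the thin direction created by the exact metric identity lets flexible
families earn unbounded likelihood by splitting clusters into ever-thinner
slabs, and BIC cannot stop them. A noise floor of a small fraction of a
feature SD caps that reward; the selected K is insensitive to the exact
value over at least 0.005–0.1.

Cluster summaries use a parametric bootstrap: B synthetic datasets of size
n are drawn from the fitted mixture and refitted with the same (K, family);
refitted components are matched to the originals by minimum-cost assignment
on the mean-distance matrix (exhaustive for K ≤ 7), and percentile
intervals are taken over the matched component means. Failed refits are
dropped and counted.

# Permutation tests

All association tests are Monte-Carlo permutation tests with the add-one
estimator $p = (1 + \#\{T^* \ge T\})/(1 + B)$, which is never zero.

* **Agents/genera vs clusters**: each landscape contributes one count for
  each of its two most important agents (or genera, by summed basal-area
  share); the observed statistic is Pearson's $\chi^2$ on the resulting
  category × cluster table, and the null permutes cluster labels across
  landscapes while keeping each landscape's category pair intact — the
  landscape is the permutation unit. A top-1 variant is available.
* **Traits vs clusters**: pairwise Kruskal–Wallis tests (midranks, standard
  tie correction) over cluster pairs with Benjamini–Hochberg adjustment.
  "Two-tailed" is interpreted as the standard upper-tail test on H, since
  H is non-negative.
* **Inside vs outside**: within each cluster, a KW permutation test of
  inside vs outside metric values. Because both strata come from the same
  landscape, the default null swaps stratum labels within landscapes
  (paired); free permutation across all observations is available by
  configuration. Landscape weights are equal (not area-weighted).

# Driver model

The annual probability that an at-risk forest pixel is disturbed is
modelled as binomial-logit with a landscape random intercept:

$$\mathrm{logit}\,p_{ijt} = \beta_0 + \beta_T \tilde T_{j,t-\ell}
 + \beta_P \tilde P_{j,t-\ell} + \beta_{TP}\tilde T\tilde P
 + \beta_{TRI}\,\widetilde{TRI}_{ij} + b_j,\qquad b_j\sim N(0,\sigma_b^2)$$

* **TRI** is the root-mean-square elevation difference between a focal
  cell and all other cells of a 7 × 7 window (~100 m radius at 30 m).
  The classical 3 × 3 index sums rather than averages; the RMS-mean form
  keeps edge-truncated windows on the same scale, and per-landscape
  z-scoring absorbs the constant factor anyway. A sum variant is available.
* **Anomalies** $\tilde T,\tilde P$ are per-landscape z-scores of the
  supplied annual series (sample SD); the baseline window is whatever
  series is supplied, recorded with the run.
* **Risk set**: a pixel contributes one record per year from the first
  modelled year until (and including) its first disturbance — the
  discrete-time-survival convention implied by a single-loss-year product.
* **Lag** $\ell \in \{0..3\}$ is shared by temperature and precipitation
  and selected by AIC over identically constructed samples (same records,
  re-joined covariates only).

**Case-control sampling.** A fraction of pixels per landscape is sampled
(all records of a sampled pixel), then absences are down-sampled per
landscape to the presence count. The per-landscape absence sampling
fraction enters the linear predictor as an offset
$\log(f_{pres}/f_{abs})$, the statistically exact generalisation of the
classical single intercept shift when prevalence differs among landscapes;
with offsets included, all fixed effects — including the intercept — are on
the population scale. The classical single-shift corrected intercept is
reported alongside. A landscape without presences is retained with a small
absence sample and flagged.

Fitting uses Laplace-approximated maximum likelihood (lme4's `glmer`, the
standard tool for this model class) behind a stable interface returning
estimates, standard errors, the coefficient covariance, $\hat\sigma_b$,
predicted landscape intercepts, log-likelihood and AIC. A boundary fit
($\hat\sigma_b \to 0$) is flagged and checked in tests against plain
IRLS logistic regression. Model comparison fits full, spatial-only (TRI)
and null (intercept-only) models on the identical sample and reports AIC
plus likelihood-ratio tests (df 3 and 1) against the $\chi^2$ reference.
Response curves draw coefficient vectors from
$N(\hat\beta, \widehat{\mathrm{Var}}(\hat\beta))$ (covariance repaired to
nearest-PSD if needed), evaluate inverse-logit predictions over a
temperature-anomaly grid at fixed precipitation levels with TRI = 0 and
random intercept 0, and report pointwise medians with 2.5/97.5% quantiles.

# The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions for all end-to-end checks.

* **DEM**: Gaussian-blurred white noise normalised to unit SD and scaled
  by a vertical relief parameter (default 60 m, blur SD 2 cells); mean
  ruggedness is strictly increasing in the relief parameter, and 0 gives a
  flat surface.
* **Climate**: stationary AR(1) series, defaults 0.8 °C and 150 mm marginal
  SD, lag-1 autocorrelation 0.3; per-landscape means drawn from wide
  temperate ranges (1–12 °C, 700–2000 mm). An SD of 0 is allowed but
  flagged, since anomalies are undefined downstream.
* **Disturbance, `pixel_iid` mode**: each at-risk pixel is disturbed
  independently with the model probability above — the generator exactly
  matches the driver-model likelihood, which is what makes clean parameter
  recovery possible. The generator is validated against its own oracle
  (plain logistic regression on the full population) before any GLMM code
  is involved.
* **Disturbance, `patchy` mode**: the same linear predictor sets the
  expected annual disturbed area, realised as discrete patches: counts are
  Poisson with mean (expected area / mean patch area), patch areas follow a
  truncated power law, seed cells prefer terrain according to the
  generative TRI coefficient, and patches grow by stochastic region
  spreading with frontier weights
  $(1-s)\cdot\text{compactness} + s\cdot\text{uniform}$, where a single
  irregularity scalar $s$ spans compact to dendritic shapes.
* **Archetypes** (low / moderate / high activity) set period prevalence
  targets of 0.31, 4.6 and 21.5% — the cluster contrasts the generator is
  meant to emulate — with patch-size laws (α = 2.8/1.9/1.5, caps 10/150/800
  cells) chosen so that AWMPS steps roughly an order of magnitude between
  groups while the cap stays below a landscape's typical period
  disturbance. The latter matters: with a cap far above the landscape's
  total disturbance, AWMPS degenerates to a single heavy-tailed draw and
  within-group variance explodes.
* **Context tables**: ranked top-2 agent draws from per-archetype
  categorical distributions (wind-dominated low, beetle/fire moderate,
  fire-dominated high); species draws preferring broadleaves (low) or
  conifers (high) from a 12-species pool with plausible height/density
  contrasts; Dirichlet shares with geometrically decaying concentration,
  flatter for the high archetype (lower dominance).

## Study conditions and their rationale

The default pipeline configuration simulates **18 low / 23 moderate / 9
high** landscapes (the composition of the emulated study's clusters) with a
60 × 60-cell (324 ha) protected core inside an unprotected matrix wide
enough to hold the full MBR-diagonal buffer, over 14 modelled years with 3
years of climate history (lags 0–3 usable). This is a deliberate
scale-down from real landscapes (≥ 2000 ha) chosen so that a full run
completes in minutes on one CPU; all rates are per-pixel, so the scale-down
changes variances, not means.

For the pattern simulations the landscape random-intercept SD is 0.25 and
landscapes additionally differ in patch geometry (jittered irregularity,
log-normal jitter on the patch-size cap). These values were chosen during
generator design so that the three archetypes remain three *distinct*
generative regimes at this reduced landscape size; with substantially
larger heterogeneity the low and moderate regimes overlap into a continuum
and the "three groups" ground truth that the end-to-end checks rely on no
longer exists in the generated data. Driver-model recovery simulations use
σ_b = 0.5, matching the magnitude implied by the emulated study's
cluster-level estimates.

Outside the protected core, the low/moderate generators emulate human land
use with 10× larger, more compact patches at a higher rate, and the
process stops at the fence. The high generator instead runs one identical
process across the whole landscape — natural disturbance does not respect
the protected-area boundary — and patches straddling the fence are clipped
analytically into both strata. The inside/outside contrast therefore has a
known truth: strongly significant for low/moderate; for high, null in
patch *shape* (AWM-PAR) and, at this reduced landscape scale, only
approximately null in patch *size*: AWMPS under a heavy-tailed patch-size
law is dominated by the largest sampled patch, which grows with region
area, and the buffer is an order of magnitude larger than the protected
core. The end-to-end checks assert the robust form of the pattern — the
high group shows a null shape contrast and by far the weakest size
contrast of the three groups.

## What the generator does *not* emulate

Spectral change detection and its omission/commission errors; irregular
landscape shapes and forest-mask holes; spatial autocorrelation of climate
across landscapes; disturbance-history legacies; inter-annual variation in
patch shape; agent-specific spatial signatures. Passing tests therefore
demonstrate that the *pipeline* is correct and calibrated under a
known-truth data-generating process of realistic structure — not that the
emulated study's empirical findings are reproduced from real data.

# Numerical choices

* EM: restarts re-drawn on component collapse; convergence when the
  log-likelihood improves by < `tol` (default 1e-8); BIC uses the
  larger-is-better convention throughout.
* Permutation p-values: add-one estimator; ≥ its floor $1/(B+1)$ by
  construction.
* MAP ties in cluster assignment break toward the lowest component index.
* GLMM: Laplace (`nAGQ = 1`) by default; the pipeline falls back to the
  faster PIRLS-only approximation (`nAGQ = 0`) when the inner optimisation
  fails on a sparse cluster, and calibration-style simulations use
  `nAGQ = 0` for speed where only differences between nested fits matter.
* Seeds: every stochastic operation takes an explicit seed; pipelines
  derive per-stage seeds from one master seed (`stage_seed`), and outputs
  record the master seed and a config hash.

# Problem sizes used in the test-suite

Monotonicity and oracle checks run on hundreds of small random grids
(≤ 64 × 64). Bootstrap coverage uses 500 replicates of n = 40 with B = 199.
Type-I calibration uses 1000 simulated nulls at 199 permutations.
Driver-model recovery fits 30 landscapes × 2025 pixels × 14 years through
the full 10% + case-control sampling path, with 200 reduced-size replicates
for confidence-interval coverage; lag recovery uses 50 seeds and model
comparison 1000 reduced-size null simulations. These sizes are the
package's chosen compromise between Monte-Carlo error and a test suite that
runs in minutes.

# Known limitations

* The patchy generator modulates only the *expected* annual area through
  the climate term; it does not reproduce the pixel-level likelihood, so
  driver-coefficient recovery is validated in `pixel_iid` mode only.
* Patch growth can stall when the risk set fragments; realised patch areas
  are then smaller than their law's draw (area conservation holds, the law
  is truncated by geography).
* BIC selection among mixtures on manifold-like data is delicate at
  n = 50; the pipeline reports the full BIC table precisely so that a
  reader can see the margin behind the selected K.
* The GLMM assumes independence of pixels given the landscape intercept;
  spatial autocorrelation within landscapes (strong in patchy data by
  construction) is not modelled, mirroring the emulated analysis.
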