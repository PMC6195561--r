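# disturbscape

Patterns and drivers of severe forest-canopy disturbance across landscapes
— a tested, fully synthetic-data-driven re-implementation of a global
disturbance-analysis workflow.

## The problem

Satellite loss-year products record, per 30 m pixel, the year in which the
forest canopy was completely lost. Given such rasters for a set of
protected landscapes and their surroundings, together with per-landscape
climate series, elevation models and ecological context (dominant
disturbance agents, tree species shares and traits), the analysis asks:

1. **How do disturbance patterns vary among landscapes?** Four metrics per
   landscape — percent of forest disturbed (*pland*), edge density (ED,
   m/ha), area-weighted mean patch size (AWMPS, ha, $\sum a_i^2/\sum a_i$)
   and area-weighted mean perimeter–area ratio (AWM-PAR, m/ha, equal to
   total perimeter / total disturbed area) — computed from patches
   delineated under an eight-neighbour rule, then clustered with Gaussian
   finite mixture models selected by BIC
   ($2\ell - p\log n$, maximised), with parametric-bootstrap confidence
   intervals for cluster characteristics.
2. **Are clusters associated with agents, genera and traits?** Monte-Carlo
   permutation tests: Pearson χ² homogeneity for the two most important
   agents/genera per landscape, Kruskal–Wallis for community-weighted
   traits, with Benjamini–Hochberg FDR across pairwise comparisons.
3. **Do natural disturbances differ from human-influenced surroundings?**
   Patch metrics inside the protected area vs a surrounding buffer whose
   width equals the diagonal of the protected area's minimum bounding
   rectangle, compared per cluster with paired permutation KW tests.
4. **What drives disturbance in space and time?** A binomial-logit mixed
   model of annual pixel-level disturbance:
   $\mathrm{logit}\,p = \beta_0 + \beta_T\tilde T_{t-\ell} +
   \beta_P\tilde P_{t-\ell} + \beta_{TP}\tilde T\tilde P +
   \beta_{TRI}\widetilde{TRI} + b_{landscape}$,
   with per-landscape z-scored climate anomalies and 7×7-window terrain
   ruggedness, lag $\ell$ chosen by AIC, case-control sampling of the rare
   presences with per-landscape offsets (population-scale intercept),
   likelihood-ratio model comparison, and simulated response curves.

Because the real inputs are large external datasets, the package ships a
**synthetic landscape generator with known generative truth** (three
activity archetypes; independent-pixel mode matching the driver model's
likelihood exactly, and a patchy seed-and-spread mode producing realistic
patch mosaics). Every stage of the pipeline is validated against that
truth or against independent brute-force oracles.

## Worked example

The default configuration simulates the full study condition — 18 low-,
23 moderate- and 9 high-activity landscapes, each a 576 ha protected core
in a larger unprotected matrix, over 14 modelled years — and runs every
stage (a few minutes on one CPU):

```r
library(disturbscape)

res <- run_pipeline(seed = 42)

res$model
#> <ds_gmm: K=3, family=full_equal, loglik=8.698, BIC=-76.492>
table(res$assignments$archetype, res$assignments$cluster)
#>            1  2  3
#>  high      0  9  0
#>  low      18  0  0
#>  moderate  0  0 23
aggregate(cbind(pland_pct, awmps_ha, awm_par_m_per_ha) ~ archetype,
          res$metrics, mean)
#>   archetype pland_pct awmps_ha awm_par_m_per_ha
#> 1      high   25.6128  48.0482            312.0
#> 2       low    0.3264   0.2224           1170.6
#> 3  moderate    4.2418   2.1802            847.2
res$context_tests$agents[c("statistic", "p_value")]
#> $statistic
#> [1] 19.52754
#> $p_value
#> [1] 0.001
```

BIC selects three mixture components (shared-covariance family) whose
memberships recover the three generative archetypes exactly. The metric
gradients match the generator's design — about 0.3%, 4.2% and 26% of
forest disturbed, area-weighted patch sizes stepping by roughly an order
of magnitude, and shape complexity (AWM-PAR) falling as activity rises —
and the two most important disturbance agents differ significantly among
clusters. Driver results per cluster sit in `res$drivers`: at this seed
the high-activity cluster selects an immediate (0-year) climate lag with a
strong positive temperature effect (0.70) amplified by dry years, the
moderate cluster a 3-year lag with a negative temperature effect (-0.31),
and the sparse low cluster — whose few hundred disturbed pixels carry
little information, as expected for rare small-scale disturbances — a
noisy 1-year lag. The full model beats the spatial-only and null models by
AIC in every cluster. `res$contrast$tests` holds the inside/outside
protected-area tests per cluster.

The `analysis/` directory contains the same workflow as numbered stage
scripts (`01_simulate.R` … `06_drivers.R`) that exchange CSV/ASCII-grid
artifacts under `results/`, so each stage can be run and inspected
independently.

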