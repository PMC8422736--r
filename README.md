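# habresp

Holling-type functional responses in habitat selection.

`habresp` is for ecologists who want to know not just *whether* an animal
selects a land-cover type, but *how its proportional use of that type changes
with how much of it is available* inside the home range — the functional
response of third-order habitat selection. Instead of stopping at a
phenomenological "selection declines with availability", the package fits the
mechanistic response forms Holling introduced for predator–prey systems:

- **type I** (linear): `h(x) = a·x`
- **type II** (concave, saturating; the Michaelis–Menten form):
  `h(x) = a·x / (b + x)`
- **type III** (sigmoid): `h(x) = a·x² / (b² + x²)`

where `x` is the relative availability of a land-cover type in an
animal-month home range, `a` is the maximum proportional use, and `b` the
availability at which use reaches half its maximum — small `b` means the
type is attractive even when scarce. From `a` and `b` follow interpretable
diagnostics: the attraction ratio `a/b`, the tipping point `x* = a − b`
(type II, when `a > b`) where use switches from disproportionately high to
disproportionately low, the type III crossings
`x₁,₂ = a/2 ± √((a/2)² − b²)` (when `b < a/2`), and the type III inflection
point `b/√3`.

## What the pipeline does

1. **Availability** — monthly 95% minimum-convex-polygon home ranges per
   individual (`mcp_home_range()`), land-cover proportions from a
   categorical raster by cell-center counting (`land_cover_proportions()`),
   with sex-specific exclusion of outsized home ranges
   (`build_availability_table()`).
2. **Pairwise logit models** — one baseline-category logit per land-cover
   type against a common reference (`build_pairwise_data()`,
   `fit_log_odds()`): binomial GAM with a fixed `log(availability)` offset
   (the null of proportional use), a penalized availability spline
   (smoothing parameter fixed at λ = 2) for the deviation from
   proportionality, a cyclic hour × month tensor smooth, sex effects, and
   random intercepts for individual and year. Candidate structures can be
   compared by animal-grouped ten-fold cross-validation
   (`cross_validate()`).
3. **Use distribution** — the multinomial logit link combines the per-type
   log odds ratios into choice probabilities
   `π_i = exp(f_i) / (1 + Σ_s exp(f_s))` that sum to one
   (`combine_use()`), traced over the observed availability range to give a
   proportional-use curve per type, time slot and sex (`use_curve()`).
4. **Holling fits** — bounded least squares fits all three forms to each
   curve and keeps the smallest residual sum of squares (`fit_holling()`),
   with `holling_diagnostics()` reporting `a/b`, `x*`, crossings, inflection
   and the selection regime.

A synthetic-data module (`sim_scenario()`, `truth_curve()`,
`simulate_telemetry()`) generates multi-individual telemetry whose
per-category use follows known Holling truths — with heterogeneous home-range
compositions, hour/month modulation, sex differences and individual-level
prevalence variation — so the whole chain can be validated against ground
truth without field data.

## Worked example

Simulate a herd whose use of meadows follows a type II truth
(`a = 0.3`, `b = 0.05`) and recover it end to end:

```r
library(habresp)

scenario <- sim_scenario(
  n_individuals = 20, fixes_per_month = 400,
  categories = c("meadow", "conifer", "mixed_old"),
  individual_prevalence_sd = 0.15, seed = 101
)
truths <- list(
  truth_curve("meadow",  "II", a = 0.3, b = 0.05),
  truth_curve("conifer", "I",  a = 0.2)
)
result <- run_pipeline(list(
  reference_category = "mixed_old",
  scenario = scenario, truths = truths,
  spec  = model_spec("smooth", "none"),
  slots = data.frame(month = 6L, hour = 0L)
))
result$summary
#> # A tibble: 2 × 14
#>   focal   sex   month  hour type      a      b a_over_b x_star ...
#> 1 conifer <NA>      6     0 I     0.197 0         NA     0
#> 2 meadow  <NA>      6     0 II    0.335 0.0610     5.48  0.274
```

The meadow curve is correctly classified as type II with `a ≈ 0.33` and
`b ≈ 0.06` (truth 0.3 and 0.05): maximum proportional use about a third of
fixes, half-saturation at ~6% availability — a strongly attractive type —
and a tipping point near `x* ≈ 0.27`: meadows are used disproportionately
often until they make up about 27% of the home range, and avoided beyond
that. The companion category is recovered as type I with slope ≈ 0.2. Under
the hood this ran 40 animal-months of simulated fixes through MCP-free
synthetic availability, two binomial GAMs with offsets and random
intercepts, the multinomial link, and three bounded least-squares fits per
curve:

```r
result$fits[["meadow|NA|6|0"]]
#> Holling type II fit (200 points)
#>   a = 0.3346 (max use), b = 0.0610 (half-saturation), rss = 0.0103
#>   candidate rss: I=2, II=0.0103, III=0.0378
```

`autoplot()` draws any fitted curve or use curve against the 1:1 line.

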