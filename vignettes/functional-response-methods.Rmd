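---
title: "Methods: Holling-type functional responses in habitat selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Holling-type functional responses in habitat selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habresp)
```

## The model

An animal inside its home range repeatedly chooses among K discrete
land-cover types. Write $x_i$ for the relative availability of type $i$ in
the animal-month home range ($\sum_i x_i = 1$) and $\pi_i$ for the
probability that the next used location falls in type $i$ (the *use
distribution*; with categorical cover types this equals proportional use).
A *functional response* is a dependence of $\pi_i$ on $x_i$ other than
direct proportionality.

The package estimates $\pi_i$ in two stages.

**Stage 1 — baseline-category logits.** For each non-reference type $i$,
fixes in type $i$ or the reference type $K$ form a binary dataset
(`present` = 1 for $i$, 0 for $K$). A binomial GAM estimates the log odds
ratio

$$f_i(x_i, h, m, s) = \alpha_i + \log x_i + g_i(x_i) + t_i(h, m) + \beta_i s
  + \epsilon_{ij} + \gamma_{iy},$$

where $\log x_i$ is a fixed **offset** encoding the null of use
proportional to availability; $g_i$ is the availability deviation — absent,
parametric in $\log x_i$, or a penalized cubic regression spline — whose
shape *is* the functional response; $t_i$ is a cyclic tensor-product smooth
in hour (period 24) and month (period 12), optionally sex-specific;
and $\epsilon_{ij}$, $\gamma_{iy}$ are individual and year random
intercepts (penalized group-level intercepts with shared variance per
grouping factor, estimated by REML). Availability is that of the *focal*
type also for reference fixes: it describes the choice situation, not the
outcome.

**Stage 2 — the multinomial link.** With $f_K \equiv 0$ for
identifiability,

$$\pi_i = \frac{\exp(f_i)}{1 + \sum_{s=1}^{K-1} \exp(f_s)},$$

each $f_s$ evaluated at its own availability from a scenario vector that
sums to one. Tracing $\pi_i$ over a grid of focal availability gives the
use curve, to which the three Holling forms are fitted by bounded least
squares:

$$h_I(x) = a\,x, \qquad h_{II}(x) = \frac{a\,x}{b + x}, \qquad
  h_{III}(x) = \frac{a\,x^2}{b^2 + x^2},$$

with $a, b \in [0, 1]$. The form with the smallest residual sum of squares
is reported, together with the attraction ratio $a/b$, the tipping point
$x^* = a - b$ (type II, $a > b$), the crossings
$x_{1,2} = a/2 \pm \sqrt{(a/2)^2 - b^2}$ (type III, $b < a/2$), and the
inflection point $b/\sqrt{3}$ (type III).

## Assumptions

- Fixes are far enough apart in time that every point of the home range is
  reachable between fixes; choices are conditionally independent given the
  covariates. No movement model or spatial autocorrelation is represented.
- The choice set equals the set of available cover types, so choice
  probability, use distribution and proportional use coincide.
- Random intercepts capture individual/year prevalence differences; there
  is no covariate for which a random slope would be meaningful here.
- Coordinates are planar; home ranges are small relative to the geoid.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| MCP level | 95% | fraction of fixes retained (peeled by distance from the centroid of all fixes) before taking the convex hull |
| minimum fixes per animal-month | 5 | the minimum for a 2-D hull; thinner months are excluded and logged |
| size cut-off | 90th percentile per sex | screen against dispersal-inflated home ranges; absolute per-sex thresholds (e.g. 182/459 ha) may be configured instead; the screen can act per month or per individual |
| availability spline penalty $\lambda$ | 2 | fixed (not estimated), controlling the smoothness of the functional-response deviation |
| spline bases | 6 knots (availability, cubic regression), 8 × 6 (cyclic hour × month) | conventional sizes; penalties keep effective complexity lower |
| use-curve grid | 200 points between the 1st and 99th percentile of observed focal availability | avoids spline extrapolation at the data edges |
| reporting slots | months {6, 12} × hours {0, 12} | summer/winter by midnight/noon |
| Holling optimizer | 9 grid starts + 2 data-driven starts, L-BFGS-B in $[0,1]^2$, then a profiled-$a$ 1-D polish | `a` enters each form linearly, so for fixed `b` the optimal `a` is a clamped quadratic minimizer; the polish removes residual optimizer slack |

## Numerical choices

- $h_{II}$ and $h_{III}$ evaluate to 0 at $x = 0, b = 0$ (the right limit).
- Type selection ties within $10^{-12}$ in RSS go to the lower
  (simpler) type number. RSS is computed on the curve grid, equally
  weighted.
- The type I slope is also bounded to $[0, 1]$ (proportional use cannot
  exceed 1 at full availability); an active bound is recorded.
- $a/b$ is reported as $+\infty$ when $b = 0$ so summary tables are total;
  the pipeline writer reports absent tipping points/crossings as 0, while
  `holling_diagnostics()` keeps them `NA` alongside an explicit regime
  label.
- The multinomial link uses a max-shifted softmax, agreeing with the direct
  formula to machine precision while immune to overflow.
- Cell inclusion in home ranges is a cell-center-in-polygon test; centers
  exactly on the boundary count as inside. MCP peeling ties keep
  earlier-recorded fixes.
- Zero-availability rows are dropped, never floored: flooring would
  fabricate availability under a log offset.
- Quasi-complete separation (extreme parametric coefficients) aborts with
  advice to coarsen the model; a failed random-intercept fit falls back to
  no random effects with a warning.

## Open design choices, and how they were resolved

- **Background composition along a use curve.** When the focal availability
  $x$ varies, the other types' availabilities are proportional rescalings
  of the per-sex mean observed availability vector onto $1 - x$. Fixing
  backgrounds at raw means and renormalizing differently would change
  curves slightly; the convention is recorded in the run manifest. Because
  the focal grid is clipped to the focal model's training range but
  background types then move off their own observed combinations,
  background splines are allowed to extrapolate (they extrapolate linearly
  on the link scale).
- **Cross-validation folds are grouped by animal** — the conservative
  choice against pseudo-replication; fold assignment is a deterministic
  greedy balance of fix counts.
- **Candidate structures** (18): three availability terms × three temporal
  terms, plus sex-specific availability deviation where legal, plus three
  smooth-availability variants without the year intercept.
- **Size screen scope**: "unrealistic home range" can be judged per
  animal-month or per individual (mean monthly area); both are supported,
  per month by default.

## The synthetic-data generator

The generator is the package's testbed: each non-reference type carries a
*truth curve* — a Holling form plus multiplicative hour/month and sex
modifiers — and each animal-month draws an availability vector from a
symmetric Dirichlet(1) (rejecting reference shares below 0.05 so the
reference offset stays finite). Implied use probabilities are the truth
curves evaluated at the drawn availabilities, scaled by the modifiers and by
log-normal individual and year effects, with the reference absorbing the
remaining mass; a scenario whose reference mass is non-positive fails
loudly rather than being silently renormalized. Fix categories are
independent multinomial draws; fixed seeds give bit-identical output.

What it emulates: heterogeneous home-range compositions spanning the
availability axis, diel/seasonal modulation, sex differences, and
between-individual prevalence variation. What it deliberately omits:
movement autocorrelation, GPS error, spatially contiguous rasters behind
the availability vectors, and availability-dependent home-range sizes. A
green end-to-end test therefore demonstrates estimator correctness for the
estimand — proportional use as a Holling function of availability — not
robustness to telemetry pathologies.

The standard recovery conditions used in tests and in
`scripts/acceptance.R` are a type II truth $a = 0.3, b = 0.05$ for the
focal type, a type I companion ($a = 0.2$), 20 individuals per sex × 400
fixes in one month, and individual prevalence SD 0.15 — sizes chosen so a
single run fits comfortably in an interactive session while leaving the
recovery tolerances ($|\hat a - a| \le 0.05$, $|\hat b - b| \le 0.03$)
clearly resolvable.

```{r recovery, eval = FALSE}
row <- run_pipeline(list(
  reference_category = "mixed_old",
  scenario = sim_scenario(
    n_individuals = 20, fixes_per_month = 400,
    categories = c("meadow", "conifer", "mixed_old"),
    individual_prevalence_sd = 0.15, seed = 101
  ),
  truths = list(
    truth_curve("meadow", "II", a = 0.3, b = 0.05),
    truth_curve("conifer", "I", a = 0.2)
  ),
  spec = model_spec("smooth", "none"),
  slots = data.frame(month = 6L, hour = 0L)
))$summary
```

## Known limitations

- The two-stage procedure propagates no uncertainty: the Holling parameters
  come with no confidence intervals. A one-stage hierarchical (e.g.
  Bayesian) formulation would fix this and is out of scope here.
- Types II and III differ mostly below $x \approx b$; when `b` is small and
  few home ranges contain little of the focal type, the II/III decision can
  rest on a sliver of data and near-ties occur.
- The individual/year effects enter the generator multiplicatively on use
  probabilities with the reference absorbing the remainder, which matches a
  clean log-odds intercept shift only while non-reference use is small;
  variance recovery tests use small baseline use accordingly.
- Raster input is limited to the plain-text ESRI ASCII grid format; no
  geodesic coordinate support.
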