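---
title: "From comparative extinction risk to tenure-aware reserve selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From comparative extinction risk to tenure-aware reserve selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tenureplan` chains two analyses that are usually run separately: a
phylogenetic comparative model of extinction risk, and minimum-set reserve
selection over a land-tenure mosaic. This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The response: a 10-point ordinal threat status

Red List categories are coarse; population trend carries additional signal.
`encode_threat_ordinal()` combines them with base scores LC = 1, NT = 3,
VU = 5, EN = 7, CR = 9, plus 1 when the trend is *decreasing*. The mapping
is monotone in category severity at fixed trend, every level 1–10 is
reachable, and EN/CR species are exactly those with scores of 7 or more
(`endangered_ordinal_base()`). There is no field-standard mapping of the 20
category-by-trend combinations onto 10 points, so this coding is the
package's own documented choice; the synthetic generator discretizes to the
same scale (empirical deciles of the latent risk), which keeps the whole
pipeline internally consistent. The ordinal response is treated as
numeric in the regression — a deliberate simplification (a pseudo-numeric
scale) rather than a cumulative-link model, which keeps the latent-risk
difference `fitted − observed` directly interpretable in scale points.

## The risk model

`risk_gls()` fits `y = X beta + e`, `e ~ N(0, sigma2 V)` by maximum
likelihood, with

`V = w_p V_phylo + w_s V_space + (1 − w_p − w_s) I`.

`V_phylo` is the phylogenetic correlation from shared branch lengths
(unit diagonal); `V_space = exp(−d/rho)` on Euclidean centroid distances.
How phylogenetic and spatial non-independence should be *combined* is
genuinely open; we chose the simplest identifiable blend — a convex
combination of unit-diagonal components — so the diagonal of `V` is exactly 1
and the weights are interpretable as variance shares. Weights and `rho` are
estimated by profile maximum likelihood: a coarse grid over the weight
simplex and distance-scaled `rho` values, refined by Nelder–Mead on
logit/log-transformed parameters (bounded to avoid degenerate `rho`).
Positive definiteness is enforced with an escalating diagonal jitter
(starting at 1e−10, recorded in the `jitter` field). ML rather than REML is
used throughout so that AICc comparisons across fixed-effects structures are
valid. Standard errors use the small-sample variance `rss/(n − p)` with
t references on `n − p` degrees of freedom; with `V = I` every quantity
reduces exactly to OLS (a property the tests check to 1e−10).

Predictors are the mammalian life-history set (log body mass and its square,
age at first reproduction, litters per year, litter size), geographic range
size, overlap proportions with two invasive predators, and range-mean
environmental layers (wet-quarter temperature, human influence, total and
late-dry-season fire frequency). `transform_standardize()` logs any column
with |skewness| > 1 (threshold configurable; `log(x + 1e−6)` when zeros are
present, never for sign-mixed columns) and z-scores everything, so
coefficients are per-SD effects. `vif_screen()` iteratively removes the
highest-VIF predictor while any VIF exceeds 5 — the threshold is our choice,
at the conservative end of common practice — and exact collinearity is
removed with a warning rather than an error. The quadratic mass term is
exempt from the screen and hierarchically bound to its linear parent.

## Stepwise search and its decision rule

`step_mam()` ranks candidate deletions by p value (ties: smaller |t|, then
column order), accepts a deletion only when AICc improves by at least 2, and
afterwards offers every deleted term one chance to re-enter under the same
rule. The covariance parameters estimated for the full model are held fixed
across all refits, so model comparisons isolate the fixed-effects structure;
this also makes the search cheap and strictly deterministic. The final model
can never have worse AICc than the full model because only improving steps
are accepted. The full decision trace (every candidate, its AICc, and the
verdict) is returned and written to the report bundle as JSON.

## Latent risk

`latent_risk()` refits the chosen model's coefficients under each tree of
the sample — only `V_phylo` changes per tree; the spatial kernel and weights
stay at the fitted values — and reports `L = mean(fitted) − observed` with
its positive part. Averaging over trees absorbs phylogenetic uncertainty;
the per-tree fitted matrix is kept as an attribute so the variance reduction
is checkable (the tests assert `var(mean) ≤ mean(var)`). Mapping follows the
mean-of-positive convention: `map_mean_positive_latent()` averages only
species with `L > 0` present in a cell, and cells with no qualifying species
are no-data rather than 0, because a mean over an empty set is undefined —
writing 0 would fabricate "zero risk".

## Planning units, costs, targets

Hexagons are flat-top with side `s` (default 7.5 km: perimeter 45 km, area
146 km²), laid from the boundary bounding box's lower-left corner and
clipped to the boundary; units with area fraction `w < 0.01` are dropped.
Cells are assigned to units by nearest center, which for this lattice is
exactly the containing hexagon. Tenure is the plurality class by area with a
fixed, conservation-status-first priority order for ties, and a Native
Title/ILUA majority combined with a majority pastoral overlay yields the
pastoral-use classes.

Costs use *modal* (not mean) MEI and HII per unit — ties at the mode resolve
to the smaller value — because both variables are coarse, step-like layers
where a mean would manufacture intermediate values. Normalization order
matters and a verbal rule does not pin it down; we normalize each variable
to [0, 1], rescale to [0.01, 100], then take the 0.4/0.6 weighted sum, which
keeps the final cost inside [0.01, 100] (the alternative order can exceed
the bounds). Cropped units have cost and feature amounts multiplied by `w`.

Targets: the current criterion takes all EN/CR species; the latent criterion
takes species with mean `L > 1.5`. Both thresholds are configurable, and a
literal top-decile mode exists, but the category/threshold rules are the
defaults because they are how "the most at-risk 10%" is operationalized in
this analysis tradition. Risk is min-max scaled to [0.25, 0.75] per
criterion (scaling jointly across criteria would let one criterion's range
distort the other's targets); an all-equal degenerate case maps to 0.5. The
proportion protected is `P = min(0.4 R + 0.6 A, 0.75)` and the absolute
target is `P` times the species' represented in-region total.

## The exact solver

No linear-programming library is part of the package's dependency set, so
the minimum-set solver is implemented in full: depth-first branch and bound
on `min c'x  s.t.  A x ≥ T`, binary `x`, with locked-in units fixed to 1 and
locked-out units fixed to 0. Lower bounds come from the Lagrangian dual
`L(y) = T'y + Σ_i min(0, c_i − (A'y)_i)`, with multipliers tuned by
subgradient ascent at the root (step halved after 20 non-improving
iterations) and reused down the tree; root reduced-cost fixing removes
variables that cannot appear in an improving solution, and branching is
dynamic on capped shortfall reduction per unit cost. With `gap = 0` the
result is proven optimal — the tests verify equality with exhaustive
enumeration over all subsets on instances up to 15 units — and ties among
equal-cost optima resolve deterministically. The capped-coverage structure
carries a real duality gap, so at the demonstration scale (~85 units,
10–20 targeted species) the packaged configuration runs the solver at a 10%
relative gap, where all four scenarios close quickly; exactness at gap 0
remains the function default and is what the oracle tests exercise. If the
node limit is hit the best incumbent is returned, flagged `"incumbent"`.
A greedy benefit-per-cost heuristic with redundancy pruning provides the
incumbent and a fallback. Boundary length is computed on the hexagon
lattice — full perimeter minus twice the shared edge per selected neighbor
pair — so cropped edge units are treated as full hexagons there; region-border
edges count fully. Reported proxy cost sums newly selected units only
(locked-in units are sunk cost); species coverage is reported for **all**
species against their represented totals, so selecting everything yields
exactly 100%.

## What the synthetic generator emulates — and what it does not

The generator (`simulate_study()`) produces internally consistent inputs
with known ground truth: birth–death ultrametric phylogenies rescaled to
unit height; log-scale Brownian traits plus independent noise; Gaussian-
filtered-noise environmental layers (chosen over variogram-based simulation
for simplicity and light dependencies); spreading-dye species ranges that
hit their target sizes exactly and are 4-connected by construction; a
tenure mosaic grown to the requested class proportions; and ordinal statuses
drawn from the true regression with phylogenetic + spatial + independent
noise, discretized by deciles so every level is populated in expectation.
A designated fraction of species has its observed status lowered by 3 scale
points (about 1.5 categories) — these "suppressed" species are the ground
truth that latent-risk recovery is tested against.

Reference study conditions (the generator defaults): a 100 × 100 grid of
1-km cells, 60 species, 20 trees, suppressed fraction 0.1, true covariance
weights (0.35, 0.15, 0.5) with a 30-km spatial range, and range sizes
log-uniform between 8% and 50% of the region. Two conditions deserve
explanation because they were genuinely open design choices:

* **Trans-boundary ranges.** Ranges grow on the region grid plus a 30-cell
  margin, with the seed cell inside the region, so the in-region proportion
  `A` varies realistically below 1 instead of being identically 1 — without
  this, every target sits at the 0.70–0.75 cap and the target formula's `A`
  term is vacuous.
* **An Indigenous-estate-dominated tenure mosaic with dispersed leasehold.**
  The default mix gives PA/IPA 18% and the Objective-2-eligible classes
  (Indigenous freehold, Native Title, Native Title pastoral use) most of the
  remainder, and the ineligible classes (pastoral, other, ILUA) are grown as
  planning-unit-scale patches with spaced seeds rather than one contiguous
  block. Both choices keep the voluntary-declaration objective *well-posed*:
  a species' capped 75% target must be attainable from eligible tenure, which
  fails when a compact range can sit wholly inside a contiguous ineligible
  cluster. Even so, feasibility is probabilistic — some random landscapes
  still produce a small shortfall for one or two species, in which case
  `build_problem()` raises a structured infeasibility report naming the
  species and shortfall instead of silently relaxing the target.

What the generator does **not** emulate: real geography (the region is a
rectangle in a planar synthetic CRS), cadastral shapes, observation error in
threat listings beyond the suppression mechanism, trait missingness,
spatially biased survey effort, or correlations between tenure and habitat
quality. Passing tests therefore demonstrate that the *methods* recover
known structure under controlled conditions — not that any particular real
landscape satisfies these models' assumptions.

## Numerical details worth knowing

* Problem sizes in the shipped tests and demonstration were chosen so a
  complete run of the suite takes well under a minute of solver time: the
  enumeration oracle uses ≤ 15 units, coefficient recovery uses 200
  replicates at n = 128, latent-risk recovery 100 replicates with 3-tree
  samples, and the end-to-end determinism check runs the full demonstration
  twice.
* All generators are driven by a single integer seed; identical
  configurations give byte-identical Newick, CSV, and GeoJSON outputs.
* Degenerate inputs are handled explicitly: constant predictor columns and
  constant cost layers are errors naming the column; an all-equal risk
  vector scales to 0.5; an empty target set is an error advising a threshold
  change; `sigma2 = 0` in the generator is the admissible noise-free limit.
* Rasters are a minimal in-package grid class with plain-text ESRI ASCII
  (.asc) I/O and GeoJSON for vector output, keeping every artifact
  text-based and diffable.

## Known limitations

The ordinal response is modelled linearly; covariance weights are estimated
once for the full model and reused during stepwise selection and per-tree
refits; boundary length treats cropped units as full hexagons; the exact
solver's practical reach at gap 0 is a few dozen free units (beyond that,
set a small gap, as the demonstration does); and Objective-2 feasibility
depends on the tenure mosaic, as discussed above.
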