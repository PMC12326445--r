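---
title: "Relative strength variability for weighted networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative strength variability for weighted networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvnet)
```

## The measures

Weighted structural connectomes carry information in their edge weights that
binary graph summaries discard, yet most weighted summaries (strength
variance, clustering, efficiency) are strongly mutually correlated. This
package implements a family of measures built on the *relative node
strength*: how strong a node is compared with the company it keeps.

With $s_i = \sum_j W_{ij}$ the strength of node $i$ and $N(i)$ its
neighbour set, the plain relative strength is

$$r_i = \frac{s_i}{\frac{1}{|N(i)|}\sum_{j \in N(i)} s_j},$$

and the edge-corrected form removes each connecting edge before comparing,

$$r_i = \left[\frac{1}{|N(i)|}\sum_{j \in N(i)}
  \frac{s_j - W_{ij}}{s_i - W_{ij}}\right]^{-1},$$

which prevents a single strong reciprocal edge from inflating both sides of
the ratio. Setting `corrected = FALSE` recovers the plain form exactly.

**RSV** is the sample standard deviation of $\{r_i\}$ over all nodes. It is
zero on strength-regular networks and largest where strong and weak nodes
interconnect directly — star-like and core–periphery organisation — so it
reads as sensitivity of the strength hierarchy to targeted attack.

**hRSV** slides a window of $w$ consecutive nodes along the strength-ranked
node sequence and averages the within-window standard deviations of $r$
($n - w + 1$ windows). Small windows compare only similarly ranked nodes,
which turns the measure into a weighted analogue of *statistical
complexity*: low for both regular lattices and homogeneous random graphs,
high for structurally diverse networks. At $w = n$ the single window is the
whole network and hRSV equals RSV identically — the package treats this as
an exact invariant, not an approximation.

## Parameters that matter

* `window_size` (hRSV): defaults follow the convention of a small window
  (4) and a quarter of the parcellation ($21$ for $85$ nodes). The package
  validates on synthetic families that only the small window separates
  hRSV from RSV: at $w = n$ their rank correlation across random networks
  is 1 by construction, and it decays as $w$ shrinks.
* `corrected` (default `TRUE`): the edge-subtraction form. Degenerate terms
  ($s_i - W_{ij} \le 0$, e.g. leaf nodes) are dropped from the mean with a
  warning; a node whose every term degenerates — or whose neighbours have
  no strength beyond the shared edge, which would send the mean ratio to
  zero and $r_i$ to infinity — falls back to the plain ratio. `degenerate
  = "error"` makes these conditions fatal instead. Thresholded connectomes
  are dense enough that this path is rarely taken; it exists so the
  library never silently emits infinities.
* `prevalence_threshold` (default 0.5): cohort-level proportional
  thresholding retains edges present (weight > 0) in *at least* the stated
  fraction of subjects — the boundary case is kept. When several
  weightings share subjects, `run_compute()` derives the mask once from
  the reference weighting (streamline count when available, since all
  diffusion-weighted variants share the streamline-defined edge support)
  and applies it to every weighting; `mask_per_weighting = TRUE` derives
  one per weighting instead, since usage differs across pipelines.
* Ordering basis for windows: population-level analyses rank nodes once by
  the cohort-mean strength vector so every subject shares a ranking
  (`compute_measures()` does this automatically); single networks rank by
  their own strengths. Ties break by node order, deterministically.
* The SD estimator uses the $n-1$ denominator everywhere, which is why
  windows require $w \ge 2$. `rsv()` reports the standard deviation as the
  canonical value and carries the variance alongside, making the SD/variance
  choice explicit rather than implicit.
* Tier decomposition: nodes are ranked descending by strength and cut into
  near-equal contiguous tiers (sizes differing by at most one, larger tiers
  at the top), so an 85-node parcellation in 4 tiers gives 22/21/21/21 with
  tier 1 the hub end.

## Comparison measures

Five standard weighted-graph summaries are provided for exactly the
comparisons the variability measures are designed to survive: node strength
variance, strength assortativity (endpoint-strength Pearson correlation over
edges, `NA` — not 0 — when the ratio is 0/0 on strength-regular graphs),
Onnela's normalised clustering coefficient ($\tilde w = W/\max W$, per-node
average, degree-<2 nodes contributing 0, divided by density), routing
efficiency (mean inverse shortest-path length with edge length $1/w$ — the
dominant connectomics convention, recorded in the run's parameter sidecar),
and diffusion efficiency (mean inverse mean-first-passage time of the
weight-proportional random walk, computed exactly via the fundamental matrix
$Z = (I - P + \mathbf{1}\pi^\top)^{-1}$, $t_{ij} = (Z_{jj} - Z_{ij})/\pi_j$;
a dense solve is trivial at $n = 85$). Disconnection is handled
asymmetrically by necessity: unreachable pairs contribute zero to routing
efficiency, while diffusion efficiency refuses disconnected input (the MFPT
is infinite) and directs the caller to the largest component.

## What the generators emulate — and what they do not

`generate_network()` produces the archetypal families used throughout the
validation suite: Erdős–Rényi and homogeneous geometric graphs (both low
RSV, low complexity), ring lattices (the regular extreme, RSV exactly 0
under uniform weights), hub/core–periphery graphs (high RSV by
construction, with one guaranteed hub tie per periphery node so no node is
isolated), and heterogeneous geometric graphs — geometric graphs whose
per-node connection radii are Pareto($\alpha = 2$) distributed, the
simplest documented route to a heterogeneous degree distribution and the
family on which windowed variability is high. Edge counts are pinned to
`round(density * n(n-1)/2)` wherever the family permits, so density is
matched across families by construction rather than by tuning. Defaults
($n = 85$, density 0.6, lognormal $\sigma = 0.5$) mirror a
group-thresholded Desikan-scale connectome.

`generate_cohort()` adds per-subject multiplicative lognormal edge noise
and Bernoulli edge dropout around a shared base network, with metadata
drawn to resemble a large ageing imaging cohort (age $\sim$ N(63.9,
7.65$^2$) truncated to [44.6, 82.7] years, 46.6% male, three sites at
58/16/26%).

These generators are stand-ins, not fits: they reproduce the qualitative
ordering of the measures across organisational archetypes, matched in
density and weight scale. They do not reproduce spatial embedding of real
parcellations, distance-dependent connection costs, hemispheric symmetry,
or the empirical weight distributions of tractography. Passing tests
therefore demonstrate correctness of the measures and the direction of
their archetype contrasts — not that effect sizes on real connectomes will
match.

One subtlety the cohort tests exposed: the all-positive correlation block
among strength variance, clustering and routing efficiency seen in real
cohorts is reproduced only when subjects share an edge support and differ
by a global *additive* weight offset (as FA-like microstructure does).
Under purely multiplicative noise the per-network max-normalisation in
Onnela clustering pushes its correlation with the other two negative. The
test suite encodes the additive design explicitly.

## Cognitive battery: imputation and g

The battery workflow mirrors standard practice for large cohort studies:
subjects missing more than `max_missing` of the tasks (default 7 of 10,
strict inequality) are excluded; remaining gaps are filled by alternating
truncated-SVD completion — initialise missing cells at column means,
project to rank $r$, restore observed entries, repeat until the imputed
entries move less than `tol` — with the rank either fixed or chosen by
masked-holdout cross-validation over ranks 1–5. Observed entries are
preserved exactly, and non-convergence is flagged, never hidden. The
hard-rank alternating scheme was chosen over nuclear-norm relaxations
because it is deterministic given a seed and entirely adequate for a
10-column battery.

`extract_g()` z-scores the tasks (correlation PCA — tasks live on
incommensurate scales) and takes the first unrotated principal component,
z-normalised, with standardised loadings (task–component correlations) and
the explained-variance proportion. The component sign is anchored so the
"higher-is-better" task with the largest absolute loading loads
positively; the anchor is recorded in the result.

A point worth stating because it is easy to miss: the first principal
component of a one-factor model does *not* estimate the generating factor
loadings. PCA absorbs a share of each task's unique variance, inflating
every loading — by up to about 0.07 for a 10-task battery with loadings
spanning 0.4–0.75, as `population_pc1()` shows in closed form. The
estimator is validated against that closed-form estimand (and against the
generating loadings only in the equal-loading case, where the inflation is
within the test band). Simulation defaults for the battery reuse a
published 10-task loading profile with magnitudes spanning 0.42–0.75,
three tasks reverse-scored.

## Incremental variance by sequential residualisation

To ask what a new network measure adds to a conventional predictor stack,
`progressive_models()` orders predictors by convention (covariates, then
mean edge weight, then common graph measures, then the focal measure),
expands factors to centred dummies in level order, and applies classical
Gram–Schmidt: each column keeps only what is orthogonal to everything
before it, unit-normalised, then z-normalised. Classical (not modified) GS
is used deliberately — it is the textbook sequential-residualisation
recipe — with a collinearity guard that rejects any column whose residual
norm falls below $10^{-12}$ of its original. Because the resulting columns
are exactly uncorrelated, each one's squared correlation with the z-scored
outcome is its incremental $R^2$, the increments sum to the joint model's
$R^2$ to machine precision, and each coefficient's $t$-test coincides with
the sequential 1-df $F$-test. Order dependence is the point, not a bug:
permuting predictors moves increments between columns but never changes
the total, and both facts are asserted in the tests.

`association_scan()` handles the simpler covariate-adjusted screens:
outcome and measure are each residualised on the covariates, the measure
residuals are z-scored, and the standardised coefficient is reported with
Benjamini–Hochberg adjustment across the scanned family (the FDR procedure
is BH, recorded per run). Residualise-then-standardise is used rather than
entering the raw measure into a joint fit because the latter's coefficient
blows up when a measure is nearly a covariate function; the residualised
formulation returns the honest answer of approximately zero. Predictor
selection for the multivariable stack is left to the caller — no
multicollinearity-based automatic dropping is hard-coded.

## Numerical conventions and degenerate inputs

* Symmetry tolerance on load is $10^{-10}$ absolute; larger asymmetries
  are an error, not silently averaged, to surface upstream mistakes.
  Negative weights and self-loops are rejected/zeroed on construction.
* Measure tables serialise as decimal text with 12 significant digits;
  a round-trip read is exact at that precision.
* `all_measures()` converts individual measure failures into `NA` with a
  warning naming the measure, so one pathological subject cannot abort a
  cohort run; `read_cohort()` does the same at the file level.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; a single pipeline seed fans out to stage seeds by
  fixed offsets, so stages are independently reproducible.

## Problem sizes used in the validation suite

The shipped tests and the replication battery run at deliberately modest
sizes chosen to exercise every code path while keeping the suite quick on
a single core: exhaustive-style oracle checks on 1,000 random graphs of up
to 6 nodes; Monte-Carlo first-passage checks with $10^5$ walkers on an
8-node graph; archetype and complexity contrasts at $n = 85$, density 0.6
over 100 seeds; factor recovery at 5,000 subjects; error-control
simulations with 500 replicates; and a 50-subject end-to-end cohort run.
`run_replication_suite()` re-derives the core claims at these scales and
writes a pass/fail report.

## Known limitations

* The generators are qualitative archetypes; none is fitted to empirical
  connectome statistics, and conclusions about real-data effect sizes do
  not follow from the synthetic contrasts.
* hRSV's tier restriction computes relative strengths on the full network
  and windows within each tier; truncating windows at tier boundaries is
  one defensible reading of a windowed tier analysis, and the only one
  implemented.
* The mean-first-passage solve is dense ($O(n^3)$); fine for parcellations
  of a few hundred nodes, inappropriate for voxel-scale graphs.
* No site harmonisation beyond covariate adjustment, no mixed-effects
  models, no factor rotation or confirmatory structure on the battery —
  all out of scope by design.
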