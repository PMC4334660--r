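---
title: "Methods: dispersal, genetic landscapes and niche models for chequered cryptic species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal, genetic landscapes and niche models for chequered cryptic species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chequer)
```

`chequer` analyses pairs of parapatric cryptic species whose island
distributions are chequered: each island holds exactly one member of the
pair. Three independent lines of evidence are computed — where the
genetic breaks are (landscape), whether dispersal could have erased them
(network + strait graph), and whether climate alone predicts them (niche
models with a biotic layer). This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic tests do and do not establish.

## 1. Residual genetic landscape

**Model.** Divergence between localities grows with distance (isolation
by distance), so raw p-distances cannot be mapped directly: a long edge
would look "divergent" for trivial reasons. We therefore regress
between-site p-distance on geographic distance and map the *residuals*.
Three decay families compete on R² = 1 − SS_res/SS_tot:

* linear: `d = a + b·g`
* log-linear: `d = a + b·ln g`
* asymptotic: `d = a·(1 − e^{−b·g})`, `a, b ≥ 0`

The winner among converged fits supplies predictions; each Delaunay
edge's residual (observed − predicted) is attributed to the segment
midpoint and interpolated by inverse distance weighting (IDW). Peaks of
the interpolated surface mark places where divergence exceeds the
regional decay trend — phylogeographic breaks, typically sea straits.

**Assumptions and choices.**

* Geographic distance is great-circle (haversine, km): planar degrees
  would distort over a study area spanning >10° of latitude. Midpoints
  are arithmetic means of (lon, lat), matching planar GIS practice at
  regional scale; no projection is applied (the datum question is
  genuinely open in this workflow — decimal-degree planarity is assumed
  and stated).
* Specimens within `tol` great-circle degrees collapse into one site
  (single linkage); default `tol = 0` (exact coordinate match).
  Between-site distance is the mean over all cross-site specimen pairs;
  a site's diagonal is its mean within-site distance.
* The regression is fitted on the Delaunay-edge pairs, not all site
  pairs, keeping the model and its residuals on the same support; an
  `fit_on = "all_pairs"` mode exists because the alternative reading is
  defensible.
* The asymptotic family uses `nls` (port algorithm, non-negative
  bounds) with multi-start (`a = max d`; `b ∈ {1/mean g, 1/max g}`);
  non-convergence is recorded, not fatal — at small geographic scales
  this family often has no stable optimum.
* IDW uses power 2 and no search radius by default (both exposed and
  logged); a cell center within 1e-9° of a data point takes that
  point's value exactly, so the surface is exact at the data and, being
  a convex combination, bounded by the residual range everywhere.
* The Delaunay triangulation is computed by Bowyer–Watson insertion and
  is verified in the tests against a brute-force empty-circumcircle
  oracle. Collinear or <3-site inputs error with advice to use direct
  pairwise mode.

## 2. Haplotype network and minimum dispersal events

**Model.** Only unambiguous sequences (no N, no IUPAC codes, no gaps)
are collapsed into haplotypes; indels are not scored as steps. Edge
weights are exact Hamming distances. The network keeps every edge
belonging to at least one minimum spanning tree (Kruskal with ties
retained), which also preserves the tie loops that statistical-parsimony
software reports as ambiguous connections; edges longer than
`connection_limit` steps are removed, so the graph may fall apart into
components.

The full statistical-parsimony connection probability is deliberately
replaced by this explicit limit, default **11 steps** — the conventional
95% parsimony bound for a ~658-bp COI barcode. Downstream dispersal
scoring depends only on adjacency and components, which the limited
spanning network reproduces for shallow intraspecific variation
(star-like clouds around a widespread haplotype). For deep or reticulate
variation the approximation degrades; the limit is a config key.

**Dispersal scoring.** Land units are merged at the −50 m isobath
(glacial–interglacial mean coastline): crossings inside a merged pair
are never dispersal. Per network component, a crossing between units u
and v is witnessed when a haplotype occurs in both, or when two adjacent
haplotypes occur in u and v. The minimum event set is a minimum spanning
tree of this evidence graph under strait-length weights (ties: shorter
length, then lexicographic unit names) — the fewest crossings explaining
the occupancy regardless of where the ancestor sat. Events are unordered
crossings: direction would need rooting information the network lacks.

**Conservative exclusion.** An event is auto-excluded as ambiguous when
*both* (a) an alternative route between its units exists through
intermediate occupied units whose longest single crossing is strictly
shorter (minimax path over strait widths), and (b) a witnessing
haplotype is interior (network degree ≥ 2), i.e. plausibly ancestral, so
its extinction or non-detection on the intermediate units is the more
parsimonious story. Expert judgment cannot be fully formalized, so a
per-event override file is first-class and every automatic decision is
logged with its triggering alternative path. Strait widths always come
from the configuration, never from coordinates: isobath geometry is
data, not computation (a missing strait falls back to the great-circle
centroid distance, flagged and warned).

## 3. Maximum-entropy niche models

**Model.** Presence-background estimation of a Gibbs distribution over
the valid raster cells: `raw(x) = e^{λ·f(x)} / Z`, fitted by maximizing
the regularized training gain

`G(λ) = mean_presences(λ·f) − ln( mean_background e^{λ·f} ) − Σ_j β_j s_j |λ_j|`

which is 0 for the null model (uniform over background). Features are
min-max scaled to [0,1]; the H class uses the linear term plus forward
and reverse hinges `max(0, v−k)/(1−k)`, `max(0, k−v)/k` at `n_knots`
equally spaced interior knots (default 30); HQP adds squares and
pairwise products. Categorical layers (the biotic hull) enter unscaled
as 0/1 with linear-class regularization.

**Fitting.** Coordinate-wise Newton steps with exact soft-thresholding
against the L1 penalty; candidate steps whose exact penalized
improvement is non-positive are rejected, so the gain is non-decreasing
by construction (asserted each cycle; a decrease is an internal error).
Coordinates are cycled in descending order of the initial gradient,
fixed thereafter, making the per-variable gain attribution (percent
contribution) deterministic. Convergence: best single-coordinate
improvement < `tol` (1e-6) or `max_iter` (200) cycles.

The penalty scale `s_j` is the presence-sample standard deviation of
feature j, floored at `range_background(f_j)/sqrt(m)`: a feature
constant across m presences is still statistically uncertain, and
without the floor its coefficient is unpenalized and diverges (the
β→∞ ⇒ λ→0 limit would fail). Default multipliers: hinge 0.5,
linear/quadratic 0.1, product 0.2, categorical 0.1 — declared, logged
and overridable rather than silently inherited.

**Outputs.** Logistic suitability `L = e^H·raw / (1 + e^H·raw)` with H
the entropy of the fitted background distribution (null model ⇒ L = 0.5
everywhere); AUC as the Mann–Whitney rank statistic (ties 0.5) of test
presences vs background under replicated 75/25 subsampling; the max
sensitivity+specificity threshold over the sorted unique scores
(sensitivity = fraction of presences ≥ t, specificity = fraction of
background < t; ties resolved to the lowest threshold); percent
contribution from the gain trace; jackknife importance as the training
gain of each variable fitted alone.

**Variable selection.** Pairwise Pearson correlations on a seeded sample
of cells valid in all layers (default 10,000); the retained set is the
*maximum-cardinality* subset with all |r| < 0.8, found exactly by
maximal-clique enumeration on the compatibility graph (≤19 variables);
ties prefer variables with lower mean absolute correlation, then input
order. Constant layers are dropped with a warning.

**Biotic layer.** The peer species' occupancy is the alpha shape of its
presence points — the union of Delaunay triangles with circumradius ≤
alpha (default 10°, effectively a locally-concave convex hull at study
scale) — rasterized to 0/1 with every presence point's own cell forced
to 1. It replaces the least important climatic variable (lowest percent
contribution, ties by input order) so the climatic and biotic model
series use the same number of variables.

## 4. The synthetic world: what it emulates, and what a green test means

`default_world_config()` states the test world once:

* a 100 × 40 grid of 0.1° cells (lon 0–10, lat 41–45); two mainlands,
  four islands and one islet, as disjoint rectangles;
* strait widths {3, 5, 12, 90, 140} km plus one isobath merge
  (Islet0 → MainlandW), reproducing the field situation's contrast between
  short *unobserved* crossings (the 5 km contact strait between the two
  central islands) and long *observed* ones (90, 140 km);
* climate: precipitation of the driest quarter as a 10 mm/degree
  longitude gradient plus N(0, 4 mm) noise; a decoy layer correlated
  with it at r ≈ 0.97 (and mildly with the noise layer, as real
  bioclim decoys are — this makes the signal variable strictly
  preferable under the selection tie-break, by construction rather than
  by chance); an independent temperature-like noise layer;
* species threshold 62 mm with logistic softening 12 mm (a transition
  spread of roughly 50 mm, the scale of the response the study system
  shows); the wet-adapted species A holds the eastern mainland and two
  islands, the dry-adapted species B the rest — mutual exclusion is
  imposed at the unit level, on top of climate;
* sequences: 658 sites, 30 fixed interspecific differences (deep
  cryptic divergence, ≈ 0.046 p-distance), Poisson(2) founder
  substitutions per planted colonization, satellite mutations with
  probability 0.25 per specimen (star-like clouds), one N-bearing
  specimen per species to exercise ambiguity exclusion;
* 2 localities × 3 specimens per occupied unit; presences drawn
  per-cell Bernoulli with probability `0.5 · plogis(±(clim − t)/12)`.

All randomness flows from one root seed through named substreams
(world = seed, haplotypes = seed+1, presences = seed+2), so stages are
independently reproducible and the whole world is byte-identical under
a repeated seed.

A green synthetic suite establishes that the pipeline recovers *planted*
structure: the exact colonization count and lengths, the landscape
maximum on the contact strait, the signal variable's jackknife rank and
the peer hull's contribution rank. It does **not** establish performance
on real data: the generator has no coalescent genealogy, no homoplasy to
speak of, no spatially autocorrelated climate noise, no observation bias
beyond uniform thinning, and rectangles for islands. In particular the
ambiguity-exclusion rule is exercised on constructed cases, not on the
messy judgment calls real networks demand — which is why the override
file exists.

One assumption matters for the threshold-recovery test: with mutual
exclusion active, the realized climate response of each species is the
climatic logistic *truncated by unit occupancy*, so its midpoint is not
the planted threshold. `simulate_presences(world, mask_units = FALSE)`
provides the pure 1-D threshold world in which the response-recovery
property is well-posed; the masked world is used everywhere else.

## 5. Degenerate inputs and tie-breaks (summary)

* NJ: Q-ties resolved to the lowest-index pair in insertion order;
  negative branch lengths clamped to 0; supports floor-rounded integer
  percent. Species assignment midpoint-roots the tree; reference
  monophyly is checked *relative to other references* (queries may
  interleave).
* p-distance: a pair with zero comparable sites is an error naming the
  pair; IUPAC ambiguity codes count as missing (conservative — no
  partial-match rule is assumed).
* Minimum spanning structures (network and events): ties retained in
  the network (they are the ambiguous connections), broken
  deterministically (shortest, then lexicographic) in the event MST,
  which is conservative for the capability histogram.
* Alpha hull with <3 points degrades to point-buffer cells with a
  warning; cocircular Delaunay degeneracies are tolerance-handled.
* max-SSS threshold with all-equal scores returns that score;
  sens/spec ties return the lowest threshold.

## 6. Known limitations

* The parsimony `connection_limit` is a convention, not an estimate;
  matching a specific statistical-parsimony run may require adjusting
  it.
* Event direction is not inferred; counts and lengths only.
* Maxent coefficients are not numerically interchangeable with the
  reference Java implementation (different regularization schedule and
  feature bookkeeping); agreement is at the level of model structure,
  gain conventions and derived summaries, not λ values.
* IDW and the Delaunay graph treat coordinates as planar; at
  continental scales or high latitudes a projected CRS should be used
  upstream.
* The eastern-basin style "occurrence-only" event reconstruction (no
  sequences) is supported only by supplying a manual unit graph.
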