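---
title: "Signal-space methods: construction, overlap geometry, and null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-space methods: construction, overlap geometry, and null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warblerspace)
```

`warblerspace` studies a community-ecology question in acoustics: when
migrant songbirds pass through the breeding range of close relatives, how
much of the residents' acoustic "signal space" do they transiently occupy?
The package implements the whole chain from song measurements to inference:
signal-space construction, convex-hull niche geometry, checklist-based
phenology, time-course models, a randomization null model, and a
phylogenetic-distance regression. This vignette documents the models and
the numerical decisions behind each stage.

## The signal space

Each song is summarised by six traits: duration (s), number of notes, and
peak, minimum, and maximum frequency plus bandwidth (Hz). Because traits
are on wildly different scales, the ordination is a PCA of the
**correlation matrix** of per-male trait means: songs are first averaged
within each male (so well-recorded males do not dominate), each trait is
z-scored, and the 6 × 6 correlation matrix is eigendecomposed. Components
with eigenvalue > 1 (Kaiser rule) are retained; for warbler-like trait
structure this yields two components — one frequency axis, one
temporal/bandwidth axis — and all downstream geometry assumes exactly two.
Scores are dimensionless "PCA units".

Two conventions are fixed because the data do not determine them:

* **Sign**: each component is flipped so its largest-magnitude loading is
  positive. Orientation is irrelevant to every downstream quantity (areas
  and distances are sign-invariant) but a fixed convention makes runs
  reproducible.
* **Ties**: eigenvalues are sorted descending; exact ties (measure-zero,
  but tests construct them) keep trait order.

Note that bandwidth = max − min frequency makes the six traits linearly
dependent, so the smallest eigenvalue is ~0; this mirrors how the traits
are measured in the field and is harmless to a correlation PCA.

## Niches and overlap geometry

A species' signalling niche is the convex hull of its males' (PC1, PC2)
scores; its area comes from the shoelace formula and its centroid is the
area-weighted polygon centroid. Fewer than 3 males, or exactly collinear
scores, is an error rather than a zero-area niche: proportions of an empty
niche are undefined, and with the study design's minimum of 4 males per
species a degenerate hull indicates broken data. The community signal
space is, by convention, the hull over **all** males' scores (the union of
species hulls is available as an option; it excludes unoccupied space
between niches and is always smaller).

Pairwise overlap is the exact intersection area of two convex hulls
(Sutherland–Hodgman clipping). Any positive area counts as "an overlap" —
no minimum-area threshold — so floating-point slivers matter: vertices
within 1e-9 PCA units are treated as coincident and intersection areas
below 1e-12 are reported as exactly zero. Hulls that touch only at a point
or an edge therefore do *not* count as overlapping.

The proportion of a focal niche covered by a *set* of other niches needs
the area of a union, where naive summation double-counts. Each other hull
is clipped to the focal hull, and the union area of the clipped convex
pieces is computed exactly by a vertical slab decomposition: the x-axis is
cut at every vertex and every pairwise edge crossing, so that inside a
slab the union's vertical cross-section length is linear in x and the
midpoint rule integrates it exactly. Monte-Carlo estimates cross-check
this machinery in the test suite; inclusion–exclusion for two polygons
holds to 1e-9.

## Phenology from checklists

The time axis comes from birding checklists. Filtering keeps complete
checklists with stationary or traveling protocols between April 1 and
June 15, and drops those with more than 10 observers, more than 5 hours,
or more than 5 km — strictly "more than", so boundary values survive.
Occurrence on a day is the percentage of that day's checklists reporting
the species; days with no checklists are *missing*, not 0% (absence of
effort is not evidence of absence). Daily values are averaged over 21
consecutive 3-day windows spanning days 96–158 (April 5 – June 6,
leap-year day numbering), and a species is "present" in a window when its
mean occurrence is **at or above** 1.5%. Replicate seasons are pooled by
calendar day before windowing; per-year averaging is available as a flag
and agrees exactly under balanced effort.

## Time-course models

For each window, the pairwise overlap table is restricted to co-present
species: counts of realized overlaps by pair type (migrant–breeding,
breeding–breeding, migrant–migrant), and for each present breeding species
the proportion of its niche covered by co-present migrants, co-present
breeders, and all co-present others. Window midpoints are standardized
(mean 0, SD 1).

Counts are modelled with a Poisson GLM (log link) of pair type crossed
with a polynomial in standardized day; degrees 1–3 are compared by AIC and
a Pearson-residual dispersion statistic is reported. Proportions are
modelled with a **fixed-effects** binomial GLM (logit link). Two
deliberate choices here:

* *No species random intercept.* A mixed model is the textbook choice for
  repeated measures per species, but proportion-of-area data in this
  family are severely overdispersed regardless, the random effect is
  orthogonal to the geometric questions the package answers, and a fixed
  species covariate is available as an option. The model metadata records
  the simplification.
* *Nominal binomial weights.* Area proportions are not counts of trials;
  each observation is given a nominal weight (default 100) and the
  dispersion statistic is reported alongside so the arbitrariness is
  visible rather than hidden.

Polynomials are raw powers of the standardized day by default (centering
already removes most odd/even collinearity); orthogonal polynomials are a
flag. At the migration peak — the window with maximum richness, ties
broken reproducibly under a seed — migrant-caused and breeder-caused
overlap of each breeding species are compared with a classic paired t
statistic. The hand-rolled statistic (rather than `t.test`, which is the
oracle in the tests) pins down the degenerate conventions: all-zero
differences give t = 0, p = 1; constant nonzero differences give infinite
t with p = 0.

## The dispersion null model

Whether niches are spread out more evenly than chance is tested by
randomization: the observed statistic is the mean Euclidean distance
between all pairs of niche centroids; null communities redraw every
individual's (PC1, PC2) position independently and uniformly within the
observed per-axis score ranges, preserving the number of species and each
species' number of males. The Z score is (observed − null mean)/null SD
with the sample-SD convention (a population-SD flag exists; at 10⁴
replicates they differ negligibly, and the package's documented
three-value example pins the convention). Classification uses ±1.96; an
empirical two-sided tail probability with the +1/(n+1) correction is
reported alongside so inference need not lean on normality of the null.
Per-pair tests resample only the two species of the pair, within the full
observed ranges, and the community summary reports the proportions of
pairs over-/under-dispersed or random.

One numerical finding worth recording: the species "centroid" on the null
side defaults to the *mean* of the sampled points; the centroid of their
convex hull is offered as a flag. The two are **not** interchangeable
numerically. Hull centroids of uniform samples are driven by extremes and
concentrate at rate 1/n, versus 1/√n for means, so the hull-based null
distribution is tighter and |Z| grows faster with per-species sample size
(in our tests, roughly twice as large by n = 24). Both conventions agree
on sign and classification, which is what the tests assert; published Z
magnitudes are comparable only within one convention. The observed side
always uses the hull centroid of the real niches.

The test suite calibrates the machinery: data generated under the null
recipe are rejected at |Z| > 1.96 in 5% ± 2 percentage points of 500
seeded repeats (2,000 replicates each, a 10-species community with 4–8
males per species — sizes chosen to keep the calibration experiment well
inside a laptop's patience while leaving binomial noise on the rate small
relative to the ±2-point band).

## Phylogenetic distance and signal-space proximity

Patristic distances (sums of branch lengths between tips) come from the
input phylogeny; the package consumes a Newick tree and does no tree
inference. The model is OLS of log centroid distance on pair type crossed
with patristic distance, with per-type simple slopes and Tukey-HSD
contrasts of the adjusted type means evaluated at the mean patristic
distance (the covariate value is configurable — the choice matters when
slopes differ). Pairs with identical centroids are excluded from the log
fit with a warning rather than offset-adjusted. Pairwise distances are not
independent observations; the output says so and reports n rather than
pretending otherwise.

## The synthetic-data generator

Every stage is testable without field data because the generator emulates
the study's three inputs:

* **Songs**: a two-level Gaussian model — species mean + individual offset
  (between-male SD) + song offset (within-male SD). The (min, peak, max)
  frequency triple is sorted into order after sampling and bandwidth is
  recomputed, which keeps marginal means at the profile means without
  rejection loops; note counts are rounded with floor 1 (the analysis
  treats them as continuous, so integerization is cosmetic); durations are
  clamped positive.
* **Checklists**: per-day detection probability is peak detectability
  scaled by a symmetric triangular phenology curve that is zero outside
  the species' arrival–departure window (Gaussian and constant curves are
  options); configurable fractions of checklists violate each filter rule.
* **Phylogeny**: a Yule tree with optional Brownian trait evolution to
  induce positive phylogenetic signal.

The bundled 30-species demo community mirrors the published study design:
19 migrants and 11 breeders, the published per-species numbers of recorded
males (4–24), 8 songs per male, breeders arriving from early April and
staying, migrants on staggered stopovers that all end by day 152. Trait
means are spread deterministically over realistic warbler ranges (peak
frequency 3.5–8 kHz, durations 1–3 s, 4–24 notes) and between-male SDs
were chosen so that roughly a fifth of species pairs overlap and mean
niche area is a few percent of the community area, the density the
published community shows. Within- versus between-male variance components
are stated in the profiles, not hidden in code, because the study itself
does not report them.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: no spatial structure (one site pool), no
observer heterogeneity or effort covariance in detection, no within-season
trait drift, a single pooled season (replicate simulations stand in for
years), and Gaussian traits with no skew or heavy tails. The geometry,
filtering, and model code are exercised fully; ecological realism of any
particular parameter set is not a claim the tests make.

## Problem sizes and runtime

The default test and analysis sizes are deliberate: the demo community has
329 males and 2,632 songs (matching the scale of the published recording
effort), community null models use 10⁴ replicates, per-pair nulls 10³,
the geometry cross-checks use 10⁵ Monte-Carlo points on 54 random
configurations, and GLM coverage experiments use 100 seeded replicates.
The full pipeline on the demo community runs in seconds; the complete test
suite in a few minutes.

## Known limitations

* All geometry is 2-D convex-hull based; kernel hypervolumes, 3-D+ overlap
  and non-convex niches are out of scope.
* The binomial time-course model is a pragmatic fixed-effects GLM, not a
  GLMM; its dispersion statistic should be read before its p-values.
* Null models randomize PCA scores, not raw traits; conclusions are about
  dispersion within the realized signal space.
* Hull area grows with sample size (the sample-size regression quantifies
  this); no correction is applied, so cross-species area comparisons
  inherit sampling-effort differences.
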