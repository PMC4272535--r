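---
title: "Validating spatial stochastic models with stmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating spatial stochastic models with stmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmc)
```

## The problem

Stochastic models of multicellular systems — growing bacterial colonies,
aggregating cell populations, developing tissues — produce simulation output
that is spatial as well as temporal. Classical statistical model checking
validates such models only against scalar time courses (concentrations,
counts). `stmc` extends the approach to *pseudo-3D* traces: at every
timepoint the state carries one or more m×n grids of non-negative values,
each value the density of some entity at a discretised position (a 2-D grid
plus a density axis, hence "pseudo-3D"). The package answers questions of
the form

> "Does the probability that a cluster of cells eventually forms and
> persists near the attractant peak exceed 0.9?"

by (1) detecting spatial entities in each trace, (2) summarising each entity
with a fixed set of spatial measures, (3) evaluating a bounded linear
spatial temporal logic (BLSTL) formula on the resulting symbolic trace, and
(4) aggregating per-trace truth values with a sequential statistical test.

## From grids to entities

Two detectors turn grids into entities.

**Regions** are connected groups of positions whose values exceed a
threshold — sectors in a colony, patches of tissue. `detect_regions()` runs
a classical image-processing pipeline: the grid is normalised to a 0–255
grayscale image (`grid_to_grayscale()`), then brightness/contrast
adjustment, grayscale morphological closing (3×3 box, `morphCloseNrOfIter`
iterations), Gaussian blur (`blurKernelSize`, with the standard
kernel-size-derived sigma when `blurStandardDev <= 0`), a strict binary
threshold, 8-connected component extraction with a two-level contour
hierarchy (outer boundary plus holes, traced through pixel centres by
Moore-neighbour tracing), Douglas–Peucker polygon approximation, and a
strict minimum-size filter (`|positions| > epsilonSize`). With neutral
parameters (unit gain, no closing, kernel 1) the pipeline reduces exactly
to thresholding plus connected components, which is the ground truth the
test suite checks against a flood-fill oracle. A `pointMode` switch treats
every above-threshold position as a one-pixel region; it is meant for
single-cell entities where a full segmentation would be overkill and pileup
is carried by the grid value itself.

Because thresholding happens after normalisation, the value threshold of
the underlying definition is expressed on the intensity scale: a raw-value
threshold `T` corresponds to `thresholdValue = round(255 * T / max)`.
Thresholding is applied to the image *after* closing and blur; those steps
deliberately modify values, and the post-processing threshold is taken as
the definition of region membership.

**Clusters** are groups of regions that lie close together —
`detect_clusters()` runs DBSCAN under the centroid-distance pseudometric
`centroid_distance()`. Plain DBSCAN assigns border points (reachable from
several clusters) to whichever cluster happens to be visited first, so its
output depends on input order. The variant used here is order-independent:
the input is first brought into a canonical (centroidY, centroidX) order, a
region is a core region when its closed neighbourhood within
`epsilonDistance` holds strictly more than `epsilonSize` regions, clusters
are the connected components of core regions, and each border region is
assigned to the cluster of its *nearest* core region (ties to the lowest
cluster label). The permutation-invariance property is tested directly
with 20 random input permutations.

Both size thresholds are strict (`> epsilonSize`), matching the strict
inequalities of the underlying definitions.

## The eleven spatial measures

Every entity is summarised by `region_measures()` / `cluster_measures()`:

* **clusteredness** — for a region, `area / (area + total hole area)`,
  a compactness score in [0, 1]; for a cluster or a collection, the
  inverse of the mean pairwise centroid distance. Collections with fewer
  than two members (or coincident centroids) use divisor 1, so a singleton
  has clusteredness 1 — this convention keeps values finite and in a
  natural range where the definitions are silent.
* **density** — mean grid value over the covered positions (pooled over
  all member positions for a cluster); for a collection, the mean member
  density divided by the mean pairwise centroid distance.
* **area** — shoelace area of the outer polygon minus hole areas; for a
  cluster, the area of the convex hull of all member regions (holes
  between regions are ignored by construction).
* **perimeter** — perimeter of the outer polygon; holes are ignored.
* **distanceFromOrigin** — minimum distance from the outer polygon to the
  centre of the discretised space, `((cols-1)/2, (rows-1)/2)`; zero when
  the origin lies inside.
* **angle** — the angle subtended at the origin P: the line through the
  hull centroid C perpendicular to PC is intersected with the convex hull,
  and the two extreme intersection points A, B define the angle APB in
  degrees. When the perpendicular line meets the hull in more than two
  points (collinear edges), the extreme intersections are used. P inside
  the hull gives 360; a point-like hull gives 0.
* **triangularMeasure / rectangularMeasure / circularMeasure** — the
  entity's area divided by the area of its minimum-area enclosing
  triangle, rotated rectangle, and circle (`shape_measure()`); fuzzy
  similarities in [0, 1]. The discrete `shape` label is the argmax of the
  three, with the fixed tie order triangular > rectangular > circular.
* **centroidX / centroidY** — the polygon-moment centroid (vertex mean for
  degenerate polygons).

The enclosing rectangle uses rotating calipers over hull edge directions
(exact, by the flush-side theorem). The enclosing circle uses a
deterministic incremental Welzl construction (exact). The enclosing
triangle exploits the flush-side property — at least one side of the
optimal triangle lies on a hull edge — and, for each flush edge, minimises
the support-line triangle area over the two remaining directions with a
vectorised grid scan refined by coordinate-wise golden-section descent;
grid lines are placed on every hull-edge normal so multi-flush optima are
hit exactly. The search is deterministic and agrees with closed-form cases
(a triangle scores 1; a square's minimal triangle has twice its area; a
regular hexagon's has 1.5 times; a disc tends to the circumscribed
equilateral triangle) to at least 1e-7, and with an independent
multi-start optimisation oracle on random hulls to 1e-5.

Degenerate inputs are handled by convention: zero-area polygons score 0 on
all three shape measures, fall back to the vertex-mean centroid, and a
region with zero total area has clusteredness 1.

`silhouette_index()` summarises a whole clustering with the mean Silhouette
width over member regions (centroid distance as dissimilarity, singleton
clusters contributing 0, via `cluster::silhouette`). With fewer than two
clusters, or only singleton clusters, the index is undefined: `NA` is
returned and no `avgClusterednessClusters` state variable is emitted for
that timepoint, so downstream comparisons on the missing variable evaluate
false rather than fabricating a value.

## STML: the trace interchange format

Traces are exchanged as STML (Spatial Temporal Markup Language) XML files:
an `<experiment>` holds one or more `<timepoint value="...">` elements,
each holding `<spatialEntity><pseudo3D type="region|cluster">` records with
one child element per measure (plus the optional `shape`), and
`<numericStateVariable><name/><value/>` records with unique names per
timepoint. The normative definition is the XSD shipped at
`system.file("extdata", "STML_L1V1.xsd", package = "stmc")`; `read_stml()`
validates against it *and* re-checks every range constraint
programmatically so violations are reported with the offending element.
Missing timepoint values are resolved as: first timepoint 0, later ones
previous value plus one, predefined values kept (`resolve_timepoint_values()`,
idempotent, strictly increasing values enforced). Numbers are written in
full-precision plain decimal, so a write/read round trip reproduces the
experiment exactly.

## BLSTL and its evaluation

`parse_pblstl()` reads statements of the form `P >= 0.9 [ formula ]` with
theta strictly inside (0, 1). Formulas combine bounded temporal operators
`F [a, b]`, `G [a, b]`, binary `U [a, b]` and `X [k]`; Boolean connectives
`~`, `^`, `V`, `=>`, `<=>`; comparisons of numeric expressions (`=` means
agreement within 1e-9 on reals); state-variable references `{name}`; the
next-state difference `d(...)`; arithmetic functions (`abs`, `ceil`,
`floor`, `round`, `sign`, `sqrt`, `trunc`; `add`, `subtract`, `multiply`,
`divide`, `power`, `min`, `max`); and statistics over the dynamic
collections `regions` and `clusters` (`count`, `mean`, `median`, `mode`,
`min`, `max`, `sum`, `stdev`, nearest-rank `percentile`, and `covariance`
across two collections). `filter(collection, constraint)` restricts a
collection by a Boolean constraint over the eleven measures compared
against constants; state variables inside filters are a semantic error.
The full grammar ships as `extdata/pblstl_grammar.ebnf`.

Evaluation (`evaluate_blstl()`) uses bounded semantics with windows
relative to the current state's time value, nesting cumulatively — the
standard bounded-LTL reading, which coincides with absolute intervals when
evaluation starts at time 0. Three deliberate conventions:

* A temporal window (or `X [k]`, or `d` at the last state) that extends
  beyond the trace end raises a `stmc_trace_too_short` error rather than
  guessing: the trace provider is responsible for supplying traces that
  cover the formula horizon.
* A missing state variable, or a non-count statistic over an empty
  collection, makes the innermost enclosing comparison false. Entity
  collections are dynamic sets whose cardinality legitimately drops to
  zero, so emptiness is a normal state of affairs, not an error.
* `covariance` pairs entities by canonical detection order and truncates
  to the shorter collection (with a warning when cardinalities differ);
  no natural pairing exists across entity types, and index pairing is the
  only order-stable choice.

The evaluator's principal oracle is a naive reference implementation of the
same semantics written independently in the test suite; 500 random
(formula, trace) pairs must agree exactly, alongside duality properties
such as `~F[a,b] phi == G[a,b] ~phi`.

There is no dedicated oscillation operator: "the quantity rises and later
falls" is expressed by nesting, e.g.
`F [a, b] ((d(e) > 0) ^ F [0, b] (d(e) < 0))`.

## Probabilistic checking

A PBLSTL statement `P ~ theta [ psi ]` asks whether the probability that
`psi` holds on a random trace satisfies the comparator. Each loaded trace
contributes one Bernoulli observation (the truth of `psi` from the trace's
first state); five algorithms decide from the stream
(`checker_config(method = ...)`):

* **SPRT** (`check_sprt`): Wald's sequential probability ratio test of
  H0: p >= theta + delta against H1: p <= theta - delta with user error
  bounds alpha, beta and indifference half-width delta (default 0.05).
  With all-true observations at theta = 0.9, delta = 0.05,
  alpha = beta = 0.05 it accepts H0 after exactly 27 observations — the
  Wald closed form, which the tests pin down.
* **Chernoff–Hoeffding estimation** (`check_chernoff`): a fixed sample of
  `ceiling(log(2/delta) / (2 eps^2))` observations (738 at
  eps = delta = 0.05), then `phat ~ theta`. Other constant conventions
  exist in the literature for this bound; the Hoeffding form above is the
  one implemented, and the sample-size function is exported so callers can
  see exactly what will be drawn.
* **Bayesian hypothesis testing** (`check_bayesian_hypothesis`): the Bayes
  factor of `{p : p ~ theta}` under a Beta(a, b) prior — posterior odds
  over prior odds, computed from the incomplete Beta function — sampled
  until it passes the threshold T or 1/T.
* **Bayesian estimation** (`check_bayesian_estimate`): sample until the
  posterior mass of `(mean - w, mean + w)` reaches the coverage c, then
  compare the posterior mean with theta.
* **Black-box** (`check_black_box`): no stopping rule — a verdict from a
  fixed set of observations with an exact one-sided binomial tail p-value
  under p = theta (small = strong support). A tie `phat == theta`
  resolves in favour of the comparator's closed side (`>=`/`<=` true,
  `>`/`<` false).

Sequential methods that exhaust the trace supply (or hit `maxTraces` /
`maxSeconds`) before deciding fall back to the black-box verdict over the
observations gathered so far, flagging `exhausted = TRUE` and
`methodUsed = "black_box"` — the same convention large benchmark runs use
when the simulation budget runs out. The SPRT here is the classical Wald
test; published refinements that reduce the number of input parameters
differ in their initialisation, not in the error guarantees, and the
classical form keeps the configuration explicit.

`check_specification()` evaluates a whole list of statements in a single
pass: each trace is loaded once and fed to every still-undecided
statement, the per-statement sequential tests advance independently, and
the results are provably identical to per-statement runs against the same
ordered provider (both routes share one tester implementation, and the
equivalence is also tested). Trace providers fix the canonical order:
lexicographic file names for `trace_provider_directory()`, invocation
order for generator scripts/functions, with per-invocation seeds derived
as `seed + i - 1`.

## The synthetic case studies

The package must be testable end to end without external simulators, so
`generate_colony_trace()` and `generate_chemotaxis_trace()` reproduce the
qualitative phenomenology the example specifications test — not the
mechanistic models that originally motivated them.

**Colony sectors.** Radial growth on a 101×101 grid from a single central
founder: every empty position 4-adjacent to the colony is colonised each
timepoint, inheriting the majority phenotype of its occupied neighbours
(ties at random) and switching wild-type → mutant with probability
`switchProbability` (default 0.05 over 40 timepoints). The switch is
one-directional by design: with symmetric switching the colonisation
process behaves like a voter model and drifts toward a fine-grained 50/50
mixture in which no coherent sector survives, whereas one-way switching at
the default rate produces distinct wedges whose triangular shape measure
dominates in a majority of seeds (a frozen-seed test asserts this). The
analysed grid is the mutant *fraction* `mutant / (wildtype + mutant)`,
zero at empty positions.

**Chemotactic aggregation.** 100 cells on a 100×100 lattice (1%
occupancy), a static Gaussian attractant with mean 50 and standard
deviation 10 in both coordinates, 200 steps recorded every 5. Each step a
cell follows the gradient with probability `attractionStrength`, picking
uniformly among the near-maximal attractant values within a relative
`tieTolerance` (3%) of the best candidate — strict uphill motion far from
the peak, local diffusion on the near-flat plateau around it — and
otherwise diffuses to a random neighbour. Two rejected alternatives
motivated this rule: strict greedy ascent stacks every cell onto the
single peak pixel, after which no cluster exists (a cluster needs more
than `epsilonSize` member regions and a one-pixel stack is one region);
a Boltzmann move kernel on the attractant value is too weak far from the
peak, where the Gaussian is nearly flat, and cells never arrive. The
near-tie rule yields a persistent multi-pixel pile-up blob, matching the
pileup imagery of the case study, and drops the mean distance to the
gradient centre by a factor of ~20 over a simulation (tested against the
<50% criterion, with a <10% null drift at strength 0).

What the generators do *not* emulate: mutation/fitness kinetics, cell
exclusion volumes, attractant dynamics (the Gaussian is static), or
realistic time scales. Passing tests therefore demonstrate that the
detection–measurement–logic–statistics pipeline behaves correctly on data
with the right spatio-temporal structure; they are not evidence about any
mechanistic model.

`trace_to_stml()` runs the full pipeline per timepoint (mutant-fraction
regions for colonies; point detection plus clustering for chemotaxis,
with the Silhouette emitted as `avgClusterednessClusters` when defined)
and returns a schema-valid experiment; `generate_stml_dataset()` writes
whole directories of STML files, and doubles as the on-demand generator
behind the `stmc synthesize` command-line tool.

## The example specifications

`extdata/specs/phase_variation.pblstl` (8 statements) and
`extdata/specs/chemotaxis.pblstl` (6 statements) transcribe the two case
studies' natural-language requirements into the package's grammar, with
constants rescaled to the generators' lattices and calibrated once from
pilot runs. Two transcription choices deserve a note. The aggregation
statement is written as persistence, `F [0, 100] (G [0, 100] (...))`,
because on a finite lattice a transient random cluster can wander near the
centre even without chemotaxis; persistence separates the two regimes
cleanly (all 20 attracted seeds true, all 20 null seeds false in the
acceptance run). And the sector-angle statement ("sectors subtending more
than 120 degrees are rare") is kept in its original form although the
synthetic colonies' sectors are far wider than real phase-variation
sectors — it is expected to be judged false on packaged data and is
shipped as a deliberately discriminating negative example.

## Problem sizes and tolerances

The test suite and the acceptance script run at desk scale by choice: 500
random formula/trace pairs for the logic oracle, 100 raster fixtures for
the geometry oracles (1e-6), 20 input permutations for order-invariance,
200 repetitions for the empirical error rates of the SPRT and the Chernoff
estimate (nominal + 0.03 slack), 20 seeds per arm for the end-to-end
chemotaxis verdicts, and 20 frozen seeds for the colony sector check.
Geometric comparisons use 1e-6 except the enclosing-triangle cross-check
(1e-5, the convergence tolerance of the independent oracle). Equality on
reals inside the logic is 1e-9.

## Known limitations

* Geometry is strictly 2-D: no volumes or 3-D shape descriptors.
* Each timepoint is analysed independently; entities are not tracked
  across time, so "the same sector" is not a first-class notion — only
  statistics of the entity population are.
* The three basic shape measures cannot describe composite patterns.
* The probabilistic layer assumes observations are i.i.d. across traces;
  nested probabilistic operators are not supported (one `P` at the top).
* The STML dialect is normatively defined by the shipped schema; files
  produced by other tools may use a different concrete layout and would
  need conversion.
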