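---
title: "Statistical model checking of multiscale spatio-temporal traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical model checking of multiscale spatio-temporal traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstmc)
```

## The problem

Multilevel computational models of biological systems — an agent-based
tissue model coupled to intracellular reaction networks, say — produce
simulation output that spans several levels of organization at once.
Verifying such a model means checking that its simulated behaviour conforms
to a formal specification that can talk about *numeric* quantities
(concentrations, pressures, counts), about *emergent spatial structures*
(cell populations, damaged-tissue patches) and about how properties at one
scale relate to properties at another. Because the models are stochastic,
a single trace proves nothing: the specification is probabilistic,
`P ⋈ θ [ψ]`, and deciding it requires statistical reasoning over many
simulation runs.

`mstmc` implements this pipeline offline: it consumes timed traces (not
models), detects and quantifies spatial entities in discretised spatial
snapshots, evaluates bounded spatio-temporal logic formulas per trace, and
aggregates per-trace Boolean outcomes with one of five approximate
probabilistic model-checking algorithms.

## The multiscale architecture graph

The hierarchy of scales and subsystems is a rooted directed tree whose
vertices are `(scale, subsystem)` pairs, written `scale.subsystem`. Two
partial orders are derived from it: `a < b` holds when the unique
root-to-`a` path passes through `b` (so `a` is a finer-grained constituent
of `b`), and `a ≤ b` also admits equality. Formulas use these orders to
quantify over whole subtrees ("all tissues below the damaged liver")
without enumerating vertices. A `scale.subsystem` mentioned in a formula
but absent from the graph is a binding error at parse time — a deliberate
choice, since a typo that silently selected nothing would make false
claims vacuously true.

## Traces and the XML trace format

A trace is a strictly increasing sequence of timepoints. Each timepoint
carries numeric observations and spatial-entity records; both are
annotated with their vertex. The XML format mirrors this structure
(`experiment` → `timepoint value="t"` → `spatialEntity` /
`numericStateVariable`), with the timepoint attribute holding the
*timestamp*, not an index. Numeric values are serialized at 17 significant
digits, which round-trips IEEE doubles exactly; the test suite asserts
bit-faithful round trips on fuzzed traces.

Two policies are worth stating explicitly:

* **Grid values are normalized to [0, 1] by the caller.** The density
  measure is then a plain mean and stays inside its declared range by
  construction.
* **A numeric variable missing at a timepoint is an error**, with an
  opt-in last-observation-carried-forward mode (`locf = TRUE`). Silent
  imputation hides simulator bugs; the default refuses to guess.

## Spatial entity detection and the eleven measures

Snapshots are analysed as images. *Regions* are 8-connected (Moore)
components of positions with value `>= threshold`; a component survives
only if it has strictly more than `min_size` positions. *Clusters* are
DBSCAN groupings of regions under the Euclidean distance between region
centroids: a region is core when its neighbour count (including itself)
reaches `min_regions`, clusters are maximal density-reachable sets, and
unreachable non-core regions are reported as noise rather than forced
into a cluster. The DBSCAN variant is the classic algorithm with
deterministic index-order iteration and earliest-core tie-breaking for
shared border regions; reproducibility was preferred over fidelity to any
undisclosed "improved" variant.

Each entity gets eleven measures. The geometric conventions are:

* Coordinates are 0-based row/col at **pixel centers**; `centroidX` is the
  column coordinate, `centroidY` the row. Contours run through pixel
  centers, so a single pixel is a degenerate point with perimeter 0. This
  avoids library-specific half-pixel offsets and makes test expectations
  exact (a solid 3×5 block has perimeter 12, not 16).
* `clusteredness` of a region is its area divided by the area of its
  hole-filled mask (exactly 1 iff hole-free); for a cluster it is
  `1 − meanPairwiseDistance / gridDiagonal`, the diagonal being the
  distance between opposite corner pixel centers — our concretization of
  a formula whose original normalizer is not printed.
* `angle` is the angular width of the tangent cone from the grid centre
  `((m−1)/2, (n−1)/2)`; 360 when the centre lies in the hull, 0 for a
  single point.
* The shape measures divide the hull area by the area of the minimum
  enclosing triangle / rotated rectangle / circle. The rectangle uses
  rotating calipers (exact) and the circle Welzl's algorithm (exact). The
  triangle enumerates triangles bounded by lines through triples of hull
  edges; every such triangle contains the hull (the lines are supporting
  lines), so the ratio is guaranteed to stay in [0, 1], but the minimum
  over flush triples is an upper bound on the true minimum area — the
  optimal triangle is only guaranteed one flush side. In practice the gap
  is small (a rasterized disc scores ≈ 0.6, close to the analytic
  π/(3√3) ≈ 0.605), and the measure is used as a similarity score, not a
  metrology primitive. Entities with degenerate (zero-area) hulls take
  all three shape measures equal to 1.

The *registry* makes entity types and measures configuration rather than
code: an XML file declares which types and measures are active and which
built-in procedures implement them, so a restricted instance (e.g.
regions-only) changes validation and evaluation behaviour everywhere at
once. The original system generated C++ source from such configurations;
a runtime registry honours the same contract with far less machinery.

## The logic and its sample-based semantics

A query `P ⋈ θ [ψ]` wraps a bounded formula `ψ` built from comparisons of
numeric expressions, Boolean connectives and the temporal operators
`G[a,b]`, `F[a,b]` and binary `U[a,b]`. Numeric expressions reference
state variables (`{name}(scaleAndSubsystem = s.s)`), apply arithmetic
functions, or apply statistical functions to *collections* — either the
values of one spatial measure over a filtered entity set at the current
instant, or one expression sampled over a time window (`[a,b] expr`).
Entity sets support union/intersection/difference and constraints on
measures and on the vertex under the partial orders.

Semantics choices, each of which materially affects results:

* **Only observed timepoints are quantified over.** This is an offline
  monitor for recorded traces; no interpolation is invented between
  samples. All window ends are inclusive except the `U` left prefix
  `[t, t′)`. `U` follows the standard strong-until reading: if its right
  argument holds at the current instant the formula is true with an empty
  prefix.
* **`d()` is the forward difference** `e(i+1) − e(i)`, not a rate — it is
  used as a sign detector ("the count increases"). Applying it at the last
  timepoint raises a horizon error rather than fabricating a value.
* **Horizon checking is eager**: the least trace duration needed by a
  formula is the sum of nested upper temporal bounds (including temporal
  collections), and evaluation refuses to start on a shorter trace,
  naming the deficit.
* **Equality of reals** uses relative tolerance `1e-9·max(1,|a|,|b|)`:
  values have usually passed through floating-point pipelines and text
  serialization.
* **Statistical functions**: count, sum, avg (mean), min, max, median,
  mode (ties to the smallest value), product, stdev and var (sample,
  n−1), skew and kurtosis (moment ratios `m₃/m₂^1.5`, `m₄/m₂²`), geomean,
  harmean, covariance (paired collections, sample), and the quantile
  functions percentile / quartile with linear interpolation between
  closest ranks (`percentile({1..100}, 90) = 90.1`).
* **Empty collections**: `count(∅) = 0`; any other statistical function
  over an empty collection makes the *smallest enclosing comparison*
  false and emits a warning. A trace with no detected entities should
  falsify claims about those entities, not crash a thousand-trace run —
  and the warning keeps the event auditable.

## The five checkers

All five algorithms consume a stream of per-trace Boolean outcomes and are
deterministic given that stream; randomness lives entirely in trace
generation.

| checker | inputs | decision rule |
|---|---|---|
| black-box | fixed n | one-sided binomial tails at θ for H0 and H1; the hypothesis with the smaller p-value (less supported) is rejected; exact ties fall back to `x/n ⋈ θ` |
| Chernoff | ε, δ | `n = ⌈(4/ε²)·ln(2/δ)⌉`, decide `x/n ⋈ θ` |
| SPRT | α, β, half-width | Wald test of `p ≥ θ+h` vs `p ≤ θ−h`; boundaries `log((1−β)/α)`, `log(β/(1−α))` |
| Bayes estimate | Beta prior, variance threshold | stop when posterior variance < T; decide by posterior mean |
| Bayes factor | Beta prior, T | posterior odds `P(H0|data)/P(H1|data)` from the Beta CDF at θ; stop at B > T or B < 1/T |

The SPRT indifference half-width is an explicit required parameter
(default 0.05 in the CLI): the source material states α = β = 5% but not
the half-width, and the observed sample sizes cannot be reproduced
without committing to one, so the gap is documented rather than hidden.
The Bayes factor defaults to the raw posterior-odds ratio (matching the
description of B as posterior confidence in H0 relative to H1); a
prior-odds-normalized variant is available behind a flag for
comparability with the hypothesis-testing literature.

Natural logarithms are used throughout.

## The synthetic world

The package generates all of its own test inputs; none are downloaded.

The **toy model** is a unicellular organism on a 2×2 grid that assimilates
a nutrient from its current position (weight 0.50), converts it to energy
(0.30) and spends one energy per von Neumann move (0.20), weights
renormalized over enabled actions; with nothing enabled the cell goes
dormant. These action semantics are reconstructed from the published
narrative and validated *exactly*: the breadth-first enumeration (exact
rational arithmetic) reproduces all 27 reachable states, all 28 printed
transition probabilities, the six terminal states and the printed path
prefix of probability 1/4. The simulator uses floats and a seeded RNG,
and every simulated path is checked to exist in the enumeration. What the
toy world does *not* emulate: large state spaces, continuous time,
multi-unit nutrient stores, or concurrent actions — a green toy test
establishes the trace/logic/checker plumbing, not scalability.

**Shape grids** rasterize rectangles, discs and annuli with exact ground
truth (area, mask centroid, fill density); overlapping shapes are rejected
because their ground truth would be ambiguous. **Bernoulli streams** give
seeded i.i.d. outcomes for validating checker error rates; the acceptance
tests use 200 Chernoff meta-replicates and 1000 SPRT replicates per
boundary (error budget 2α), sizes chosen to keep the whole suite inside a
few minutes while leaving the Monte-Carlo noise well below the asserted
bounds.

## Known limitations

* 3D spatial entities and volume measures are out of scope.
* The triangle measure is an upper-bound approximation (see above).
* The surface syntax of the logic is reconstructed from a handful of
  published statements; the original grammar may differ in token
  spellings. The AST, semantics and binding rules are specified and
  tested independently of the surface syntax.
* Entity identity is per-timepoint; entities are not tracked across time.
* Traces are evaluated sequentially; no parallel trace evaluation.
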