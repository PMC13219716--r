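---
title: "Quantifying and simulating pavement-cell shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and simulating pavement-cell shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavecell)
```

## The problem

Epidermal pavement cells of many vascular plants take on interlocking,
jigsaw-puzzle shapes. The working model is mechanical: as a cell enlarges
in more than one direction, the unsupported span of its outer wall grows,
and with it the turgor-induced tensile stress; interdigitated lobes keep
the largest unsupported span — measured by the largest empty circle (LEC)
— small without limiting cell size. `pavecell` provides the three
computational layers needed to study this idea from cell outlines alone:

1. **Shape descriptors** for polygonal contours: area, perimeter,
   lobeyness, min-axis, and the LEC.
2. A **mass-spring simulator** of puzzle-cell emergence under
   time-varying, anisotropic tissue growth.
3. **Survey statistics** that aggregate per-species descriptor
   relationships across many species.

A fourth layer, the synthetic-data generators, produces every input the
pipeline needs, with known ground truth, so the whole package is testable
without microscopy data.

## Shape descriptors

All descriptors operate on a `contour`: a simple polygon (microns,
implicit closure, counter-clockwise).

* **Lobeyness** is the cell perimeter divided by the perimeter of the
  convex hull — the inverse of convexity. It is exactly 1 for convex
  outlines, scale- and rotation-invariant, and distinguishes genuinely
  lobed cells from long gently-curved ones.
* **Min-axis** is the width of the smallest enclosing rectangle: the
  minimum over axis orientations of the projection extent of the convex
  hull. Orientations are sampled densely (default 3600 over half a turn —
  width is pi-periodic, so sampling `[0, pi)` is equivalent to sampling a
  full turn); an exact mode minimises the per-hull-edge support width
  instead and is used to cross-check the sampled mode. The min-axis
  separates long thin cells (small min-axis, no need to lobe) from cells
  large in both dimensions.
* **LEC** is the radius (equivalently diameter or area — all derived
  fields are reported) of the largest circle inside the outline, found by
  best-first quadtree refinement of the signed distance to the boundary.
  A grid cell whose optimistic bound (centre distance + half-diagonal)
  cannot beat the incumbent by more than the tolerance is pruned; the
  default tolerance is 0.5% of the min-axis. Non-unique centres (e.g. a
  rectangle's medial segment) are legal; the refinement returns one
  maximiser deterministically, preferring smaller (x, y) on ties at equal
  radius.
* **Directional lobe bias** supports the simulator experiments: the
  excess total `|dy|` of the contour over its hull, divided by the
  analogous `|dx|` excess. Values above 1 mean vertically protruding
  lobes. Convex cells have no excess and are flagged `NA` rather than
  forced to a number.

Every descriptor has an independent brute-force oracle in the test suite
(gift-wrapping hull, edge-support width, dense-grid LEC, Monte-Carlo
area), and property tests check rigid-motion invariance, scaling
exponents, the bound chain `2 * lec_radius <= min_axis`, and monotonicity
of lobeyness in lobe amplitude.

## Contour cleaning

Traced outlines carry three kinds of defect, each handled explicitly and
never silently:

* **Duplicate consecutive vertices** are dropped on construction.
* **Self-intersections** ("vertices out of order") are repaired by
  flagging the vertices incident to crossing edges and replacing them with
  their cyclic 1-neighbourhood average, iterating. When symmetric
  configurations stall this local smoothing (a perfect bowtie shrinks
  self-similarly and never uncrosses), the repair reverses the vertex run
  between the two crossing edges — the literal re-ordering of out-of-order
  vertices — and resumes smoothing. The result always passes an `O(n^2)`
  segment-intersection check.
* **Cells stored in multiple pieces** (blank-line-separated blocks in one
  file) are rejected with a `multipiece` error, mirroring the practice of
  removing such cells rather than guessing a merge.

Smoothing uses the unweighted closed 1-neighbourhood mean `(1/3, 1/3,
1/3)`, the plainest reading of a "position average of the 1-neighborhood";
a single pass is the default for noise reduction. The triangle corner case
is real: one pass maps all three vertices to the centroid, so `n = 3`
warns and a collapse below three distinct points errors. Coincidence and
degeneracy thresholds (`1e-12` in area, exact equality for duplicate
points) are implementation choices, documented here rather than inferred
from any measurement protocol.

Files hold one whitespace- or comma-separated `x y` pair per line in
microns, `#` comments allowed, last vertex not repeated. Labeled datasets
live in a `root/clade/species/organ/sample.txt` tree; loading assigns the
group fields from path components, skips (and logs) files at the wrong
depth, and keeps per-file failures in the returned object.

## The mass-spring model

Cells are vertex cycles on a shared planar spring network. The model is
fully damped: at each growth step the interior is brought to force
equilibrium, inertial dynamics play no role.

Per step:

1. **Boundary growth.** Rim vertices are scaled anisotropically about the
   template centroid by the per-step factors `(fx, fy)`; rim spring rest
   lengths follow (rim growth is imposed, not elastic). Schedules are
   either rate functions `g(t)` discretised as `1 + g/n` per step, or —
   for the presets — piecewise-linear per-axis *scale profiles* whose
   telescoped ratios make the cumulative product exact. The canonical
   scenario family reaches exactly 10x in x and 16x in y; its constant
   variant moves the rim at constant speed (a displacement-rate ratio of
   15:9, about 1.6:1).
2. **Relaxation.** Jacobi-style damped iteration: each free vertex moves
   by `dt * F / W` with `W` its summed incident stiffness and `dt = 0.4`,
   which is contractive for spring networks; convergence is declared when
   the largest per-vertex force, normalised by `W` times the mean rest
   length, drops below `relax_tolerance` (default `1e-5`). Non-convergence
   within `max_relax_iters` is recorded per step, warned about, and aborts
   the run if it affects more than half the steps.
3. **Uncrossing guard.** A relaxation step can push a pinched neck just
   past itself; vertices on crossing edges are locally averaged (rim
   excluded) until each cell is simple again. This is a numerical guard,
   not a modelling ingredient: it acts on the rare just-crossed
   configurations and keeps every snapshot's cells simple polygons.
4. **Plastic yield.** Interior wall rest lengths move toward the current
   length (rate 1 by default, i.e. a fully incremental/hypoelastic
   update): each step is a small elastic increment about the previous
   state, so imposed growth propagates inward smoothly while residual
   elastic energy stays bounded.
5. **Wall subdivision.** Walls stretched beyond 1.6x the initial edge
   length split at their midpoint, so boundary resolution tracks the
   10-16x growth and lobes remain resolvable.
6. **Connection placement.** The microtubule/cellulose proxy. Within each
   cell, a chord between outline vertices is admitted iff it lies inside
   the cell, is no longer than `conn_len_factor * lec_target` (default
   1.5x the initial cell size — the free-span target), leaves both
   endpoints within `theta_max = 30` degrees of the inward wall normal,
   and has at least one endpoint in a concave region (negative turn on the
   CCW outline). Admitted chords become stiff springs (`k_conn = 10 *
   k_wall`) at their current length; they keep that rest length while they
   persist, and are released when strained beyond 15% (the proxy detaches
   rather than pinning the tissue indefinitely) or when they no longer lie
   inside their cell. Re-evaluation happens every step.
7. **Division** (optional). While `t <= f_div` (default the first 20% of
   steps), any cell above the area threshold (default twice the initial
   mean cell area) splits along the shortest chord through its centroid —
   the classical shortest-path plane rule. A division whose daughters
   would not be simple polygons is skipped and logged.

The emergent behaviour reproduces the qualitative signatures the model is
known for: with connections disabled nothing lobes (mean lobeyness stays
below 1.02); isotropic growth yields lobed cells while strongly
anisotropic growth at the same cumulative area yields simpler elongated
ones; a terminal anisotropic phase leaves lobes oriented along its
direction, so isotropic-then-vertical schedules end with median
directional lobe bias above 1 and their time-reversal below 1; and early
divisions produce smaller, less lobed cells.

### Constants and their provenance

`k_wall = 1`, `k_conn = 10`, `theta_max = 30` degrees, length cap
`1.5x` cell size, breakage strain 15%, division threshold `2x` initial
mean cell area: none of these are printed in the source literature (they
live in a deposited model description not reproduced here). They are
implementation defaults chosen once to land in the regime where all the
qualitative orderings above hold simultaneously with well-conditioned
geometry (cells simple, tissue tiled exactly), and are exposed in
`sim_config()` for exploration. The growth-curve `.func` reader
interpolates control points piecewise-linearly; the upstream editor's
spline semantics are intentionally not reproduced.

The maize scenario pair deserves a note. The forward scenario applies a
longitudinal (y) dominant phase then a transverse (x) dominant phase on an
elongated-cell template — cells end elongated with transversely oriented
lobes, as in a grass leaf. The reversed scenario applies the identical
per-step factors in reverse order (transverse-dominant first,
longitudinal-dominant last): exact per-step reversal is the only
parameter-free definition of reversing a growth sequence, and it is what
the time-reversal invariants test. Phase magnitudes (y 3x then 1.5x; x
1.2x then 4x, over 150+
steps) were set so that the terminal phase reorients lobes rather than
erasing them; with much stronger terminal elongation the stretched cells
straighten and the bias signal vanishes.

### Problem sizes

The scenario defaults (300 steps, 64 cells) match the canonical runs; the
package's own acceptance analyses run reduced configurations — 16 cells at
100 steps (150 for the maize pair) with 4 springs per wall side — which
preserve every ordering tested while keeping a full scenario sweep to a
few minutes. Lobe depth depends on the per-step growth rate (pinned spans
must persist for several steps to buckle), so reduced step counts are
paired with proportionally reduced cumulative growth where a comparison
needs stable absolute lobeyness: the division-effect comparison runs the
constant weakly anisotropic schedule to (5x, 8x) over 100 steps, divisions
off versus on for the first 20% of steps, which preserves the ordering at
every seed tested. The methods are deterministic given the template jitter
seed, the only stochastic element.

## Survey statistics

Per species, from the per-cell metric table:

* **Pearson r** between min-axis and lobeyness (undefined-variance cases
  are flagged, not propagated), classified *moderate-to-high* when
  `r >= 0.3` (boundary inclusive) and *weak* otherwise.
* **95th-percentile lobeyness** by the nearest-rank definition
  (`ceiling(q/100 * n)`-th order statistic), so a real cell is always
  selected; ties break by label. This upper-range statistic captures a
  species' *capacity* to lobe even when most cells are simple.
* **Origin-constrained quadratic fits** `y = beta x + alpha x^2` of LEC
  area against cell area, and of LEC diameter against min-axis. A
  negative `alpha` (concave-downward) means the LEC grows more slowly than
  cell size — the stress-limitation signature. Sign aggregation uses the
  area-area fit.
* The **survey** counts species with `r >= 0.3` and with `alpha < 0`,
  reports exact and integer-rounded percentages, and applies an exact
  two-sided binomial test (doubled smaller tail, capped at 1 — identical
  to the minimum-likelihood definition at null probability 1/2) to the
  alpha signs. Species with undefined r or failed fits stay in the
  denominator as weak/unknown by default; `drop_undefined = TRUE` gives
  the excluding convention, since reported denominators do not always say
  which was used. Both per-species fitting (the default, required by the
  sign count) and pooled fitting across species are possible by passing a
  pooled table.

## Synthetic data: what it emulates, and what it does not

`make_lobed_contour()` samples `r(theta) = R (1 + a cos k theta)`,
scaled anisotropically and rotated. This star family was chosen because
its convexity and simplicity boundaries are analytic (simple for
`a < 0.5`), lobeyness is monotone in `a`, and every metric has a
predictable target. `make_species()` draws cell widths log-uniformly over
1.5 orders of magnitude (mimicking the size span of real surveys) and
couples lobe amplitude to width through `a(w) = a0 + s (w - w0) + noise`,
clipped to `[0, 0.45]`: a positive slope with small noise plants a
moderate-to-high min-axis-lobeyness correlation and a concave LEC-area
relation; zero slope with large noise plants the null. `make_survey()`
writes a labeled tree plus a truth manifest so the full pipeline's
recovery of the planted coupled fraction can be checked against exact
binomial error.

The generators are statistical stand-ins only: they do not reproduce
wall-thickness variation, stomatal lineages, tracing noise correlation,
organ-level gradients, or any real taxon. Passing recovery tests therefore
demonstrates that the pipeline measures what it claims on shapes with
known structure — not that any biological conclusion transfers to a
particular dataset.

## Numerical choices and limitations

* Orientation is normalised CCW on construction; signed area decides.
* The min-axis tie (near-circular outlines) resolves to the smallest
  qualifying angle; all metrics are invariant to the choice.
* Percentile selection is nearest-rank by design; interpolating
  definitions would return values no cell attains.
* The LEC refinement is robust to noisy, deeply lobed outlines but is a
  tolerance-bounded search: radii are exact only to the requested
  tolerance, and sliver polygons thinner than the tolerance warn.
* The simulator has no turgor pressure term, no 3D walls, no explicit
  microtubule dynamics, and no collision handling beyond the uncrossing
  guard; connections are a geometric proxy. Rim vertices stay rim for the
  whole run, including after divisions of rim-adjacent cells.
* Simulated tissues at strongly reduced size (few cells, few springs per
  wall) lobe less and with more seed-to-seed variance than the full-size
  configuration; orderings are stable across seeds, absolute lobeyness
  values are not.

## A worked example

```{r example, eval = FALSE}
# plant a 40-species survey with 75% width-coupled species
root <- file.path(tempdir(), "survey")
manifest <- make_survey(root, n_species = 40, fraction_coupled = 0.75,
                        n_cells = 150, rng_seed = 1)

cells <- metrics_table(load_labeled_tree(root))
summaries <- species_summaries(cells)
survey(summaries)
# recovered moderate-to-high fraction ~ the planted 75%,
# and alpha < 0 for essentially all coupled species
```
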