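---
title: "Fractal morphometry of dendritic arbors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal morphometry of dendritic arbors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborfract)
```

## The problem

A neuron's dendritic arbor must expose enough membrane to collect
synaptic inputs while keeping the material and metabolic costs of its
dendrites in check. One compact way to characterize how an arbor spans
space is fractal dimension: a perfectly straight dendrite has dimension
1, a space-filling tangle approaches 3, and real dendrites sit in
between. `arborfract` measures this geometry on 3D reconstructions
(SWC files, coordinates in micrometres) at two levels:

* **branch level** — a *branch* is any path from the soma to a dendrite
  tip. Two independent estimators quantify its weave: the coastline
  (divider) dimension `D_BC` and the tortuosity-scaling dimension
  `D_BT`. Agreement between two estimators with different systematic
  errors is the key evidence that the weave is genuinely fractal.
* **arbor level** — the box-counting dimension `D_A` of the whole
  arbor, which reflects the interplay of branches *and* the gaps
  between them, not just branch weave.

A distortion model (the angle multiplier `alpha`) rescales every weave
and fork angle while preserving segment lengths, generating arbors
whose branch geometry is systematically straighter (`alpha < 1`) or
curlier (`alpha > 1`) than natural. Connectivity/cost metrics and the
balance ratios `R_PA` and `R_PV` then ask whether the natural geometry
optimizes the trade-off between connectivity potential and cost.

## Branch estimators

### Coastline (divider) method

`segment_with_ruler()` generalizes the classic divider walk to a 3D
polyline: a sphere of radius `L_R` is centred on the soma-side end; the
first ruler ends where the branch crosses the sphere; the sphere is
re-centred there and the walk repeats. Two rules make this
deterministic:

* only crossings at arc length strictly beyond the current centre are
  admissible (already-segmented branch is never re-entered), and among
  them the one with the shortest path length along the branch is taken;
* the crossing is solved exactly per polyline segment (a quadratic in
  the segment parameter), never by sampling. A tangency (zero
  discriminant) counts as a crossing; this is measure-zero on real
  data.

The final partial ruler is counted as a fraction: 12 full rulers at
`L_R` = 10 µm plus a 2 µm remainder give `N` = 12.2. `D_BC` is the
negated slope of log10 `N` against log10 `L_R`.

The fit range is 4–40 µm. Below ~4 µm (the median reconstruction
segment length) a ruler measures the straightness of individual
cylindrical segments, not the branch's weave; one order of magnitude
above that keeps nearly all branches usable. A branch whose end-to-end
length `L_E` is under 40 µm cannot support the range and is excluded
(flagged, never silently dropped). The default grid is 20 log-spaced
ruler lengths; the grid density is a free choice and the estimate is
insensitive to it.

For cross-branch comparison, `pooled_normalized_dimension()` plots all
branches against `L_R / L_E` and fits only the normalized range shared
by every branch, capped at 0.75 orders of magnitude (trimmed
symmetrically in log space when wider) so that no branch dominates
either end. The pooled estimate matches the mean per-branch `D_BC` on
homogeneous ensembles; when branches differ strongly in tortuosity the
pooled cloud shifts and a small systematic gap (~0.03 at our natural
weave) opens — this is a property of pooling, not a bug, and is why
per-branch `D_BC` is the primary statistic.

### Tortuosity scaling

Tortuosity `T = L_P / L_D` (path length over end-to-end distance) is
measured across *all* vertex-to-vertex sub-paths of a branch
(`tortuosity_table()`). Sub-paths are restricted to polyline vertices;
endpoints are not interpolated inside segments. Because sibling
branches share their proximal polylines, identical sub-paths recur
across branches; `deduplicate_paths()` collapses them by canonical
endpoint-pair key before fitting.

Individual `(L_P, T)` records are extremely noisy, so records are
binned log-uniformly in `L_P` over the same 4–40 µm range (12 bins by
default), the arithmetic mean `T` per bin is fitted on log-log axes,
and the slope `S` maps to a dimension via `D_BT = 1 / (1 - S)`. The
standard error propagates by the delta method
(`stderr(D) = D^2 stderr(S)`). Bins are equally weighted; weighting by
occupancy would let the (dense) fine scales dominate. Note that the
regression stderr of a *single-branch* fit understates its true noise,
because sub-paths of one branch are strongly correlated: the honest
noise comparison is the spread of per-branch estimates against the
pooled stderr, and that is what the test suite asserts.

The two estimators are independent: one measures how ruler counts
grow, the other how average meander grows. On synthetic ensembles of
50+ branches they agree within joint uncertainty, and both hit exactly
1 on straight branches.

## Arbor box counting

`box_scaling()` inserts the arbor into a grid of cubes anchored at the
bounding-box minimum corner and counts occupied cells over 15
log-spaced box sizes from 4 µm (the shared fine cut-off) to
`L_grid / 4`, where `L_grid` is the largest bounding-box side. `D_A` is
the negated log-log slope. Occupancy is judged on the centerline
resampled at a quarter of the smallest box size: dendrite width
(1.4 µm) lies below the fine-scale cut-off, so radius-aware
voxelization would not change counts in the fitted range. A point
exactly on the far face of the enclosing grid belongs to the last cell.
No grid-offset averaging is performed; rotation of the arbor moves
`D_A` by well under the fit noise, which the suite checks.

## The distortion model

`decompose_to_angles()` is a lossless local chart of the arbor: per
node, the incoming segment length, the bend angle (weave `theta` at
continuation nodes, fork `phi` at branch-point children), and a torsion
angle locating the bending plane in a frame parallel-transported along
the path. Stem roots keep absolute positions and initial directions.
`apply_angle_multiplier()` rebuilds positions depth-first with every
bend multiplied by `alpha`, torsions and lengths untouched, so:

* `alpha = 1` reproduces the original to 1e-6 µm (round-trip identity);
* path lengths `L_B` and dendrite volume `V_m` are invariant for any
  `alpha`;
* measured angles of the distorted arbor are exactly `alpha` times the
  originals (clipped just below π, with the clip count reported).

At exactly collinear nodes the bending axis is undefined but also
unneeded (the scaled angle is still 0); torsion is set to 0 there.
Torsion is held fixed under distortion — re-randomizing it would
destroy the depth-first inheritance of upstream rotations that makes
the distortion a pure angle-rescaling. Intersections introduced by
distortion are reported (`self_intersection_report()`), never
repaired; across `alpha` in [0.5, 2] on natural-statistics synthetic
arbors the offending fraction stays far below 1% of segment pairs.

## Connectivity and cost metrics

* `P` — profile area: the arbor is orthogonally projected along each of
  64 deterministic Fibonacci-sphere directions, the silhouette is
  dilated by 2 µm (room for spine growth around each dendrite), and the
  dilated area is averaged over views. Areas are measured on a 0.5 µm
  raster; a pixel counts when its centre lies within
  (radius + expansion) of the projected centerline. The raster
  reproduces closed forms (stadium, disk) to ~0.2% and converges to the
  mean-projection (Cauchy) value for a capsule.
* `A_s` — dendrite surface area: each cylinder's lateral surface is
  tessellated (32 circumferential facets, i.e. a 16-facet prism
  subdivided once; up to 8 axial rings), faces whose three corners lie
  strictly inside another segment's cylinder are removed (junction
  overlap correction), and the rest are summed. Within 1% of closed
  forms at the default tessellation.
* `V_m` — sum of cylinder volumes; junction overlaps are ignored
  (declared approximation, exact under distortion).
* `A_b`, `V_b` — surface area and volume of the convex hull of the
  node positions. The hull is an incremental beneath-beyond
  implementation (no 3D hull was available in the dependency stack) and
  is verified against a brute-force facet-enumeration oracle.

`balance_curves()` fits each normalized metric (`P/A_b`, `A_s/A_b`,
`V_m/V_b`) as a quadratic in `D_A` across the `alpha` ensemble,
differentiates analytically, and returns
`R_PA = d(P/A_b)/dD_A / d(A_s/A_b)/dD_A` (and `R_PV` with `V_m/V_b`).
A quadratic is the lowest-order differentiable model that can express a
peak over seven ensemble points; grid points where the denominator
derivative vanishes are masked rather than extrapolated.

## The synthetic generator

The generator exists so every stage is testable without experimental
data. Its defaults emulate CA1 basal arbor statistics: median segment
length 2.4 µm with lognormal spread, dendrite radius 0.7 µm (1.4 µm
width), 4 primary stems, ~32 soma-to-tip branches, branch path lengths
drawn at 141 ± 20 µm, arbor radius ≈ 100 µm, and ~3 mm total dendritic
length. Several design choices are worth spelling out:

* **Hemispheric stems.** Basal arbors occupy roughly a hemisphere on
  the stratum-oriens side of the soma; stems are well-spread but
  confined there, which roughly doubles spatial density relative to a
  full sphere.
* **Radial cap with tangential steering.** Growth beyond the ~100 µm
  radius is steered tangentially instead of truncated, so mean branch
  length and arbor radius can both match their targets: paths keep
  their drawn length while the arbor stays confined.
* **Proximal bifurcations.** Splits occur at 5–20% of the remaining
  target length, mirroring the proximal bias of basal-arbor
  bifurcations and producing a realistic total dendritic length.
* **Self-avoidance.** Sibling forks open to opposite sides, a mild
  radial tropism (weight 0.1) pulls growth outward, and each step is
  deflected away from dendrite already placed within 10 µm (weight
  0.3). These interactions are recorded in the final geometry as weave
  bends, so the natural `alpha = 1` arbor is the *maximally spread*
  configuration: rescaling angles in either direction disrupts the
  avoidance and clusters branches, which is exactly why the arbor
  dimension `D_A(alpha)` is U-shaped with its minimum at the natural
  state. Without the avoidance term the left arm of the U disappears
  (straightened branches inflate the arbor and dilute its coarse-scale
  density), so the term is load-bearing, not cosmetic.
* **Weave calibration.** The standalone weave-branch generator uses a
  folded-normal bend of mean 0.25 rad per 2.4 µm step, calibrated once
  so that pooled branch dimensions over 4–40 µm land at ≈ 1.04, the
  natural CA1 value; inside arbors the recipe uses a smaller random
  bend (0.09 rad) because avoidance and tropism bends contribute the
  rest, landing mean branch dimensions ≈ 1.05 (equivalently, mean
  `D_A` ≈ 1.30, comfortably above the branch dimension — arbor
  complexity comes from branches *plus* gaps).

What the generator does **not** emulate: reconstruction noise, tapering
radii, spines, multifurcations (it only bifurcates, though the analysis
side supports multifurcations), apical arbors, and tissue boundaries
other than the radial cap. Passing tests on synthetic data therefore
validate the estimators and the pipeline mechanics, not any claim about
real neurons; analyses of real reconstructions should treat the
published population values as the reference.

## Numerical choices and degenerate inputs

* Base-10 logs everywhere; ordinary least squares for every log-log
  fit; fits require ≥ 3 points in range and error otherwise.
* Sphere-crossing admissibility uses a strict arc-length tolerance of
  1e-9 µm; branch geometry below that tolerance is rejected as
  degenerate.
* Zero-length segments, coincident sub-path endpoints (closed loops),
  coplanar hull input, slopes `S >= 1` in the tortuosity mapping, and
  soma-only arbors all raise typed errors naming the offending node
  where applicable.
* All generators accept a seed, restore the caller's RNG state, and are
  bit-reproducible; pipeline outputs are byte-identical across reruns
  and carry a provenance record (config hash, package and R versions).

## Problem sizes in the shipped tests

The test suite runs the full pipeline at deliberately modest sizes
chosen to exercise every code path: ensembles of 5 arbors (~1300 nodes
each) for the distortion properties, 60–100 weave branches for
estimator cross-checks and the dense-march ruler oracle, 1e5 points for
the filled-cube saturation check, and a level-8 H-tree (D = 1.5) for
the known-dimension fixture. Larger studies simply scale these inputs.

## Known limitations

* `V_m` and `A_s` treat junctions approximately (declared above);
  for thick, short dendrites the bias would grow.
* The pooled `D_BCN` inherits a heterogeneity bias (see above); it is
  reported for cross-branch comparison, not as the primary statistic.
* Box counting uses a single grid anchoring; offset averaging would
  reduce (already small) anchoring noise at the cost of determinism.
* The balance-curve smoother is quadratic; richer ensembles could
  support splines, at the cost of non-analytic derivatives.
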