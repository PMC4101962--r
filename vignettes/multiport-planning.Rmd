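---
title: "Methods: collision-free multiport trajectory planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collision-free multiport trajectory planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the geometric model behind `multiport`, the
numerical choices made where the design was genuinely open, what the
synthetic phantom does and does not emulate, and the known limitations.

## The planning model

Minimally invasive multiport surgery of the lateral skull base replaces the
open mastoidectomy with up to three narrow straight drill canals from the
skull surface to a deep target. Planning reduces to a purely geometric
question: which straight segments from a candidate entry region to the
target keep a sufficient distance from every structure that must not be
violated?

The package models a drill path as a *capsule*: the segment from entry
`p` to target `t`, inflated by the drill radius `r_d`, plus two additive
scalar margins — a clinical safety distance `s` and a navigation/drilling
inaccuracy `e`. Everything is decided by the single derived quantity

> required clearance = `r_d + s + e`,

compared against the *axis clearance* `c`: the minimum Euclidean distance
from the segment to the triangulated surface of any critical structure.
A trajectory is collision-free iff `c >= r_d + s + e`. Two modelling
consequences follow:

* the comparison is **non-strict**: a capsule that exactly grazes a
  structure at distance equal to the required clearance passes. The tie is
  of measure zero in any real configuration; fixing it non-strict makes the
  reported "distance to the closest structure" the exact binding quantity.
* the reported clearance is that of the **axis**, not of the cylinder
  surface (subtract `r_d` for the latter). This is stated in the report
  metadata, because either convention is defensible.

The largest drill a corridor admits while preserving the margins is
`d_max = 2 (c − s − e)`, floored at zero. The drill radius enters the
feasibility test but not `d_max`: a feasible trajectory therefore always
satisfies `d_max >= 2 r_d`. Where no critical structure exists at all the
clearance is reported as `Inf` (and `d_max` as unbounded) rather than
raising an error; degenerate configurations occur routinely in validation.

The skull bone itself is never a collision obstacle — it is the drilled
medium. Structures become obstacles only if flagged critical and not named
in the per-target noncritical list (the target's own structure is
conventionally noncritical; the ossicles may be declared noncritical when
residual hearing is not relevant, as for a cochlear-implant target).

### Entry candidates

Candidate entries are the triangle centroids of the skull surface mesh
within Euclidean distance ρ of the seed point, after snapping the seed to
its nearest centroid. Euclidean (not geodesic) distance is used: for the
small entry regions of keyhole planning (ρ of a few to ~10 mm on a
surface with ~60 mm curvature radius) the two are nearly identical, and the
Euclidean ball is cheap and unambiguous. Candidates are ordered by distance
to the snapped seed with triangle-index tie-breaks, and every downstream
iteration preserves that order, so outputs are byte-stable across runs.

### Risk coloring

Collision-free trajectories are color-coded linearly in clearance:
`risk = (c_max − c) / (c_max − c_min)`, mapping the safest path to 0
(blue) and the riskiest to 1 (red). A single trajectory, or an all-equal
set, maps to 0 — with no spread there is nothing to rank.

### Triples: cumulative angle, merge length, selection

For three CFTs sharing a target, the three pairwise angles between the
target→entry unit vectors are summed into the cumulative angle (CA). The
target→entry orientation (rather than entry→target) makes "ports spread
apart on the skull" read as *large* angles; CA ≤ 540°. Angles are computed
as `atan2(|u × v|, u·v)`, the numerically stable form of the clamped
arccos — exact at 0° and 180°.

Two cylinders of radii `r1`, `r2` meeting at the target at angle α overlap
out to the merge length `L = (r1 + r2) / (2 sin(α/2))` from the target
along each axis; α = 0 is reported as an infinite-overlap flag (`Inf`).
Distal fusion (small `L`) creates working space at the target; proximal
fusion (large `L`) collapses separate ports into one canal.

The published protocol left triple selection to the surgeon, guided by two
stated maximisation criteria: distance to critical structures, and spread
between entry points. The package automates this as a weighted score

```
score = w_c * (min clearance / max clearance of the candidate set)
      + w_a * (CA / 540)
```

with default weights `w_c = w_a = 1` — a declared convention, not a
reproduction of the experts' implicit weighting; both weights are exposed.
The search is exhaustive over all triples of the `m_cap = 40`
highest-clearance CFTs (clearance-descending, entry-lexicographic
canonical order); with the cap disabled it provably reproduces full brute
force. Ties break by larger CA, then lexicographic entry coordinates, so
the result is independent of input ordering.

### Region summaries

Achievable diameters are summarised per named skull-surface region
(nearest-centroid assignment of entries to labeled triangles; a labeling
utility assigns regions by nearest seed point when no anatomical
parcellation is supplied): n, percentage, median, Q1, Q3, min, max, and
Tukey outliers (outside `Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`). Quartiles use
linear interpolation between order statistics (R's default type 7); SPSS
conventions differ slightly, and determinism across platforms was judged
more important than matching any one statistics package. The convention is
recorded in the report metadata.

## Geometry kernels

Segment-triangle distance is computed exactly (closest-point routines for
point/triangle and segment/segment, plus a piercing test), and mesh
clearance as the minimum over triangles with witness points on axis and
mesh. The accelerated path prunes with a bounding-sphere hierarchy whose
node bound is a true lower bound on the segment-to-node distance, so it
returns *identical* distances to the exhaustive scan — the equality (within
1e-9 mm, in practice bit-exact) is asserted over 200 seeded instances in
the test suite. Distance queries are 1-Lipschitz in endpoint perturbations
and invariant under shared rigid motions; both properties are tested.

A segment lying wholly inside a closed structure has a positive distance
to the structure's *wall*; containment is therefore tested separately by
ray parity, at the entry, the target and the midpoint of the axis. The
midpoint probe also rejects a piercing axis in the degenerate
`radius = 0` limit, where the distance test alone (0 ≥ 0) would pass.
Parity rays use fixed direction sets with deterministic fallback when a
ray grazes an edge. For a non-watertight mesh the containment test is
skipped with a warning; surfaces produced by the package's own extraction
are always closed, so this arises only with degraded external meshes.
Probing three points (not the continuum) is exact whenever each obstacle's
intersection with the axis line is connected — true for the convex-ish
anatomy analogues here; a piercing axis is in any case caught by the
distance test for any positive drill radius.

## Surface extraction

Surfaces are extracted from the binary indicator of each label at
iso-level 0.5 by marching tetrahedra on the Kuhn (Freudenthal) six-tet
decomposition of each cell. Unlike the classic 256-case cube tables, the
tet decomposition has no ambiguous configurations, so the surface is
guaranteed crack-free; with the volume padded by background layers every
extracted surface is closed — which the downstream containment queries
require. Labels are extracted one at a time (multi-label junction topology
is never an issue), and degenerate faces are removed at mesh construction
(area ≤ 1e-12 mm²).

Vertex placement needs care. A binary indicator puts every vertex at an
edge midpoint, which *systematically overestimates* surface area — about
+9% for a digitised 10 mm ball at 0.25 mm spacing, independent of
resolution (the staircase never flattens). The package therefore uses a
hybrid rule:

* **topology** — which grid edges the surface crosses — follows the raw
  binary indicator, so one-voxel-thin structures (a chorda tympani at
  coarse spacing, the single-voxel test case) are never lost;
* **vertex position** along each crossing edge is interpolated from a
  separable 3×3×3 box mean of the indicator, falling back to the midpoint
  on edges where the smoothed field does not straddle the level.

This removes the staircase bias where the surface is smooth (measured ball
area error +0.15% at 0.5 mm and +0.5% at 0.25 mm spacing, versus the 3%
acceptance bound) while preserving binary topology everywhere. The
smoothing support is fixed at one voxel per axis; it is a geometric
de-biasing step, not a denoising filter, and has no tunable strength.

Label volumes are read from NIfTI with the voxel-centre convention on
axis-aligned grids; axis permutations and flips in the affine are
canonicalised, while oblique or sheared orientations raise an explicit
error rather than being silently reinterpreted — resampling upstream is
the supported path.

The brain safety margin of the published pipeline was produced by a
semi-automatic ray-casting tool whose construction is not reproducible
from its description; the package instead provides exact anisotropic
Euclidean dilation of the brain/dura mask by a configurable margin
(`dilate_mask()`, default 0.5 mm in the examples). This is a conservative,
deterministic approximation, monotone in the margin, not a reproduction of
the original procedure.

## The synthetic phantom

Real temporal-bone planning rests on 20 patient CTs that cannot ship with
a software package. The phantom module replaces them with scenes built
from primitives chosen so that every distance the planner computes has a
closed-form (or 1-D-minimisation) oracle:

* a hollow hemispherical **bone dome** (outer radius 62 mm, thickness 4 mm
  in the bundled scene) standing in for the temporal squama;
* **capsules** for nerve and vessel analogues (facial nerve, chorda,
  jugular/carotid, sigmoid sinus), **spheres** for cochlea-, ossicle- and
  dura-like bodies, **torus arcs** for semicircular-canal analogues;
* targets at ~25 mm (round-window-like), ~40 mm (internal-auditory-
  canal-like) and ~55 mm (petrous-apex-like) depth below the outer
  surface, matching the depth range of the clinical targets.

Each scene exists in three mutually consistent representations: the
analytic registry (ground truth), directly tessellated meshes with a
stated chord-error bound, and a voxelized label volume. The tessellations
are inscribed, so the mesh distance to a primitive lies within
`[analytic, analytic + chord]`; the chord budget is split per parameter
direction so the bound holds on doubly curved patches. Voxelization
refuses overlapping primitives (labels would silently overwrite). The
default spacing is 0.25 mm isotropic — the scale of a clinical
temporal-bone CT — while the bundled end-to-end scene uses 0.5 mm, which
keeps the full file pipeline (NIfTI + STL + plan) in the tens of seconds
on one CPU without changing any conclusion drawn from it.

`random_scene()` draws seeded scenes that *guarantee by construction* at
least one corridor of recorded analytic clearance `c*` from the surface to
the target: obstacles are rejection-sampled away from the corridor (and
from each other). Monotonicity studies (the feasible set shrinks as the
safety distance grows) run on 20 such scenes.

What the phantom does **not** emulate: real anatomical shape variation,
imaging noise, segmentation error, or inter-patient statistics. Passing
the phantom suite therefore validates the *geometry and logic* of the
planner — distances, feasibility, selection, reporting — not clinical
performance on patient data; the published per-region diameter statistics
across 20 patients are inputs the package cannot and does not reproduce.

## Problem sizes and tolerances

The shipped validation uses: meshes up to ~2000 triangles for the
equality-of-query tests (200 seeded instances); 50 seeded analytic-phantom
configurations at chord error ≤ 0.05 mm; a 10 mm ball digitised at 0.25 mm
(≈86³ voxels, ≈180k faces) for extraction fidelity; 20 seeded scenes × 5
safety-distance steps for monotonicity; and the bundled three-target scene
(≈265×265×137 voxels at 0.5 mm) end to end. These sizes were chosen as the
smallest that exercise every code path at full fidelity; all scale linearly
upward.

Key numerical tolerances: accelerated-vs-brute clearance 1e-9 mm
(identical arithmetic, different traversal); mesh-vs-analytic clearance
bounded by the tessellation chord error (0.05 mm in validation); rigid-
motion invariance 1e-6 mm (conditioning of the rotation); angle identities
exact at 0°/180° by the atan2 form, rotation invariance 1e-9 degrees.

## Known limitations

* Straight rigid trajectories only; no steerable or curved drilling.
* The scalar inaccuracy `e` is an isotropic bound; no anisotropic
  navigation-error model.
* Entry regions are Euclidean balls on the mesh, not geodesic patches.
* The containment probe set (entry, target, midpoint) is exact only for
  obstacles whose axis intersection is connected; exotic non-convex
  obstacles threaded exactly through a zero-radius axis could evade it.
* No mesh smoothing/decimation post-processing; extracted surfaces are
  used as-is.
* The automated triple score is a transparent stand-in for expert
  judgement; its default weights are a convention and should be reviewed
  per indication.
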