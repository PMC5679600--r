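---
title: "From volumes to landmarks: methods and design notes"
author: "crestmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From volumes to landmarks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A CT or similar scan yields a 3D scalar volume: intensities $p = v(x, y, z)$
sampled on a regular grid. Many downstream tasks (registration, matching,
morphometry) want a handful of salient *landmark points* on the anatomical
surface inside that volume. `crestmark` automates the reduction
volume (3D) → surface (2D) → crest lines (1D) → landmarks (0D) as three
independent phases; each phase consumes only the previous phase's output,
so any phase can be re-run from saved files.

The distinguishing choice is that all differential geometry is computed
from the *volume* (the implicit function and its derivatives), not from
discrete mesh operators: the mesh supplies positions and connectivity, the
field supplies curvature.

# Phase 1 — surface construction

The isosurface at intensity $p_c$ is the zero set of
$F(q) = \mathrm{trilinear}(v)(q) - p_c$. The full 8-corner tri-linear
interpolant is used, so $F$ at a lattice node equals the stored intensity
minus $p_c$ exactly and $F$ is linear along any axis-aligned segment within
a cell. Index coordinates are mapped to world coordinates through the voxel
spacing (anisotropic spacings are common in CT; all geometry below happens
in world space).

Meshing is by *continuation*, not exhaustive scanning:

1. **Seed search.** March from a start point (supervised if the user knows
   where the object is, random restarts otherwise) until the field changes
   sign between consecutive steps, then bisect the bracketing pair —
    24 bisections or an interval below $10^{-4}$ of a cube edge,
   whichever first.
2. **Cube tracking.** From the cube containing the seed, propagate across
   every face whose four corner signs are mixed. Each tracked cube is
   visited once; cubes with any corner outside the volume are discarded
   (open boundary: no geometry is generated outside the grid), which is why
   the synthetic generator keeps shapes at a ≥ 2-voxel margin so meshes
   stay closed. Since only surface-crossing cubes are visited, work scales
   with surface area, $O(n^2)$ for volume size $n$, rather than $O(n^3)$.
3. **Triangulation.** Each cube is split into the six tetrahedra sharing
   the main diagonal (Kuhn split). A tetrahedron with mixed corner signs
   yields one triangle (3+1 split) or two (2+2 split), with vertices at the
   linear zero $t = v_a/(v_a - v_b)$ along each sign-change edge and
   normals oriented toward decreasing $F$ (fields are inside-positive, so
   normals point outward). The tetrahedral table was chosen over a 256-case
   cube table because it has no ambiguous saddle configurations and the
   Kuhn split keeps face diagonals consistent between neighbouring cubes,
   making the mesh watertight by construction.

Vertices are welded by *integer lattice edge key*, never by distance
tolerance: two triangles sharing a cube edge refer to bit-identical vertex
records. (A crossing that lands exactly on a lattice corner — a field value
of exactly zero — is keyed by the corner itself, since several edges then
share it.) Exact welding is what makes the triangles-per-vertex ratio
behave: a closed genus-0 mesh satisfies $V - E + F = 2$ and $2E = 3F$,
hence $T = 2V - 4$ and ratio $T/V = 2 - 4/V \rightarrow 2$ from below as
the mesh refines. The test suite asserts this identity and the closedness
of every synthetic mesh.

**Cube size.** Default: the smallest voxel spacing (resolution-matched);
a `cube_frac` convenience expresses it as a fraction of the data extent.
Too large loses detail; too small can disconnect thin features — the suite
checks that halving the cube size never splits a well-resolved sphere.

# Phase 2 — crest lines

Per mesh vertex, the gradient $g = \nabla F$ and Hessian $H$ of the field
(central differences, default step $h$ = half a voxel per axis; one-sided
fallbacks at the domain boundary are flagged) give the shape operator of
the level set,
$$ S = -\frac{1}{|g|}\, P H P, \qquad P = I - \hat g \hat g^{\mathsf T}, $$
whose two tangent eigenpairs are the principal curvatures
$k_{max} \ge k_{min}$ and directions $t_{max}, t_{min}$. Under the
inside-positive convention a sphere of radius $r$ has $k = +1/r$. From
these: Gaussian curvature $K = k_{max} k_{min}$ and curvedness
$C = \sqrt{(k_{max}^2 + k_{min}^2)/2}$ (zero on planes, $1/r$ on spheres).
Vertices with $|g|$ below a floor ($10^{-8}$ of the mean gradient
magnitude) have no defined normal and are flagged; triangles touching them
produce no crest geometry.

Crest points are zero-crossings of the *extremality*
$e_{max} = \nabla k_{max} \cdot t_{max}$. The field derivative of
$k_{max}$ is not available in closed form, so $\nabla k_{max}$ is estimated
from the first-ring neighbourhood with per-axis weights
$$ \frac{\partial k_0}{\partial x}
   = \frac{\sum_i W_{i.x}\,(k_i - k_0)}{\sum_i |W_{i.x}|}, \qquad
   W_{i.x} = \lambda\, W_{i.a.x} + (1 - \lambda)\, W_{i.d.x}, $$
where the angle weight $W_{i.a.x} = (x_i - x_0)\big/\sqrt{(y_i - y_0)^2 +
(z_i - z_0)^2}$ is the signed cotangent of the edge/axis angle (cyclically
permuted per axis) and the distance weight is the normalized edge length
$W_{i.d} = Dist_i / \sum_j Dist_j$.

Parameters and their defaults:

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 0.5 | angle/distance mix; 1 = pure angle, 0 = pure distance |
| `cot_cap` | $10^3$ | clamp for the cotangent, which is singular for a neighbour exactly along the axis |
| $h$ | 0.5 voxel | finite-difference step (truncation vs. grid-noise trade-off) |

$\lambda = 0.5$ is an even mix chosen in the absence of any stated
preference; every output records the $\lambda$ it was produced with.

**What the estimator can and cannot do.** On a regular planar hex ring
with a linear curvature field, the angle-bearing mixes
($\lambda \in \{0.5, 1\}$) recover the in-plane gradient component with the
correct sign and within 25% magnitude; the cross-axis response is zero.
The pure distance weight ($\lambda = 0$) is direction-blind: its weights
are positive and even in direction, so on any ring whose distance-weighted
centroid coincides with the target the response is exactly zero; it only
reads a gradient from asymmetric rings, and then its magnitude equals the
weighted-centroid offset. Both behaviours are pinned in the test suite
against an independently coded brute-force evaluation of the weight
formulas.

**Sign consistency.** $t_{max}$ is only defined up to sign and $e_{max}$
is odd in it, so raw per-vertex signs would create spurious zero-crossings.
Before the per-triangle sign test, the directions of vertices 2 and 3 are
flipped to have non-negative dot product with vertex 1's direction (their
$e$ values flip accordingly) — the standard fix from the extremal-mesh
literature. Per vertex, the stored representative makes the
largest-magnitude component positive; at near-umbilic points
($|k_{max} - k_{min}| < 10^{-6}$) the eigenvector of the larger-magnitude
eigenvalue is kept, so output is deterministic.

A triangle whose three aligned $e$ values share a sign contains no crest;
otherwise the two edges joining the odd-signed vertex carry linearly
interpolated crossings joined as one segment (exact zeros count as
positive, which places the crossing on the vertex itself — a deterministic
tie-break). $K$ and $C$ are interpolated to the crossing with the same
edge parameter. Segments sharing a mesh edge are chained into polylines,
deterministically (lowest point id starts; greedy smallest-id extension).

**A degenerate case worth knowing.** On any surface of revolution with
$k_{max}$ along the circumferential direction — e.g. a prolate 2:1:1
ellipsoid — $\nabla k_{max}$ is meridional while $t_{max}$ is
circumferential, so $e_{max} \equiv 0$ analytically and the discrete zero
set is pure estimator noise. The package's ellipsoid fixtures are therefore
*triaxial* (16, 8, 6), where the $k_{max}$ crest is the long principal
section: reflection symmetry forces $e_{max}$ through zero across the
$z = 0$ ellipse, and the long-axis poles (the Gaussian-curvature maxima)
lie on it. Noise-driven isolated crossings still occur elsewhere on smooth
surfaces — they carry near-zero $|e|$ and low $K$, are grid-orientation
dependent, and are removed downstream by the curvature threshold; the
rigid-motion stability test accordingly compares the substantial chains,
not the isolated-crossing noise floor.

# Phase 3 — landmark identification

1. **Threshold.** Keep crest points with high Gaussian curvature. Default:
   the top 10% (percentile mode, scale-free across datasets; an absolute
   mode is kept for reproduction attempts). Thresholding is on signed $K$ —
   dome-like corners are large positive — with an option for $|K|$.
2. **Choose K.** K-means needs the cluster count. Default: try
   $K \in [2, \min(15, n-1)]$ and keep the $K$ maximizing the mean
   silhouette coefficient $s = (b - a)/\max(a, b)$ (ties to the smaller
   $K$). The $\sqrt{n/2}$ rule of thumb is available as an alternative,
   and a fixed $K$ can be forced. At the worked-example candidate size
   ($n = 118$, $\sqrt{59} \approx 7.68 \to 8$) the two selectors agree —
   the suite pins this; at the default 10% threshold the rule of thumb
   instead tracks the much larger candidate count, so silhouette is the
   default.
3. **Cluster.** Lloyd K-means on candidate *coordinates* (spatial clusters,
   not curvature-feature clusters) with k-means++-style seeding, 10
   restarts, best inertia kept; fully determined by the run seed.
4. **Select.** One landmark per cluster: the member with maximal
   curvedness (ties to the lowest candidate index). Landmarks are always
   actual candidate points, never centroids, so they lie on the crest
   lines by construction.

# The synthetic generator

`analyticShape()` / `voxelize()` produce spheres, ellipsoids, tori and
superellipsoids with optional i.i.d. Gaussian noise, all inside-positive.
The "smooth cube" — the canonical landmark test object — is a
superellipsoid $1 - \sum |u_i/a_i|^p$ with even exponent $p = 6$: a cube
with rounded edges and exactly 8 curvature-concentrated corners. The study
volume is fixed once: half-width 20 voxels, centered in a $64^3$
unit-spacing grid (comfortably over the 2-voxel closure margin), no noise.
At these conditions the end-to-end pipeline selects $K = 8$ by silhouette
and places one landmark at each corner, robustly across seeds; the
acceptance script re-runs exactly this.

`expectedGeometry()` supplies closed-form curvature oracles (sphere
$k = 1/r$; ellipsoid from the semiaxes; torus from ring/tube radii) used
by the curvature tests; the test suite additionally cross-checks the shape
operator's $K$ and mean curvature against direct gradient/Hessian
closed-form identities — two independent computation routes.

What the generator does *not* emulate: CT noise physics (beam hardening,
partial-volume effects), anisotropic blur, or multi-object scenes. Passing
tests on these fixtures therefore demonstrate correctness of the geometry
and of the pipeline composition, not robustness to scanner artefacts; on
real scans the noise sensitivity of third-order quantities (a curvature
gradient) is the known weak point, and the manifest's caveat counters
(degenerate vertices, clamped cotangents, skipped triangles) are there to
make it observable.

# Numerical choices, in one place

* Sign convention: inside-positive fields; zero field values count as
  positive everywhere a sign is needed (seed cube polarity, tet case
  table, extremality patterns).
* Cell ownership is half-open; a query exactly on the volume's top face
  belongs to the last cell.
* Bisection: 24 iterations or interval $< 10^{-4}$ cube, whichever first.
* Welding is exact (integer edge keys); degenerate zero-area triangles
  (possible only through exact-zero corners) are dropped.
* Eigen tie-breaks and $t_{max}$ sign normalization as above.
* K-means: Lloyd, k-means++ seeding, 10 restarts, seeded RNG; silhouette
  ties go to smaller $K$.
* All CSV/VTK output is printed at 9 significant digits and OBJ at full
  precision, so fixed-seed runs are byte-identical and a phase split at
  any boundary resumes bit-exactly.

# Problem sizes

The test suite runs on meshes of roughly $3\,000$–$30\,000$ vertices
(spheres and ellipsoids at cube size 0.5–2, smooth cubes at $48^3$ and
$64^3$), sizes at which every geometric property tested is already stable;
the same code path handles larger volumes unchanged, with cost growing
with surface area.

# Known limitations

* Single connected component per run (one seed); multi-object volumes
  need one run per object with supervised starts.
* No mesh smoothing or anti-aliasing: on noisy real data the crest phase
  inherits full grid noise, amplified by third-order differentiation.
* The distance weight's direction blindness means $\lambda \to 0$
  configurations degrade the gradient estimate on symmetric
  neighbourhoods.
* Landmarks are geometric, not semantic: no anatomical labels or
  cross-subject correspondence.
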