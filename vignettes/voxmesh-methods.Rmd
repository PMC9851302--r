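---
title: "voxmesh: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxmesh: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Segmented neuroscience geometry — neuronal and glial membranes from electron
microscopy, vessel networks vectorized from optical stacks, traced
morphology skeletons — must be watertight before it can feed
reaction–diffusion simulation, tetrahedralization or morphometry. A
triangular mesh is watertight if and only if it has no self-intersecting
triangles, zero non-manifold edges, zero non-manifold vertices and no
boundary edges. Real segmentations violate all four conditions at once, and
local surgery (hole stitching, intersection clipping) tends to fail
precisely on the heavily damaged inputs where it is most needed.

`voxmesh` instead routes every input through a voxel intermediate. Geometry
is only ever *rasterized* — an operation that is insensitive to
connectivity defects — and the output surface is re-extracted from the
volume, so watertightness is established by construction and then verified,
not patched in place. The price is resolution-dependent: detail below the
voxel scale is lost, and several quantitative limitations discussed below
follow directly from that trade-off.

## Grids and anchoring

A grid is isotropic and uniform: `grid_spec(origin, voxel_size, dims)`.
Resolution is given in voxels per micron (`voxel_size = 1/resolution`);
voxel `i` (0-based) occupies the half-open world interval
`[origin + i*h, origin + (i+1)*h)`, making point-in-voxel assignment
unambiguous. `grid_from_aabb()` pads the input extent by 2 voxels per side
by default: flood filling needs an exterior corridor, and isosurface
extraction needs the set region strictly inside the grid. Occupancy is one
bit per voxel when serialized (`ceiling(N/8)` bytes, LSB-first within each
byte, x fastest then y then z); in memory a logical array is used for fast
whole-grid algebra. The BIT/HDR, RAW/HDR and NRRD writers carry dims, data
precision, voxel size and origin in self-describing plain-text headers.
The bit-packing order is a convention of this package, not a claim of
file-level compatibility with any other tool's 1-bit format.

## Conservative rasterization and the dilation offset

A voxel is set iff its closed box intersects the closed triangle, decided
by the separating-axis test over the 13 candidate axes (3 box axes, the
triangle normal, 9 edge cross-products). Touching counts as overlap. The
candidate voxels per triangle are restricted to the triangle's bounding-box
footprint, and the result has set-union semantics: it is independent of
triangle order, and duplicated facets change nothing — this is also the
concurrency contract. Degenerate (zero-area) triangles still mark the
voxels their bounding boxes touch.

Conservatism dilates the surface. For a surface element with unit normal
`u`, a voxel box of side `h` intersects it when the box center is within
`(h/2)(|u_x| + |u_y| + |u_z|)` of the plane; averaged over isotropic
orientations `E[|u_i|] = 1/2`, so the mean outward dilation is `0.75 h`.
Mesh-rasterizing pipelines therefore apply an inward offset of `0.75 h`
along smoothed vertex normals after optimization (`compensate_dilation`).
Two numerical safeguards apply: the normal field is relaxed over vertex
one-rings before offsetting (the offset rivals local edge lengths on raw
isosurface output, where divergent neighbor normals would fold triangles),
and the offset is reverted locally wherever it would make opposite walls of
a thin feature cross. Volume- and mask-derived grids classify voxel
*centers* and carry no such bias, so `volume2mesh`/`mask2mesh` do not
compensate. The `0.75` constant comes from the derivation above; observed
effective dilation varies by shape (axis-aligned faces and strongly curved
tubes sit below the isotropic mean), which bounds the accuracy achievable
at a given resolution — see Limitations.

## Solid voxelization

The interior of a shell is filled per slice: the exterior of a slice is the
4-connected flood from all border pixels through unset pixels, and the
filled slice is the input plus the complement of the exterior. 4-connected
propagation prevents diagonal leakage through 8-connected shell corners.
Each slice is a pure function of its own pixels; any execution order (or
parallel schedule) gives identical grids — that purity is the parallelism
contract, and the tests assert it indirectly through determinism.

A single-axis fill fails on shapes whose interior is hidden behind a loop
aligned with the slicing axis: every z-slice of a torus standing on its
symmetry axis sees an annulus whose hole is "interior" in 2D. Three-way
mode fills along x, y and z and ANDs the three results, then ORs the
original shell back in so one-voxel-thick features survive the AND. The
same mechanism bridges small punctures: a gap of a few voxels is closed by
the fills from the two axes that do not look through it. The default is a
single z fill; three-way is opt-in (`solid = "three-way"`) and is always
used by the vasculature pipeline, whose graphs are cyclic by nature.

## Isosurface extraction

Grid values are treated as samples at voxel centers; bit grids take values
{0, 1} with the isovalue implicitly 0.5, so crossing vertices land at
voxel-face midpoints and the geometry is resolution-independent.

The primal extractor walks a fixed decomposition of every cell (the cube
between 8 adjacent centers) into 6 tetrahedra sharing the cell's main
diagonal. Within a tetrahedron the sign configuration is unambiguous — the
three cases (1, 2 or 3 corners inside) have unique triangulations — so no
case table and no asymptotic decider are needed, and neighboring cells
agree on their shared face diagonals by construction. Crossing vertices are
cached per global sample-pair edge; consequently the output is closed and
consistently orientable whenever the set region stays off the grid
boundary, which padding guarantees. This tetrahedral-decomposition variant
produces 2–3 times more raw triangles than a tabulated 256-case cell
walker, a cost the downstream coarsening removes; in exchange the rare
non-manifold cell configurations of tabulated marching cubes cannot occur.
Orientation is normalized afterwards by propagation from a seed triangle
and a positive-volume convention.

The dual extractor places one vertex per mixed cell at the average of its
cube-edge crossings (no quadric error minimization, no adaptivity) and one
quadrilateral per sign-change sample edge, connecting the four incident
cells' vertices; each quad is stored as two triangles sharing its shorter
diagonal. It preserves thin features with fewer primitives but can emit
non-manifold edges in rare configurations; those are caught by the repair
stage, which runs regardless of the chosen extractor.

## Smoothing

Finite resolution gives extracted surfaces staircase artifacts. The
smoothing kernel at a vertex is the weighted mean of its neighbors minus
the vertex, with each edge weighted by the average of the cotangents at the
two corners opposite it (one cotangent on boundary edges); weights are
clamped to at least `1e-6` so obtuse-dominated one-rings cannot flip signs.
Each iteration interpolates the vertex toward the kernel by the smoothing
value λ (> 0 required) and, if the inflate value μ < 0 is enabled, pushes
back by the same kernel form evaluated at the moved positions — the classic
two-phase construction that dampens Laplacian shrinkage on thin parts.
Weights and neighbor lists are rebuilt between iterations, not within one.
Defaults: λ = 0.6, μ = −0.55, 10 iterations. Boundary vertices are frozen.

## Adaptive optimization

Each of the (default 5) iterations performs, in order: *flat coarsening* —
interior edges whose two incident faces deviate by less than
`flat_angle_deg` (default 8°) are collapse candidates; *dense coarsening* —
edges shorter than `min_edge_length` (default 0.1 voxel) qualify where the
local dihedral deviation stays below `dense_angle_deg` (default 60°, a
guard protecting sharp features); and *normal-based smoothing* — vertices
relax toward their one-ring centroid, restricted to the tangent plane of
the area-weighted one-ring normal, which regularizes triangle shape
without the systematic inward drift of full centroid smoothing.

Candidates are processed shortest-edge-first (ties broken by vertex index,
for determinism); each accepted collapse moves both endpoints to the edge
midpoint and blocks the endpoints' one-rings for the rest of the batch, so
the batch result is order-independent. A collapse is rejected if the
endpoints share more than two neighbors (the link condition, which would
create a non-manifold edge) or if any surviving incident face's normal
would turn by 90° or more. A batch that nevertheless breaks closedness is
discarded wholesale. Triangle count is non-increasing, and a closed input
stays closed.

## Repair loop

`repair_to_watertight()` iterates up to `max_rounds` (default 5): weld
vertices closer than `1e-6` µm (a snap-to-lattice weld, so float export and
import of shared corners cannot fabricate boundary edges); drop exact
duplicate and zero-area triangles; apply the partition policy; excise every
triangle participating in a self-intersection (the excised neighborhood
widens by one ring per round, so a fill that recreates the same crossing
cannot persist); duplicate the shared vertex of disconnected triangle fans;
trim extra triangles at edges with incidence above two; and fill the
resulting boundary loops, smallest first, by ear clipping in the loop's
best-fit plane with a centroid fan as fallback for non-simple projections.
Loops longer than 200 edges abort with advice to re-voxelize in three-way
mode instead — geometric filling of a large gap invents shape, whereas the
volumetric route repairs it faithfully. Isolated vertices are reported
separately and stripped on output but do not count against watertightness.

## Morphology pipelines

SWC skeletons are parsed into sections — maximal unbranched sample chains
between branching or terminal nodes, each sample a position plus
cross-sectional radius; the branch-point sample is shared with child
sections so swept geometry is continuous. Neurons must be acyclic; the
vasculature reader merges coincident sample positions (the 7-column parent
pointer cannot express a back edge, so vectorized datasets close loops by
repeating coordinates) and permits cycles and multiple components.

*Conditioning.* Zero or near-zero radii are linearly interpolated from the
nearest valid neighbors along the section; zero-length segments are merged;
radius sequences of sections with five or more samples are median-filtered
(window 3). Oversampled sections are adaptively resampled by a greedy walk
that keeps a sample only when it is farther than the local radius from the
last kept sample; endpoints are always kept and no kept sample ever moves.

*Proxy synthesis.* For acyclic morphologies, every root-to-leaf path
(depth-first, starting at the soma centroid so no gap opens at the soma) is
resampled with cubic Hermite segments whose knot tangents come from the
centripetal Catmull–Rom formulation (α = 0.5, one-sided differences at the
ends; the implementation matches the Barry–Goldman closed form to machine
precision in the tests) and swept with a circular cross-section of 16
vertices per ring, frames propagated by parallel transport so the tube does
not twist, ends closed by fans whose apex sits half a radius beyond the end
point (a rounded cap that keeps terminal samples strictly interior). For
cyclic graphs each section is swept independently and an icosphere is
packed at every junction with radius equal to the largest terminal-sample
radius among the sections meeting there. Proxies may interpenetrate freely:
they are only ever rasterized.

*Soma.* The deformable-sphere step stands in for a finite-element soma
model: a subdivision-3 icosphere at the soma centroid with the mean soma
radius (mean distance from the type-1 centroid to the root sections' first
samples, falling back to the type-1 radius) is pulled, per connected
neurite, by translating the vertex cluster inside the spherical cap of
angular radius `asin(r_neurite / r_soma)` toward the initial segment in
`pull_steps` increments, then rescaled uniformly about the centroid so the
enclosed volume returns to the initial sphere's volume. This surrogate
reproduces the two properties the pipeline relies on — a plausible bulge
toward each neurite and exact volume preservation — without a mechanical
model. Roots whose first sample lies beyond `k = 2` mean soma radii are
reported as detached and bridged straight to the centroid.

*Astrocytes.* Endfeet arrive as a documented JSON sidecar (per patch:
`vertices`, per-vertex `thickness`, `triangles`) since no standard format
carries combined branching and surface data. Patch edges longer than the
local thickness are midpoint-subdivided (thickness averaged) until
compliant; the thickened sheet is rasterized as the union of spheres of
radius thickness/2 at vertices, triangle centroids and along edges at
half-voxel spacing. The astrocyte pipeline polygonizes the combined shell
*without* solid filling and then removes all partitions interior to (or
smaller than) the largest-area one, which is the membrane.

## Synthetic data

All tests and the acceptance script run on generated fixtures: analytic
shapes with known Euler characteristic and volume (icospheres, tori,
boxes), seeded damage (`break_mesh`: facet deletion, duplication, vertex
jitter, shifted overlapping copies — the defect classes seen in real
segmentations), SWC generators for bifurcating neurons with tapering radii
(kept at or above 0.35 µm so branches stay resolvable at 5 voxels/µm),
vascular loop graphs with a prescribed cycle rank, endfeet patches, and
lattice ball masks. Generators are seed-deterministic and restore the RNG
stream. What they do *not* emulate: EM segmentation noise statistics,
realistic dendritic spine geometry, contact-site anatomy, or the scale of
full cortical-circuit meshes — passing tests demonstrate the engine's
contracts (watertightness, topology recovery, bounded drift) on geometry of
the same defect classes and feature scales, not performance on any specific
imaging dataset.

## Problem sizes and parameters

The test suite and `scripts/acceptance.R` use spheres of radius 1.5–3 µm,
tori up to major radius 2.5 µm, neuron fixtures with 2 stems and depth ≤ 2,
single-loop vessel graphs and ball masks up to radius 32 voxels, at 5
voxels/µm (convergence checks run 8→16→32 voxels per radius). These sizes
exercise grids up to ~70³ voxels and meshes up to ~40 000 triangles —
large enough for every contract to bind, small enough that the whole suite
runs in a couple of minutes on one CPU.

| parameter | default | meaning |
|---|---|---|
| `resolution` | 5 voxels/µm | rasterization density; 10 for subcellular detail |
| `padding` | 2 voxels | exterior corridor for flood fill |
| `solid` | `"z"` | slice fill axis; `"three-way"` for loops/gaps |
| λ, μ, iterations | 0.6, −0.55, 10 | two-phase smoothing |
| `flat_angle_deg` | 8° | coplanarity threshold for coarsening |
| `dense_angle_deg` | 60° | guard angle for short-edge collapse |
| `min_edge_length` | 0.1 voxel | dense-coarsening length threshold |
| optimization iterations | 5 | coarsen/relax rounds |
| weld tolerance | 1e-6 µm | vertex coincidence |
| compensation offset | 0.75 voxel | mean conservative-dilation undo |
| `k` (soma connectivity) | 2 | detachment threshold in soma radii |

## Known limitations

- **Sharp features are rounded at the voxel scale.** Edges and corners
  lose material to smoothing and cannot be recovered by the isotropic
  dilation offset; volume fidelity contracts apply to smooth shapes.
- **Thin high-curvature features** (tube radius below ~5 voxels) show a
  volume deficit: the effective conservative dilation there falls below
  the isotropic-mean 0.75 h that is compensated. Raise the resolution for
  thin structures (the `fine` preset exists for this).
- **Single-axis solid voxelization fails on axis-aligned loops** (the
  torus counter-example above); use three-way mode for anything suspected
  to contain loops. Three-way mode also erases *real* tunnels narrower
  than ~2 voxels, by the same mechanism that repairs gaps.
- **Sub-voxel separations fuse.** Two membranes closer than one voxel
  rasterize into one connected solid; this is inherent to the volumetric
  route.
- The dual extractor can emit locally non-manifold configurations that
  cost a repair round; the primal extractor is the safe default.
- `enclosed_volume()` requires a closed, orientable surface; Möbius-like
  inputs are rejected rather than silently mis-measured.
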