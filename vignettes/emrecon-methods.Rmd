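---
title: "Methods: volume reconstruction and circuit annotation in emrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume reconstruction and circuit annotation in emrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrecon)
```

# Overview

Serial-section electron microscopy delivers stacks of tissue sections,
each imaged as multiple overlapping camera tiles. The tiles arrive with
imprecise stage positions and the sections themselves are deformed by
cutting, beam heat and charging. `emrecon` implements the computational
chain that turns such collections into an annotated, measurable volume:

1. **Composition** — every tile is a `patch()` carrying its source
   image, a chain of coordinate transforms into world space, an alpha
   mask, a display range and a composite mode; `render_region()`
   composes any world-space rectangle of a section from its patches.
2. **Registration** — invariant features (`extract_features()`,
   `match_and_filter()`) drive within-section montaging
   (`montage_layer()`), cross-section linear alignment
   (`align_series_linear()`) and joint global pose optimization
   (`optimize_global_pose()`); residual non-linear distortion is
   removed by block matching plus a spring mesh (`elastic_align()`).
3. **Annotation** — neuronal arbors are confidence-weighted skeleton
   trees (`skeleton_tree()`), synapses are polyadic connectors
   (`connector()`), both organised under a template-constrained
   project tree (`project()`, `validate_project()`).
4. **Measurement and exchange** — cable lengths, path distances,
   betweenness centrality, area-list volumetry with marching-cubes
   meshes, vesicle–cleft distances and double-disector counts; export
   to SWC, NeuroML and adjacency tables.

A deterministic generator (`make_texture()`, `cut_tiles()`,
`deformation_truth()`, `simulate_arbor()`, `simulate_circuit()`)
produces fixtures with machine-readable ground truth for every one of
these steps; the whole test suite runs on such fixtures.

# Coordinates, transforms and rendering

Pixels are 0-based with the centre of pixel $(x, y)$ at
$(x + 0.5,\, y + 0.5)$; bounding boxes are half-open; world
coordinates are floats. A transform chain maps local tile coordinates
to world coordinates, first-to-last. `flatten_chain()` collapses runs
of adjacent linear transforms into a single $2 \times 3$ matrix, so a
chain of any length evaluates in one step per non-linear element; the
flattened mapping agrees with sequential evaluation to well below
$10^{-6}$ px (a test asserts this on $10^4$ random points).

Three non-linear transform families are provided:

* **Moving least squares** (`transform_mls()`): the standard
  image-deformation scheme with weights $w_i = 1/\lVert p_i - v
  \rVert^{2\alpha}$ and a per-point translation / rigid / similarity /
  affine model. Landmarks are interpolated exactly; far from all
  landmarks the map tends to the global least-squares model.
* **Piecewise-affine meshes** (`transform_mesh()`): barycentric
  interpolation over a triangulation; inverted by swapping rest and
  moved vertices.
* **Chains** mixing the above with linear elements.

Rendering inverse-maps every output pixel through each patch chain
(linear parts exactly, MLS through a mesh discretisation at 8 px
spacing) and samples the source bilinearly; samples outside the
source contribute alpha 0. Composite arithmetic uses the standard
pixel definitions (e.g. difference $=|a-b|$), with each patch's
contribution weighted by its alpha mask; `colorize_ycbcr` takes luma
from the composed grayscale canvas and chroma (BT.601) from an RGB
overlay patch. The original sources are never modified: splitting a
tile along a polygonal line (`split_patch()`) produces two patches
that share the image and carry complementary masks whose pointwise
sum equals the original — so the two halves render exactly like the
whole.

Mipmap pyramids (`build_mipmaps()`) bake transforms, mask and display
range into level 0 and halve by 2×2 area means; a render at scale $s$
would read level $\lfloor -\log_2 s \rfloor$. `render_region()` itself
always resamples from the source at the requested scale — it is the
reference path; the pyramid exists for display-style consumers, and
tests check the level dimension rule and the block-mean property
rather than routing rendering through it.

Contrast tooling follows the practice of EM screening: tile-based
CLAHE (`clahe_filter()`, per-block clipped histograms, bilinearly
interpolated monotone transfer functions, global fallback for
oversized blocks) and dual-range composition
(`dual_range_compose()`) which maps a masked region — say the dark
band under a support-film fold — through its own display range.

# Feature-based registration

`extract_features()` implements a difference-of-Gaussians detector
(3 scales per octave, $\sigma_0 = 1.6$, contrast threshold 3/255,
Hessian edge ratio 10) with in-plane sub-pixel refinement, dominant
orientations from a smoothed 36-bin gradient histogram (up to two per
keypoint) and a 4×4×8 oriented gradient-histogram descriptor sampled
over a rotated window of radius $6\sigma$, normalised and clipped at
0.2. On the synthetic EM texture a 90° rotation re-detects and
re-matches essentially all features; the test requires at least half
within 2 px.

`match_and_filter()` pairs descriptors by nearest-neighbour distance
under a ratio-of-distances test (default 0.92) and runs random-sample
consensus (default 1000 iterations, inlier threshold 3 px, minimum
inlier ratio 0.05) for the requested linear model, refined by
iterated least squares on the consensus set. An empty result is the
"no overlap" signal, not an error.

## Pose relaxation

`relax_poses()` is the shared solver: each tile (or section) is
re-fitted in Gauss-Seidel sweeps to all its inlier correspondences
mapped through its neighbours' current poses, under a
translation → rigid → affine schedule that avoids early shear. Two
numerical choices matter:

* The translation phase is solved **exactly** as a weighted graph
  Laplacian system rather than by sweeping: global modes (a whole
  block of tiles shifting relative to the gauge) decay too slowly
  through local sweeps and can stall a change-based stopping rule.
* The sweep phases stop when the mean point-transfer residual changes
  by less than $10^{-4}$ px. A looser threshold (say $10^{-2}$) can
  stop while a slowly-diffusing global rotation still holds whole
  rows of tiles a pixel away from equilibrium — the residual descends
  monotonically but in small steps.

The first tile of the first layer is the gauge. Because the gauge
tile's own (unknown) perturbation defines the output frame, recovery
is scored gauge-invariantly: `pose_error_rms()` maps tile corners
through recovered and true transforms, removes one global rigid fit,
and reports the RMS of what remains.

`montage_layer()` adds a polish pass after the feature solve: each
connected tile pair is rendered into its overlap at the current poses
and block-matched by normalised cross-correlation (12 px sample grid,
sub-pixel peak). Feature localisation on resampled, noisy tiles
carries a small spatially-correlated bias that averaging over
matches cannot remove; NCC matching of the actual rendered overlap
does, taking the 3×3 recovery experiment from roughly half a pixel
RMS down to below 0.1 px.

# Elastic alignment

`block_match()` computes, on a regular grid, the displacement
maximising the NCC of blocks (default radius 16 px) within a search
radius, with parabolic sub-pixel refinement of the correlation peak;
flat blocks are emitted with $r = 0$. `filter_matches()` removes
samples with $r$ below 0.7 and samples deviating more than 3 px from
their local median. The surviving samples become external springs
tied into a triangulated spring mesh by barycentric coordinates;
internal springs (stiffness 0.1) penalise deviation from rest length,
external springs (stiffness 1.0, weighted by $r$) pull toward the
matched targets. `elastic_relax_mesh()` integrates the forces with
damped explicit steps until the maximum vertex force falls below
tolerance, halving the step size if the total energy rises
persistently.

Defaults: displacement grid every 24 px and mesh spacing 32 px. The
mesh spacing deserves a note: a piecewise-linear mesh of spacing $h$
cannot represent a sinusoidal field of amplitude $A$ and wavelength
$\lambda$ better than about $A (2\pi h/\lambda)^2 / 8$ at mid-edge.
For the study condition ($A = 5$ px, $\lambda = 256$ px) a 64 px mesh
leaves ~1 px of pure discretisation error — more than the whole error
budget — while 32 px leaves ~0.25 px; that, not the spring constants,
drove the default. With these defaults the recovered field differs
from the truth by ≈0.3–0.5 px mean (≈7–13% of the pre-elastic
residual) on $1024^2$ sections.

The generator's deformation truths are sinusoids
($d_x = A\sin 2\pi y/\lambda$, $d_y = A\sin 2\pi x/\lambda$) or sums
of Gaussian bumps; `deform_section()` applies them by backward
warping, so block matching should recover $+d$ at each grid point.

# Skeletons, connectors and circuits

A skeleton is a rooted tree whose directed edges carry integer
confidences 0–5 (default 5) expressing the operator's certainty in
each continuity decision; nodes carry tags and a radius (treeline) or
2d area (areatree) payload. Node $z$ is the centre of its layer —
section thickness, not sub-layer position, limits $z$ resolution in
anisotropic serial-section data, so a finer convention would be
noise. Editing preserves the undirected (edge, confidence) multiset:
`reroot()` reverses parent pointers along one path (confidences stay
with their undirected edge), `split_tree()` removes one edge,
`merge_trees()` reroots the donor at the attachment node and re-issues
colliding ids from `max(id) + 1` in order. These algebraic facts are
tested over a thousand random arbors.

`betweenness_centrality()` implements Brandes' dependency
accumulation on the undirected tree, counting unordered endpoint
pairs; `restrict` limits the counted pairs to branch nodes or to
tagged synapse nodes (both interpretations of "relative to other
nodes, branches or synapses" are provided because the choice is a
view, not a model). Results agree integer-exactly with brute-force
path enumeration on all trees up to $n = 30$, and with
`igraph::betweenness()` as an independent implementation.

Connectors relate one origin to any number of targets (monadic to
polyadic synapses), every link carrying its own confidence.
`build_circuit()` drops links below the link-confidence threshold,
severs skeletons at edges below the edge-confidence threshold
(links re-attach to the component that contains their node, labelled
`tree#k` beyond the first), and counts surviving origin→target links
as edge weights. Conservation (total weight = surviving links) and
monotonicity in both thresholds are tested over random circuits.
Free-point connector ends have no neuron identity; they are excluded
from circuit edges but kept, flagged incomplete, in
`partner_table()`.

Exchange: SWC (one line per node, 1-based sequential ids, calibrated
units, root type 1 at the soma by convention; confidences, tags,
layers and original ids ride in a `#` annex so the round trip is
lossless), NeuroML Level 3 v1.8.1 (MorphML segments per skeleton
edge, NetworkML connections per link with connector id and confidence
as properties — the version is pinned in the document and
overridable), adjacency CSV (square, sorted ids), and the package's
own project XML covering every object type.

# Ontology

A `template()` is a user-defined controlled vocabulary: each abstract
type lists the child types it may be represented by; primitive kinds
(area lists, treelines, areatrees, connectors, balls, pipes) are
leaves. `validate_project()` reports every parent/child relation or
binding that the template does not allow, and enforces a
single-parent rule for bound primitives (a primitive under two groups
would make group measurements double-count; detaching is the default
on deletion). `group_measure()` aggregates kind-specific measures
depth-first below any node and appends a totals row; totals equal the
flat sum over leaves and are invariant to child order.

# Volumetry and stereology

Area lists store painted polygons per layer; fills are resolved by
the even-odd rule at pixel centres, which makes boolean paint
operations and areas exact on the pixel grid (no floating-point
polygon clipping). Volume is $\sum_\ell \text{area}_\ell \times
\text{thickness}_\ell$; for a digital sphere of radius 20 px this is
within 2% of $\tfrac43\pi r^3$.

`marching_tetrahedra()` extracts iso-surfaces by marching cubes with
a six-tetrahedron cell decomposition sharing the main diagonal — the
decomposition resolves the ambiguous cube cases and makes every
interior surface watertight (each edge shared by exactly two
triangles), which the tests assert directly. Area lists are meshed
from their binary volumes (vertices at voxel-edge midpoints; layers
are replicated along $z$ toward isotropy first); balls and pipes are
rasterised as signed-distance fields (spheres; tubes with linearly
interpolated centreline and radius) and iso-surfaced at zero, giving
sub-voxel surfaces — the sphere's mesh area lands within 5% of
$4\pi r^2$.

`vesicle_cleft_distances()` reports, per ball, the minimum calibrated
3D distance from its centre to any cleft voxel centre (checked
against exhaustive enumeration on small fixtures).
`double_disector()` matches markers between two sections greedily by
ascending distance within a match radius — deterministic and faithful
to the visual overlay-grid protocol — and counts unmatched markers of
the second section as newly appearing objects; a planted-truth
simulation with 200 markers and jitter below half the radius is
recovered exactly.

# The synthetic generator and what it does not emulate

Every generator output is a pure function of its parameters and one
integer seed (sub-streams are derived at fixed offsets). The texture
is band-limited noise plus dark Voronoi-edge membranes and blob
organelles — enough statistical structure for feature detection and
block matching, with an 8-bit histogram spanning well over 100 gray
levels. Tile sets emulate stage acquisition: overlapping crops
sampled under known translation/rigid perturbations with additive
Gaussian noise and linear shading, nominal origins rounded to integer
pixels so the jitter-free mosaic reassembles the texture exactly.
Deformations are smooth analytic fields; artifacts are fold bands and
dark blobs with truth masks.

The generator does **not** emulate real EM: no section-to-section
content change (biology!), no charging, staining gradients beyond
linear shading, lens distortion, tears, or debris. Passing tests
therefore demonstrate the algorithms' correctness and their accuracy
under controlled deformation and noise — not segmentation-grade
performance on real micrographs. Study sizes used by the tests and
the acceptance script: $768^2$ texture cut 3×3 at 20% overlap for
montaging, $1024^2$ sections for elastic alignment, 1000 random
arbors ($n \le 200$) for format round trips, 100 random circuits for
threshold sweeps.

# Degenerate inputs and error conventions

Constant images yield empty feature lists; empty match results mean
"no overlap"; a correspondence graph that is disconnected montages
per component with a warning but is an error for global pose
optimization (which exists precisely to tie sparse montages
together); block matches on flat blocks carry $r = 0$ so the filter
removes them; filtering everything away warns and returns an empty
field. Degenerate linear transforms, collinear affine landmark
triples, inconsistent duplicate MLS landmarks, self-intersecting
paint polygons, splitting a tree at its root and merging a tree with
itself are errors with stable message prefixes (`invalid-transform`,
`degenerate-landmarks`, `inconsistent-landmarks`, `geometry error`,
`invalid-split`, `self-merge`).

# Known limitations

* Pipes interpolate linearly between control points; no spline.
* MLS inversion is mesh-approximate (8 px grid) rather than exact.
* The NeuroML writer targets morphology and connectivity exchange,
  not simulation-ready biophysics.
* Alpha masks persist as 8-bit PNGs.
* Lens-distortion estimation, interactive display, out-of-core
  caching and automatic segmentation are out of scope.
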