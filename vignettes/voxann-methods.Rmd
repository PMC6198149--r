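---
title: "voxann: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxann: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxann)
```

This vignette records the models, conventions and numerical choices
behind voxann, in the spirit of a methods section: what the voxel store
actually guarantees, which knobs matter, and where a design was
genuinely open and a choice had to be made.

## The multiresolution voxel model

A volume is a sparse set of 16×16×16-voxel chunks per mip level. Level 0
is full resolution; level *L* halves X and Y (`ceil(dims/2^L)`) and
leaves Z untouched, because serial-section data is strongly anisotropic
(sections are typically 5–10× thicker than the in-plane pixel): at
6×6×30 nm voxels, halving Z alongside XY would destroy section
registration long before the in-plane detail is exhausted. Chunks are
the unit of allocation, caching and compression; an unallocated chunk
reads as the background value 0, so an empty petavoxel-scale volume
costs nothing.

**Cross-level semantics (authoritative writes).** The store must answer
one awkward question: what does a voxel read when different mip levels
hold conflicting explicit data? We adopt a deterministic rule — a write
at level *L* is authoritative for its footprint. It deletes explicit
finer-level data underneath, and re-reduces every coarser level over the
footprint; reads at a finer level inherit by 2×2 XY replication from the
nearest coarser level with explicit data. This matches the natural
workflow (block in a region coarsely, then refine locally — the fine
correction wins where it was made, the coarse paint persists elsewhere)
and makes every edit script replayable against a dense reference model,
which is exactly how the store is tested. Explicitness is tracked per
voxel (each chunk carries a bit mask next to its values): chunk-granular
tracking would silently freeze inherited values for the untouched part
of a partially written chunk, which we found diverges from the dense
model as soon as a later write changes the coarse data nearby.

**Downsampling.** Image kinds reduce by the arithmetic mean of each 2×2
XY child group, rounded half-up; RGB reduces per channel. Label volumes
cannot be averaged, so each coarse voxel takes the majority label of its
children, ties broken by the smallest id — deterministic, and stable
under re-reduction. Because majority voting does not commute with id
relabeling (children (1,2,9,9) have majority 9, but mapping 1→2 flips it
to 2), weld/merge/delete re-reduce the affected footprints after
applying an id map rather than mapping coarse voxels directly.

**Z-order and the container.** Chunk payloads are serialized in Morton
(Z-) order with x in the least-significant bit of each 3-bit group —
an internal storage detail, verified only through bijectivity and
round-trips. The segmentation container is a little-endian format of
this package (magic `VSG1`): a header, the metadata text embedded as a
blob, and per level a tree of 16×16×16-pointer index blocks whose leaf
pointers address deflate-compressed chunk records. Only allocated chunks
are stored, so the file grows with painted content, not with the nominal
dataset extent; saving is a full rewrite, which also covers extending a
previously saved subregion. Bit-compatibility with any external
container format is a non-goal.

**Cache contract.** The LRU bookkeeping models the part of caching that
carries correctness weight: least-recently-used *clean* chunks are
evicted first, and a modified chunk is never discarded — if capacity is
exceeded while everything resident is dirty, the LRU dirty chunk is
spilled to a disk store and can be faulted back in. View-centric
prefetching and loader threads are interactive concerns and are out of
scope.

## Masking and the paint engine

Every edit is the intersection of up to three masks:

* the **pen mask** — Euclidean disks of diameter *d* (a voxel belongs if
  its center is within *d*/2 of the stamp center, ties included; a
  diameter-3 pen covers the full 3×3 square since the corner distance
  √2 ≤ 1.5) stamped along the per-voxel interpolated polyline;
* the **target-mode mask** — everywhere, only background (current id 0),
  or only voxels of the paint id's direct parent (the standard way to
  carve a child object out of its parent);
* the **source mask** — computed on a *different* layer: voxels whose
  value (or chosen RGB channel) lies in a range, or equals the value
  picked at the seed. Both variants are restricted to the connected
  component containing the seed. The range mask is how a
  boundary-probability map guides tracing: interiors are the low-value
  contiguous regions, so a fill seeded inside an object cannot cross its
  membrane. Whether a brightness-range mask should demand contiguity at
  all is ambiguous; we implement the contiguous reading (it is the one
  that makes boundary-map tracing safe) and flag it here.

Connectivity is 4-connected within a section and 6-connected in 3D.
Diagonal connectivity would leak through one-voxel membranes — the very
structures these masks exist to respect.

Auto-close treats "enclosed" as: background components of the section
not reachable from the section border after the stroke is applied
(flood from the border). Z-gap fill scans each painted XY column up to
`max_paint_depth` sections in both directions; finding the paint id at
distance *k* fills the *k*−1 intervening voxels, subject to the target
mode but not to source masks (it is a scan over the paint layer only).
It is monotone in the depth parameter by construction.

## Proofreading

Split errors are corrected non-destructively by collecting fragments
into a folder and welding: all descendant ids are relabeled to the
lowest descendant id (the survivor — a deterministic choice we document
rather than inherit from any external convention), conserving voxel
mass. Merge errors are corrected by erasing the false bridge and
recoloring one connected component; `split_components()` gives every
component beyond the largest a fresh id (lowest free ids), with size
ties broken by the smallest component-minimum Morton index so the
outcome never depends on labeling order.

Combining two segmentations resolves conflicts voxel-by-voxel: source
precedence overwrites nonzero target voxels, target precedence protects
them. Colliding source ids are moved to the lowest free target ids by
default and the map is reported. External 64-bit ids are truncated to
24 bits for display; exact nonzero multiples of 2²⁴ map to the sentinel
2²⁴−1 rather than 0 so no object silently vanishes — one consistent way
to honor the requirement that such ids must not disappear, chosen here.

## Rendering

Segment meshes are blocky voxel-face meshes: one quad per exposed face,
scaled by the (level-adjusted) voxel size. The area of such a mesh
overestimates the true surface of a smooth object by construction;
smoothing is deliberately external. The payoff is exactness where it is
testable: a single 6×6×30 nm voxel meshes to precisely
2·36 + 4·180 = 792 nm², and every finite object yields a closed
2-manifold. Isosurfaces instead use marching tetrahedra on the
Kuhn/Freudenthal 6-tetrahedra cell decomposition — face-consistent
across the lattice, hence watertight without case tables — with linear
edge interpolation; coincident vertices are welded and triangles
degenerated by the surface passing exactly through a sample are dropped.
On a smooth radial field of radius 14 voxels the sphere area is
reproduced within ~1 % (the tolerance we test is 5 %).

Projections cast rays along a cardinal axis: max intensity, first
nonzero hit, or first-hit modulated by Lambertian shading with normals
from the central-difference depth gradient and an ambient floor of 0.2.
No illumination formula is canonical for this kind of offline preview;
Lambert-from-depth is the simplest model with the right monotonicity
(surfaces tilting away from the light darken), and the light direction
is a parameter. The 16 pattern bitmaps used to mix a segment's two
colors are fixed 8×8 masks defined in this package (pattern 0 empty,
15 full, stripes/checkers/dots between); compositing uses standard
normal/add/multiply blending with per-layer and selected-branch alphas.

## The phantom generator

`make_phantom()` emulates the geometry that matters to the editing and
proofreading operations: tube-like objects (smoothed random-walk
centerlines along Z, dilated to radius 4 voxels) and ellipsoidal blobs,
bright interiors (180) against a mid background (120) with one-voxel
dark membranes (40) and additive Gaussian noise (sd 10) at 6×6×30 nm
voxels — values picked once as representative of stained EM tissue.
Objects are placed with a one-voxel background gap: real neurites are
separated by membranes, and the gap is what makes an injected merger
(relabeling two near-adjacent objects to one id) separable again by
connected-component splitting. Error injection cuts objects at a random
interior Z plane (splits) and relabels near-adjacent pairs within two
6-steps (mergers), recording every event in a ledger so a scripted
repair can be verified to recover the truth exactly (Rand index 1).

What the phantom does *not* emulate: realistic EM texture, imaging
artifacts, alignment error, or learned boundary-probability maps (the
map is the exact label-boundary shell, optionally blurred). Passing
tests therefore demonstrate the correctness of the operations'
semantics, not robustness to real-data noise — on real data the same
masked fill will leak wherever a membrane prediction is broken, which is
precisely why these tools are interactive in practice.

## Numerical and scale choices

Coordinates are 0-based (x, y, z); boxes are half-open; sizes are nm.
Test and acceptance problem sizes are chosen so the whole suite runs in
well under a minute of compute on one core while still exercising
multi-chunk, multi-level paths: oracle-equivalence scripts use 12³–16³
volumes (220 randomized scripts), round-trips use up to 256×256
sections (the id encoding is checked exhaustively over all 65536 ids),
the recovery property uses the default 48×48×16 phantom, and the
isosurface check uses a 40³ radial field. The dense shadow model, BFS
flood fills, per-column Z scans and the list-based LRU used as oracles
live in the test helpers and share no code with the package.

## Known limitations

* The in-memory chunk index is a hash map; the 16³ pointer-block tree
  exists in the container format (and is validated there), not as the
  in-memory index structure.
* Image IO is PNG/TIFF/RAW only, both directions: segmentations and
  round-trip guarantees do not survive lossy formats, so none are
  offered.
* `read_region` materializes dense blocks; reading a whole teravoxel
  level is not meaningful. Operations that scan "the volume" (weld
  histograms, extents) scan the painted bounding box.
* No undo stack and no concurrent editing: edits are scripted, callers
  snapshot containers.
* Mesh smoothing, skeletonization and interactive viewing are out of
  scope by design.
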