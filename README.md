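# voxann

Headless R toolkit for dense volume annotation of serial-section electron
microscopy (and other large 3D image) data: the compute core of a
volume-annotation workflow without any GUI. It is aimed at connectomics
labs that paint, proofread and measure neurite segmentations on EM stacks,
and at tool builders who need a scriptable, testable voxel store.

## What it provides

* **Sparse chunked voxel store** — volumes are collections of
  16×16×16-voxel chunks allocated on demand, with XY-only powers-of-two
  mipmaps (serial sections are anisotropic, so Z is never resampled; a
  4096² section has 2048², 1024², 512², 256² reductions). Unallocated
  chunks read as background 0. A write at mip level *L* is authoritative:
  it removes explicit finer data under its footprint and re-reduces every
  coarser level (images by rounded 2×2 means, labels by majority vote
  with smallest-id ties), so coarse painting and fine corrections
  coexist deterministically. LRU cache bookkeeping protects modified
  chunks: dirty blocks are spilled to disk, never dropped.
* **Segment hierarchy** — segments (ids 1..65535, 16-bit voxels) carry a
  label, two 24-bit RGB colors plus one of 16 patterns (an almost 52-bit
  color key: `(c1·2²⁴ + c2)·16 + pattern`), anchor points, bounding boxes
  and a folder tree with collapse-state color resolution, collect,
  weld and delete-subtree operations.
* **Masked painting** — every edit is the intersection of a pen mask
  (Euclidean disks along the stroke), a target-mode mask (paint all /
  background only / parent only) and optionally a *trans-layer* source
  mask from a second layer: a brightness range or the picked value,
  restricted to the connected region around the seed. Auto-close fills
  drawn contours; Max-Paint-Depth fills Z-gaps between outlines painted
  every *k*-th section (outlines 8 apart fill the 7 skipped sections).
* **Proofreading** — connected-component splitting, folder welding,
  voxel-precedence merging of independently traced segmentations
  (source precedence overwrites, target precedence protects nonzero
  voxels) with id renumbering, and 24-bit truncation handling for
  external ids (nonzero multiples of 2²⁴ map to the sentinel 2²⁴−1, not
  to background).
* **IO** — PNG/TIFF stack import/export (tiled, with manifest), JSON
  volume descriptors, id-image stacks (id high byte in green, low byte in
  blue), a sparse single-file segmentation container with 16³-fan-out
  pointer-block trees and deflated Z-order chunk records, and a
  tab-separated metadata text round-trip.
* **Rendering & measurement** — voxel-face OBJ meshes (area 2(s₁s₂)+...
  exact for cuboids; deliberately blocky, smoothing is external),
  marching-tetrahedra isosurfaces, particle clouds at component
  centroids, box/scale-bar models, cardinal-axis projections with
  Lambertian depth-gradient illumination, layer compositing, and
  volume/surface/distance measurements in nm.
* **Synthetic phantoms** — seeded neurite-like tube/blob phantoms with
  membranes and noise, boundary-probability maps, and split/merge error
  injection with a ledger, so the whole pipeline is testable offline.

## Worked example

Semi-automatic tracing against a boundary-probability map — seed one
fill inside an object and let the trans-layer mask carve out its shape:

```r
library(voxann)

ph   <- make_phantom(phantom_spec(seed = 7))        # 48x48x16 vx, 6x6x30 nm
bmap <- make_boundary_map(ph$truth)                 # 255 on object shells
seg  <- create_volume(c(48, 48, 16), c(6, 6, 30), "id16", num_levels = 2)

truth    <- as_array(ph$truth)
interior <- truth == 1L & as_array(bmap) == 0L      # inside object 1
seed     <- which(interior, arr.ind = TRUE)[1, ] - 1L

n <- flood_fill(seg, seed, 1L,
                mask_spec(source_mode = "value_range", lo = 0, hi = 127),
                source = bmap)
n
#> [1] 387
measure(seg, 1)[c("voxel_count", "volume_nm3", "surface_area_nm2")]
#> $voxel_count
#> [1] 387
#> $volume_nm3
#> [1] 417960
#> $surface_area_nm2
#> [1] 70416
particle_cloud(seg, 1)$count
#> [1] 1
```

The fill recovers the 387-voxel interior of object 1 (the one-voxel
membrane shell stays unlabeled — 768 voxels including the shell), a
single connected component of 417,960 nm³ whose blocky mesh surface is
70,416 nm²; `write_obj(segment_mesh(seg, 1), "object1.obj")` exports it
for any 3D package.

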