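Package: voxann
Title: Sparse Chunked Voxel Volumes for Volume EM Annotation and Proofreading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for dense volume annotation of serial-section
    electron microscopy (and other 3D image) data. Provides a sparse, chunked,
    multiresolution voxel container (16-voxel cubes, XY-only powers-of-two
    mipmaps, pointer-block indexed storage, LRU cache bookkeeping with
    dirty-block protection), hierarchical segment metadata with collapse-state
    color resolution, masked voxel painting and flood filling (pen, target-mode
    and trans-layer source masks, auto-close contour filling, Z-gap fill),
    proofreading operations (weld, component splitting, volume merging with
    source/target precedence and id renumbering), image-stack and segmentation
    container import/export, and offline rendering (voxel-face surface meshes,
    marching-tetrahedra isosurfaces, particle clouds, projection images with
    Lambertian illumination, layer compositing) plus volume, surface-area and
    distance measurements. Ships a deterministic synthetic phantom generator
    (neurite-like tubes, boundary-probability maps, split/merge error
    injection) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
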