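#' Edit constraint specification (masking)
#'
#' Every paint or fill operation is constrained by the intersection of up
#' to three masks: the pen mask (where the tool touches), a target-layer
#' mask (`paint_all`: everywhere; `background_only`: voxels currently 0;
#' `parent_only`: voxels currently labeled with the paint id's direct
#' parent), and optionally a trans-layer source mask computed from a
#' second layer (a brightness/color range, or the value picked at the
#' seed), restricted to the connected region containing the seed.
#'
#' @param target_mode one of `"paint_all"`, `"background_only"`,
#'   `"parent_only"`.
#' @param source_mode one of `"none"`, `"value_range"`, `"picked_value"`.
#' @param lo,hi inclusive value range for `source_mode = "value_range"`.
#' @param channel source channel: `"gray"` (the raw value) or `"r"`,
#'   `"g"`, `"b"` for `rgb24` source layers.
#' @param restrict_level mip level at which edits are applied (NULL: the
#'   stroke's / the volume's level 0).
#' @param max_paint_depth Z-gap fill distance in sections (0 disables).
#' @return a `mask_spec` object.
#' @export
mask_spec <- function(target_mode = c("paint_all", "background_only", "parent_only"),
                      source_mode = c("none", "value_range", "picked_value"),
                      lo = 0L, hi = 255L, channel = "gray",
                      restrict_level = NULL, max_paint_depth = 0L) {
  target_mode <- match.arg(target_mode)
  source_mode <- match.arg(source_mode)
  if (lo > hi) stop("value range requires lo <= hi")
  if (!channel %in% c("gray", "r", "g", "b")) stop("unknown source channel")
  structure(list(target_mode = target_mode, source_mode = source_mode,
                 lo = as.integer(lo), hi = as.integer(hi), channel = channel,
                 restrict_level = restrict_level,
                 max_paint_depth = as.integer(max_paint_depth)),
            class = "mask_spec")
}

#' Pen stroke description
#'
#' @param z section index (0-based) at the stroke's level.
#' @param centers n x 2 matrix (or length-2 vector) of 0-based XY centers
#'   along the stroke; consecutive centers are connected.
#' @param diameter pen tooltip diameter in voxels at the editing level.
#' @param id paint id (0 erases).
#' @param level mip level the stroke is drawn at.
#' @return a `pen_stroke` object.
#' @export
pen_stroke <- function(z, centers, diameter = 1L, id = 1L, level = 0L) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2, byrow = TRUE)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (diameter < 1) stop("pen diameter must be >= 1 voxel")
  structure(list(z = as.integer(z), centers = centers,
                 diameter = as.numeric(diameter), id = as.integer(id),
                 level = as.integer(level)),
            class = "pen_stroke")
}

#' Rasterize a pen stroke into a section mask
#'
#' The mask is the union of Euclidean disks of the pen diameter stamped at
#' every voxel along the polyline through the stroke centers (per-voxel
#' stepping). A voxel belongs to a disk when its center lies within
#' `diameter / 2` of the stamp center, ties included; a diameter-3 pen
#' therefore covers the full 3x3 square (corner distance sqrt(2) <= 1.5).
#'
#' @param stroke a [pen_stroke()].
#' @param section_dims integer (width, height) of the section at the
#'   stroke's level.
#' @return logical width x height matrix.
#' @export
make_pen_mask <- function(stroke, section_dims) {
  w <- section_dims[1]; h <- section_dims[2]
  if (any(stroke$centers[, 1] < 0 | stroke$centers[, 1] >= w |
          stroke$centers[, 2] < 0 | stroke$centers[, 2] >= h))
    stop("stroke centers must lie within the section")
  # disk stamp offsets
  r <- stroke$diameter / 2
  rr <- ceiling(r)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  # per-voxel polyline interpolation
  pts <- stroke$centers[1, , drop = FALSE]
  if (nrow(stroke$centers) > 1) for (i in 2:nrow(stroke$centers)) {
    a <- stroke$centers[i - 1, ]; b <- stroke$centers[i, ]
    n <- max(abs(b - a)); n <- max(1, ceiling(n))
    t <- seq_len(n) / n
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  pts <- unique(round(pts))
  m <- matrix(FALSE, w, h)
  for (i in seq_len(nrow(pts))) {
    xs <- pts[i, 1] + off$dx; ys <- pts[i, 2] + off$dy
    ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
    m[cbind(xs[ok] + 1L, ys[ok] + 1L)] <- TRUE
  }
  m
}

#' Label connected components of a voxel mask
#'
#' 6-connected in 3D; a 2D matrix (or a single-section array) yields
#' 4-connected in-plane labeling. Labels are 1..k in scan order,
#' background 0.
#'
#' @param mask logical array (2D or 3D).
#' @return integer array of component labels, same shape.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array")
  if (length(d) == 2L) d <- c(d, 1L)
  lab <- .label_components_cpp(as.logical(mask), as.integer(d))
  dim(lab) <- dim(mask)
  lab
}

# target-mode admissibility over a block of current segmentation values
.target_mask <- function(cur, mode, paint_id, table = NULL) {
  switch(mode,
    paint_all = array(TRUE, dim = dim(cur) %||% length(cur)),
    background_only = cur == 0L,
    parent_only = {
      if (is.null(table)) stop("parent_only masking needs a segment table")
      p <- table$parent_id[match(paint_id, table$id)]
      if (is.na(p)) stop(sprintf("paint id %d is not in the segment table", paint_id))
      if (p == 0L) stop("parent_only masking requires the paint id to have a parent segment")
      cur == p
    })
}

#' Target-layer mask over a footprint
#'
#' @param vol the target `id16` volume.
#' @param mode target mode (see [mask_spec()]).
#' @param paint_id the id being painted.
#' @param table segment table (needed for `parent_only`).
#' @param footprint half-open bbox at `level`.
#' @param level mip level.
#' @return logical array over the footprint.
#' @export
target_mask <- function(vol, mode, paint_id, table = NULL,
                        footprint = NULL, level = 0L) {
  if (is.null(footprint)) footprint <- c(0L, 0L, 0L, level_extent(vol, level))
  cur <- read_region(vol, level, footprint)
  .target_mask(cur, mode, paint_id, table)
}

# source channel extraction
.source_channel <- function(arr, kind, channel) {
  if (kind != "rgb24" || channel == "gray") return(arr)
  ch <- unpack_rgb24(arr)[[channel]]
  array(ch, dim = dim(arr))
}

# mask over a source block: in-range (or picked-value) voxels restricted
# to the connected component containing the seed
.source_mask <- function(src, kind, spec, seed_local) {
  v <- .source_channel(src, kind, spec$channel)
  if (spec$source_mode == "picked_value") {
    pv <- v[matrix(seed_local + 1L, 1)]
    ok <- v == pv
  } else {
    ok <- v >= spec$lo & v <= spec$hi
  }
  if (!ok[matrix(seed_local + 1L, 1)])
    stop("seed voxel is outside the source mask range")
  lab <- label_components(ok)
  lab == lab[matrix(seed_local + 1L, 1)]
}

#' Trans-layer source mask over a footprint
#'
#' `value_range`: voxels whose source value (chosen channel) lies in
#' `[lo, hi]`; `picked_value`: voxels equal to the value at the seed. Both
#' are restricted to the connected component containing the seed
#' (4-connected within a section, 6-connected in 3D).
#'
#' @param source the source layer (`chunked_volume`).
#' @param spec a [mask_spec()] with `source_mode != "none"`.
#' @param seed 0-based (x, y, z) seed at `level`.
#' @param footprint half-open bbox at `level` (default: whole level).
#' @param level mip level.
#' @return logical array over the footprint.
#' @export
source_mask <- function(source, spec, seed, footprint = NULL, level = 0L) {
  if (spec$source_mode == "none") stop("spec has no source mode")
  if (is.null(footprint)) footprint <- c(0L, 0L, 0L, level_extent(source, level))
  seed <- as.integer(seed)
  if (any(seed < footprint[1:3]) || any(seed >= footprint[4:6]))
    stop("seed lies outside the footprint")
  src <- read_region(source, level, footprint)
  .source_mask(src, source$value_kind, spec, seed - footprint[1:3])
}

#' Apply a pen stroke under masking
#'
#' The painted set is the intersection of the rasterized pen mask, the
#' target-mode mask and (when a source layer is given with a source mode)
#' the trans-layer source mask seeded at the first stroke center. With
#' `auto_close = TRUE`, background regions of the section that are not
#' reachable from the section border after painting are filled too (empty
#' closed contours). If the spec's `max_paint_depth` is nonzero, Z-gap
#' filling runs over the painted set afterwards. A paint id of 0 erases.
#'
#' @param vol target `id16` volume.
#' @param stroke a [pen_stroke()].
#' @param spec a [mask_spec()].
#' @param source optional source layer for trans-layer masking.
#' @param table segment table (for `parent_only` and anchor bookkeeping).
#' @param auto_close fill enclosed background contours.
#' @return list with counts: `painted`, `closed`, `zfilled`, `total`.
#' @export
apply_stroke <- function(vol, stroke, spec = mask_spec(), source = NULL,
                         table = NULL, auto_close = FALSE) {
  level <- spec$restrict_level %||% stroke$level
  level <- .check_level(vol, level)
  ext <- level_extent(vol, level)
  z <- stroke$z
  if (z < 0L || z >= ext[3]) stop("stroke section outside volume")
  pen <- make_pen_mask(stroke, ext[1:2])
  box <- c(0L, 0L, z, ext[1], ext[2], z + 1L)
  cur <- read_region(vol, level, box)
  cur2 <- matrix(cur, ext[1], ext[2])
  tm <- matrix(.target_mask(cur, spec$target_mode, stroke$id, table),
               ext[1], ext[2])
  sm <- matrix(TRUE, ext[1], ext[2])
  if (spec$source_mode != "none") {
    if (is.null(source)) stop("source mode set but no source layer given")
    seed <- c(round(stroke$centers[1, ]), z)
    sm <- matrix(source_mask(source, spec, seed, box, level), ext[1], ext[2])
  }
  painted <- pen & tm & sm
  newsec <- cur2
  newsec[painted] <- stroke$id
  closed <- matrix(FALSE, ext[1], ext[2])
  if (auto_close && stroke$id != 0L) {
    bg <- newsec == 0L
    lab <- label_components(bg)
    border <- unique(c(lab[1, ], lab[ext[1], ], lab[, 1], lab[, ext[2]]))
    enclosed <- bg & !(lab %in% setdiff(border, 0L))
    closed <- enclosed & tm & sm
    newsec[closed] <- stroke$id
  }
  write_region(vol, level, box, array(newsec, dim = c(ext[1], ext[2], 1L)))
  nz <- 0L
  if (spec$max_paint_depth > 0L && stroke$id != 0L) {
    xy <- which(painted | closed, arr.ind = TRUE) - 1L
    nz <- zgap_fill(vol, xy, z, stroke$id, spec$max_paint_depth,
                    target_mode = spec$target_mode, table = table,
                    level = level)
  }
  if (!is.null(table) && stroke$id %in% table$id) {
    i <- match(stroke$id, table$id)
    if (is.na(table$anchor_x[i]) && any(painted)) {
      first <- which(painted, arr.ind = TRUE)[1, ] - 1L
      table$anchor_x[i] <- first[1]; table$anchor_y[i] <- first[2]
      table$anchor_z[i] <- z
    }
  }
  list(painted = sum(painted), closed = sum(closed), zfilled = nz,
       total = sum(painted) + sum(closed) + nz,
       table = if (is.null(table)) NULL else table)
}

#' Fill Z-gaps between painted sections (Max Paint Depth)
#'
#' For every XY coordinate of the painted set, scans up to `max_depth`
#' sections in both Z directions for a voxel already carrying the paint
#' id; if one is found at distance `k <= max_depth`, the `k - 1`
#' intervening voxels are filled (subject to the target mode). Painting
#' outlines every eighth section with depth 8 therefore fills the seven
#' skipped sections wherever the outlines overlap in XY.
#'
#' @param vol target `id16` volume.
#' @param xy n x 2 matrix of 0-based XY coordinates (the painted set).
#' @param z the painted section.
#' @param paint_id the paint id.
#' @param max_depth maximum gap distance in sections (>= 1).
#' @param target_mode target mode applied to the filled voxels.
#' @param table segment table for `parent_only`.
#' @param level mip level.
#' @return number of voxels filled, invisibly.
#' @export
zgap_fill <- function(vol, xy, z, paint_id, max_depth,
                      target_mode = "paint_all", table = NULL, level = 0L) {
  if (max_depth < 1L) stop("max_depth must be >= 1")
  if (nrow(xy) == 0L) return(invisible(0L))
  ext <- level_extent(vol, level)
  z0 <- max(0L, z - max_depth); z1 <- min(ext[3], z + max_depth + 1L)
  bx <- c(min(xy[, 1]), min(xy[, 2]), z0,
          max(xy[, 1]) + 1L, max(xy[, 2]) + 1L, z1)
  arr <- read_region(vol, level, bx)
  li <- cbind(xy[, 1] - bx[1] + 1L, xy[, 2] - bx[2] + 1L)
  filled <- 0L
  for (dir in c(-1L, 1L)) {
    firstk <- rep(NA_integer_, nrow(xy))
    for (k in seq_len(max_depth)) {
      zz <- z + dir * k
      if (zz < z0 || zz >= z1) break
      v <- arr[cbind(li, zz - bx[3] + 1L)]
      hit <- is.na(firstk) & v == paint_id
      firstk[hit] <- k
    }
    for (k in seq_len(max_depth)) {
      sel <- !is.na(firstk) & firstk > k    # fill strictly between
      if (!any(sel)) next
      zz <- z + dir * k
      ii <- cbind(li[sel, , drop = FALSE], zz - bx[3] + 1L)
      curv <- arr[ii]
      ok <- switch(target_mode,
                   paint_all = rep(TRUE, length(curv)),
                   background_only = curv == 0L,
                   parent_only = {
                     p <- table$parent_id[match(paint_id, table$id)]
                     curv == p
                   })
      ii <- ii[ok & curv != paint_id, , drop = FALSE]
      if (nrow(ii)) { arr[ii] <- paint_id; filled <- filled + nrow(ii) }
    }
  }
  if (filled > 0L) write_region(vol, level, bx, arr)
  invisible(filled)
}

#' Masked flood fill (2D or 3D)
#'
#' Recolors the connected component of the seed over the fill predicate:
#' voxels carrying the seed's current value, intersected with the target
#' and (optional) source masks. Connectivity is 4-connected within the
#' seed's section in 2D, 6-connected in 3D. A seed excluded by the mask
#' fills nothing (with a warning).
#'
#' @param vol target `id16` volume.
#' @param seed 0-based (x, y, z) seed.
#' @param new_id replacement id.
#' @param spec a [mask_spec()].
#' @param dimensionality `"3D"` (default) or `"2D"`.
#' @param source optional source layer.
#' @param table segment table.
#' @return number of voxels recolored.
#' @export
flood_fill <- function(vol, seed, new_id, spec = mask_spec(),
                       dimensionality = c("3D", "2D"), source = NULL,
                       table = NULL) {
  dimensionality <- match.arg(dimensionality)
  level <- spec$restrict_level %||% 0L
  level <- .check_level(vol, level)
  ext <- level_extent(vol, level)
  seed <- as.integer(seed)
  if (any(seed < 0L) || any(seed >= ext)) stop("seed outside volume")
  box <- if (dimensionality == "2D")
    c(0L, 0L, seed[3], ext[1], ext[2], seed[3] + 1L)
  else c(0L, 0L, 0L, ext)
  arr <- read_region(vol, level, box)
  sl <- seed - box[1:3]
  seed_val <- arr[matrix(sl + 1L, 1)]
  pred <- arr == seed_val &
    .target_mask(arr, spec$target_mode, new_id, table)
  if (spec$source_mode != "none") {
    if (is.null(source)) stop("source mode set but no source layer given")
    pred <- pred & source_mask(source, spec, seed, box, level)
  }
  if (!pred[matrix(sl + 1L, 1)]) {
    warning("seed voxel is excluded by the mask; nothing filled")
    return(0L)
  }
  lab <- label_components(pred)
  comp <- lab == lab[matrix(sl + 1L, 1)]
  n <- sum(comp)
  arr[comp] <- new_id
  write_region(vol, level, box, arr)
  n
}

#' Pipette: value under a point
#'
#' @param vol a `chunked_volume`.
#' @param point 0-based (x, y, z) at `level`.
#' @param level mip level.
#' @return the effective value (segment id or image value).
#' @export
pick <- function(vol, point, level = 0L) {
  point <- as.integer(point)
  effective_value(vol, level, point[1], point[2], point[3])
}

#' Per-id voxel counts
#'
#' Counts effective level-0 voxels per nonzero id over the painted region.
#'
#' @param vol an `id16` volume.
#' @param id optional single id; if given, returns its count.
#' @return named integer vector of counts (or a single count).
#' @export
id_histogram <- function(vol, id = NULL) {
  bb <- .painted_bbox(vol)
  if (is.null(bb)) {
    return(if (is.null(id)) stats::setNames(integer(0), character(0)) else 0L)
  }
  arr <- read_region(vol, 0L, bb)
  if (!is.null(id)) return(sum(arr == id))
  tb <- table(arr[arr != 0L])
  stats::setNames(as.integer(tb), names(tb))
}
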