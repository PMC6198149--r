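#' Fixed 8x8 pattern bitmaps
#'
#' Sixteen repo-defined binary 8x8 tiling masks used to mix a segment's
#' two display colors (pattern 0 is empty = pure color1; pattern 15 is
#' full = pure color2 at full pattern strength).
#'
#' @param pattern index 0..15.
#' @return logical 8x8 matrix (`TRUE` = color2 pixel).
#' @export
pattern_bitmap <- function(pattern) {
  pattern <- as.integer(pattern)
  if (pattern < 0L || pattern > 15L) stop("pattern must lie in 0..15")
  x <- matrix(0:7, 8, 8); y <- t(x)
  switch(pattern + 1L,
    matrix(FALSE, 8, 8),                  # 0 solid color1
    (x + y) %% 2 == 0,                    # 1 fine checker
    y %% 2 == 0,                          # 2 horizontal stripes
    x %% 2 == 0,                          # 3 vertical stripes
    (x + y) %% 4 == 0,                    # 4 diagonal stripes
    (x - y) %% 4 == 0,                    # 5 anti-diagonal stripes
    x %% 4 == 0 & y %% 4 == 0,            # 6 dots
    x %% 4 == 0 | y %% 4 == 0,            # 7 grid
    ((x %/% 2) + (y %/% 2)) %% 2 == 0,    # 8 coarse checker
    y %% 4 < 2,                           # 9 wide horizontal stripes
    x %% 4 < 2,                           # 10 wide vertical stripes
    (x + y) %% 4 == 0 | (x - y) %% 4 == 0,# 11 diagonal cross-hatch
    x %% 4 == 2 & y %% 4 == 2,            # 12 sparse dots
    (x %% 4) > (y %% 4),                  # 13 triangles
    x %% 2 == 0 & y %% 2 == 1,            # 14 offset dots
    matrix(TRUE, 8, 8))                   # 15 solid color2
}

#' Layer view settings for compositing
#'
#' @param layer a `chunked_volume` (image or segmentation).
#' @param alpha layer opacity in `[0, 1]`.
#' @param sel_alpha opacity of the selected branch (segmentation layers);
#'   defaults to `alpha`.
#' @param selected_id id whose subtree is the "selected branch".
#' @param pattern_strength 0..1 mix between color1 and the pattern's
#'   color2 pixels.
#' @param gain per-channel color gain (length 3).
#' @param offset per-channel additive offset in 0..1 units.
#' @param blend `"normal"`, `"add"` or `"multiply"`.
#' @return a `layer_view` object.
#' @export
layer_view <- function(layer, alpha = 1, sel_alpha = NULL, selected_id = NULL,
                       pattern_strength = 0, gain = c(1, 1, 1),
                       offset = c(0, 0, 0),
                       blend = c("normal", "add", "multiply")) {
  blend <- match.arg(blend)
  clamp01 <- function(v) pmin(1, pmax(0, v))
  structure(list(layer = layer, alpha = clamp01(alpha),
                 sel_alpha = clamp01(sel_alpha %||% alpha),
                 selected_id = selected_id,
                 pattern_strength = clamp01(pattern_strength),
                 gain = gain, offset = offset, blend = blend),
            class = "layer_view")
}

# RGB (w x h x 3 in 0..1) + alpha matrix for one layer's section
.layer_pixels <- function(view, table, z, bbox, level) {
  vol <- view$layer
  arr <- read_region(vol, level, c(bbox[1], bbox[2], z, bbox[3], bbox[4], z + 1L))
  w <- dim(arr)[1]; h <- dim(arr)[2]
  m <- matrix(arr, w, h)
  rgbv <- array(0, dim = c(w, h, 3))
  if (vol$value_kind == "id16") {
    a <- matrix(0, w, h)
    ids <- sort(unique(m[m != 0L]))
    sel_branch <- if (!is.null(view$selected_id) && !is.null(table))
      segment_descendants(table, view$selected_id, include_self = TRUE)
    else integer(0)
    pat_x <- (matrix(seq_len(w) - 1L + bbox[1], w, h)) %% 8L
    pat_y <- (matrix(rep(seq_len(h) - 1L + bbox[2], each = w), w, h)) %% 8L
    for (id in ids) {
      dc <- if (!is.null(table) && id %in% table$id)
        resolve_display_color(table, id)
      else list(color1 = .default_color(id), color2 = .default_color(id, 0.55),
                pattern = 0L)
      bmp <- pattern_bitmap(dc$pattern)
      sel <- m == id
      on <- bmp[cbind(pat_x[sel] + 1L, pat_y[sel] + 1L)]
      mix <- view$pattern_strength * on
      c1 <- unlist(unpack_rgb24(dc$color1)) / 255
      c2 <- unlist(unpack_rgb24(dc$color2)) / 255
      for (ch in 1:3) {
        pl <- rgbv[, , ch]
        pl[sel] <- (1 - mix) * c1[ch] + mix * c2[ch]
        rgbv[, , ch] <- pl
      }
      a[sel] <- if (id %in% sel_branch) view$sel_alpha else view$alpha
    }
  } else {
    if (vol$value_kind == "gray8") {
      for (ch in 1:3) rgbv[, , ch] <- m / 255
    } else {
      ch3 <- unpack_rgb24(m)
      rgbv[, , 1] <- matrix(ch3$r, w, h) / 255
      rgbv[, , 2] <- matrix(ch3$g, w, h) / 255
      rgbv[, , 3] <- matrix(ch3$b, w, h) / 255
    }
    for (ch in 1:3)
      rgbv[, , ch] <- pmin(1, pmax(0, rgbv[, , ch] * view$gain[ch] +
                                     view$offset[ch]))
    a <- matrix(view$alpha, w, h)
  }
  list(rgb = rgbv, alpha = a)
}

#' Composite layers into a 2D section image
#'
#' Bottom-to-top per-pixel compositing of image and segmentation layers.
#' Segmentation pixels are colored through [resolve_display_color()] with
#' the pattern bitmap mixing color1 and color2, and take the view's
#' `sel_alpha` when the segment lies in the selected branch, `alpha`
#' otherwise (so `alpha = 0`, `sel_alpha = 1` shows only the selected
#' branch). Image layers pass through their color filter, then blend
#' (`normal`: `a*src + (1-a)*dst`; `add`; `multiply`).
#'
#' @param layers list of [layer_view()]s, bottom first.
#' @param table a `segment_table` (colors for segmentation layers).
#' @param z section index.
#' @param bbox XY box `c(x0, y0, x1, y1)` at `level` (default: full).
#' @param level mip level.
#' @return numeric array (width, height, 3) in 0..1.
#' @export
composite_section <- function(layers, table = NULL, z, bbox = NULL,
                              level = 0L) {
  stopifnot(length(layers) >= 1L)
  ext <- level_extent(layers[[1]]$layer, level)
  for (lv in layers)
    if (!identical(level_extent(lv$layer, level), ext))
      stop("layers do not share geometry at this level")
  if (is.null(bbox)) bbox <- c(0L, 0L, ext[1], ext[2])
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  out <- array(0, dim = c(w, h, 3))
  for (view in layers) {
    px <- .layer_pixels(view, table, z, bbox, level)
    for (ch in 1:3) {
      s <- px$rgb[, , ch]; a <- px$alpha; dst <- out[, , ch]
      out[, , ch] <- switch(view$blend,
        normal = a * s + (1 - a) * dst,
        add = pmin(1, dst + a * s),
        multiply = dst * ((1 - a) + a * s))
    }
  }
  out
}

#' Projection image along a cardinal axis
#'
#' `max`: per-ray maximum intensity; `first-hit`: color of the first
#' nonzero voxel along the ray; `illuminated`: first-hit color modulated
#' by Lambertian shading computed from the depth-map gradient normal
#' (configurable light direction, ambient term 0.2).
#'
#' @param vol a `chunked_volume`.
#' @param axis `"X"`, `"Y"` or `"Z"` (ray direction; rays run from low to
#'   high index).
#' @param method `"max"`, `"first-hit"` or `"illuminated"`.
#' @param bbox half-open 3D bbox at `level` (default: full volume).
#' @param level mip level.
#' @param table segment table for `id16` colors.
#' @param light light direction (normalized internally).
#' @param ambient ambient light fraction.
#' @return numeric array (u, v, 3) in 0..1.
#' @export
projection_image <- function(vol, axis = c("Z", "Y", "X"),
                             method = c("max", "first-hit", "illuminated"),
                             bbox = NULL, level = 0L, table = NULL,
                             light = c(1, 1, 1) / sqrt(3), ambient = 0.2) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  ext <- level_extent(vol, level)
  if (is.null(bbox)) bbox <- c(0L, 0L, 0L, ext)
  arr <- read_region(vol, level, bbox)
  vs <- vol$voxel_size_nm * c(2^level, 2^level, 1)
  ax <- match(axis, c("X", "Y", "Z"))
  keep <- setdiff(1:3, ax)
  arr <- aperm(arr, c(keep, ax))
  d <- dim(arr)
  uv_vs <- vs[keep]; ray_vs <- vs[ax]
  to_rgb <- function(vals) {
    out <- array(0, dim = c(length(vals), 3))
    if (vol$value_kind == "gray8") out[, 1] <- out[, 2] <- out[, 3] <- vals / 255
    else if (vol$value_kind == "rgb24") {
      ch <- unpack_rgb24(vals)
      out[, 1] <- ch$r / 255; out[, 2] <- ch$g / 255; out[, 3] <- ch$b / 255
    } else {
      for (id in sort(unique(vals[vals != 0]))) {
        colr <- if (!is.null(table) && id %in% table$id)
          resolve_display_color(table, id)$color1 else .default_color(id)
        cc <- unlist(unpack_rgb24(colr)) / 255
        sel <- vals == id
        out[sel, 1] <- cc[1]; out[sel, 2] <- cc[2]; out[sel, 3] <- cc[3]
      }
    }
    out
  }
  img <- array(0, dim = c(d[1], d[2], 3))
  if (method == "max") {
    mx <- apply(arr, c(1, 2), max)
    rgbv <- to_rgb(as.vector(mx))
    for (ch in 1:3) img[, , ch] <- matrix(rgbv[, ch], d[1], d[2])
    return(img)
  }
  hitval <- matrix(0L, d[1], d[2])
  depth <- matrix(NA_real_, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    new <- is.na(depth) & sl != 0L
    hitval[new] <- sl[new]
    depth[new] <- k * ray_vs
  }
  rgbv <- to_rgb(as.vector(hitval))
  for (ch in 1:3) img[, , ch] <- matrix(rgbv[, ch], d[1], d[2])
  if (method == "illuminated") {
    light <- light / sqrt(sum(light^2))
    dfill <- depth
    dfill[is.na(dfill)] <- max(depth, na.rm = TRUE) + ray_vs  # behind everything
    gx <- (rbind(dfill[-1, , drop = FALSE], dfill[d[1], , drop = FALSE]) -
             rbind(dfill[1, , drop = FALSE], dfill[-d[1], , drop = FALSE])) /
      (2 * uv_vs[1])
    gy <- (cbind(dfill[, -1, drop = FALSE], dfill[, d[2], drop = FALSE]) -
             cbind(dfill[, 1, drop = FALSE], dfill[, -d[2], drop = FALSE])) /
      (2 * uv_vs[2])
    nrm <- sqrt(gx^2 + gy^2 + 1)
    lam <- pmax(0, (-gx * light[1] - gy * light[2] + light[3]) / nrm)
    shade <- ambient + (1 - ambient) * lam
    shade[is.na(depth)] <- 1
    for (ch in 1:3) img[, , ch] <- img[, , ch] * shade
  }
  img
}

#' Write an RGB image array as PNG
#'
#' @param img numeric array (width, height, 3) in 0..1.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_image_png <- function(img, path) {
  out <- aperm(img, c(2, 1, 3))     # png expects (row = y, col = x)
  png::writePNG(pmin(1, pmax(0, out)), path)
  invisible(path)
}

#' Particle cloud: prototype meshes at component centroids
#'
#' Finds the 6-connected components of a segment, computes each
#' component's centroid (mean voxel center, nm), and instances a
#' prototype mesh at every centroid (for example a small sphere standing
#' for a vesicle). Also returns the centroid list and the count of
#' separately painted regions.
#'
#' @param vol an `id16` volume.
#' @param id the segment id.
#' @param prototype a `triangle_mesh` centered at the origin (default: a
#'   small octahedron of radius one mean voxel).
#' @param level mip level.
#' @return list with `mesh`, `centroids` (n x 3 nm) and `count`.
#' @export
particle_cloud <- function(vol, id, prototype = NULL, level = 0L) {
  arr <- as_array(vol, level)
  vs <- vol$voxel_size_nm * c(2^level, 2^level, 1)
  lab <- label_components(arr == id)
  k <- max(lab)
  if (is.null(prototype)) prototype <- octahedron_mesh(mean(vs))
  if (k == 0L)
    return(list(mesh = triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                centroids = matrix(0, 0, 3), count = 0L))
  cen <- matrix(0, k, 3)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab))
  for (j in seq_len(k)) {
    cj <- co[lab[idx] == j, , drop = FALSE]
    cen[j, ] <- (colMeans(cj) - 0.5) * vs     # voxel centers at +0.5
  }
  inst <- lapply(seq_len(k), function(j) {
    m <- prototype
    m$vertices <- sweep(m$vertices, 2, cen[j, ], `+`)
    m$group <- rep(sprintf("particle%d", j), length(m$group))
    m
  })
  list(mesh = .cat_meshes(inst), centroids = cen, count = k)
}

#' @rdname particle_cloud
#' @param radius octahedron radius in nm.
#' @export
octahedron_mesh <- function(radius = 1) {
  v <- radius * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))
  tr <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
              c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  triangle_mesh(v, tr, rep("proto", 8))
}

# axis-aligned cuboid between lo and hi (nm), outward orientation
.cuboid_mesh <- function(lo, hi, group = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: x fastest (1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) ...)
  quads <- rbind(c(2, 4, 8, 6),   # +x
                 c(1, 5, 7, 3),   # -x
                 c(3, 7, 8, 4),   # +y
                 c(1, 2, 6, 5),   # -y
                 c(5, 6, 8, 7),   # +z
                 c(1, 3, 4, 2))   # -z
  tr <- do.call(rbind, lapply(seq_len(6), function(i)
    rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
  triangle_mesh(v, tr, rep(group, 12))
}

#' 3D box and scale-bar meshes
#'
#' Boxes mark locations in the dataset: `wireframe` exports the 12 edges
#' as OBJ line elements, `solid` a closed single-color cuboid, and
#' `textured` a cuboid together with images of the six boundary sections
#' of the box sampled from `vol` (returned in `$textures`, keyed
#' `x0,x1,y0,y1,z0,z1`). The scale bar is a cuboid of exactly the
#' requested length.
#'
#' @param bbox_vx half-open voxel bbox (level 0) of the box.
#' @param vol the volume (required for `textured`; supplies voxel size).
#' @param mode `"wireframe"`, `"solid"` or `"textured"`.
#' @param voxel_size_nm voxel size when no volume is given.
#' @return list with `mesh` and (textured only) `textures`.
#' @export
box_mesh <- function(bbox_vx, vol = NULL,
                     mode = c("wireframe", "solid", "textured"),
                     voxel_size_nm = c(1, 1, 1)) {
  mode <- match.arg(mode)
  bbox_vx <- as.integer(bbox_vx)
  if (any(bbox_vx[4:6] <= bbox_vx[1:3])) stop("degenerate box")
  vs <- if (!is.null(vol)) vol$voxel_size_nm else voxel_size_nm
  lo <- bbox_vx[1:3] * vs; hi <- bbox_vx[4:6] * vs
  if (mode == "wireframe") {
    v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                               z = c(lo[3], hi[3])))
    ln <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                c(1, 5), c(2, 6), c(3, 7), c(4, 8))
    return(list(mesh = triangle_mesh(v, matrix(0L, 0, 3), character(0),
                                     lines = ln)))
  }
  m <- .cuboid_mesh(lo, hi)
  if (mode == "solid") return(list(mesh = m))
  if (is.null(vol)) stop("textured boxes need a source volume")
  b <- bbox_vx
  tex <- list(
    x0 = read_region(vol, 0L, c(b[1], b[2], b[3], b[1] + 1L, b[5], b[6])),
    x1 = read_region(vol, 0L, c(b[4] - 1L, b[2], b[3], b[4], b[5], b[6])),
    y0 = read_region(vol, 0L, c(b[1], b[2], b[3], b[4], b[2] + 1L, b[6])),
    y1 = read_region(vol, 0L, c(b[1], b[5] - 1L, b[3], b[4], b[5], b[6])),
    z0 = read_region(vol, 0L, c(b[1], b[2], b[3], b[4], b[5], b[3] + 1L)),
    z1 = read_region(vol, 0L, c(b[1], b[2], b[6] - 1L, b[4], b[5], b[6])))
  list(mesh = m, textures = lapply(tex, drop))
}

#' @rdname box_mesh
#' @param length_nm exact scale-bar length in nm.
#' @param axis axis the bar runs along (1 = X, 2 = Y, 3 = Z).
#' @param thickness_nm bar thickness.
#' @param origin_nm bar origin corner.
#' @export
scalebar_mesh <- function(length_nm, axis = 1L, thickness_nm = length_nm / 10,
                          origin_nm = c(0, 0, 0)) {
  hi <- origin_nm + thickness_nm
  hi[axis] <- origin_nm[axis] + length_nm
  .cuboid_mesh(origin_nm, hi, group = "scalebar")
}
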