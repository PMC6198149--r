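#' JSON volume descriptor for tiled image datasets
#'
#' Describes an image stack stored as per-section (optionally tiled)
#' image files: a filename pattern with `{level}`, `{section}`, `{row}`
#' and `{col}` placeholders, the tile size, the level-0 stack dimensions,
#' the voxel size, the number of mip levels and the value kind. The
#' descriptor serializes to/from a JSON text file.
#'
#' @param name dataset name.
#' @param pattern filename pattern containing all four placeholders.
#' @param tile_size_px integer (width, height) of a tile.
#' @param dims_vx level-0 (X, Y, Z) voxel counts.
#' @param voxel_size_nm voxel size in nm.
#' @param num_levels mip levels available on disk.
#' @param value_kind `"gray8"` or `"rgb24"`.
#' @return a `volume_descriptor` object.
#' @export
volume_descriptor <- function(name, pattern, tile_size_px, dims_vx,
                              voxel_size_nm = c(1, 1, 1), num_levels = 1L,
                              value_kind = "gray8") {
  for (ph in c("{level}", "{section}", "{row}", "{col}"))
    if (!grepl(ph, pattern, fixed = TRUE))
      stop(sprintf("pattern must contain the %s placeholder", ph))
  tile_size_px <- as.integer(tile_size_px)
  dims_vx <- as.integer(dims_vx)
  if (any(tile_size_px < 1L) || any(dims_vx < 1L))
    stop("tile size and dims must be positive")
  structure(list(name = name, pattern = pattern, tile_size_px = tile_size_px,
                 dims_vx = dims_vx, voxel_size_nm = as.numeric(voxel_size_nm),
                 num_levels = as.integer(num_levels),
                 value_kind = value_kind),
            class = "volume_descriptor")
}

#' @rdname volume_descriptor
#' @param desc a `volume_descriptor`.
#' @param path JSON file path.
#' @export
write_descriptor <- function(desc, path) {
  jsonlite::write_json(unclass(desc), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname volume_descriptor
#' @export
read_descriptor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  volume_descriptor(x$name, x$pattern, x$tile_size_px, x$dims_vx,
                    x$voxel_size_nm, x$num_levels, x$value_kind)
}

.fill_pattern <- function(pattern, level, section, row, col) {
  s <- gsub("{level}", level, pattern, fixed = TRUE)
  s <- gsub("{section}", sprintf("%04d", section), s, fixed = TRUE)
  s <- gsub("{row}", sprintf("%03d", row), s, fixed = TRUE)
  gsub("{col}", sprintf("%03d", col), s, fixed = TRUE)
}

# lexicographic-numeric ("natural") filename order
.natural_order <- function(x) {
  b <- basename(x)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", b)))
  order(is.na(num), num, b)
}

# read one image file into an integer matrix (gray8) or packed rgb24
.read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use .png or .tif)", ext)))
  if (length(dim(img)) == 2L) {
    m <- t(round(img * 255))
    storage.mode(m) <- "integer"
    attr(m, "kind") <- "gray8"
    return(m)
  }
  nc <- dim(img)[3]
  r <- t(round(img[, , 1] * 255)); g <- t(round(img[, , 2] * 255))
  b <- t(round(img[, , 3] * 255))
  m <- rgb24(r, g, b)
  dim(m) <- dim(r)
  attr(m, "kind") <- if (nc >= 3) "rgb24" else "gray8"
  m
}

# write an integer matrix (x, y) as an image file; kind gray8 or rgb24
.write_image_file <- function(m, path, kind) {
  ext <- tolower(tools::file_ext(path))
  if (kind == "gray8") img <- t(m) / 255
  else {
    ch <- unpack_rgb24(m)
    img <- array(0, dim = c(ncol(m), nrow(m), 3))
    img[, , 1] <- t(matrix(ch$r, nrow(m))) / 255
    img[, , 2] <- t(matrix(ch$g, nrow(m))) / 255
    img[, , 3] <- t(matrix(ch$b, nrow(m))) / 255
  }
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, compression = "deflate"),
    raw = {
      if (kind == "gray8") writeBin(as.raw(as.vector(m)), path)
      else {
        ch <- unpack_rgb24(as.vector(m))
        writeBin(as.raw(as.vector(rbind(ch$r, ch$g, ch$b))), path)
      }
    },
    stop(sprintf("unsupported export format '.%s' (use .png, .tif or .raw)", ext)))
  invisible(path)
}

#' Import an image stack into a chunked volume
#'
#' `x` is either a directory of per-section PNG/TIFF images (loaded in
#' lexicographic-numeric order) or a [volume_descriptor()] (or path to
#' its JSON file) describing a tiled layout, in which case the level-0
#' tiles are assembled. Level-0 voxels equal the source pixels; mip
#' levels are recomputed by 2x2 XY reduction. Mixed gray/RGB sections and
#' missing tiles are errors.
#'
#' @param x directory path, descriptor object, or descriptor JSON path.
#' @param voxel_size_nm voxel size (directory import; descriptors carry
#'   their own).
#' @param num_levels mip levels to compute (directory import).
#' @return a `chunked_volume` (`gray8` or `rgb24`).
#' @export
import_image_stack <- function(x, voxel_size_nm = c(1, 1, 1),
                               num_levels = 1L) {
  if (is.character(x) && dir.exists(x)) {
    files <- list.files(x, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop(sprintf("no section images found in %s", x))
    files <- files[.natural_order(files)]
    secs <- lapply(files, .read_image_file)
    kinds <- vapply(secs, attr, "", "kind")
    if (length(unique(kinds)) != 1L)
      stop("mixed bit depths: stack contains both gray and RGB sections")
    dms <- vapply(secs, dim, integer(2))
    if (any(dms[1, ] != dms[1, 1]) || any(dms[2, ] != dms[2, 1]))
      stop("inconsistent section dimensions across the stack")
    arr <- array(0L, dim = c(dms[1, 1], dms[2, 1], length(secs)))
    for (z in seq_along(secs)) arr[, , z] <- secs[[z]]
    return(volume_from_array(arr, voxel_size_nm, kinds[1], num_levels))
  }
  desc <- if (inherits(x, "volume_descriptor")) x else read_descriptor(x)
  d <- desc$dims_vx
  ts <- desc$tile_size_px
  arr <- array(0L, dim = d)
  nrows <- ceiling(d[2] / ts[2]); ncols <- ceiling(d[1] / ts[1])
  base <- attr(desc, "dir") %||% "."
  for (z in seq_len(d[3]) - 1L) for (r in seq_len(nrows) - 1L)
    for (cc in seq_len(ncols) - 1L) {
      f <- file.path(base, .fill_pattern(desc$pattern, 0L, z, r, cc))
      if (!file.exists(f)) stop(sprintf("missing tile: %s", f))
      m <- .read_image_file(f)
      if (attr(m, "kind") != desc$value_kind)
        stop(sprintf("tile %s has kind %s, descriptor says %s",
                     f, attr(m, "kind"), desc$value_kind))
      xs <- (cc * ts[1] + 1L):min(d[1], (cc + 1L) * ts[1])
      ys <- (r * ts[2] + 1L):min(d[2], (r + 1L) * ts[2])
      arr[xs, ys, z + 1L] <- m[seq_along(xs), seq_along(ys)]
    }
  volume_from_array(arr, desc$voxel_size_nm, desc$value_kind,
                    desc$num_levels)
}

#' Export a volume region as an image stack
#'
#' Writes one image per section, or a row/column-indexed tile mosaic when
#' `tile_size` is given. Partial edge tiles are padded with 0 and flagged
#' in the sidecar `manifest.json` (which also records the geometry so RAW
#' exports are self-describing). Lossless formats only: `png`, `tif`,
#' `raw`.
#'
#' @param vol a `chunked_volume` (`gray8` or `rgb24`).
#' @param dir output directory (created).
#' @param level mip level to export.
#' @param bbox half-open bbox at that level (default: whole level).
#' @param fmt `"png"`, `"tif"` or `"raw"`.
#' @param tile_size optional integer (width, height) for tiled export.
#' @param prefix filename prefix.
#' @return (invisibly) character vector of files written.
#' @export
export_image_stack <- function(vol, dir, level = 0L, bbox = NULL,
                               fmt = "png", tile_size = NULL,
                               prefix = "sec") {
  if (!fmt %in% c("png", "tif", "raw"))
    stop(sprintf("unsupported format '%s' (use png, tif or raw)", fmt))
  ext <- level_extent(vol, level)
  if (is.null(bbox)) bbox <- c(0L, 0L, 0L, ext)
  bbox <- .check_bbox(bbox, ext)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- read_region(vol, level, bbox)
  d <- dim(arr)
  files <- character(0); padded <- list()
  for (z in seq_len(d[3])) {
    sec <- arr[, , z, drop = TRUE]
    dim(sec) <- d[1:2]
    if (is.null(tile_size)) {
      f <- file.path(dir, sprintf("%s_%04d.%s", prefix, z - 1L + bbox[3], fmt))
      .write_image_file(sec, f, vol$value_kind)
      files <- c(files, f)
    } else {
      ts <- as.integer(tile_size)
      nr <- ceiling(d[2] / ts[2]); nc <- ceiling(d[1] / ts[1])
      for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
        tile <- matrix(0L, ts[1], ts[2])
        xs <- (cc * ts[1] + 1L):min(d[1], (cc + 1L) * ts[1])
        ys <- (r * ts[2] + 1L):min(d[2], (r + 1L) * ts[2])
        tile[seq_along(xs), seq_along(ys)] <- sec[xs, ys]
        f <- file.path(dir, sprintf("%s_%04d_r%03d_c%03d.%s", prefix,
                                    z - 1L + bbox[3], r, cc, fmt))
        .write_image_file(tile, f, vol$value_kind)
        files <- c(files, f)
        if (length(xs) < ts[1] || length(ys) < ts[2])
          padded[[length(padded) + 1L]] <- basename(f)
      }
    }
  }
  manifest <- list(value_kind = vol$value_kind, level = level, bbox = bbox,
                   voxel_size_nm = vol$voxel_size_nm, format = fmt,
                   tile_size = tile_size,
                   padded_tiles = unlist(padded) %||% character(0))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Export / import segmentation ids as RGB image stacks
#'
#' Segment ids are encoded into the image color channels: green carries
#' the high byte (`id %/% 256`), blue the low byte (`id %% 256`), red is
#' reserved as 0. `import_id_images()` decodes such a stack and writes it
#' onto `target` (or a fresh volume) under the merge precedence rule:
#' `"source"` overwrites nonzero target voxels, `"target"` only writes
#' where the target is empty. A nonzero red channel on import triggers a
#' warning and is ignored.
#'
#' @param vol an `id16` volume.
#' @param dir output/input directory.
#' @param level,bbox region exported.
#' @param prefix filename prefix.
#' @return `export_id_images()` the files written (invisibly);
#'   `import_id_images()` the merged `id16` volume.
#' @export
export_id_images <- function(vol, dir, level = 0L, bbox = NULL,
                             prefix = "ids") {
  stopifnot(vol$value_kind == "id16")
  ext <- level_extent(vol, level)
  if (is.null(bbox)) bbox <- c(0L, 0L, 0L, ext)
  bbox <- .check_bbox(bbox, ext)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- read_region(vol, level, bbox)
  d <- dim(arr)
  files <- character(0)
  for (z in seq_len(d[3])) {
    sec <- arr[, , z]
    enc <- rgb24(0L, sec %/% 256L, sec %% 256L)
    dim(enc) <- d[1:2]
    f <- file.path(dir, sprintf("%s_%04d.png", prefix, z - 1L + bbox[3]))
    .write_image_file(enc, f, "rgb24")
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname export_id_images
#' @param target optional existing `id16` volume merged into.
#' @param precedence `"source"` or `"target"`.
#' @param voxel_size_nm,num_levels geometry when no target is given.
#' @export
import_id_images <- function(dir, target = NULL,
                             precedence = c("source", "target"),
                             voxel_size_nm = c(1, 1, 1), num_levels = 1L) {
  precedence <- match.arg(precedence)
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop(sprintf("no id images found in %s", dir))
  files <- files[.natural_order(files)]
  secs <- lapply(files, .read_image_file)
  dms <- vapply(secs, dim, integer(2))
  arr <- array(0L, dim = c(dms[1, 1], dms[2, 1], length(secs)))
  red_seen <- FALSE
  for (z in seq_along(secs)) {
    ch <- unpack_rgb24(secs[[z]])
    if (any(ch$r != 0L)) red_seen <- TRUE
    arr[, , z] <- ch$g * 256L + ch$b
  }
  if (red_seen)
    warning("nonzero red channel in id images; red is reserved and was ignored")
  if (is.null(target))
    return(volume_from_array(arr, voxel_size_nm, "id16", num_levels))
  stopifnot(target$value_kind == "id16")
  d <- dim(arr)
  cur <- read_region(target, 0L, c(0L, 0L, 0L, d))
  hit <- arr != 0L
  if (precedence == "source") cur[hit] <- arr[hit]
  else { wr <- hit & cur == 0L; cur[wr] <- arr[wr] }
  write_region(target, 0L, c(0L, 0L, 0L, d), cur)
  target
}
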