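#' Segment metadata tables
#'
#' A `segment_table` is a data.frame with one row per segment: `id`
#' (1..65535), `parent_id` (0 = root), `label`, two packed 24-bit RGB
#' colors `color1`/`color2` plus a `pattern` index 0..15, an optional
#' anchor voxel (`anchor_x/y/z`, NA when unset), an optional half-open
#' level-0 bounding box (`bbox_x0..bbox_z1`, NA when empty) and a
#' `collapsed` flag (meaningful for folder nodes). Parent links form a
#' rooted tree; folders are ordinary segments that happen to have
#' children, so they are selectable and colorable like any object.
#'
#' @return `segment_table()` returns an empty table.
#' @export
segment_table <- function() {
  structure(
    data.frame(id = integer(), parent_id = integer(), label = character(),
               color1 = integer(), color2 = integer(), pattern = integer(),
               anchor_x = integer(), anchor_y = integer(), anchor_z = integer(),
               bbox_x0 = integer(), bbox_y0 = integer(), bbox_z0 = integer(),
               bbox_x1 = integer(), bbox_y1 = integer(), bbox_z1 = integer(),
               collapsed = logical(), stringsAsFactors = FALSE),
    class = c("segment_table", "data.frame"))
}

# deterministic default coloring: golden-angle hue walk over ids
.default_color <- function(id, v = 1) {
  h <- (id * 0.6180339887) %% 1
  m <- grDevices::col2rgb(grDevices::hsv(h, 0.75, v))
  rgb24(m[1, ], m[2, ], m[3, ])
}

#' Add a segment to a table
#'
#' @param table a `segment_table`.
#' @param id segment id (1..65535); default: lowest free id.
#' @param parent_id parent segment id (0 = root folder).
#' @param label label text.
#' @param color1,color2 packed 24-bit colors (see [rgb24()]); defaults are
#'   deterministic per-id hues.
#' @param pattern pattern index 0..15.
#' @param anchor optional (x, y, z) anchor voxel.
#' @param collapsed collapse flag for folder display.
#' @return the updated table.
#' @export
add_segment <- function(table, id = NULL, parent_id = 0L, label = "",
                        color1 = NULL, color2 = NULL, pattern = 0L,
                        anchor = NULL, collapsed = FALSE) {
  stopifnot(inherits(table, "segment_table"))
  if (is.null(id)) id <- setdiff(seq_len(MAX_SEG_ID), table$id)[1L]
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > MAX_SEG_ID)
    stop("segment ids must lie in 1..65535")
  if (id %in% table$id) stop(sprintf("segment id %d already exists", id))
  parent_id <- as.integer(parent_id)
  if (parent_id != 0L && !(parent_id %in% table$id))
    stop(sprintf("parent id %d does not exist", parent_id))
  if (pattern < 0L || pattern > 15L) stop("pattern must lie in 0..15")
  if (is.null(color1)) color1 <- .default_color(id)
  if (is.null(color2)) color2 <- .default_color(id, v = 0.55)
  anchor <- if (is.null(anchor)) rep(NA_integer_, 3) else as.integer(anchor)
  row <- data.frame(id = id, parent_id = parent_id, label = as.character(label),
                    color1 = as.integer(color1), color2 = as.integer(color2),
                    pattern = as.integer(pattern),
                    anchor_x = anchor[1], anchor_y = anchor[2], anchor_z = anchor[3],
                    bbox_x0 = NA_integer_, bbox_y0 = NA_integer_, bbox_z0 = NA_integer_,
                    bbox_x1 = NA_integer_, bbox_y1 = NA_integer_, bbox_z1 = NA_integer_,
                    collapsed = isTRUE(collapsed), stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(table), row)
  class(out) <- c("segment_table", "data.frame")
  out
}

.seg_row <- function(table, id) {
  i <- match(id, table$id)
  if (is.na(i)) stop(sprintf("unknown segment id %s", id))
  i
}

# ids of all strict descendants of `id` (id = 0 means everything)
segment_descendants <- function(table, id, include_self = FALSE) {
  kids <- table$id[table$parent_id == id]
  out <- integer(0)
  for (k in kids) out <- c(out, k, segment_descendants(table, k))
  if (include_self && id != 0L) out <- c(id, out)
  out
}

# root path of a segment: ids from the root-most ancestor down to the parent
.root_path <- function(table, id) {
  path <- integer(0)
  p <- table$parent_id[.seg_row(table, id)]
  while (p != 0L) {
    path <- c(p, path)
    p <- table$parent_id[.seg_row(table, p)]
  }
  path
}

#' Display color under folder collapsing
#'
#' A segment inside a collapsed folder is shown in that folder's colors;
#' with nested collapsed folders the outermost collapsed ancestor on the
#' path from the root wins. A collapsed segment itself still shows its own
#' colors (collapsing affects its contents, not the folder node).
#'
#' @param table a `segment_table`.
#' @param id segment id.
#' @return list with `color1`, `color2`, `pattern` (and `source_id`, the
#'   id whose colors are used).
#' @export
resolve_display_color <- function(table, id) {
  id <- as.integer(id)
  i <- .seg_row(table, id)
  src <- id
  for (a in .root_path(table, id)) {           # root-most first
    if (table$collapsed[.seg_row(table, a)]) { src <- a; break }
  }
  j <- .seg_row(table, src)
  list(color1 = table$color1[j], color2 = table$color2[j],
       pattern = table$pattern[j], source_id = src)
}

#' Pack two 24-bit colors and a pattern into a 52-bit key
#'
#' Combining two 24-bit RGB colors with one of 16 patterns yields a color
#' space of almost 52 bits; the key is
#' `(color1 * 2^24 + color2) * 16 + pattern`, injective and below `2^52`
#' (exactly representable in a double).
#'
#' @param color1,color2 packed 24-bit colors.
#' @param pattern pattern index 0..15.
#' @param key a key from `encode_color_key()`.
#' @return a numeric key / a list with `color1`, `color2`, `pattern`.
#' @export
encode_color_key <- function(color1, color2, pattern) {
  color1 <- as.numeric(color1); color2 <- as.numeric(color2)
  pattern <- as.numeric(pattern)
  if (any(color1 < 0 | color1 > 16777215) || any(color2 < 0 | color2 > 16777215))
    stop("colors must be packed 24-bit values (0..16777215)")
  if (any(pattern < 0 | pattern > 15)) stop("pattern must lie in 0..15")
  (color1 * 2^24 + color2) * 16 + pattern
}

#' @rdname encode_color_key
#' @export
decode_color_key <- function(key) {
  key <- as.numeric(key)
  if (any(key < 0 | key >= 2^52)) stop("key must lie in [0, 2^52)")
  pattern <- key %% 16
  rest <- (key - pattern) / 16
  color2 <- rest %% 2^24
  list(color1 = as.integer((rest - color2) / 2^24),
       color2 = as.integer(color2), pattern = as.integer(pattern))
}

#' Collect (translocate) a segment into a folder
#'
#' Reparents `id` under `dest_folder_id`; voxels are untouched. Moves that
#' would create a cycle (a folder into its own subtree) are rejected.
#'
#' @param table a `segment_table`.
#' @param id segment to move.
#' @param dest_folder_id destination folder id (0 = root).
#' @return the updated table.
#' @export
collect <- function(table, id, dest_folder_id) {
  i <- .seg_row(table, id)
  dest_folder_id <- as.integer(dest_folder_id)
  if (dest_folder_id != 0L) .seg_row(table, dest_folder_id)
  if (dest_folder_id == id ||
      dest_folder_id %in% segment_descendants(table, id))
    stop("cannot collect a segment into its own subtree")
  table$parent_id[i] <- dest_folder_id
  table
}

# apply an id -> id map to every voxel of a segmentation volume, then
# re-reduce coarser mip data over the touched footprints (label majority
# voting does not commute with relabeling, so coarse chunks are rebuilt
# from the mapped finer data)
relabel_voxels <- function(vol, map) {
  stopifnot(vol$value_kind == "id16")
  old_ids <- as.integer(names(map))
  map <- as.integer(map)
  touched <- list()
  for (key in ls(vol$chunks)) {
    ch <- get(key, envir = vol$chunks, inherits = FALSE)
    hit <- ch$m & ch$v %in% old_ids
    if (!any(hit)) next
    ch$v[hit] <- map[match(ch$v[hit], old_ids)]
    assign(key, ch, envir = vol$chunks)
    touched[[length(touched) + 1L]] <-
      as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
  }
  keys <- character(0)
  if (length(touched)) {
    lv <- vapply(touched, `[`, integer(1), 1L)
    for (tc in touched[order(lv)]) {            # finest first
      L <- tc[1]; cc <- tc[2:4]
      ext <- level_extent(vol, L)
      b <- c(cc * CHUNK_EDGE, pmin((cc + 1L) * CHUNK_EDGE, ext))
      keys <- c(keys, .chunk_key(L, cc[1], cc[2], cc[3]))
      if (L + 1L < vol$num_levels) for (M in L:(vol$num_levels - 2L)) {
        reduce_to_coarser(vol, M, b)
        extC <- level_extent(vol, M + 1L)
        b <- c(b[1] %/% 2L, b[2] %/% 2L, b[3],
               min(extC[1], as.integer(ceiling(b[4] / 2))),
               min(extC[2], as.integer(ceiling(b[5] / 2))), b[6])
        keys <- c(keys, .chunk_keys_in(M + 1L, b))
      }
    }
  }
  .prune_keys(vol, unique(keys))
  invisible(vol)
}

#' Weld all segments of a folder into one
#'
#' Relabels the voxels of every strict descendant of `folder_id` to the
#' lowest descendant id (the survivor), removes the other descendant
#' records, and sets the survivor's bounding box to the union of the
#' members' boxes. Total labeled voxel count is unchanged.
#'
#' @param table a `segment_table`.
#' @param vol the `id16` volume holding the voxels.
#' @param folder_id folder whose contents are welded.
#' @return list with `table` (updated) and `survivor` (the surviving id).
#' @export
weld <- function(table, vol, folder_id) {
  .seg_row(table, folder_id)
  members <- segment_descendants(table, folder_id)
  if (length(members) == 0L) stop("folder has no descendant segments to weld")
  survivor <- min(members)
  gone <- setdiff(members, survivor)
  if (length(gone)) {
    relabel_voxels(vol, stats::setNames(rep(survivor, length(gone)), gone))
    rows <- table$id %in% members
    bb <- table[rows, c("bbox_x0", "bbox_y0", "bbox_z0",
                        "bbox_x1", "bbox_y1", "bbox_z1")]
    i <- .seg_row(table, survivor)
    if (any(!is.na(bb$bbox_x0))) {
      table$bbox_x0[i] <- min(bb$bbox_x0, na.rm = TRUE)
      table$bbox_y0[i] <- min(bb$bbox_y0, na.rm = TRUE)
      table$bbox_z0[i] <- min(bb$bbox_z0, na.rm = TRUE)
      table$bbox_x1[i] <- max(bb$bbox_x1, na.rm = TRUE)
      table$bbox_y1[i] <- max(bb$bbox_y1, na.rm = TRUE)
      table$bbox_z1[i] <- max(bb$bbox_z1, na.rm = TRUE)
    }
    # children of removed members are adopted by the survivor
    table$parent_id[table$parent_id %in% gone] <- survivor
    table <- table[!(table$id %in% gone), , drop = FALSE]
  }
  list(table = table, survivor = survivor)
}

#' Delete a segment and its whole subtree
#'
#' Sets every voxel of the subtree's ids to 0 and removes the records;
#' the freed ids may be reused afterwards.
#'
#' @param table a `segment_table`.
#' @param vol the `id16` volume (or NULL to edit metadata only).
#' @param id subtree root (the root folder 0 cannot be deleted).
#' @return the updated table.
#' @export
delete_subtree <- function(table, vol, id) {
  id <- as.integer(id)
  if (id == 0L) stop("the root folder cannot be deleted")
  .seg_row(table, id)
  ids <- segment_descendants(table, id, include_self = TRUE)
  if (!is.null(vol))
    relabel_voxels(vol, stats::setNames(rep(0L, length(ids)), ids))
  out <- table[!(table$id %in% ids), , drop = FALSE]
  class(out) <- c("segment_table", "data.frame")
  out
}

# tight level-0 bounding box of all allocated data (half-open), or NULL
.painted_bbox <- function(vol) {
  df <- allocated_chunks(vol)
  if (nrow(df) == 0L) return(NULL)
  f <- 2^df$level
  ext <- vol$dims_vx
  x0 <- min(df$cx * CHUNK_EDGE * f); x1 <- max((df$cx + 1) * CHUNK_EDGE * f)
  y0 <- min(df$cy * CHUNK_EDGE * f); y1 <- max((df$cy + 1) * CHUNK_EDGE * f)
  z0 <- min(df$cz * CHUNK_EDGE); z1 <- max((df$cz + 1) * CHUNK_EDGE)
  as.integer(c(max(0, x0), max(0, y0), max(0, z0),
               min(ext[1], x1), min(ext[2], y1), min(ext[3], z1)))
}

#' Recompute anchors and bounding boxes from the voxels
#'
#' Sets each segment's bounding box to the tight half-open box over its
#' level-0 voxels (empty box -> NA). Anchors that are unset default to the
#' segment's first voxel in scan order (x fastest, then y, then z); anchors
#' already set are never moved.
#'
#' @param table a `segment_table`.
#' @param vol the `id16` volume.
#' @return the updated table.
#' @export
recompute_extents <- function(table, vol) {
  bb <- .painted_bbox(vol)
  bcols <- c("bbox_x0", "bbox_y0", "bbox_z0", "bbox_x1", "bbox_y1", "bbox_z1")
  table[, bcols] <- NA_integer_
  if (is.null(bb)) return(table)
  arr <- read_region(vol, 0L, bb)
  idx <- which(arr != 0L)
  if (length(idx) == 0L) return(table)
  co <- arrayInd(idx, dim(arr))
  vals <- arr[idx]
  for (id in sort(unique(vals))) {
    i <- match(id, table$id)
    if (is.na(i)) next
    sel <- vals == id
    cs <- co[sel, , drop = FALSE]
    table$bbox_x0[i] <- min(cs[, 1]) - 1L + bb[1]
    table$bbox_y0[i] <- min(cs[, 2]) - 1L + bb[2]
    table$bbox_z0[i] <- min(cs[, 3]) - 1L + bb[3]
    table$bbox_x1[i] <- max(cs[, 1]) + bb[1]
    table$bbox_y1[i] <- max(cs[, 2]) + bb[2]
    table$bbox_z1[i] <- max(cs[, 3]) + bb[3]
    if (is.na(table$anchor_x[i])) {
      first <- cs[which.min(idx[sel]), ]
      table$anchor_x[i] <- first[1] - 1L + bb[1]
      table$anchor_y[i] <- first[2] - 1L + bb[2]
      table$anchor_z[i] <- first[3] - 1L + bb[3]
    }
  }
  table
}

#' Find segments by id or label substring
#'
#' @param table a `segment_table`.
#' @param query an id (numeric) or a label substring (character).
#' @return the matching rows.
#' @export
find_segments <- function(table, query) {
  if (is.numeric(query)) table[table$id %in% as.integer(query), , drop = FALSE]
  else table[grepl(query, table$label, fixed = TRUE), , drop = FALSE]
}

# structural validity: unique ids, existing parents, acyclic
.validate_table <- function(table) {
  if (anyDuplicated(table$id)) stop("duplicate segment ids")
  bad <- setdiff(setdiff(table$parent_id, 0L), table$id)
  if (length(bad)) stop(sprintf("dangling parent id(s): %s",
                                paste(bad, collapse = ", ")))
  for (id in table$id) {
    seen <- integer(0); p <- table$parent_id[match(id, table$id)]
    while (p != 0L) {
      if (p %in% seen || p == id) stop("segment hierarchy contains a cycle")
      seen <- c(seen, p)
      p <- table$parent_id[match(p, table$id)]
    }
  }
  invisible(table)
}
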