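#' Sparse chunked multiresolution voxel volumes
#'
#' A `chunked_volume` stores voxel data in 16x16x16-voxel chunks allocated
#' on demand, with a pyramid of XY-only powers-of-two mipmap levels
#' (level 0 is full resolution; level L halves X and Y, Z is never
#' resampled because serial sections are anisotropic). Unallocated chunks
#' read as the background value 0 everywhere. Three value kinds are
#' supported: `gray8` (0..255), `rgb24` (packed 24-bit 0..16777215) and
#' `id16` (segment ids 0..65535).
#'
#' Cross-level semantics follow an authoritative-write rule: a write at
#' level L deletes explicit finer-level data under its footprint and
#' re-reduces every coarser level over it, so the finest explicit level at
#' any location is authoritative and reads at finer levels inherit by 2x2
#' XY replication from the nearest coarser explicit level.
#'
#' @param dims_vx integer (X, Y, Z) voxel counts at level 0.
#' @param voxel_size_nm numeric (sx, sy, sz) voxel edge lengths in nm.
#' @param value_kind one of `"gray8"`, `"rgb24"`, `"id16"`.
#' @param num_levels number of mip levels (>= 1); level `num_levels - 1`
#'   must still have at least one voxel in X or Y, i.e.
#'   `2^(num_levels - 1) <= max(X, Y)`.
#' @return an object of class `chunked_volume`.
#' @examples
#' v <- create_volume(c(32, 32, 4), c(6, 6, 30), "id16", num_levels = 2)
#' level_extent(v, 1)   # 16 16 4
#' @export
create_volume <- function(dims_vx, voxel_size_nm = c(1, 1, 1),
                          value_kind = c("gray8", "rgb24", "id16"),
                          num_levels = 1L) {
  value_kind <- match.arg(value_kind)
  dims_vx <- as.integer(dims_vx)
  if (length(dims_vx) != 3L || anyNA(dims_vx) || any(dims_vx < 1L))
    stop("dims_vx must be three positive voxel counts (X, Y, Z)")
  voxel_size_nm <- as.numeric(voxel_size_nm)
  if (length(voxel_size_nm) != 3L || any(!is.finite(voxel_size_nm)) ||
      any(voxel_size_nm <= 0))
    stop("voxel_size_nm must be three positive lengths")
  num_levels <- as.integer(num_levels)
  if (is.na(num_levels) || num_levels < 1L)
    stop("num_levels must be a positive integer")
  if (2^(num_levels - 1L) > max(dims_vx[1:2]))
    stop("too many mip levels for these XY dimensions: need 2^(num_levels-1) <= max(X, Y)")
  vol <- new.env(parent = emptyenv())
  vol$dims_vx <- dims_vx
  vol$voxel_size_nm <- voxel_size_nm
  vol$value_kind <- value_kind
  vol$num_levels <- num_levels
  vol$chunks <- new.env(hash = TRUE, parent = emptyenv())
  class(vol) <- "chunked_volume"
  vol
}

#' @export
print.chunked_volume <- function(x, ...) {
  cat(sprintf("<chunked_volume %s  %d x %d x %d vx  voxel %g x %g x %g nm  %d level(s)  %d chunk(s)>\n",
              x$value_kind, x$dims_vx[1], x$dims_vx[2], x$dims_vx[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3],
              x$num_levels, n_allocated_chunks(x)))
  invisible(x)
}

#' Voxel extent of a mip level
#'
#' X and Y are halved (rounded up) per level; Z is unchanged.
#'
#' @param vol a `chunked_volume`.
#' @param level mip level (0-based).
#' @return integer (X, Y, Z) extent at that level.
#' @export
level_extent <- function(vol, level) {
  .check_level(vol, level)
  ext <- vol$dims_vx
  c(as.integer(ceiling(ext[1] / 2^level)),
    as.integer(ceiling(ext[2] / 2^level)),
    ext[3])
}

.check_level <- function(vol, level) {
  if (length(level) != 1L || is.na(level) || level < 0 ||
      level >= vol$num_levels)
    stop(sprintf("unknown mip level %s (volume has levels 0..%d)",
                 paste(level, collapse = ","), vol$num_levels - 1L))
  invisible(as.integer(level))
}

.check_bbox <- function(bbox, ext) {
  bbox <- as.integer(bbox)
  if (length(bbox) != 6L || anyNA(bbox))
    stop("bbox must be c(x0, y0, z0, x1, y1, z1), half-open, 0-based")
  if (any(bbox[4:6] <= bbox[1:3]))
    stop("bbox is empty (x1 > x0, y1 > y0, z1 > z0 required)")
  if (any(bbox[1:3] < 0L) || any(bbox[4:6] > ext))
    stop(sprintf("bbox [%s) outside level extent (%s)",
                 paste(bbox, collapse = ","), paste(ext, collapse = ",")))
  bbox
}

.kind_max <- function(value_kind) {
  switch(value_kind, gray8 = 255L, id16 = MAX_SEG_ID, rgb24 = 16777215L)
}

.check_values <- function(values, value_kind) {
  if (anyNA(values)) stop("values must not contain NA")
  mx <- .kind_max(value_kind)
  if (any(values < 0L) || any(values > mx)) {
    if (value_kind == "id16")
      stop("segmentation voxels are limited to 16-bit values per voxel (65535 segments maximally)")
    stop(sprintf("values out of range for %s (0..%d)", value_kind, mx))
  }
  invisible(values)
}

.chunk_key <- function(level, cx, cy, cz) {
  paste(level, cx, cy, cz, sep = "|")
}

# chunk coordinates of allocated chunks intersecting bbox at `level`
.chunks_overlapping <- function(vol, level, bbox) {
  c0 <- bbox[1:3] %/% CHUNK_EDGE
  c1 <- (bbox[4:6] - 1L) %/% CHUNK_EDGE
  ngrid <- prod(c1 - c0 + 1)
  keys <- ls(vol$chunks)
  if (ngrid > length(keys)) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    out <- list()
    for (p in parts) {
      pc <- as.integer(p)
      if (pc[1] == level && all(pc[2:4] >= c0) && all(pc[2:4] <= c1))
        out[[length(out) + 1L]] <- pc[2:4]
    }
    return(out)
  }
  out <- list()
  for (cz in c0[3]:c1[3]) for (cy in c0[2]:c1[2]) for (cx in c0[1]:c1[1]) {
    if (exists(.chunk_key(level, cx, cy, cz), envir = vol$chunks,
               inherits = FALSE))
      out[[length(out) + 1L]] <- c(cx, cy, cz)
  }
  out
}

#' List allocated chunks
#'
#' @param vol a `chunked_volume`.
#' @param level optional mip level filter.
#' @return data.frame with columns `level`, `cx`, `cy`, `cz`.
#' @export
allocated_chunks <- function(vol, level = NULL) {
  keys <- ls(vol$chunks)
  if (length(keys) == 0L)
    return(data.frame(level = integer(), cx = integer(), cy = integer(),
                      cz = integer()))
  m <- do.call(rbind, lapply(strsplit(keys, "|", fixed = TRUE), as.integer))
  df <- data.frame(level = m[, 1], cx = m[, 2], cy = m[, 3], cz = m[, 4])
  if (!is.null(level)) df <- df[df$level == level, , drop = FALSE]
  df[order(df$level, df$cz, df$cy, df$cx), , drop = FALSE]
}

#' @rdname allocated_chunks
#' @export
n_allocated_chunks <- function(vol, level = NULL) {
  if (is.null(level)) length(ls(vol$chunks)) else nrow(allocated_chunks(vol, level))
}

#' Read a dense block of voxels
#'
#' Returns the effective values over a half-open box at a mip level:
#' explicit data at the requested level where present, otherwise inherited
#' by 2x2 XY replication from the nearest coarser explicit level, otherwise
#' the background value 0. Reading never allocates chunks.
#'
#' @param vol a `chunked_volume`.
#' @param level mip level.
#' @param bbox integer `c(x0, y0, z0, x1, y1, z1)` half-open, 0-based, within
#'   the level extent.
#' @return integer array of dim `c(x1-x0, y1-y0, z1-z0)`.
#' @export
read_region <- function(vol, level, bbox) {
  level <- .check_level(vol, level)
  ext <- level_extent(vol, level)
  bbox <- .check_bbox(bbox, ext)
  d <- bbox[4:6] - bbox[1:3]
  out <- array(0L, dim = d)
  if (length(ls(vol$chunks)) == 0L) return(out)
  for (M in seq(vol$num_levels - 1L, level)) {
    f <- as.integer(2^(M - level))
    bM <- c(bbox[1] %/% f, bbox[2] %/% f, bbox[3],
            as.integer(ceiling(bbox[4] / f)), as.integer(ceiling(bbox[5] / f)),
            bbox[6])
    for (cc in .chunks_overlapping(vol, M, bM)) {
      ch <- get(.chunk_key(M, cc[1], cc[2], cc[3]), envir = vol$chunks,
                inherits = FALSE)
      m0 <- pmax(bM[1:3], cc * CHUNK_EDGE)
      m1 <- pmin(bM[4:6], (cc + 1L) * CHUNK_EDGE)
      lx <- max(bbox[1], m0[1] * f):(min(bbox[4], m1[1] * f) - 1L)
      ly <- max(bbox[2], m0[2] * f):(min(bbox[5], m1[2] * f) - 1L)
      lz <- m0[3]:(m1[3] - 1L)
      sx <- (lx %/% f) - cc[1] * CHUNK_EDGE + 1L
      sy <- (ly %/% f) - cc[2] * CHUNK_EDGE + 1L
      sz <- lz - cc[3] * CHUNK_EDGE + 1L
      dx <- lx - bbox[1] + 1L; dy <- ly - bbox[2] + 1L; dz <- lz - bbox[3] + 1L
      cur <- out[dx, dy, dz, drop = FALSE]
      ov <- ch$v[sx, sy, sz, drop = FALSE]
      om <- ch$m[sx, sy, sz, drop = FALSE]
      cur[om] <- ov[om]                    # only explicit voxels override
      out[dx, dy, dz] <- cur
    }
  }
  out
}

# set explicit voxel data at one level, no cross-level propagation.
# Chunks carry a per-voxel explicitness mask ($m) next to the values
# ($v): only written voxels become authoritative, so untouched voxels in
# a partially covered chunk keep inheriting from coarser levels even when
# those change later. Returns the touched chunk keys.
.set_explicit <- function(vol, level, bbox, values) {
  c0 <- bbox[1:3] %/% CHUNK_EDGE
  c1 <- (bbox[4:6] - 1L) %/% CHUNK_EDGE
  touched <- character(0)
  for (cz in c0[3]:c1[3]) for (cy in c0[2]:c1[2]) for (cx in c0[1]:c1[1]) {
    cc <- c(cx, cy, cz)
    key <- .chunk_key(level, cx, cy, cz)
    ch <- if (exists(key, envir = vol$chunks, inherits = FALSE))
      get(key, envir = vol$chunks, inherits = FALSE)
    else list(v = array(0L, dim = rep(CHUNK_EDGE, 3)),
              m = array(FALSE, dim = rep(CHUNK_EDGE, 3)))
    o0 <- pmax(bbox[1:3], cc * CHUNK_EDGE)
    o1 <- pmin(bbox[4:6], (cc + 1L) * CHUNK_EDGE)
    ix <- (o0[1]:(o1[1] - 1L)) - cc[1] * CHUNK_EDGE + 1L
    iy <- (o0[2]:(o1[2] - 1L)) - cc[2] * CHUNK_EDGE + 1L
    iz <- (o0[3]:(o1[3] - 1L)) - cc[3] * CHUNK_EDGE + 1L
    ch$v[ix, iy, iz] <-
      values[(o0[1]:(o1[1] - 1L)) - bbox[1] + 1L,
             (o0[2]:(o1[2] - 1L)) - bbox[2] + 1L,
             (o0[3]:(o1[3] - 1L)) - bbox[3] + 1L]
    ch$m[ix, iy, iz] <- TRUE
    assign(key, ch, envir = vol$chunks)
    touched <- c(touched, key)
  }
  touched
}

# 2x2 XY reduction of a dense block (mean for images, majority with
# smallest-id tie-break for labels); Z untouched. Handles odd edges by
# reducing over the children that exist.
.reduce_block <- function(block, value_kind) {
  d <- dim(block)
  ow <- as.integer(ceiling(d[1] / 2)); oh <- as.integer(ceiling(d[2] / 2))
  pick <- function(dx, dy) {
    xi <- 2L * seq_len(ow) - 1L + dx
    yi <- 2L * seq_len(oh) - 1L + dy
    okx <- xi <= d[1]; oky <- yi <= d[2]
    m <- array(NA_integer_, dim = c(ow, oh, d[3]))
    m[okx, oky, ] <- block[xi[okx], yi[oky], , drop = FALSE]
    m
  }
  a <- pick(0L, 0L); b <- pick(1L, 0L); cc <- pick(0L, 1L); dd <- pick(1L, 1L)
  if (value_kind == "id16") {
    cand <- cbind(as.vector(a), as.vector(b), as.vector(cc), as.vector(dd))
    best_score <- rep(-Inf, nrow(cand)); best <- integer(nrow(cand))
    for (j in 1:4) {
      cj <- cand[, j]
      cnt <- rowSums(cand == cj, na.rm = TRUE)
      score <- ifelse(is.na(cj), -Inf, cnt * 2^17 - cj)
      take <- score > best_score
      best[take] <- cj[take]
      best_score[take] <- score[take]
    }
    return(array(best, dim = c(ow, oh, d[3])))
  }
  mean4 <- function(ch_a, ch_b, ch_c, ch_d) {
    s <- array(0, dim = dim(ch_a)); n <- array(0L, dim = dim(ch_a))
    for (m in list(ch_a, ch_b, ch_c, ch_d)) {
      ok <- !is.na(m)
      s[ok] <- s[ok] + m[ok]
      n[ok] <- n[ok] + 1L
    }
    as.integer(floor(s / n + 0.5))   # round half up
  }
  if (value_kind == "gray8")
    return(array(mean4(a, b, cc, dd), dim = c(ow, oh, d[3])))
  # rgb24: per-channel mean, repacked
  r <- mean4(a %/% 65536L, b %/% 65536L, cc %/% 65536L, dd %/% 65536L)
  g <- mean4((a %/% 256L) %% 256L, (b %/% 256L) %% 256L,
             (cc %/% 256L) %% 256L, (dd %/% 256L) %% 256L)
  bl <- mean4(a %% 256L, b %% 256L, cc %% 256L, dd %% 256L)
  array(r * 65536L + g * 256L + bl, dim = c(ow, oh, d[3]))
}

#' Reduce a footprint to the next coarser mip level
#'
#' Recomputes level `level + 1` explicit data over the given footprint from
#' the effective values at `level`. Image kinds use the rounded (half-up)
#' arithmetic mean of each 2x2 XY child group; `id16` uses the majority
#' label with ties broken by the smallest id. This runs automatically
#' inside [write_region()]; it is exposed for direct use and testing.
#'
#' @param vol a `chunked_volume`.
#' @param level source level (level + 1 must exist).
#' @param footprint half-open bbox at `level` (default: whole level).
#' @return (invisibly) the reduced block written at level `level + 1`.
#' @export
reduce_to_coarser <- function(vol, level, footprint = NULL) {
  level <- .check_level(vol, level)
  if (level + 1L >= vol$num_levels)
    stop(sprintf("level %d is the coarsest level; cannot reduce further", level))
  ext <- level_extent(vol, level)
  if (is.null(footprint)) footprint <- c(0L, 0L, 0L, ext)
  footprint <- .check_bbox(footprint, ext)
  extC <- level_extent(vol, level + 1L)
  bM <- c(footprint[1] %/% 2L, footprint[2] %/% 2L, footprint[3],
          pmin(as.integer(ceiling(footprint[4] / 2)), extC[1]),
          pmin(as.integer(ceiling(footprint[5] / 2)), extC[2]),
          footprint[6])
  cb <- c(bM[1] * 2L, bM[2] * 2L, bM[3],
          min(ext[1], bM[4] * 2L), min(ext[2], bM[5] * 2L), bM[6])
  red <- .reduce_block(read_region(vol, level, cb), vol$value_kind)
  .set_explicit(vol, level + 1L, bM, red)
  invisible(red)
}

#' Write a dense block of voxels
#'
#' Writes values over a half-open box at a mip level, allocating chunks on
#' demand. The write is authoritative for its level: explicit finer-level
#' data under the footprint is removed (partially covered finer chunks are
#' overwritten with the replicated new values instead), and every coarser
#' level is re-reduced over the footprint. All-zero chunks whose removal
#' does not change any read are pruned, so erasing everything returns the
#' volume to zero allocated chunks.
#'
#' @inheritParams read_region
#' @param values integer array matching the bbox shape, or a single value
#'   recycled over the box. Ids above 65535 are rejected for `id16`.
#' @return (invisibly) the number of voxels whose effective value changed.
#' @export
write_region <- function(vol, level, bbox, values) {
  level <- .check_level(vol, level)
  ext <- level_extent(vol, level)
  bbox <- .check_bbox(bbox, ext)
  d <- bbox[4:6] - bbox[1:3]
  if (length(values) == 1L) values <- array(as.integer(values), dim = d)
  if (!is.array(values) || !identical(as.integer(dim(values)), as.integer(d)))
    stop("values shape does not match bbox")
  storage.mode(values) <- "integer"
  .check_values(values, vol$value_kind)
  old <- read_region(vol, level, bbox)
  changed <- sum(old != values)
  touched <- .set_explicit(vol, level, bbox, values)
  # authoritative write: clear explicit finer data under the footprint
  if (level > 0L) for (M in (level - 1L):0L) {
    f <- as.integer(2^(level - M))
    extM <- level_extent(vol, M)
    fp <- c(bbox[1] * f, bbox[2] * f, bbox[3],
            min(extM[1], bbox[4] * f), min(extM[2], bbox[5] * f), bbox[6])
    for (cc in .chunks_overlapping(vol, M, fp)) {
      cb0 <- cc * CHUNK_EDGE
      key <- .chunk_key(M, cc[1], cc[2], cc[3])
      ch <- get(key, envir = vol$chunks, inherits = FALSE)
      o0 <- pmax(fp[1:3], cb0)
      o1 <- pmin(fp[4:6], cb0 + CHUNK_EDGE)
      ix <- (o0[1]:(o1[1] - 1L)) - cb0[1] + 1L
      iy <- (o0[2]:(o1[2] - 1L)) - cb0[2] + 1L
      iz <- (o0[3]:(o1[3] - 1L)) - cb0[3] + 1L
      ch$m[ix, iy, iz] <- FALSE
      ch$v[ix, iy, iz] <- 0L
      if (any(ch$m)) assign(key, ch, envir = vol$chunks)
      else rm(list = key, envir = vol$chunks)
      touched <- c(touched, key)
    }
  }
  # re-reduce coarser levels over the footprint
  if (level + 1L < vol$num_levels) {
    prev <- bbox
    for (M in (level + 1L):(vol$num_levels - 1L)) {
      reduce_to_coarser(vol, M - 1L, prev)
      extM <- level_extent(vol, M)
      prev <- c(prev[1] %/% 2L, prev[2] %/% 2L, prev[3],
                min(extM[1], as.integer(ceiling(prev[4] / 2))),
                min(extM[2], as.integer(ceiling(prev[5] / 2))), prev[6])
      touched <- c(touched, .chunk_keys_in(M, prev))
    }
  }
  .prune_keys(vol, unique(touched))
  invisible(changed)
}

.chunk_keys_in <- function(level, bbox) {
  c0 <- bbox[1:3] %/% CHUNK_EDGE
  c1 <- (bbox[4:6] - 1L) %/% CHUNK_EDGE
  g <- expand.grid(cx = c0[1]:c1[1], cy = c0[2]:c1[2], cz = c0[3]:c1[3])
  .chunk_key(level, g$cx, g$cy, g$cz)
}

# remove all-zero chunks whose removal leaves every read unchanged
# (coarsest level first so zero data cascades down the pyramid)
.prune_keys <- function(vol, keys) {
  keys <- keys[vapply(keys, exists, logical(1), envir = vol$chunks,
                      inherits = FALSE)]
  if (length(keys) == 0L) return(invisible(vol))
  lv <- as.integer(vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1L))
  for (key in keys[order(-lv)]) {
    ch <- get(key, envir = vol$chunks, inherits = FALSE)
    if (any(ch$v[ch$m] != 0L)) next
    pc <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    ext <- level_extent(vol, pc[1])
    cb <- c(pc[2:4] * CHUNK_EDGE, pmin((pc[2:4] + 1L) * CHUNK_EDGE, ext))
    rm(list = key, envir = vol$chunks)
    if (any(read_region(vol, pc[1], cb) != 0L))
      assign(key, ch, envir = vol$chunks)   # removal would change reads
  }
  invisible(vol)
}

#' Prune removable all-zero chunks over the whole volume
#'
#' @param vol a `chunked_volume`.
#' @return the volume, invisibly.
#' @export
prune_chunks <- function(vol) {
  .prune_keys(vol, ls(vol$chunks))
}

#' Effective voxel value at a coordinate
#'
#' The value at the requested level if its chunk holds explicit data,
#' otherwise inherited by XY replication from the nearest coarser level
#' with explicit data, otherwise 0.
#'
#' @param vol a `chunked_volume`.
#' @param level mip level.
#' @param x,y,z 0-based voxel coordinate at that level.
#' @return integer value.
#' @export
effective_value <- function(vol, level, x, y, z) {
  read_region(vol, level, c(x, y, z, x + 1L, y + 1L, z + 1L))[1L]
}

#' Materialize a whole mip level as a dense array
#'
#' @param vol a `chunked_volume`.
#' @param level mip level (default 0).
#' @return integer array of the level extent.
#' @export
as_array <- function(vol, level = 0L) {
  read_region(vol, level, c(0L, 0L, 0L, level_extent(vol, level)))
}

#' Build a volume from a dense array
#'
#' @param arr integer 3D array (level-0 data, X-fastest).
#' @inheritParams create_volume
#' @return a `chunked_volume` with all mip levels computed.
#' @export
volume_from_array <- function(arr, voxel_size_nm = c(1, 1, 1),
                              value_kind = c("gray8", "rgb24", "id16"),
                              num_levels = 1L) {
  value_kind <- match.arg(value_kind)
  d <- dim(arr)
  if (length(d) != 3L) stop("arr must be a 3D array")
  vol <- create_volume(d, voxel_size_nm, value_kind, num_levels)
  storage.mode(arr) <- "integer"
  write_region(vol, 0L, c(0L, 0L, 0L, d), arr)
  vol
}

#' Pack / unpack 24-bit RGB voxel values
#'
#' @param r,g,b channel values 0..255.
#' @param v packed values.
#' @return `rgb24()` returns packed integers `r*65536 + g*256 + b`;
#'   `unpack_rgb24()` a list with components `r`, `g`, `b`.
#' @export
rgb24 <- function(r, g, b) {
  as.integer(r) * 65536L + as.integer(g) * 256L + as.integer(b)
}

#' @rdname rgb24
#' @export
unpack_rgb24 <- function(v) {
  v <- as.integer(v)
  list(r = v %/% 65536L, g = (v %/% 256L) %% 256L, b = v %% 256L)
}

#' Chunk-grid geometry of a level
#'
#' `chunk_grid_dims` is the number of chunks per axis; `chunk_index_depth`
#' the minimum depth of a fan-out-16^3 pointer-block tree addressing that
#' grid (one 16x16x16 block addresses 16 chunks per axis per tree level).
#'
#' @param vol a `chunked_volume`.
#' @param level mip level.
#' @return integer vector / integer.
#' @export
chunk_grid_dims <- function(vol, level = 0L) {
  as.integer(ceiling(level_extent(vol, level) / CHUNK_EDGE))
}

#' @rdname chunk_grid_dims
#' @export
chunk_index_depth <- function(vol, level = 0L) {
  g <- max(chunk_grid_dims(vol, level))
  max(1L, as.integer(ceiling(log(g) / log(CHUNK_EDGE) - 1e-12)))
}
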