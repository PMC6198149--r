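#' Z-order (Morton) index of chunk-local coordinates
#'
#' Interleaves the 4 bits of each coordinate of a position inside a
#' 16x16x16 chunk into a single linear index, with `x` occupying the
#' least-significant bit of each 3-bit group, then `y`, then `z`. The
#' mapping is a bijection from \code{[0,16)^3} onto \code{[0,4096)} and is
#' the storage order used for chunk payloads in the segmentation container.
#'
#' @param x,y,z integer vectors of chunk-local coordinates in `[0, 16)`.
#' @return integer vector of linear indices in `[0, 4096)`.
#' @examples
#' zorder_index(0, 0, 0)  # 0
#' zorder_index(1, 0, 0)  # 1
#' zorder_index(0, 1, 0)  # 2
#' zorder_index(0, 0, 1)  # 4
#' @export
zorder_index <- function(x, y, z) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("coordinates must be non-missing integers")
  if (any(x < 0L | x >= CHUNK_EDGE | y < 0L | y >= CHUNK_EDGE |
          z < 0L | z >= CHUNK_EDGE))
    stop("chunk-local coordinates must lie in [0, 16)")
  idx <- 0L
  for (b in 0:3) {
    bit <- bitwShiftL(1L, b)
    idx <- idx +
      bitwShiftL(bitwAnd(bitwShiftR(x, b), 1L), 3L * b) * 1L +
      bitwShiftL(bitwAnd(bitwShiftR(y, b), 1L), 3L * b) * 2L +
      bitwShiftL(bitwAnd(bitwShiftR(z, b), 1L), 3L * b) * 4L
  }
  idx
}

# permutation p such that payload_in_file[i] = chunk_column_major[p[i]];
# cached once per session.
.zorder_perm_cache <- new.env(parent = emptyenv())

.zorder_perm <- function() {
  if (is.null(.zorder_perm_cache$p)) {
    g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
    zi <- zorder_index(g$x, g$y, g$z)
    p <- integer(CHUNK_VOX)
    p[zi + 1L] <- seq_len(CHUNK_VOX)
    .zorder_perm_cache$p <- p
    .zorder_perm_cache$inv <- order(p)
  }
  .zorder_perm_cache$p
}

.zorder_unperm <- function() {
  .zorder_perm()
  .zorder_perm_cache$inv
}

# global Morton index used only as a deterministic spatial tie-break
# (components compared by their minimum index). Exact for coords < 2^17.
.morton_global <- function(x, y, z) {
  v <- numeric(length(x))
  for (b in 0:16) {
    pb <- 2^(3 * b)
    v <- v + (bitwAnd(bitwShiftR(as.integer(x), b), 1L)) * pb +
      (bitwAnd(bitwShiftR(as.integer(y), b), 1L)) * 2 * pb +
      (bitwAnd(bitwShiftR(as.integer(z), b), 1L)) * 4 * pb
  }
  v
}
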