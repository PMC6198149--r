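#' Isosurface mesh of an image volume (marching tetrahedra)
#'
#' Extracts the brightness isosurface at `threshold` from a gray layer.
#' Each cell of the voxel-center sample grid is split into 6 tetrahedra
#' (Kuhn/Freudenthal decomposition, which is face-consistent across
#' neighboring cells, so the resulting surface is watertight); surface
#' vertices are linearly interpolated along tetrahedron edges and scaled
#' to nm. A threshold outside the data range yields an empty mesh.
#'
#' @param vol a `gray8` `chunked_volume`.
#' @param threshold iso value; voxels with value > threshold are inside.
#' @param level mip level.
#' @return a `triangle_mesh` (group `"iso"`).
#' @export
isosurface_mesh <- function(vol, threshold, level = 0L) {
  if (vol$value_kind != "gray8") stop("isosurfaces need a gray8 layer")
  level <- .check_level(vol, level)
  arr <- as_array(vol, level)
  d <- dim(arr)
  vs <- vol$voxel_size_nm * c(2^level, 2^level, 1)
  empty <- triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), character(0))
  if (any(d < 2L)) return(empty)
  nc <- (d[1] - 1L) * (d[2] - 1L) * (d[3] - 1L)
  corner_val <- function(o) {
    as.vector(arr[(1:(d[1] - 1L)) + o[1], (1:(d[2] - 1L)) + o[2],
                  (1:(d[3] - 1L)) + o[3]])
  }
  cg <- expand.grid(x = 0:(d[1] - 2L), y = 0:(d[2] - 2L), z = 0:(d[3] - 2L))
  cell0 <- as.matrix(cg)                      # 0-based cell origin voxel
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ey <- diag(3)
  verts <- list()
  for (p in perms) {
    offs <- list(c(0, 0, 0), ey[p[1], ], ey[p[1], ] + ey[p[2], ], c(1, 1, 1))
    vals <- vapply(offs, corner_val, numeric(nc))     # nc x 4
    inside <- vals > threshold
    case <- inside %*% c(1, 2, 4, 8)
    if (all(case == 0) || all(case == 15)) next
    interp <- function(sel, a, b) {
      va <- vals[sel, a]; vb <- vals[sel, b]
      t <- (threshold - va) / (vb - va)
      base <- cell0[sel, , drop = FALSE]
      pos <- base + matrix(offs[[a]], sum(sel), 3, byrow = TRUE) + 0.5 +
        t * matrix(offs[[b]] - offs[[a]], sum(sel), 3, byrow = TRUE)
      sweep(pos, 2, vs, `*`)
    }
    for (cs in 1:14) {
      sel <- case == cs
      if (!any(sel)) next
      ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) != 0L)
      if (length(ins) == 1L || length(ins) == 3L) {
        pivot <- if (length(ins) == 1L) ins else setdiff(1:4, ins)
        oth <- setdiff(1:4, pivot)
        p1 <- interp(sel, pivot, oth[1])
        p2 <- interp(sel, pivot, oth[2])
        p3 <- interp(sel, pivot, oth[3])
        verts[[length(verts) + 1L]] <-
          rbind(p1, p2, p3)[rep(seq_len(sum(sel)), each = 3) +
                              c(0, 1, 2) * sum(sel), , drop = FALSE]
      } else {
        i <- ins[1]; j <- ins[2]; kl <- setdiff(1:4, ins)
        pik <- interp(sel, i, kl[1]); pil <- interp(sel, i, kl[2])
        pjk <- interp(sel, j, kl[1]); pjl <- interp(sel, j, kl[2])
        n <- sum(sel)
        t1 <- rbind(pik, pil, pjl)[rep(seq_len(n), each = 3) + c(0, 1, 2) * n, ,
                                   drop = FALSE]
        t2 <- rbind(pik, pjl, pjk)[rep(seq_len(n), each = 3) + c(0, 1, 2) * n, ,
                                   drop = FALSE]
        verts[[length(verts) + 1L]] <- rbind(t1, t2)
      }
    }
  }
  if (length(verts) == 0L) return(empty)
  v <- do.call(rbind, verts)
  tris <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  # weld coincident vertices and drop triangles degenerated by the surface
  # passing exactly through a grid sample
  key <- apply(round(v, 9), 1, paste, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  v2 <- v[match(uk, key), , drop = FALSE]
  tr2 <- matrix(map[tris], ncol = 3)
  ok <- tr2[, 1] != tr2[, 2] & tr2[, 2] != tr2[, 3] & tr2[, 1] != tr2[, 3]
  tr2 <- tr2[ok, , drop = FALSE]
  if (nrow(tr2) == 0L) return(empty)
  triangle_mesh(v2, tr2, rep("iso", nrow(tr2)))
}
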