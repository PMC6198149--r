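#' Triangle meshes and Wavefront OBJ export
#'
#' A `triangle_mesh` holds vertices in nanometer coordinates (voxel index
#' times voxel size), a triangle index matrix, a per-triangle object
#' group and one material color per group. Optional line segments (for
#' wireframe boxes) are written as OBJ `l` elements.
#'
#' @param vertices n x 3 numeric matrix (nm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise seen from outside.
#' @param group character/factor of length m (object names).
#' @param materials named list of RGB colors in 0..1 (per group name).
#' @param lines optional k x 2 integer matrix of line segments.
#' @return a `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, triangles, group = NULL,
                          materials = list(), lines = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (is.null(group)) group <- rep("object", nrow(triangles))
  structure(list(vertices = vertices, triangles = triangles,
                 group = as.character(group), materials = materials,
                 lines = lines),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles, %d group(s)>\n",
              nrow(x$vertices), nrow(x$triangles),
              length(unique(x$group))))
  invisible(x)
}

#' Total triangle area of a mesh (nm^2)
#'
#' @param mesh a `triangle_mesh`.
#' @return total area; attribute `by_group` holds per-group areas.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  out <- sum(areas)
  attr(out, "by_group") <- tapply(areas, mesh$group, sum)
  out
}

#' Closed-2-manifold check
#'
#' TRUE when every undirected edge (after welding vertices at identical
#' coordinates) is shared by exactly two triangles.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(FALSE)
  key <- apply(round(mesh$vertices, 6), 1, paste, collapse = ",")
  vid <- match(key, unique(key))
  tr <- matrix(vid[mesh$triangles], ncol = 3)
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(ek) == 2L)
}

# exposed-face quads of mask (padded comparison), returned as a mesh;
# vertices on the voxel corner lattice in nm
.voxel_face_mesh <- function(mask, origin_vx, voxel_nm, group) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  verts <- list(); tris <- list(); nv <- 0L
  # face normal directions: +x,-x,+y,-y,+z,-z ; quad corner offsets chosen
  # counter-clockwise seen from outside
  faces <- list(
    list(s = c(1, 0, 0),  corners = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))),
    list(s = c(-1, 0, 0), corners = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0))),
    list(s = c(0, 1, 0),  corners = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))),
    list(s = c(0, -1, 0), corners = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1))),
    list(s = c(0, 0, 1),  corners = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))),
    list(s = c(0, 0, -1), corners = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0))))
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  for (f in faces) {
    nb_idx <- Map(function(r, s) r + s, core, as.list(f$s))
    nb <- pad[nb_idx[[1]], nb_idx[[2]], nb_idx[[3]], drop = FALSE]
    expo <- which(mask & !nb)
    if (length(expo) == 0L) next
    co <- arrayInd(expo, d) - 1L
    for (i in seq_len(length(expo))) {
      cs <- sweep(f$corners, 2, co[i, ] + origin_vx, `+`)
      cs <- sweep(cs, 2, voxel_nm, `*`)
      verts[[length(verts) + 1L]] <- cs
      tris[[length(tris) + 1L]] <- rbind(nv + c(1L, 2L, 3L), nv + c(1L, 3L, 4L))
      nv <- nv + 4L
    }
  }
  if (nv == 0L)
    return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), character(0)))
  v <- do.call(rbind, verts)
  tr <- do.call(rbind, tris)
  # weld duplicate corner vertices
  key <- apply(v, 1, paste, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  v2 <- v[match(uk, key), , drop = FALSE]
  triangle_mesh(v2, matrix(map[tr], ncol = 3),
                rep(group, nrow(tr)))
}

#' Voxel-face surface mesh of segments
#'
#' Blocky meshing: one quad (two triangles) per exposed voxel face — a
#' face between an `id` voxel and any non-`id` voxel — scaled by the
#' (level-adjusted) voxel size. The mesh of a finite object is closed and
#' its area deliberately overestimates the true surface because of the
#' voxel roughness; smoothing is left to external tools. One group per id
#' with its display color as material.
#'
#' @param vol an `id16` volume.
#' @param ids segment ids to mesh.
#' @param level mip level to mesh at.
#' @param table optional `segment_table` for material colors.
#' @return a `triangle_mesh` with one group `"seg<id>"` per id.
#' @export
segment_mesh <- function(vol, ids, level = 0L, table = NULL) {
  level <- .check_level(vol, level)
  vs <- vol$voxel_size_nm * c(2^level, 2^level, 1)
  arr <- as_array(vol, level)
  meshes <- list()
  for (id in ids) {
    mask <- arr == id
    if (!any(mask)) {
      warning(sprintf("segment %d has no voxels at level %d; empty group", id, level))
      next
    }
    meshes[[length(meshes) + 1L]] <-
      .voxel_face_mesh(mask, c(0L, 0L, 0L), vs, sprintf("seg%d", id))
  }
  out <- .cat_meshes(meshes)
  for (id in ids) {
    colr <- if (!is.null(table) && id %in% table$id)
      unlist(unpack_rgb24(resolve_display_color(table, id)$color1)) / 255
    else unlist(unpack_rgb24(.default_color(id))) / 255
    out$materials[[sprintf("seg%d", id)]] <- colr
  }
  out
}

.cat_meshes <- function(meshes) {
  meshes <- Filter(function(m) nrow(m$triangles) > 0, meshes)
  if (length(meshes) == 0L)
    return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), character(0)))
  nv <- 0L; vs <- list(); ts <- list(); gs <- list(); mats <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    ts[[length(ts) + 1L]] <- m$triangles + nv
    gs[[length(gs) + 1L]] <- m$group
    mats <- c(mats, m$materials)
    nv <- nv + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, ts), unlist(gs), mats)
}

#' Write a mesh as Wavefront OBJ (+ MTL)
#'
#' One OBJ group (`g`)/material per object group; coordinates in nm,
#' right-handed. A sidecar `.mtl` with the group colors is written next
#' to the OBJ and referenced via `mtllib`.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output `.obj` path.
#' @return the path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  mtl_path <- sub("\\.obj$", ".mtl", path)
  lines <- c("# voxann OBJ export",
             sprintf("mtllib %s", basename(mtl_path)))
  lines <- c(lines, sprintf("v %.6g %.6g %.6g", mesh$vertices[, 1],
                            mesh$vertices[, 2], mesh$vertices[, 3]))
  for (g in unique(mesh$group)) {
    sel <- mesh$group == g
    lines <- c(lines, sprintf("g %s", g), sprintf("usemtl %s", g),
               sprintf("f %d %d %d", mesh$triangles[sel, 1],
                       mesh$triangles[sel, 2], mesh$triangles[sel, 3]))
  }
  if (!is.null(mesh$lines))
    lines <- c(lines, sprintf("l %d %d", mesh$lines[, 1], mesh$lines[, 2]))
  writeLines(lines, path)
  mlines <- "# voxann materials"
  for (g in unique(mesh$group)) {
    colr <- mesh$materials[[g]] %||% c(0.8, 0.8, 0.8)
    mlines <- c(mlines, sprintf("newmtl %s", g),
                sprintf("Kd %.4f %.4f %.4f", colr[1], colr[2], colr[3]))
  }
  writeLines(mlines, mtl_path)
  invisible(path)
}
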