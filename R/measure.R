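#' Measure a segment
#'
#' Volume is the level-0 voxel count times the voxel volume; surface area
#' is the summed triangle area of the blocky voxel-face mesh (an
#' overestimate of the true surface because of voxel roughness — smooth
#' externally for better estimates); the bounding box is the tight
#' half-open box over the voxels.
#'
#' @param vol an `id16` volume.
#' @param id segment id.
#' @return list with `voxel_count`, `volume_nm3`, `surface_area_nm2`,
#'   `bbox` (or NULL when the segment is empty).
#' @export
measure <- function(vol, id) {
  n <- id_histogram(vol, id)
  if (n == 0L)
    return(list(voxel_count = 0L, volume_nm3 = 0, surface_area_nm2 = 0,
                bbox = NULL))
  bb <- .painted_bbox(vol)
  arr <- read_region(vol, 0L, bb)
  idx <- which(arr == id)
  co <- arrayInd(idx, dim(arr))
  bbox <- c(apply(co, 2, min) - 1L + bb[1:3], apply(co, 2, max) + bb[1:3])
  area <- mesh_area(suppressWarnings(segment_mesh(vol, id)))
  list(voxel_count = as.integer(n),
       volume_nm3 = as.numeric(n) * prod(vol$voxel_size_nm),
       surface_area_nm2 = as.numeric(area),
       bbox = as.integer(bbox))
}

#' Euclidean distance between two voxel coordinates (nm)
#'
#' Coordinates are scaled anisotropically by the voxel size before the
#' distance is taken.
#'
#' @param p1,p2 voxel coordinates (x, y, z), level 0.
#' @param voxel_size_nm voxel size, or a `chunked_volume` to take it from.
#' @return distance in nm.
#' @export
point_distance <- function(p1, p2, voxel_size_nm = c(1, 1, 1)) {
  if (inherits(voxel_size_nm, "chunked_volume"))
    voxel_size_nm <- voxel_size_nm$voxel_size_nm
  sqrt(sum(((as.numeric(p1) - as.numeric(p2)) * voxel_size_nm)^2))
}
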