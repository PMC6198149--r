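#' Split a segment into its connected components
#'
#' Each 6-connected component of `id` beyond the largest receives a fresh
#' id (the lowest free ids, added to the table as siblings under `id`'s
#' parent); the largest component keeps `id`. Size ties are broken in
#' favor of the component whose minimum global Z-order (Morton) index is
#' smallest. Voxel mass is conserved.
#'
#' @param vol an `id16` volume.
#' @param table a `segment_table` containing `id`.
#' @param id the segment to split.
#' @return list with `table` (updated) and `ids` (the component ids,
#'   keeper first, in decreasing component size).
#' @export
split_components <- function(vol, table, id) {
  id <- as.integer(id)
  .seg_row(table, id)
  bb <- .painted_bbox(vol)
  if (is.null(bb)) stop(sprintf("segment %d has no voxels", id))
  arr <- read_region(vol, 0L, bb)
  mask <- arr == id
  if (!any(mask)) stop(sprintf("segment %d has no voxels", id))
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 1L) return(list(table = table, ids = id))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  minz <- rep(Inf, k)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab)) - 1L
  mz <- .morton_global(co[, 1] + bb[1], co[, 2] + bb[2], co[, 3] + bb[3])
  for (j in seq_len(k)) minz[j] <- min(mz[lab[idx] == j])
  keeper <- order(-sizes, minz)[1L]
  parent <- table$parent_id[.seg_row(table, id)]
  label0 <- table$label[.seg_row(table, id)]
  others <- setdiff(order(-sizes, minz), keeper)
  new_ids <- integer(0)
  for (j in seq_along(others)) {
    free <- setdiff(seq_len(MAX_SEG_ID), table$id)[1L]
    if (is.na(free)) stop("no free segment ids left")
    table <- add_segment(table, id = free, parent_id = parent,
                         label = sprintf("%s.split%d", label0, j))
    new_ids <- c(new_ids, free)
    arr[lab == others[j]] <- free
  }
  write_region(vol, 0L, bb, arr)
  list(table = table, ids = c(id, new_ids))
}

#' Merge policy for combining segmentations
#'
#' @param precedence `"source"`: nonzero source voxels overwrite the
#'   target; `"target"`: only empty target voxels are written (existing
#'   target voxels are write protected).
#' @param renumber `"offset"`: source ids colliding with target ids move
#'   to the lowest free ids; `"keep"`: source ids are kept as-is
#'   (colliding ids alias the target's segments); `"map"`: use `map`.
#' @param map named integer vector (names = source ids) for
#'   `renumber = "map"`.
#' @return a `merge_policy` object.
#' @export
merge_policy <- function(precedence = c("source", "target"),
                         renumber = c("offset", "keep", "map"), map = NULL) {
  precedence <- match.arg(precedence)
  renumber <- match.arg(renumber)
  if (renumber == "map" && is.null(map)) stop("renumber = 'map' needs a map")
  structure(list(precedence = precedence, renumber = renumber, map = map),
            class = "merge_policy")
}

#' Merge one segmentation onto another
#'
#' Voxel conflicts are resolved voxel-by-voxel under the policy's
#' precedence rule; source ids are renumbered per the policy, and the
#' source's segment tree is attached under a new folder in the merged
#' table. Geometry (dims, voxel size, levels) must match.
#'
#' @param target,source lists with elements `volume` (an `id16`
#'   `chunked_volume`) and `table` (a `segment_table`).
#' @param policy a [merge_policy()].
#' @param folder_label label of the folder holding the merged-in segments.
#' @return list with `volume`, `table`, and `id_map` (named vector: source
#'   id -> merged id).
#' @export
merge_volumes <- function(target, source, policy = merge_policy(),
                          folder_label = "merged") {
  tv <- target$volume; sv <- source$volume
  if (!identical(tv$dims_vx, sv$dims_vx) ||
      !identical(tv$num_levels, sv$num_levels))
    stop("target and source must share dims and mip levels")
  ttab <- target$table; stab <- source$table
  src_ids <- sort(stab$id)
  id_map <- switch(policy$renumber,
    keep = stats::setNames(src_ids, src_ids),
    map = {
      m <- policy$map[as.character(src_ids)]
      if (anyNA(m)) stop("explicit map does not cover all source ids")
      stats::setNames(as.integer(m), src_ids)
    },
    offset = {
      free <- setdiff(seq_len(MAX_SEG_ID), ttab$id)
      out <- integer(length(src_ids))
      taken <- ttab$id
      fi <- 1L
      for (i in seq_along(src_ids)) {
        sid <- src_ids[i]
        if (!(sid %in% taken)) out[i] <- sid
        else {
          while (free[fi] %in% taken) fi <- fi + 1L
          out[i] <- free[fi]; fi <- fi + 1L
        }
        taken <- c(taken, out[i])
      }
      stats::setNames(out, src_ids)
    })
  if (any(id_map > MAX_SEG_ID)) stop("id overflow after renumbering")
  out_vol <- create_volume(tv$dims_vx, tv$voxel_size_nm, "id16", tv$num_levels)
  tarr <- as_array(tv, 0L)
  sarr <- as_array(sv, 0L)
  hit <- sarr != 0L
  sarr[hit] <- id_map[match(sarr[hit], src_ids)]
  merged <- tarr
  if (policy$precedence == "source") merged[hit] <- sarr[hit]
  else { wr <- hit & tarr == 0L; merged[wr] <- sarr[wr] }
  if (any(merged != 0L))
    write_region(out_vol, 0L, c(0L, 0L, 0L, tv$dims_vx), merged)
  # metadata: target tree + a folder carrying the (renumbered) source tree
  out_tab <- ttab
  if (nrow(stab) > 0L) {
    folder <- setdiff(seq_len(MAX_SEG_ID), c(out_tab$id, id_map))[1L]
    out_tab <- add_segment(out_tab, id = folder, parent_id = 0L,
                           label = folder_label)
    stab2 <- as.data.frame(stab)
    stab2$id <- unname(id_map[as.character(stab2$id)])
    stab2$parent_id <- ifelse(stab2$parent_id == 0L, folder,
                              unname(id_map[as.character(stab2$parent_id)]))
    out_tab <- rbind(as.data.frame(out_tab), stab2)
    class(out_tab) <- c("segment_table", "data.frame")
    .validate_table(out_tab)
  }
  list(volume = out_vol, table = out_tab, id_map = id_map)
}

#' Truncate external object ids to 24 bits
#'
#' Imported automatic segmentations may carry 64-bit object ids, of which
#' only 24 bits are representable (16,777,215 distinct objects); distinct
#' ids that agree modulo 2^24 therefore merge. Exact nonzero multiples of
#' 2^24 map to the reserved sentinel 2^24 - 1 instead of 0, so such
#' objects do not silently disappear into background.
#'
#' @param id64 non-negative numeric ids (64-bit range; exact up to 2^53).
#' @return 24-bit display ids.
#' @export
truncate_id_24 <- function(id64) {
  id64 <- as.numeric(id64)
  if (any(id64 < 0)) stop("ids must be non-negative")
  out <- id64 %% 2^24
  out[out == 0 & id64 > 0] <- 2^24 - 1
  as.integer(out)
}
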