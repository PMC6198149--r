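#' Synthetic EM-like phantom specification
#'
#' Describes a deterministic phantom: neurite-like tubes (smoothed random
#' walks along Z, dilated to a radius) and ellipsoidal blobs on a medium
#' background, with dark one-voxel membranes at object borders and
#' additive Gaussian noise. Defaults emulate anisotropic serial-section
#' EM at 6 x 6 x 30 nm voxels: bright interiors (~180), dark membranes
#' (~40), mid background (~120), noise sd 10.
#'
#' @param dims integer (X, Y, Z) voxel counts.
#' @param voxel_size_nm voxel size (defaults 6 x 6 x 30 nm).
#' @param n_tubes number of tube objects.
#' @param n_blobs number of blob objects.
#' @param tube_radius tube radius in voxels (XY).
#' @param interior,membrane,background gray levels.
#' @param noise_sd additive Gaussian noise sd (clipped to 0..255).
#' @param num_levels mip levels of the generated volumes.
#' @param seed RNG seed; the same spec and seed reproduce the phantom
#'   bit-identically.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(48L, 48L, 16L), voxel_size_nm = c(6, 6, 30),
                         n_tubes = 3L, n_blobs = 2L, tube_radius = 4,
                         interior = 180L, membrane = 40L, background = 120L,
                         noise_sd = 10, num_levels = 2L, seed = 1L) {
  structure(list(dims = as.integer(dims), voxel_size_nm = voxel_size_nm,
                 n_tubes = as.integer(n_tubes), n_blobs = as.integer(n_blobs),
                 tube_radius = tube_radius, interior = as.integer(interior),
                 membrane = as.integer(membrane),
                 background = as.integer(background),
                 noise_sd = noise_sd, num_levels = as.integer(num_levels),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# stamp a disk of `id` into slice plane of labels; collisions are checked
# with a one-voxel safety margin so distinct objects never touch (membranes
# separate real neurites, and downstream component splitting relies on it).
# Returns updated plane or NULL on collision.
.stamp_disk <- function(plane, cx, cy, r, id) {
  d <- dim(plane)
  rc <- r + 1.5
  xs <- max(1L, floor(cx - rc)):min(d[1], ceiling(cx + rc))
  ys <- max(1L, floor(cy - rc)):min(d[2], ceiling(cy + rc))
  if (length(xs) == 0L || length(ys) == 0L) return(plane)
  g <- expand.grid(x = xs, y = ys)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  guard <- g[d2 <= rc^2, , drop = FALSE]
  ex <- plane[cbind(guard$x, guard$y)]
  if (any(ex != 0L & ex != id)) return(NULL)
  core <- g[d2 <= r^2, , drop = FALSE]
  plane[cbind(core$x, core$y)] <- id
  plane
}

#' Generate a phantom image volume with ground-truth labels
#'
#' Tubes are random-walk centerlines running through the full Z range,
#' dilated to the spec radius in XY; blobs are axis-aligned ellipsoids.
#' Objects are placed disjointly (placement retries; an overcrowded spec
#' errors out). The image is the background gray with bright object
#' interiors, a one-voxel dark membrane at every voxel bordering a
#' different label (including background), and clipped Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`gray8` volume), `truth` (`id16` volume) and
#'   `n_objects`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dims
  labels <- array(0L, dim = d)
  next_id <- 1L
  r <- spec$tube_radius
  for (t in seq_len(spec$n_tubes)) {
    placed <- FALSE
    for (attempt in 1:25) {
      cx <- runif(1, r + 1, d[1] - r)
      cy <- runif(1, r + 1, d[2] - r)
      drift <- c(0, 0)
      trial <- labels
      ok <- TRUE
      px <- cx; py <- cy
      for (z in seq_len(d[3])) {
        drift <- 0.7 * drift + rnorm(2, sd = 0.6)
        px <- min(max(px + drift[1], r + 1), d[1] - r)
        py <- min(max(py + drift[2], r + 1), d[2] - r)
        pl <- .stamp_disk(trial[, , z], px, py, r, next_id)
        if (is.null(pl)) { ok <- FALSE; break }
        trial[, , z] <- pl
      }
      if (ok) { labels <- trial; next_id <- next_id + 1L; placed <- TRUE; break }
    }
    if (!placed)
      stop("overcrowded phantom spec: could not place all tubes disjointly")
  }
  for (b in seq_len(spec$n_blobs)) {
    placed <- FALSE
    for (attempt in 1:50) {
      rr <- c(runif(1, 2, r + 1), runif(1, 2, r + 1),
              runif(1, 1.5, max(2, d[3] / 5)))
      ce <- c(runif(1, rr[1] + 1, d[1] - rr[1]),
              runif(1, rr[2] + 1, d[2] - rr[2]),
              runif(1, rr[3] + 1, d[3] - rr[3]))
      xs <- floor(ce[1] - rr[1]):ceiling(ce[1] + rr[1])
      ys <- floor(ce[2] - rr[2]):ceiling(ce[2] + rr[2])
      zs <- max(1, floor(ce[3] - rr[3])):min(d[3], ceiling(ce[3] + rr[3]))
      g <- expand.grid(x = xs, y = ys, z = zs)
      sel <- ((g$x - ce[1]) / rr[1])^2 + ((g$y - ce[2]) / rr[2])^2 +
        ((g$z - ce[3]) / rr[3])^2 <= 1
      g <- g[sel, , drop = FALSE]
      ii <- cbind(g$x, g$y, g$z)
      if (nrow(ii) == 0L) next
      if (any(labels[ii] != 0L)) next
      # keep one voxel of background between objects (all axes)
      grow <- ii
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        sh <- ii
        sh[, ax] <- pmin(pmax(sh[, ax] + s, 1L), d[ax])
        grow <- rbind(grow, sh)
      }
      grow <- unique(grow)
      if (any(labels[grow] != 0L)) next
      labels[ii] <- next_id
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      stop("overcrowded phantom spec: could not place all blobs disjointly")
  }
  img <- array(as.numeric(spec$background), dim = d)
  img[labels != 0L] <- spec$interior
  shell <- .boundary_voxels(labels)
  img[shell] <- spec$membrane
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), sd = spec$noise_sd)
  img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = d)
  list(image = volume_from_array(img, spec$voxel_size_nm, "gray8",
                                 spec$num_levels),
       truth = volume_from_array(labels, spec$voxel_size_nm, "id16",
                                 spec$num_levels),
       n_objects = next_id - 1L)
}

# logical array: voxels (of any label, incl. background) with a 6-neighbor
# of a different label, restricted to labeled voxels' borders
.boundary_voxels <- function(labels) {
  d <- dim(labels)
  out <- array(FALSE, dim = d)
  shift_neq <- function(ax, s) {
    idx_a <- lapply(seq_len(3), function(k) seq_len(d[k]))
    idx_b <- idx_a
    if (s > 0) { idx_a[[ax]] <- 1:(d[ax] - 1); idx_b[[ax]] <- 2:d[ax] }
    else       { idx_a[[ax]] <- 2:d[ax];       idx_b[[ax]] <- 1:(d[ax] - 1) }
    a <- do.call(`[`, c(list(labels), idx_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(labels), idx_b, list(drop = FALSE)))
    neq <- a != b
    r <- array(FALSE, dim = d)
    r <- do.call(`[<-`, c(list(r), idx_a, list(neq)))
    r
  }
  for (ax in 1:3) for (s in c(1, -1)) out <- out | shift_neq(ax, s)
  out & labels != 0L
}

#' Boundary-probability map from ground-truth labels
#'
#' Each voxel is assigned 255 when any of its 6 neighbors carries a
#' different label (object/object or object/background border) and 0
#' otherwise, optionally box-blurred. Object interiors stay connected
#' within the map's low-value region, so a range-masked fill seeded
#' inside an object recovers it.
#'
#' @param truth an `id16` ground-truth volume.
#' @param blur box-blur radius in voxels (0 = crisp).
#' @return a `gray8` volume.
#' @export
make_boundary_map <- function(truth, blur = 0L) {
  labels <- as_array(truth, 0L)
  d <- dim(labels)
  # boundaries belong to the objects: the one-voxel shell of every labeled
  # object is marked, background stays low so object interiors remain the
  # connected low-value regions a masked fill can recover
  out <- .boundary_voxels(labels)
  m <- array(ifelse(out, 255L, 0L), dim = d)
  if (blur > 0L) {
    k <- 2L * blur + 1L
    sm <- array(0, dim = d)
    for (dx in -blur:blur) for (dy in -blur:blur) {
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      sm <- sm + m[xs, ys, , drop = FALSE]
    }
    m <- array(as.integer(round(sm / k^2)), dim = d)
  }
  volume_from_array(m, truth$voxel_size_nm, "gray8", truth$num_levels)
}

#' Inject split and merge errors into a segmentation
#'
#' Splits cut selected objects at a random interior Z plane into two ids;
#' mergers relabel selected 6-adjacent id pairs to a single id. Every
#' injected error is recorded in a ledger so scripted proofreading can be
#' verified against it.
#'
#' @param truth an `id16` ground-truth volume.
#' @param split_rate,merge_rate per-object / per-touching-pair error
#'   probabilities in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `seg` (the corrupted volume), `table` (a matching
#'   `segment_table`) and `ledger` (data.frame: `type`, `id_a`, `id_b`).
#' @export
corrupt_segmentation <- function(truth, split_rate = 0.5, merge_rate = 0.5,
                                 seed = 1L) {
  stopifnot(split_rate >= 0, split_rate <= 1, merge_rate >= 0, merge_rate <= 1)
  set.seed(seed)
  arr <- as_array(truth, 0L)
  d <- dim(arr)
  ids <- sort(unique(arr[arr != 0L]))
  ledger <- data.frame(type = character(), id_a = integer(), id_b = integer(),
                       stringsAsFactors = FALSE)
  next_id <- if (length(ids)) max(ids) + 1L else 1L
  for (id in ids) {
    if (runif(1) >= split_rate) next
    zs <- range(which(apply(arr == id, 3, any)))
    if (zs[2] - zs[1] < 1L) next       # needs at least two sections
    cands <- seq(zs[1] + 1L, zs[2])
    cut <- cands[sample.int(length(cands), 1L)]
    sel <- arr == id
    sel[, , seq_len(cut - 1L)] <- FALSE
    arr[sel] <- next_id
    ledger <- rbind(ledger, data.frame(type = "split", id_a = id,
                                       id_b = next_id))
    next_id <- next_id + 1L
  }
  # merger candidates: pairs of ids within two 6-steps of each other —
  # objects separated by a one-voxel membrane, the classic agglomeration
  # error of automatic segmentations
  dilate6 <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      idx_a <- lapply(seq_len(3), function(k) seq_len(d[k]))
      idx_b <- idx_a
      if (s > 0) { idx_a[[ax]] <- 1:(d[ax] - 1); idx_b[[ax]] <- 2:d[ax] }
      else       { idx_a[[ax]] <- 2:d[ax];       idx_b[[ax]] <- 1:(d[ax] - 1) }
      sub <- do.call(`[`, c(list(m), idx_b, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(out), idx_a, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idx_a, list(cur | sub)))
    }
    out
  }
  ids2 <- sort(unique(arr[arr != 0L]))
  pairs <- list()
  if (length(ids2) > 1L) {
    dil <- lapply(ids2, function(id) dilate6(arr == id))
    names(dil) <- ids2
    for (i in seq_along(ids2)) for (j in seq_along(ids2)) {
      if (i >= j) next
      if (any(dil[[i]] & dil[[j]]))
        pairs[[length(pairs) + 1L]] <- cbind(ids2[i], ids2[j])
    }
  }
  if (length(pairs)) {
    pr <- unique(do.call(rbind, pairs))
    for (i in seq_len(nrow(pr))) {
      if (runif(1) >= merge_rate) next
      a <- pr[i, 1]; b <- pr[i, 2]
      if (!any(arr == b) || !any(arr == a)) next
      arr[arr == b] <- a
      ledger <- rbind(ledger, data.frame(type = "merge", id_a = a, id_b = b))
    }
  }
  seg <- volume_from_array(arr, truth$voxel_size_nm, "id16",
                           truth$num_levels)
  tab <- segment_table()
  for (id in sort(unique(arr[arr != 0L])))
    tab <- add_segment(tab, id = id, label = sprintf("object %d", id))
  list(seg = seg, table = tab, ledger = ledger)
}

#' Rand index between two labelings
#'
#' Fraction of voxel pairs on which two segmentations agree (same-object
#' vs different-object); 1 for identical partitions up to renaming.
#'
#' @param a,b integer arrays of identical shape.
#' @return the Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ct <- table(as.vector(a), as.vector(b))
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(as.numeric(ct)))
  sum_a <- sum(ch2(as.numeric(rowSums(ct))))
  sum_b <- sum(ch2(as.numeric(colSums(ct))))
  total <- ch2(as.numeric(n))
  (total + 2 * sum_ij - sum_a - sum_b) / total
}
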