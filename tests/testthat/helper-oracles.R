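# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package: dense per-level
# arrays, explicit loops, queue-based flood fills, a list-based LRU.

# ---- dense shadow model of the multiresolution store --------------------

shadow_create <- function(dims, kind, nlevels) {
  exts <- lapply(seq_len(nlevels) - 1L, function(L)
    c(ceiling(dims[1] / 2^L), ceiling(dims[2] / 2^L), dims[3]))
  list(kind = kind, nlevels = nlevels, exts = exts,
       val = lapply(exts, function(e) array(0L, e)),
       exp = lapply(exts, function(e) array(FALSE, e)))
}

# effective dense array at a level: walk coarse -> fine, replicating
shadow_effective <- function(sv, level) {
  ext <- sv$exts[[level + 1L]]
  eff <- array(0L, ext)
  for (M in rev(seq(level, sv$nlevels - 1L))) {
    f <- 2^(M - level)
    em <- sv$exp[[M + 1L]]; vm <- sv$val[[M + 1L]]
    for (x in seq_len(ext[1])) for (y in seq_len(ext[2])) for (z in seq_len(ext[3])) {
      cx <- (x - 1L) %/% f + 1L; cy <- (y - 1L) %/% f + 1L
      if (em[cx, cy, z]) eff[x, y, z] <- vm[cx, cy, z]
    }
  }
  eff
}

shadow_reduce_pair <- function(vals, kind) {
  vals <- vals[!is.na(vals)]
  if (kind == "id16") {
    cnt <- table(vals)
    best <- max(cnt)
    return(min(as.integer(names(cnt)[cnt == best])))
  }
  as.integer(floor(mean(vals) + 0.5))
}

shadow_write <- function(sv, level, bbox, values) {
  xs <- (bbox[1] + 1L):bbox[4]; ys <- (bbox[2] + 1L):bbox[5]
  zs <- (bbox[3] + 1L):bbox[6]
  sv$val[[level + 1L]][xs, ys, zs] <- values
  sv$exp[[level + 1L]][xs, ys, zs] <- TRUE
  if (level > 0L) for (M in seq(0L, level - 1L)) {
    f <- 2^(level - M)
    extM <- sv$exts[[M + 1L]]
    fx <- (bbox[1] * f + 1L):min(extM[1], bbox[4] * f)
    fy <- (bbox[2] * f + 1L):min(extM[2], bbox[5] * f)
    sv$exp[[M + 1L]][fx, fy, zs] <- FALSE
  }
  if (level + 1L < sv$nlevels) for (M in seq(level + 1L, sv$nlevels - 1L)) {
    eff <- shadow_effective(sv, M - 1L)
    extM <- sv$exts[[M + 1L]]
    cx <- (bbox[1] %/% 2^(M - level) ):
      (min(extM[1], ceiling(bbox[4] / 2^(M - level))) - 1L)
    cy <- (bbox[2] %/% 2^(M - level)):
      (min(extM[2], ceiling(bbox[5] / 2^(M - level))) - 1L)
    for (x in cx) for (y in cy) for (z in zs - 1L) {
      kids <- c()
      for (dx in 0:1) for (dy in 0:1) {
        px <- 2L * x + dx + 1L; py <- 2L * y + dy + 1L
        if (px <= dim(eff)[1] && py <= dim(eff)[2])
          kids <- c(kids, eff[px, py, z + 1L])
      }
      sv$val[[M + 1L]][x + 1L, y + 1L, z + 1L] <-
        shadow_reduce_pair(kids, sv$kind)
      sv$exp[[M + 1L]][x + 1L, y + 1L, z + 1L] <- TRUE
    }
    level <- level   # footprint scaling handled via 2^(M - level) above
  }
  sv
}

# ---- queue-based flood fill ---------------------------------------------

bfs_component <- function(mask, seed) {
  d <- dim(mask)
  if (length(d) == 2L) { dim(mask) <- c(d, 1L); seed <- c(seed, 1L); d <- dim(mask) }
  out <- array(FALSE, d)
  if (!mask[seed[1], seed[2], seed[3]]) return(out)
  queue <- list(seed)
  out[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (dlt in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      q <- p + dlt
      if (any(q < 1L) || any(q > d)) next
      if (mask[q[1], q[2], q[3]] && !out[q[1], q[2], q[3]]) {
        out[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out
}

bfs_label_all <- function(mask) {
  d <- dim(mask); if (length(d) == 2L) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  lab <- array(0L, d); k <- 0L
  for (i in which(mask & lab == 0L)) {
    if (lab[i] != 0L) next
    k <- k + 1L
    comp <- bfs_component(mask, arrayInd(i, d)[1, ])
    lab[comp] <- k
  }
  lab
}

# ---- per-column Z-gap scan ----------------------------------------------

zgap_oracle <- function(arr, xy, z, id, depth) {
  # returns array after gap fill with paint_all mode; xy 0-based
  nz <- dim(arr)[3]
  for (r in seq_len(nrow(xy))) {
    x <- xy[r, 1] + 1L; y <- xy[r, 2] + 1L
    for (dir in c(-1L, 1L)) {
      hit <- NA
      for (k in seq_len(depth)) {
        zz <- z + dir * k + 1L
        if (zz < 1L || zz > nz) break
        if (arr[x, y, zz] == id) { hit <- k; break }
      }
      if (!is.na(hit) && hit > 1L)
        for (k in seq_len(hit - 1L)) arr[x, y, z + dir * k + 1L] <- id
    }
  }
  arr
}

# ---- reference LRU with dirty protection --------------------------------

lru_create <- function(cap) list(cap = cap, res = character(0),
                                 dirty = character(0), spill = character(0))

lru_touch <- function(st, key, modify = FALSE) {
  if (key %in% st$spill) { st$spill <- setdiff(st$spill, key); modify <- TRUE }
  st$res <- c(setdiff(st$res, key), key)
  if (modify) st$dirty <- union(st$dirty, key)
  while (length(st$res) > st$cap) {
    clean <- st$res[!(st$res %in% st$dirty)]
    if (length(clean)) {
      st$res <- setdiff(st$res, clean[1])
    } else {
      v <- st$res[1]
      st$spill <- c(st$spill, v)
      st$dirty <- setdiff(st$dirty, v)
      st$res <- setdiff(st$res, v)
    }
  }
  st
}

# random id16 volume for round-trip tests
random_seg_array <- function(dims, n_blobs = 4, seed = 1) {
  set.seed(seed)
  arr <- array(0L, dims)
  for (i in seq_len(n_blobs)) {
    c0 <- sapply(dims, function(d) sample.int(d, 1))
    r <- sample(2:4, 1)
    xs <- max(1, c0[1] - r):min(dims[1], c0[1] + r)
    ys <- max(1, c0[2] - r):min(dims[2], c0[2] + r)
    zs <- max(1, c0[3] - 1):min(dims[3], c0[3] + 1)
    arr[xs, ys, zs] <- i
  }
  arr
}
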