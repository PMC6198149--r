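#' Single-file sparse segmentation container
#'
#' Saves an `id16` volume plus its segment metadata to one little-endian
#' binary file (magic `VSG1`). Only allocated chunks are stored, so file
#' size grows with painted content, not with the nominal dataset
#' dimensions. Each mip level is indexed by a tree of 16x16x16 pointer
#' blocks whose leaf pointers reference deflate-compressed chunk records
#' (voxels stored as 16-bit little-endian values in Z-order);
#' `load_segmentation(save_segmentation(...))` reproduces the volume —
#' every level's explicit chunks — and metadata bit-identically.
#'
#' @param vol an `id16` `chunked_volume`.
#' @param table a `segment_table` (may be empty).
#' @param path output file.
#' @return `save_segmentation()` the path, invisibly;
#'   `load_segmentation()` a list with `volume` and `table`.
#' @export
save_segmentation <- function(vol, table = segment_table(), path) {
  stopifnot(inherits(vol, "chunked_volume"))
  if (vol$value_kind != "id16")
    stop("only id16 volumes are stored in segmentation containers")
  meta_raw <- charToRaw(paste(export_metadata_text(table), collapse = "\n"))
  nl <- vol$num_levels
  perm <- .zorder_perm()
  levels_info <- vector("list", nl)
  for (L in seq_len(nl) - 1L) {
    df <- allocated_chunks(vol, L)
    D <- chunk_index_depth(vol, L)
    payloads <- vector("list", nrow(df))
    if (nrow(df) > 0L) for (i in seq_len(nrow(df))) {
      ch <- get(.chunk_key(L, df$cx[i], df$cy[i], df$cz[i]),
                envir = vol$chunks, inherits = FALSE)
      v <- as.vector(ch$v)[perm]                    # file order = Z-order
      m <- as.vector(ch$m)[perm]
      b <- c(writeBin(as.integer(v), raw(), size = 2L, endian = "little"),
             as.raw(as.integer(m)))                 # explicitness mask bytes
      payloads[[i]] <- memCompress(b, type = "gzip")
    }
    # sparse pointer-block tree: nodes keyed by tier and coordinate prefix
    # (a node at 0-based tier T covers chunk coords sharing c %/% 16^(D-T))
    nodes <- list()
    if (nrow(df) > 0L) for (t in seq_len(D)) {
      span <- 16L^(D - t + 1L)
      nodes[[t]] <- unique(paste(t, df$cx %/% span, df$cy %/% span,
                                 df$cz %/% span, sep = "|"))
    }
    levels_info[[L + 1L]] <- list(df = df, D = D, payloads = payloads,
                                  nodes = nodes)
  }
  header_size <- 4L + 4L + 4L + 12L + 24L + 4L + (4L + length(meta_raw)) +
    nl * (4L + 8L + 4L)
  block_size <- POINTER_FANOUT * 8L
  pos <- header_size
  for (L in seq_len(nl)) {
    info <- levels_info[[L]]
    info$node_off <- list()
    for (t in seq_along(info$nodes)) {
      offs <- stats::setNames(pos + (seq_along(info$nodes[[t]]) - 1L) * block_size,
                              info$nodes[[t]])
      info$node_off[[t]] <- offs
      pos <- pos + length(info$nodes[[t]]) * block_size
    }
    if (nrow(info$df) > 0L) {
      sz <- vapply(info$payloads, length, integer(1)) + 20L
      info$chunk_off <- pos + cumsum(c(0L, head(sz, -1L)))
      pos <- pos + sum(sz)
    } else info$chunk_off <- numeric(0)
    levels_info[[L]] <- info
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VSG1"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(match(vol$value_kind, c("gray8", "rgb24", "id16")) - 1L, con,
           size = 4L, endian = "little")
  writeBin(vol$dims_vx, con, size = 4L, endian = "little")
  writeBin(vol$voxel_size_nm, con, size = 8L, endian = "little")
  writeBin(vol$num_levels, con, size = 4L, endian = "little")
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  for (L in seq_len(nl)) {
    info <- levels_info[[L]]
    root <- if (nrow(info$df) > 0L) info$node_off[[1]][[1]] else 0
    writeBin(nrow(info$df), con, size = 4L, endian = "little")
    writeBin(as.numeric(root), con, size = 8L, endian = "little")
    writeBin(info$D, con, size = 4L, endian = "little")
  }
  for (L in seq_len(nl)) {
    info <- levels_info[[L]]
    df <- info$df; D <- info$D
    for (t in seq_along(info$nodes)) {
      child_span <- 16L^(D - t)                    # chunk span of one slot
      for (key in info$nodes[[t]]) {
        pc <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])[2:4]
        entries <- numeric(POINTER_FANOUT)
        if (t < D) {                               # children are blocks
          ck <- info$nodes[[t + 1L]]
          cm <- do.call(rbind, lapply(strsplit(ck, "|", fixed = TRUE),
                                      function(p) as.integer(p)[2:4]))
          sel <- which(cm[, 1] %/% 16L == pc[1] & cm[, 2] %/% 16L == pc[2] &
                         cm[, 3] %/% 16L == pc[3])
          for (j in sel) {
            s <- cm[j, ] %% 16L
            entries[1L + s[1] + 16L * s[2] + 256L * s[3]] <-
              info$node_off[[t + 1L]][[ck[j]]]
          }
        } else {                                   # leaf tier -> chunk records
          sel <- which(df$cx %/% 16L == pc[1] & df$cy %/% 16L == pc[2] &
                         df$cz %/% 16L == pc[3])
          for (j in sel) {
            s <- c(df$cx[j], df$cy[j], df$cz[j]) %% 16L
            entries[1L + s[1] + 16L * s[2] + 256L * s[3]] <- info$chunk_off[j]
          }
        }
        writeBin(entries, con, size = 8L, endian = "little")
      }
    }
    if (nrow(df) > 0L) for (i in seq_len(nrow(df))) {
      writeBin(c(L - 1L, df$cx[i], df$cy[i], df$cz[i]), con, size = 4L,
               endian = "little")
      writeBin(length(info$payloads[[i]]), con, size = 4L, endian = "little")
      writeBin(info$payloads[[i]], con)
    }
  }
  invisible(path)
}

.read_checked <- function(con, what, n, size, pos_hint) {
  v <- readBin(con, what, n = n, size = size, endian = "little",
               signed = if (size == 2L) FALSE else TRUE)
  if (length(v) != n)
    stop(sprintf("corrupt container: unexpected end of file near offset %.0f",
                 pos_hint))
  v
}

#' @rdname save_segmentation
#' @export
load_segmentation <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 4L)
  if (length(magic) < 4L || !identical(rawToChar(magic), "VSG1"))
    stop("corrupt container: bad magic at offset 0 (expected 'VSG1')")
  version <- .read_checked(con, integer(), 1L, 4L, 4)
  if (version != 1L) stop(sprintf("unsupported container version %d", version))
  kind <- c("gray8", "rgb24", "id16")[.read_checked(con, integer(), 1L, 4L, 8) + 1L]
  dims <- .read_checked(con, integer(), 3L, 4L, 12)
  vs <- .read_checked(con, numeric(), 3L, 8L, 24)
  nl <- .read_checked(con, integer(), 1L, 4L, 48)
  nmeta <- .read_checked(con, integer(), 1L, 4L, 52)
  meta_raw <- readBin(con, raw(), n = nmeta)
  if (length(meta_raw) != nmeta)
    stop("corrupt container: unexpected end of file in metadata block")
  table <- parse_metadata_text(strsplit(rawToChar(meta_raw), "\n")[[1]])
  lv <- vector("list", nl)
  for (L in seq_len(nl))
    lv[[L]] <- list(n = .read_checked(con, integer(), 1L, 4L, 56),
                    root = .read_checked(con, numeric(), 1L, 8L, 60),
                    D = .read_checked(con, integer(), 1L, 4L, 68))
  vol <- create_volume(dims, vs, kind, nl)
  unperm <- .zorder_unperm()
  read_block <- function(off) {
    seek(con, off)
    .read_checked(con, numeric(), POINTER_FANOUT, 8L, off)
  }
  read_chunk <- function(off) {
    seek(con, off)
    hdr <- .read_checked(con, integer(), 4L, 4L, off)
    clen <- .read_checked(con, integer(), 1L, 4L, off + 16)
    comp <- readBin(con, raw(), n = clen)
    if (length(comp) != clen)
      stop(sprintf("corrupt container: truncated chunk record at offset %.0f", off))
    b <- memDecompress(comp, type = "gzip")
    if (length(b) != 3L * CHUNK_VOX)
      stop(sprintf("corrupt container: bad chunk payload at offset %.0f", off))
    v <- readBin(b[seq_len(2L * CHUNK_VOX)], integer(), n = CHUNK_VOX,
                 size = 2L, endian = "little", signed = FALSE)
    m <- as.integer(b[2L * CHUNK_VOX + seq_len(CHUNK_VOX)]) != 0L
    ch <- list(v = array(v[unperm], dim = rep(CHUNK_EDGE, 3)),
               m = array(m[unperm], dim = rep(CHUNK_EDGE, 3)))
    assign(.chunk_key(hdr[1], hdr[2], hdr[3], hdr[4]), ch, envir = vol$chunks)
  }
  for (L in seq_len(nl)) {
    if (lv[[L]]$n == 0L || lv[[L]]$root == 0) next
    walk <- function(off, tier) {
      entries <- read_block(off)
      for (off2 in entries[entries != 0]) {
        if (tier < lv[[L]]$D - 1L) walk(off2, tier + 1L) else read_chunk(off2)
      }
    }
    walk(lv[[L]]$root, 0L)
  }
  list(volume = vol, table = table)
}
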