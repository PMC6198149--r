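#' LRU chunk-cache bookkeeping with dirty-block protection
#'
#' Models the residency contract of a chunk cache: least-recently-used
#' *unmodified* chunks are evicted first, and a modified (dirty) chunk is
#' never discarded — when capacity is exceeded and only dirty chunks
#' remain, they are spilled to a disk-backed store instead of being
#' dropped. `cache_touch()` records a use (optionally marking the chunk
#' modified and optionally attaching a payload); capacity is enforced
#' after every touch.
#'
#' @param capacity_chunks maximum number of resident chunks (>= 1).
#' @param spill_dir directory for spilled dirty payloads (created on
#'   demand; defaults to a session temp directory).
#' @return `cache_create()` returns a `chunk_cache` object.
#' @examples
#' cs <- cache_create(2)
#' cache_touch(cs, "A"); cache_touch(cs, "B"); cache_touch(cs, "C")
#' cache_resident(cs)   # "B" "C" — A was the LRU clean chunk
#' @export
cache_create <- function(capacity_chunks, spill_dir = NULL) {
  capacity_chunks <- as.integer(capacity_chunks)
  if (is.na(capacity_chunks) || capacity_chunks < 1L)
    stop("capacity must be >= 1 chunk")
  cs <- new.env(parent = emptyenv())
  cs$capacity <- capacity_chunks
  cs$resident <- character(0)       # recency order, oldest first
  cs$modified <- character(0)
  cs$spilled <- character(0)
  cs$evicted <- character(0)
  cs$payloads <- new.env(hash = TRUE, parent = emptyenv())
  cs$spill_dir <- spill_dir %||% file.path(tempdir(), "voxann-spill")
  class(cs) <- "chunk_cache"
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cache_create
#' @param cs a `chunk_cache`.
#' @param key chunk key (any string).
#' @param modify flag the chunk as modified (dirty).
#' @param payload optional chunk data kept with the key (spilled to disk
#'   if the dirty chunk overflows the cache).
#' @return `cache_touch()` returns, invisibly, the keys evicted or spilled
#'   by this touch.
#' @export
cache_touch <- function(cs, key, modify = FALSE, payload = NULL) {
  stopifnot(inherits(cs, "chunk_cache"), is.character(key), length(key) == 1L)
  if (key %in% cs$spilled) {      # bring a spilled chunk back in
    cs$spilled <- setdiff(cs$spilled, key)
    f <- file.path(cs$spill_dir, paste0(utils::URLencode(key, reserved = TRUE), ".rds"))
    if (is.null(payload) && file.exists(f)) payload <- readRDS(f)
    if (file.exists(f)) unlink(f)
    modify <- TRUE                # spilled chunks are dirty by definition
  }
  cs$resident <- c(setdiff(cs$resident, key), key)
  if (modify) cs$modified <- union(cs$modified, key)
  if (!is.null(payload)) assign(key, payload, envir = cs$payloads)
  invisible(.cache_enforce(cs))
}

.cache_enforce <- function(cs) {
  out <- character(0)
  while (length(cs$resident) > cs$capacity) {
    clean <- setdiff(cs$resident, cs$modified)
    if (length(clean) > 0L) {
      victim <- cs$resident[match(TRUE, cs$resident %in% clean)]  # LRU clean
      cs$evicted <- c(cs$evicted, victim)
      if (exists(victim, envir = cs$payloads, inherits = FALSE))
        rm(list = victim, envir = cs$payloads)
    } else {
      victim <- cs$resident[1L]   # LRU dirty: spill, never drop
      if (!dir.exists(cs$spill_dir))
        dir.create(cs$spill_dir, recursive = TRUE)
      if (exists(victim, envir = cs$payloads, inherits = FALSE)) {
        saveRDS(get(victim, envir = cs$payloads, inherits = FALSE),
                file.path(cs$spill_dir,
                          paste0(utils::URLencode(victim, reserved = TRUE), ".rds")))
        rm(list = victim, envir = cs$payloads)
      }
      cs$spilled <- c(cs$spilled, victim)
      cs$modified <- setdiff(cs$modified, victim)
    }
    cs$resident <- setdiff(cs$resident, victim)
    out <- c(out, victim)
  }
  out
}

#' Evict chunks to make room
#'
#' Returns the list of chunks removed from residency so that
#' `needed_chunks` more fit within capacity. Clean chunks are evicted in
#' LRU order; dirty chunks are spilled to the disk store, never discarded.
#'
#' @param cs a `chunk_cache`.
#' @param needed_chunks number of additional chunk slots required.
#' @return character vector of evicted/spilled keys.
#' @export
cache_evict <- function(cs, needed_chunks = 0L) {
  stopifnot(inherits(cs, "chunk_cache"))
  target <- max(0L, cs$capacity - as.integer(needed_chunks))
  out <- character(0)
  old_cap <- cs$capacity
  cs$capacity <- target
  out <- .cache_enforce(cs)
  cs$capacity <- old_cap
  out
}

#' @rdname cache_create
#' @export
cache_resident <- function(cs) cs$resident

#' @rdname cache_create
#' @export
cache_modified <- function(cs) cs$modified

#' @rdname cache_create
#' @export
cache_spilled <- function(cs) cs$spilled

#' @export
print.chunk_cache <- function(x, ...) {
  cat(sprintf("<chunk_cache cap %d: %d resident (%d dirty), %d spilled>\n",
              x$capacity, length(x$resident), length(x$modified),
              length(x$spilled)))
  invisible(x)
}
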