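test_that("level geometry follows XY-only halving", {
  v <- create_volume(c(32, 32, 4), value_kind = "gray8", num_levels = 2)
  expect_identical(level_extent(v, 1), c(16L, 16L, 4L))
  v1 <- create_volume(c(1, 1, 1), value_kind = "id16")
  expect_identical(as_array(v1), array(0L, c(1, 1, 1)))
  v5 <- create_volume(c(4096, 4096, 8), value_kind = "gray8", num_levels = 5)
  edges <- sapply(0:4, function(L) level_extent(v5, L)[1])
  expect_identical(edges, c(4096L, 2048L, 1024L, 512L, 256L))
})

test_that("constructor rejects invalid volumes", {
  expect_error(create_volume(c(0, 4, 4)), "positive")
  expect_error(create_volume(c(4, 4, 4), value_kind = "float32"))
  expect_error(create_volume(c(4, 4, 4), value_kind = "gray8",
                             num_levels = 4), "levels")
})

test_that("z-order index interleaves bits x, then y, then z, bijectively", {
  expect_identical(zorder_index(0, 0, 0), 0L)
  expect_identical(zorder_index(1, 0, 0), 1L)
  expect_identical(zorder_index(0, 1, 0), 2L)
  expect_identical(zorder_index(0, 0, 1), 4L)
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  zi <- zorder_index(g$x, g$y, g$z)
  expect_identical(sort(zi), 0:4095)
  expect_error(zorder_index(16, 0, 0), "\\[0, 16\\)")
})

test_that("reads and writes round-trip; empty volumes read zero", {
  v <- create_volume(c(40, 40, 8), value_kind = "gray8", num_levels = 2)
  expect_true(all(read_region(v, 0, c(3, 3, 1, 20, 20, 5)) == 0L))
  expect_identical(n_allocated_chunks(v), 0L)
  write_region(v, 0, c(4, 4, 0, 12, 12, 4), 7L)
  expect_true(all(read_region(v, 0, c(4, 4, 0, 12, 12, 4)) == 7L))
})

test_that("segment ids are capped at 65535", {
  v <- create_volume(c(16, 16, 16), value_kind = "id16")
  expect_silent(write_region(v, 0, c(0, 0, 0, 1, 1, 1), 65535L))
  expect_error(write_region(v, 0, c(0, 0, 0, 1, 1, 1),
                            array(65536, c(1, 1, 1))), "65535")
})

test_that("an aligned 16^3 write allocates exactly one chunk", {
  v <- create_volume(c(64, 64, 16), value_kind = "id16")
  write_region(v, 0, c(16, 16, 0, 32, 32, 16), 1L)
  expect_identical(n_allocated_chunks(v, 0), 1L)
})

test_that("coarse writes replicate to finer levels (authoritative write)", {
  v <- create_volume(c(32, 32, 4), value_kind = "id16", num_levels = 3)
  write_region(v, 1, c(2, 3, 1, 5, 6, 2), 9L)
  a0 <- read_region(v, 0, c(4, 6, 1, 10, 12, 2))
  expect_true(all(a0 == 9L))
  # explicit fine write overrides the inherited coarse value
  write_region(v, 0, c(4, 6, 1, 5, 7, 2), 3L)
  expect_identical(effective_value(v, 0, 4, 6, 1), 3L)
  expect_identical(effective_value(v, 0, 5, 6, 1), 9L)
  # level-2 paint read at level 0 inside the 4x4 footprint
  v2 <- create_volume(c(32, 32, 4), value_kind = "id16", num_levels = 3)
  write_region(v2, 2, c(1, 1, 0, 2, 2, 1), 5L)
  expect_true(all(read_region(v2, 0, c(4, 4, 0, 8, 8, 1)) == 5L))
})

test_that("downsampling uses mean for images, smallest-id majority for labels", {
  g <- create_volume(c(4, 4, 1), value_kind = "gray8", num_levels = 2)
  write_region(g, 0, c(0, 0, 0, 2, 2, 1), array(c(10L, 10L, 20L, 20L), c(2, 2, 1)))
  expect_identical(read_region(g, 1, c(0, 0, 0, 1, 1, 1))[1], 15L)
  s <- create_volume(c(4, 4, 1), value_kind = "id16", num_levels = 2)
  write_region(s, 0, c(0, 0, 0, 2, 2, 1), array(c(5L, 5L, 9L, 0L), c(2, 2, 1)))
  expect_identical(read_region(s, 1, c(0, 0, 0, 1, 1, 1))[1], 5L)
  write_region(s, 0, c(2, 2, 0, 4, 4, 1), array(c(3L, 7L, 7L, 3L), c(2, 2, 1)))
  expect_identical(read_region(s, 1, c(1, 1, 0, 2, 2, 1))[1], 3L)
})

test_that("rgb24 volumes reduce per channel", {
  v <- create_volume(c(2, 2, 1), value_kind = "rgb24", num_levels = 2)
  vals <- rgb24(c(10L, 20L, 30L, 40L), c(0L, 0L, 0L, 0L), c(255L, 255L, 255L, 255L))
  write_region(v, 0, c(0, 0, 0, 2, 2, 1), array(vals, c(2, 2, 1)))
  got <- unpack_rgb24(read_region(v, 1, c(0, 0, 0, 1, 1, 1))[1])
  expect_identical(got$r, 25L)
  expect_identical(got$b, 255L)
})

test_that("reduction is idempotent and inverts replication on constant blocks", {
  v <- create_volume(c(8, 8, 2), value_kind = "id16", num_levels = 2)
  write_region(v, 0, c(0, 0, 0, 8, 8, 2), 4L)
  before <- as_array(v, 1)
  reduce_to_coarser(v, 0)
  expect_identical(as_array(v, 1), before)
  # replication then reduction of a constant coarse block is identity
  v2 <- create_volume(c(8, 8, 2), value_kind = "id16", num_levels = 2)
  write_region(v2, 1, c(0, 0, 0, 4, 4, 2), 6L)
  fine <- as_array(v2, 0)
  write_region(v2, 0, c(0, 0, 0, 8, 8, 2), fine)
  expect_true(all(as_array(v2, 1)[1:4, 1:4, ] == 6L))
})

test_that("erasing everything prunes the volume back to zero chunks", {
  v <- create_volume(c(32, 32, 8), value_kind = "id16", num_levels = 2)
  write_region(v, 0, c(3, 3, 1, 20, 20, 6), 5L)
  expect_gt(n_allocated_chunks(v), 0L)
  write_region(v, 0, c(3, 3, 1, 20, 20, 6), 0L)
  expect_identical(n_allocated_chunks(v), 0L)
  # freeing an all-zero chunk never changes reads
  write_region(v, 0, c(0, 0, 0, 16, 16, 8), 2L)
  snap <- as_array(v, 0)
  prune_chunks(v)
  expect_identical(as_array(v, 0), snap)
})

test_that("random multi-level edit scripts match the dense shadow model", {
  set.seed(42)
  for (rep in 1:8) {
    kind <- if (rep %% 2 == 0) "id16" else "gray8"
    dims <- c(sample(10:24, 1), sample(10:24, 1), sample(3:6, 1))
    nl <- sample(2:3, 1)
    v <- create_volume(dims, value_kind = kind, num_levels = nl)
    sv <- shadow_create(dims, kind, nl)
    for (op in 1:6) {
      L <- sample.int(nl, 1) - 1L
      ext <- level_extent(v, L)
      p0 <- sapply(ext, function(e) sample.int(e, 1) - 1L)
      p1 <- pmin(ext, p0 + sapply(ext, function(e) sample.int(6, 1)))
      bbox <- c(p0, p1)
      d <- p1 - p0
      vals <- array(sample(0:(if (kind == "id16") 9 else 255),
                           prod(d), replace = TRUE), d)
      write_region(v, L, bbox, vals)
      sv <- shadow_write(sv, L, bbox, vals)
    }
    for (L in seq_len(nl) - 1L)
      expect_identical(as_array(v, L), shadow_effective(sv, L),
                       label = sprintf("rep %d level %d", rep, L))
  }
})

test_that("sparsity: chunk count bounded by touched footprint", {
  v <- create_volume(c(256, 256, 64), value_kind = "id16", num_levels = 2)
  write_region(v, 0, c(0, 0, 0, 16, 16, 16), 1L)
  write_region(v, 0, c(240, 240, 48, 256, 256, 64), 2L)
  expect_identical(n_allocated_chunks(v, 0), 2L)
  expect_lte(n_allocated_chunks(v), 4L)   # + one reduced chunk each at level 1
})

test_that("pointer-tree depth is minimal for the chunk grid", {
  v <- create_volume(c(256, 256, 16), value_kind = "id16")
  expect_identical(chunk_grid_dims(v, 0), c(16L, 16L, 1L))
  expect_identical(chunk_index_depth(v, 0), 1L)
  big <- create_volume(c(2^20, 2^20, 100), value_kind = "id16")
  expect_identical(chunk_index_depth(big, 0), 4L)
})
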