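test_that("pen masks are Euclidean disks along the stroke polyline", {
  m1 <- make_pen_mask(pen_stroke(0, c(5, 5), diameter = 1), c(12, 12))
  expect_identical(sum(m1), 1L)
  expect_true(m1[6, 6])
  # diameter 3: all 9 voxels of the 3x3 square (corner distance sqrt(2) <= 1.5)
  m3 <- make_pen_mask(pen_stroke(0, c(5, 5), diameter = 3), c(12, 12))
  expect_identical(sum(m3), 9L)
  m2 <- make_pen_mask(pen_stroke(0, rbind(c(4, 4), c(5, 4)), diameter = 1),
                      c(12, 12))
  expect_identical(sum(m2), 2L)
  # a polyline visits every voxel between distant centers
  ml <- make_pen_mask(pen_stroke(0, rbind(c(0, 0), c(9, 0)), diameter = 1),
                      c(12, 12))
  expect_identical(sum(ml), 10L)
  expect_error(make_pen_mask(pen_stroke(0, c(20, 0)), c(12, 12)), "within")
})

test_that("target modes admit the right voxels", {
  arr <- array(0L, c(8, 8, 1)); arr[1:4, , 1] <- 4L
  v <- volume_from_array(arr, value_kind = "id16")
  tab <- add_segment(add_segment(segment_table(), id = 4), id = 9, parent_id = 4)
  fp <- c(0L, 0L, 0L, 8L, 8L, 1L)
  expect_true(all(target_mask(v, "paint_all", 9, tab, fp)))
  bg <- target_mask(v, "background_only", 9, tab, fp)
  expect_identical(which(bg), which(arr == 0L))
  pa <- target_mask(v, "parent_only", 9, tab, fp)
  expect_identical(which(pa), which(arr == 4L))
  tab2 <- add_segment(segment_table(), id = 5)
  expect_error(target_mask(v, "parent_only", 5, tab2, fp), "parent")
})

test_that("source masks honor value range, picked value and contiguity", {
  # two rooms separated by a high-value wall
  img <- array(10L, c(9, 5, 1)); img[5, , 1] <- 200L
  src <- volume_from_array(img, value_kind = "gray8")
  spec <- mask_spec(source_mode = "value_range", lo = 0, hi = 127)
  m <- source_mask(src, spec, c(1, 2, 0))
  expect_true(all(m[1:4, , 1]))
  expect_false(any(m[5:9, , 1]))         # wall and the other room excluded
  # picked value on a candidate-segment source layer
  cand <- array(0L, c(8, 8, 1)); cand[2:4, 2:4, 1] <- 9L; cand[6:8, 6:8, 1] <- 9L
  sv <- volume_from_array(cand, value_kind = "id16")
  mp <- source_mask(sv, mask_spec(source_mode = "picked_value"), c(2, 2, 0))
  expect_identical(which(mp), which(bfs_component(cand == 9L, c(3, 3, 1))))
  expect_error(source_mask(src, spec, c(4, 2, 0)), "outside the source mask")
})

test_that("random thresholded mazes match a brute-force flood fill", {
  set.seed(31)
  for (rep in 1:10) {
    img <- array(sample(c(10L, 200L), 14 * 14, TRUE, prob = c(0.6, 0.4)),
                 c(14, 14, 1))
    seeds <- which(img[, , 1] <= 127, arr.ind = TRUE)
    s <- seeds[sample.int(nrow(seeds), 1), ]
    src <- volume_from_array(img, value_kind = "gray8")
    m <- source_mask(src, mask_spec(source_mode = "value_range", lo = 0, hi = 127),
                     c(s[1] - 1L, s[2] - 1L, 0))
    expect_identical(which(m), which(bfs_component(img <= 127L, c(s, 1L))))
  }
})

test_that("strokes paint the three-mask intersection", {
  arr <- array(0L, c(16, 16, 2)); arr[1:8, 1:16, 1] <- 7L
  v <- volume_from_array(arr, value_kind = "id16")
  img <- array(10L, c(16, 16, 2)); img[, 9:16, ] <- 200L
  src <- volume_from_array(img, value_kind = "gray8")
  spec <- mask_spec(target_mode = "background_only",
                    source_mode = "value_range", lo = 0, hi = 127)
  # centered stroke: pen disk x target-background x source-low-range
  st <- pen_stroke(0, c(8, 4), diameter = 7, id = 2)
  res <- apply_stroke(v, st, spec, source = src)
  got <- as_array(v)[, , 1]
  pen <- make_pen_mask(st, c(16, 16))
  expected <- pen & (arr[, , 1] == 0L) & (img[, , 1] <= 127L)
  expect_identical(got == 2L, expected)
  expect_identical(res$painted, sum(expected))
  # a stroke entirely outside the source mask paints nothing
  v2 <- volume_from_array(array(0L, c(16, 16, 1)), value_kind = "id16")
  src2 <- volume_from_array(array(200L, c(16, 16, 1)), value_kind = "gray8")
  st2 <- pen_stroke(0, c(3, 3), diameter = 3, id = 2)
  expect_error(apply_stroke(v2, st2, spec, source = src2), "outside")
})

test_that("auto-close fills the interior of a closed contour", {
  v <- volume_from_array(array(0L, c(21, 21, 1)), value_kind = "id16")
  th <- seq(0, 2 * pi, length.out = 80)
  ring <- unique(round(cbind(10 + 6 * cos(th), 10 + 6 * sin(th))))
  st <- pen_stroke(0, rbind(ring, ring[1, ]), diameter = 1, id = 5)
  res <- apply_stroke(v, st, auto_close = TRUE)
  got <- as_array(v)[, , 1]
  expect_gt(res$closed, 0)
  expect_identical(got[11, 11], 5L)               # center filled
  expect_identical(got[1, 1], 0L)                 # outside untouched
  inner <- sum(got == 5L)
  expect_gte(inner, nrow(ring) + res$closed)
})

test_that("painting with background mode never alters nonzero voxels; erase undoes paint", {
  set.seed(32)
  for (rep in 1:10) {
    arr <- array(sample(c(0L, 3L), 12 * 12, TRUE), c(12, 12, 1))
    v <- volume_from_array(arr, value_kind = "id16")
    ctr <- c(sample(0:11, 1), sample(0:11, 1))
    st <- pen_stroke(0, ctr, diameter = 5, id = 8)
    apply_stroke(v, st, mask_spec(target_mode = "background_only"))
    after <- as_array(v)[, , 1]
    expect_true(all(after[arr[, , 1] == 3L] == 3L))
    # erasing exactly the painted set restores the original
    erase <- pen_stroke(0, ctr, diameter = 5, id = 0)
    apply_stroke(v, erase, mask_spec(target_mode = "paint_all"))
    restored <- as_array(v)[, , 1]
    expect_identical(restored[arr[, , 1] == 0L],
                     arr[, , 1][arr[, , 1] == 0L])
  }
})

test_that("Z-gap fill bridges outlines up to the depth bound", {
  # identical disks at z = 0 and z = 8, depth 8: seven sections filled
  v <- create_volume(c(16, 16, 10), value_kind = "id16")
  disk <- make_pen_mask(pen_stroke(0, c(8, 8), diameter = 5, id = 1), c(16, 16))
  for (z in c(0L, 8L))
    write_region(v, 0, c(0, 0, z, 16, 16, z + 1L),
                 array(ifelse(disk, 1L, 0L), c(16, 16, 1)))
  xy <- which(disk, arr.ind = TRUE) - 1L
  n <- zgap_fill(v, xy, 0L, 1L, 8L)
  expect_identical(n, sum(disk) * 7L)
  for (z in 1:7)
    expect_identical(as_array(v)[, , z + 1] == 1L, unname(disk))
  # nearest same-id voxel at distance 9: nothing filled
  v2 <- create_volume(c(8, 8, 12), value_kind = "id16")
  for (z in c(0L, 9L))
    write_region(v2, 0, c(3, 3, z, 4, 4, z + 1L), 1L)
  expect_identical(zgap_fill(v2, cbind(3L, 3L), 0L, 1L, 8L), 0L)
})

test_that("Z-gap fill matches a per-column scan and is monotone in depth", {
  set.seed(33)
  for (rep in 1:8) {
    arr <- array(0L, c(6, 6, 14))
    arr[cbind(sample(1:6, 30, TRUE), sample(1:6, 30, TRUE),
              sample(1:14, 30, TRUE))] <- 1L
    z <- 6L
    arr[, , z + 1L] <- ifelse(matrix(runif(36) < 0.4, 6, 6), 1L, arr[, , z + 1L])
    xy <- which(arr[, , z + 1L] == 1L, arr.ind = TRUE) - 1L
    if (nrow(xy) == 0L) next
    depth <- sample(2:6, 1)
    v <- volume_from_array(arr, value_kind = "id16")
    zgap_fill(v, xy, z, 1L, depth)
    expect_identical(as_array(v), zgap_oracle(arr, xy, z, 1L, depth))
    # monotone: a larger depth fills a superset
    v2 <- volume_from_array(arr, value_kind = "id16")
    zgap_fill(v2, xy, z, 1L, depth + 3L)
    expect_true(all(as_array(v)[as_array(v) == 1L] ==
                      as_array(v2)[as_array(v) == 1L]))
  }
})

test_that("flood fill recolors only the seeded component", {
  arr <- array(0L, c(16, 16, 4))
  arr[2:5, 2:5, 1:2] <- 5L
  arr[10:13, 10:13, 3:4] <- 5L
  v <- volume_from_array(arr, value_kind = "id16")
  n <- flood_fill(v, c(3, 3, 1), 6L)
  expect_identical(n, 32L)
  expect_identical(unname(id_histogram(v, 6)), 32L)
  expect_identical(unname(id_histogram(v, 5)), 32L)
  # diagonal-only contact is not connected under 6-connectivity
  arr2 <- array(0L, c(6, 6, 1)); arr2[1:2, 1:2, 1] <- 4L; arr2[3:4, 3:4, 1] <- 4L
  v2 <- volume_from_array(arr2, value_kind = "id16")
  flood_fill(v2, c(1, 1, 0), 9L)
  expect_identical(unname(id_histogram(v2, 9)), 4L)
  expect_identical(unname(id_histogram(v2, 4)), 4L)
})

test_that("2D fill stays inside the seed section", {
  arr <- array(7L, c(6, 6, 3))
  v <- volume_from_array(arr, value_kind = "id16")
  flood_fill(v, c(2, 2, 1), 8L, dimensionality = "2D")
  expect_true(all(as_array(v)[, , 2] == 8L))
  expect_true(all(as_array(v)[, , c(1, 3)] == 7L))
})

test_that("range-masked fill segments a boundary-map region", {
  img <- array(0L, c(12, 12, 3))
  img[6, , ] <- 255L                              # wall splits the volume
  src <- volume_from_array(img, value_kind = "gray8")
  v <- create_volume(c(12, 12, 3), value_kind = "id16")
  spec <- mask_spec(source_mode = "value_range", lo = 0, hi = 127)
  n <- flood_fill(v, c(1, 1, 0), 3L, spec, source = src)
  expect_identical(n, 5L * 12L * 3L)
  expect_true(all(as_array(v)[1:5, , ] == 3L))
  expect_true(all(as_array(v)[6:12, , ] == 0L))
})

test_that("a masked seed warns and fills nothing", {
  arr <- array(0L, c(6, 6, 1)); arr[3, 3, 1] <- 2L
  v <- volume_from_array(arr, value_kind = "id16")
  expect_warning(n <- flood_fill(v, c(2, 2, 0), 9L,
                                 mask_spec(target_mode = "background_only")),
                 "excluded")
  expect_identical(n, 0L)
})

test_that("picked-value masking copies a source component exactly", {
  set.seed(34)
  for (rep in 1:5) {
    cand <- random_seg_array(c(20, 20, 6), n_blobs = 3, seed = rep * 3)
    src <- volume_from_array(cand, value_kind = "id16")
    tgt <- create_volume(c(20, 20, 6), value_kind = "id16")
    w <- which(cand > 0L, arr.ind = TRUE)
    s <- w[sample.int(nrow(w), 1), ] - 1L
    flood_fill(tgt, s, 1L, mask_spec(source_mode = "picked_value"),
               source = src)
    comp <- bfs_component(cand == cand[s[1] + 1, s[2] + 1, s[3] + 1], s + 1L)
    expect_identical(as_array(tgt) == 1L, comp)
  }
})

test_that("the pipette reads effective values across levels", {
  v <- create_volume(c(16, 16, 2), value_kind = "id16", num_levels = 2)
  expect_identical(pick(v, c(3, 3, 0)), 0L)
  write_region(v, 0, c(2, 2, 0, 4, 4, 1), 6L)
  expect_identical(pick(v, c(3, 3, 0)), 6L)
  v2 <- create_volume(c(16, 16, 2), value_kind = "id16", num_levels = 2)
  write_region(v2, 1, c(1, 1, 0, 3, 3, 1), 4L)
  expect_identical(pick(v2, c(3, 3, 0)), 4L)      # inherited from level 1
})
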