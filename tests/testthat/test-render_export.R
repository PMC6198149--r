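test_that("a single anisotropic voxel meshes to the exact cuboid", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 1L
  v <- volume_from_array(arr, c(6, 6, 30), "id16")
  m <- segment_mesh(v, 1)
  expect_identical(nrow(m$triangles), 12L)
  expect_equal(as.numeric(mesh_area(m)), 2 * (6 * 6) + 4 * (6 * 30))  # 792
  expect_true(is_closed_mesh(m))
  # a 2x1x1 bar loses the shared face: 20 triangles
  arr2 <- array(0L, c(4, 4, 4)); arr2[2:3, 2, 2] <- 1L
  m2 <- segment_mesh(volume_from_array(arr2, c(6, 6, 30), "id16"), 1)
  expect_identical(nrow(m2$triangles), 20L)
  expect_true(is_closed_mesh(m2))
})

test_that("mesh area equals the exposed-face count and meshes stay closed", {
  set.seed(51)
  for (rep in 1:4) {
    arr <- random_seg_array(c(14, 14, 6), n_blobs = 2, seed = rep)
    arr[arr != 1L] <- 0L
    if (!any(arr == 1L)) next
    v <- volume_from_array(arr, c(5, 4, 20), "id16")
    m <- segment_mesh(v, 1)
    # brute-force exposed-face area oracle
    d <- dim(arr); area <- 0
    vs <- c(5, 4, 20)
    face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
    for (i in which(arr == 1L)) {
      co <- arrayInd(i, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + s
        outside <- nb[ax] < 1L || nb[ax] > d[ax]
        if (outside || arr[nb[1], nb[2], nb[3]] != 1L)
          area <- area + face_area[ax]
      }
    }
    expect_equal(as.numeric(mesh_area(m)), area)
    expect_true(is_closed_mesh(m))
  }
})

test_that("mesh orientation encloses the correct signed volume", {
  arr <- array(0L, c(6, 6, 6)); arr[2:4, 2:3, 2:5] <- 1L
  v <- volume_from_array(arr, c(2, 3, 4), "id16")
  m <- segment_mesh(v, 1)
  a <- m$vertices[m$triangles[, 1], , drop = FALSE]
  b <- m$vertices[m$triangles[, 2], , drop = FALSE]
  cc <- m$vertices[m$triangles[, 3], , drop = FALSE]
  sv <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  expect_equal(sv, sum(arr == 1L) * prod(c(2, 3, 4)))   # outward normals
})

test_that("isosurfaces are empty for uniform data and closed for a ball", {
  flat <- volume_from_array(array(100L, c(8, 8, 8)), value_kind = "gray8")
  expect_identical(nrow(isosurface_mesh(flat, 100)$triangles), 0L)
  d <- 20
  co <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  r2 <- (co$x - 10.5)^2 + (co$y - 10.5)^2 + (co$z - 10.5)^2
  ball <- array(ifelse(r2 <= 36, 200L, 0L), c(d, d, d))
  vb <- volume_from_array(ball, value_kind = "gray8")
  m <- isosurface_mesh(vb, 100)
  expect_gt(nrow(m$triangles), 0L)
  expect_true(is_closed_mesh(m))
  expect_identical(nrow(isosurface_mesh(vb, 300)$triangles), 0L)
})

test_that("sphere isosurface area is within 5% of 4*pi*r^2", {
  d <- 44; r <- 16
  co <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  cen <- (d + 1) / 2
  dist <- sqrt((co$x - cen)^2 + (co$y - cen)^2 + (co$z - cen)^2)
  # smooth radial field so linear interpolation lands on the true sphere
  val <- pmax(0, pmin(255, 128 + 8 * (r - dist)))
  vol <- volume_from_array(array(as.integer(round(val)), c(d, d, d)),
                           value_kind = "gray8")
  m <- isosurface_mesh(vol, 127.7)   # off-grid threshold, radius shift < 0.04 vx
  expect_true(is_closed_mesh(m))
  expect_lt(abs(as.numeric(mesh_area(m)) - 4 * pi * r^2) / (4 * pi * r^2), 0.05)
})

test_that("particle clouds count components and place centroids at voxel centers", {
  arr <- array(0L, c(12, 12, 6))
  arr[2:3, 2:3, 2] <- 4L; arr[8:9, 8:9, 3] <- 4L; arr[5, 11, 5] <- 4L
  v <- volume_from_array(arr, c(10, 10, 10), "id16")
  pc <- particle_cloud(v, 4)
  expect_identical(pc$count, 3L)
  expect_identical(max(bfs_label_all(arr == 4L)), 3L)
  # single voxel at (2,2,2) 0-based, 10 nm voxels: centroid (25,25,25)
  a1 <- array(0L, c(5, 5, 5)); a1[3, 3, 3] <- 1L
  pc1 <- particle_cloud(volume_from_array(a1, c(10, 10, 10), "id16"), 1)
  expect_equal(as.vector(pc1$centroids), c(25, 25, 25))
  expect_true(is_closed_mesh(pc1$mesh))
})

test_that("boxes and scale bars have exact geometry", {
  sb <- scalebar_mesh(1000, axis = 1)
  expect_equal(max(sb$vertices[, 1]) - min(sb$vertices[, 1]), 1000)
  expect_identical(nrow(sb$triangles), 12L)
  expect_true(is_closed_mesh(sb))
  solid <- box_mesh(c(0, 0, 0, 2, 2, 2), mode = "solid",
                    voxel_size_nm = c(6, 6, 30))
  expect_identical(nrow(solid$mesh$triangles), 12L)
  expect_equal(max(solid$mesh$vertices[, 3]), 60)
  wf <- box_mesh(c(0, 0, 0, 1, 1, 1), mode = "wireframe")
  expect_identical(nrow(wf$mesh$lines), 12L)
  expect_identical(nrow(wf$mesh$triangles), 0L)
  expect_error(box_mesh(c(0, 0, 0, 0, 2, 2), mode = "solid"), "degenerate")
})

test_that("textured box faces sample the volume sections verbatim", {
  set.seed(52)
  arr <- array(sample(0:255, 8 * 8 * 4, TRUE), c(8, 8, 4))
  v <- volume_from_array(arr, value_kind = "gray8")
  bx <- box_mesh(c(1, 1, 0, 7, 7, 4), vol = v, mode = "textured")
  expect_identical(bx$textures$z0, arr[2:7, 2:7, 1])
  expect_identical(bx$textures$x1, arr[7, 2:7, 1:4])
})

test_that("projections: empty volumes are black, first-hit picks the front voxel", {
  v <- create_volume(c(8, 8, 4), value_kind = "gray8")
  expect_true(all(projection_image(v, "Z", "max") == 0))
  # an id plane at z=1 behind an id plane at z=0? first-hit returns the front
  arr <- array(0L, c(8, 8, 4)); arr[, , 2] <- 3L
  seg <- volume_from_array(arr, value_kind = "id16")
  tab <- add_segment(segment_table(), id = 3, color1 = rgb24(255, 0, 0))
  img <- projection_image(seg, "Z", "first-hit", table = tab)
  expect_true(all(img[, , 1] == 1) && all(img[, , 2] == 0))
  # max projection of gray takes the brightest voxel per ray
  g <- array(0L, c(4, 4, 3)); g[1, 1, 2] <- 200L; g[1, 1, 3] <- 100L
  gm <- projection_image(volume_from_array(g, value_kind = "gray8"), "Z", "max")
  expect_equal(gm[1, 1, 1], 200 / 255)
})

test_that("illumination darkens surfaces tilted away from the light", {
  # hemisphere bulging toward the viewer, light from straight ahead
  d <- 31
  arr <- array(0L, c(d, d, 16))
  cen <- (d + 1) / 2
  for (x in 1:d) for (y in 1:d) {
    r2 <- (x - cen)^2 + (y - cen)^2
    if (r2 <= 12^2) {
      ztop <- 14 - round(sqrt(12^2 - r2) * 14 / 12)
      arr[x, y, (ztop + 1):16] <- 200L
    }
  }
  v <- volume_from_array(arr, value_kind = "gray8")
  img <- projection_image(v, "Z", "illuminated", light = c(0, 0, 1))
  mid <- img[round(cen), round(cen), 1]
  edge <- img[round(cen) + 10, round(cen), 1]
  expect_gt(mid, edge)   # slope increases toward the rim -> darker
})

test_that("compositing honors alpha, selection and pattern endpoints", {
  arr <- array(0L, c(8, 8, 1)); arr[1:4, , 1] <- 1L; arr[5:8, , 1] <- 2L
  seg <- volume_from_array(arr, value_kind = "id16")
  tab <- segment_table()
  tab <- add_segment(tab, id = 1, color1 = rgb24(255, 0, 0),
                     color2 = rgb24(0, 0, 255), pattern = 15)
  tab <- add_segment(tab, id = 2, color1 = rgb24(0, 255, 0))
  # Alpha 0 / SelAlpha 1: only the selected branch is visible
  img <- composite_section(list(layer_view(seg, alpha = 0, sel_alpha = 1,
                                           selected_id = 1)),
                           tab, z = 0)
  expect_true(all(img[1:4, , 1] == 1))
  expect_true(all(img[5:8, , ] == 0))
  # a single opaque image layer passes through verbatim
  gray <- volume_from_array(array(123L, c(8, 8, 1)), value_kind = "gray8")
  gi <- composite_section(list(layer_view(gray, alpha = 1)), NULL, z = 0)
  expect_equal(gi[3, 3, 1], 123 / 255)
  # pattern strength endpoints: 0 -> color1, 1 at an on-pixel -> color2
  i0 <- composite_section(list(layer_view(seg, pattern_strength = 0)), tab, 0)
  expect_equal(i0[2, 2, ], c(1, 0, 0))
  i1 <- composite_section(list(layer_view(seg, pattern_strength = 1)), tab, 0)
  expect_equal(i1[2, 2, ], c(0, 0, 1))   # pattern 15 is all color2
})

test_that("blend modes combine layers as specified", {
  a <- volume_from_array(array(102L, c(4, 4, 1)), value_kind = "gray8")  # 0.4
  b <- volume_from_array(array(51L, c(4, 4, 1)), value_kind = "gray8")   # 0.2
  add <- composite_section(list(layer_view(a), layer_view(b, blend = "add")),
                           NULL, 0)
  expect_equal(add[1, 1, 1], 0.6)
  mul <- composite_section(list(layer_view(a), layer_view(b, blend = "multiply")),
                           NULL, 0)
  expect_equal(mul[1, 1, 1], 0.4 * 0.2)
  half <- composite_section(list(layer_view(a), layer_view(b, alpha = 0.5)),
                            NULL, 0)
  expect_equal(half[1, 1, 1], 0.5 * 0.2 + 0.5 * 0.4)
})

test_that("measurements follow the voxel geometry", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 1L
  v <- volume_from_array(arr, c(6, 6, 30), "id16")
  m <- measure(v, 1)
  expect_identical(m$voxel_count, 1L)
  expect_equal(m$volume_nm3, 1080)
  expect_equal(m$surface_area_nm2, 792)
  expect_identical(m$bbox, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(point_distance(c(0, 0, 0), c(0, 0, 10), c(6, 6, 30)), 300)
  expect_equal(point_distance(c(0, 0, 0), c(1, 1, 0), v), sqrt(72))
  # random blob: volume = count x voxel volume
  set.seed(53)
  arr2 <- random_seg_array(c(16, 16, 6), n_blobs = 2, seed = 5)
  v2 <- volume_from_array(arr2, c(5, 5, 25), "id16")
  m2 <- measure(v2, 1)
  expect_equal(m2$volume_nm3, sum(arr2 == 1L) * 625)
})

test_that("OBJ export writes groups, materials and faces", {
  arr <- array(0L, c(4, 4, 2)); arr[2, 2, 1] <- 1L; arr[3, 3, 2] <- 2L
  v <- volume_from_array(arr, c(6, 6, 30), "id16")
  m <- segment_mesh(v, c(1, 2))
  p <- file.path(tempdir(), "two.obj")
  write_obj(m, p)
  txt <- readLines(p)
  expect_true(any(grepl("^mtllib two\\.mtl", txt)))
  expect_identical(sum(grepl("^g ", txt)), 2L)
  expect_identical(sum(grepl("^f ", txt)), 24L)
  mtl <- readLines(sub("obj$", "mtl", p))
  expect_identical(sum(grepl("^newmtl", mtl)), 2L)
  # empty segment warns
  expect_warning(segment_mesh(v, 99), "no voxels")
})
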