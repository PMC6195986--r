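test_that("threshold is inclusive at the 140 HU cut-off", {
  vol <- ct_volume(array(c(139, 140, 141, -1000, 700, 0, 139.999, 140.0001),
                         c(2, 2, 2)), spacing = rep(1, 3))
  m <- threshold_mask(vol)
  expect_identical(as.vector(m$data),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  air <- ct_volume(array(-1000, c(3, 3, 3)), spacing = rep(1, 3))
  expect_equal(sum(threshold_mask(air)$data), 0)
})

test_that("raising the threshold never adds voxels", {
  set.seed(7)
  vol <- ct_volume(array(stats::runif(6^3, -1000, 2000), c(6, 6, 6)),
                   spacing = rep(1, 3))
  thresholds <- c(-500, 0, 140, 500, 1500)
  counts <- vapply(thresholds, function(t) sum(threshold_mask(vol, t)$data),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(threshold_mask(vol, 500)$data <= threshold_mask(vol, 140)$data))
})

test_that("largest_component keeps the biggest blob and honours the tie-break", {
  a <- array(FALSE, c(6, 6, 6))
  a[1:2, 1:5, 1] <- TRUE  # 10 voxels
  a[5:6, 1:2, 6] <- TRUE  # 4 voxels, far corner
  m <- structure(list(data = a, spacing = rep(1, 3), origin = rep(0, 3)),
                 class = "binary_mask")
  out <- largest_component(m)
  expect_equal(sum(out$data), 10)
  expect_true(all(out$data[1:2, 1:5, 1]))

  single <- m; single$data[] <- FALSE; single$data[2:3, 2:3, 2:3] <- TRUE
  expect_identical(largest_component(single)$data, single$data)

  tie <- m; tie$data[] <- FALSE
  tie$data[1:2, 1:2, 1] <- TRUE # first in linear order
  tie$data[5:6, 5:6, 6] <- TRUE # same size, later
  kept <- largest_component(tie)
  expect_true(all(kept$data[1:2, 1:2, 1]))
  expect_false(any(kept$data[5:6, 5:6, 6]))

  empty <- m; empty$data[] <- FALSE
  expect_error(largest_component(empty), class = "cleftmorph_empty_mask_error")
  expect_error(largest_component(m, connectivity = 8),
               class = "cleftmorph_parameter_error")
})

test_that("6- vs 26-connectivity differ across a diagonal contact", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE
  a[2, 2, 2] <- TRUE
  m <- structure(list(data = a, spacing = rep(1, 3), origin = rep(0, 3)),
                 class = "binary_mask")
  expect_equal(sum(largest_component(m, 26)$data), 2)
  expect_equal(sum(largest_component(m, 6)$data), 1)
})

test_that("iso-surface of a voxelised sphere recovers the analytic area within 2%", {
  mesh <- extract_isosurface(threshold_mask(voxel_sphere(10, 0.5)))
  expect_lt(abs(mesh_surface_area(mesh) / (4 * pi * 100) - 1), 0.02)
})

test_that("iso-surface of a voxelised cube recovers 2400 mm^2 within 2%", {
  mesh <- extract_isosurface(threshold_mask(voxel_cube(10, 0.5)))
  expect_lt(abs(mesh_surface_area(mesh) / 2400 - 1), 0.02)
})

test_that("iso-surface area error shrinks as spacing decreases", {
  err <- vapply(c(1.0, 0.5), function(sp) {
    mesh <- extract_isosurface(threshold_mask(voxel_sphere(10, sp)))
    abs(mesh_surface_area(mesh) / (4 * pi * 100) - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("a uniform volume has no iso-surface", {
  vol <- ct_volume(array(0, c(4, 4, 4)), spacing = rep(1, 3))
  expect_error(extract_isosurface(vol, iso = 140),
               class = "cleftmorph_empty_surface_error")
})

test_that("iso-surfacing a watertight solid gives a closed, consistently wound mesh", {
  mesh <- extract_isosurface(threshold_mask(voxel_sphere(6, 1)))
  expect_length(boundary_loops(mesh), 0)
  # outward orientation: signed volume by divergence theorem is positive
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1], ]; v1 <- v[f[, 2], ]; v2 <- v[f[, 3], ]
  vol6 <- sum(v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
                v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
                v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]))
  expect_gt(vol6 / 6, 0.8 * 4 / 3 * pi * 6^3)
})

test_that("STL round trips preserve geometry at float precision", {
  sq <- unit_square_mesh()
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(sq, pb)
  expect_equal(mesh_surface_area(read_stl(pb)), 1.0, tolerance = 1e-6)

  pa <- withr::local_tempfile(fileext = ".stl")
  write_stl(sq, pa, dialect = "ascii")
  expect_equal(mesh_surface_area(read_stl(pa)),
               mesh_surface_area(read_stl(pb)), tolerance = 1e-5)

  sphere <- make_icosphere(radius = 7.3, subdivisions = 3, center = c(1, -2, 5))
  a0 <- mesh_surface_area(sphere)
  ps <- withr::local_tempfile(fileext = ".stl")
  write_stl(sphere, ps)
  back <- read_stl(ps)
  expect_equal(nrow(back$faces), nrow(sphere$faces))
  expect_lt(abs(mesh_surface_area(back) / a0 - 1), 1e-4)
})

test_that("malformed STL input is rejected", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid junk", "  facet normal 0 0 1", "garbage"), p)
  expect_error(read_stl(p), class = "cleftmorph_format_error")
})
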