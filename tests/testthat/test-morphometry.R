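test_that("mesh_surface_area handles exact, degenerate and empty cases", {
  expect_equal(mesh_surface_area(unit_square_mesh()), 1.0)
  degen <- tri_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                    matrix(c(1, 2, 3), 1))
  expect_equal(mesh_surface_area(degen), 0)
  empty <- tri_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_equal(mesh_surface_area(empty), 0)
})

test_that("icosphere area converges to 4*pi*r^2", {
  sph <- make_icosphere(radius = 10, subdivisions = 4)
  expect_lt(abs(mesh_surface_area(sph) / (4 * pi * 100) - 1), 0.005)
})

test_that("surface area is rigid-motion invariant and scales quadratically", {
  set.seed(42)
  mesh <- make_icosphere(radius = 3, subdivisions = 2)
  a0 <- mesh_surface_area(mesh)
  for (k in 1:5) {
    th <- stats::runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])), c(0, sin(th[2]), cos(th[2])))
    moved <- transform_mesh(mesh, Rz %*% Rx, stats::rnorm(3, sd = 50))
    expect_equal(mesh_surface_area(moved), a0, tolerance = 1e-9)
    s <- stats::runif(1, 0.1, 8)
    scaled <- tri_mesh(mesh$vertices * s, mesh$faces)
    expect_equal(mesh_surface_area(scaled), a0 * s^2, tolerance = 1e-9)
  }
})

test_that("cleft_percentage reproduces every printed case-series percentage exactly", {
  cohort <- example_cohort()
  pct <- cleft_percentage(cohort$cleft_area_mm2, cohort$total_area_mm2)
  expect_identical(pct, c(11L, 34L, 56L, 34L, 60L, 46L, 32L, 20L, 48L, 64L))
})

test_that("percentage rounds half away from zero and validates inputs", {
  expect_identical(cleft_percentage(0.5, 100), 1L)   # 0.5 -> 1
  expect_identical(cleft_percentage(55.5, 100), 56L) # .5 upward
  expect_identical(cleft_percentage(0, 100), 0L)
  expect_identical(cleft_percentage(79, 142), 56L)   # 55.6 -> 56
  expect_error(cleft_percentage(10, 0), class = "cleftmorph_parameter_error")
  expect_error(cleft_percentage(101, 100), class = "cleftmorph_consistency_error")
})

test_that("total palate area sums residual sheet and fills", {
  sq <- unit_square_mesh()
  expect_equal(total_palate_area(sq), 1)
  expect_equal(total_palate_area(sq, list(sq, sq)), 3)
})

test_that("defect extent recovers the dimensions of simple shapes", {
  rect <- grid_sheet_mesh(function(x, y) 0 * x,
                          xs = seq(0, 5, by = 0.25), ys = seq(0, 20, by = 0.25))
  ext <- measure_cleft_extent(rect, long_axis = c(0, 1, 0))
  expect_equal(unname(ext["length"]), 20)
  expect_equal(unname(ext["width_min"]), 5)
  expect_equal(unname(ext["width_max"]), 5)

  # trapezoid widening from 2 to 8 mm over a 15 mm length
  ys <- seq(0, 15, by = 0.2)
  tz <- do.call(rbind, lapply(ys, function(y) {
    w <- 2 + (8 - 2) * y / 15
    cbind(seq(-w / 2, w / 2, length.out = 25), y, 0)
  }))
  nxp <- 25
  idx <- function(i, j) i + (j - 1) * nxp
  i <- rep(seq_len(nxp - 1), length(ys) - 1)
  j <- rep(seq_len(length(ys) - 1), each = nxp - 1)
  trap <- tri_mesh(tz, rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))))
  ext2 <- measure_cleft_extent(trap, long_axis = c(0, 1, 0))
  expect_equal(unname(ext2["length"]), 15)
  # stations keep off the extreme 5% of the length, so the narrowest
  # sampled cross-section sits at y = 0.75 where the width is 2.3
  expect_lt(abs(ext2["width_min"] - 2), 0.4)
  expect_lt(abs(ext2["width_max"] - 8), 0.4)

  flat_line <- tri_mesh(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)),
                        matrix(c(1, 2, 3), 1))
  expect_error(measure_cleft_extent(flat_line, long_axis = c(0, 1, 0)),
               class = "cleftmorph_degenerate_geometry_error")
})

test_that("report CSV mirrors the case table and recomputes percentages", {
  cohort <- example_cohort()
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    cleft_measurement(animal_id = as.character(cohort$dog_no[i]),
                      breed = cohort$breed[i],
                      cleft_area = cohort$cleft_area_mm2[i],
                      total_palate_area = cohort$total_area_mm2[i],
                      n_loops = 1L)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  rep <- build_report(rows, path)
  expect_equal(rep$percentage, c(11L, 34L, 56L, 34L, 60L, 46L, 32L, 20L, 48L, 64L))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 10)
  expect_equal(back$percentage,
               cleft_percentage(back$cleft_area_mm2, back$total_area_mm2))

  empty_path <- withr::local_tempfile(fileext = ".csv")
  build_report(list(), empty_path)
  empty <- readr::read_csv(empty_path, show_col_types = FALSE)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("dog_no", "total_area_mm2", "cleft_area_mm2", "percentage")
                  %in% names(empty)))
})

test_that("measurement records enforce their invariants", {
  expect_error(cleft_measurement("a", cleft_area = 10, total_palate_area = 5),
               class = "cleftmorph_consistency_error")
  expect_error(cleft_measurement("a", cleft_area = 1, total_palate_area = 5,
                                 width_min = 3, width_max = 2),
               class = "cleftmorph_consistency_error")
  m <- cleft_measurement("a", cleft_area = 10, total_palate_area = 40)
  expect_s3_class(m, "tbl_df")
  expect_identical(m$percentage, 25L)
})
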