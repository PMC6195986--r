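test_that("cropping to a covering ROI is the identity; plane cuts split exactly", {
  sphere <- make_icosphere(radius = 5, subdivisions = 3)
  a0 <- mesh_surface_area(sphere)
  whole <- crop_mesh(sphere, roi_box(c(-6, 6), c(-6, 6), c(-6, 6)))
  expect_equal(mesh_surface_area(whole), a0, tolerance = 1e-12)

  sq <- unit_square_mesh()
  left <- crop_mesh(sq, roi_planes(list(list(point = c(0.5, 0, 0),
                                             normal = c(-1, 0, 0)))))
  right <- crop_mesh(sq, roi_planes(list(list(point = c(0.5, 0, 0),
                                              normal = c(1, 0, 0)))))
  expect_equal(mesh_surface_area(left), 0.5, tolerance = 1e-6)
  expect_equal(mesh_surface_area(right), 0.5, tolerance = 1e-6)

  expect_error(crop_mesh(sq, roi_box(c(5, 6), c(5, 6), c(5, 6))),
               class = "cleftmorph_empty_result_error")
  expect_error(roi_box(c(1, 1), c(0, 1), c(0, 1)),
               class = "cleftmorph_parameter_error")
})

test_that("cropping the phantom palate to an analysis window matches the region oracle", {
  spec <- standard_suite()$curved_midline_5mm
  spec$cleft_outlines <- list() # intact shell
  ph <- generate_phantom(spec)
  mesh <- extract_isosurface(largest_component(threshold_mask(ph$volume)))
  box <- ph$truth$palate_box
  # a window 1 mm inside the shell borders, so the crop - not the shell
  # edge - defines the analysed area
  window <- list(x = box$xlim + c(1, -1), y = box$ylim + c(1, -1))
  cropped <- crop_mesh(mesh, roi_box(window$x, window$y, box$zlim + c(-1, 1)))
  sheet <- oral_surface_sheet(cropped)
  oracle <- true_surface_area(spec, cbind(window$x[c(1, 2, 2, 1)],
                                          window$y[c(1, 1, 2, 2)]))
  expect_lt(abs(mesh_surface_area(sheet) / oracle - 1), 0.03)
})

test_that("defect detection separates clefts from sutures and orders loops by area", {
  # one 5 mm cleft plus a sub-millimetre suture slit: exactly one loop
  spec <- phantom_spec(
    name = "cleft_and_suture", a = 0.015,
    cleft_outlines = list(rect_poly_for_tests(-2.5, 2.5, 4, 20)),
    suture_slits = list(list(p0 = c(6, 6), p1 = c(6, 18), width = 0.5)),
    seed = 301L)
  ph <- generate_phantom(spec)
  mask <- largest_component(threshold_mask(ph$volume))
  loops <- detect_defect_boundary(extract_isosurface(mask),
                                  wall_mesh = extract_isosurface(mask, smooth_iterations = 3))
  expect_length(loops, 1)

  # intact palate: no loops at all
  phc <- cached_phantom("intact_control_sutures")
  maskc <- largest_component(threshold_mask(phc$volume))
  expect_length(detect_defect_boundary(extract_isosurface(maskc)), 0)

  # two disjoint clefts: two loops, larger projected area first
  mb <- cached_measurement("curved_bilateral_4_3mm")
  fills <- attr(mb, "fills")
  expect_length(fills, 2)
  areas <- vapply(fills, function(f) f$boundary$projected_area, numeric(1))
  expect_true(areas[1] > areas[2])
})

test_that("patch fitting reproduces plane and quadratic sheets to 1e-6 mm", {
  xs <- seq(-10, 10, by = 0.4)
  ys <- seq(0, 20, by = 0.4)
  probe <- cbind(rep(seq(0.1, 0.9, length.out = 25), 25),
                 rep(seq(0.1, 0.9, length.out = 25), each = 25))

  plane_f <- function(x, y) 0.3 * x - 0.1 * y + 2
  mesh_p <- grid_sheet_mesh(plane_f, xs, ys)
  patch_p <- fit_fill_patch(mesh_p, ellipse_loop3d(plane_f), support_band_mm = 30)
  Sp <- eval_patch(patch_p, probe)
  expect_lt(max(abs(Sp[, 3] - plane_f(Sp[, 1], Sp[, 2]))), 1e-6)

  quad_f <- function(x, y) 0.02 * x^2
  mesh_q <- grid_sheet_mesh(quad_f, xs, ys)
  patch_q <- fit_fill_patch(mesh_q, ellipse_loop3d(quad_f), support_band_mm = 30)
  Sq <- eval_patch(patch_q, probe)
  expect_lt(max(abs(Sq[, 3] - quad_f(Sq[, 1], Sq[, 2]))), 1e-6)
  expect_lt(attr(patch_q, "rms_fit"), 1e-6)
})

test_that("fit fails loudly without support and converges on phantom clefts", {
  tiny <- grid_sheet_mesh(function(x, y) 0 * x, seq(-1, 1, 1), seq(0, 2, 1))
  expect_error(fit_fill_patch(tiny, ellipse_loop3d(function(x, y) 0 * x)),
               class = "cleftmorph_insufficient_support_error")

  meas <- cached_measurement("curved_midline_5mm")
  fill <- attr(meas, "fills")[[1]]
  expect_lte(fill$rms_fit, 0.2)
  truth <- cached_phantom("curved_midline_5mm")$truth
  expect_lt(abs(mesh_surface_area(fill$fill_mesh) / truth$cleft_area_true - 1), 0.03)
})

test_that("tessellation area converges and matches quadrature on a quadratic sheet", {
  # planar unit-square patch: area exactly 1
  ctrl <- array(0, c(4, 4, 3))
  g <- seq(0, 1, length.out = 4)
  ctrl[, , 1] <- matrix(rep(g, 4), 4)
  ctrl[, , 2] <- matrix(rep(g, each = 4), 4)
  flat <- surface_patch(ctrl)
  expect_equal(mesh_surface_area(tessellate_patch(flat, 32)), 1, tolerance = 1e-9)

  # z = x^2 over [0,1]^2: area = integral of sqrt(1 + 4 x^2)
  quad_f <- function(x, y) x^2
  mesh_q <- grid_sheet_mesh(quad_f, seq(-0.2, 1.2, by = 0.05), seq(-0.2, 1.2, by = 0.05))
  sq_loop <- rbind(cbind(seq(0, 1, 0.01), 0), cbind(1, seq(0, 1, 0.01)),
                   cbind(seq(1, 0, -0.01), 1), cbind(0, seq(1, 0, -0.01)))
  sq_loop <- sq_loop[!duplicated(sq_loop), ]
  bl <- boundary_loop(cbind(sq_loop, quad_f(sq_loop[, 1], sq_loop[, 2])))
  patch <- fit_fill_patch(mesh_q, bl, support_band_mm = 3)
  trimmed64 <- trim_to_outline(tessellate_patch(patch, 64), bl)
  target <- stats::integrate(function(x) sqrt(1 + 4 * x^2), 0, 1)$value
  expect_lt(abs(mesh_surface_area(trimmed64) / target - 1), 0.005)

  trimmed128 <- trim_to_outline(tessellate_patch(patch, 128), bl)
  expect_lt(abs(mesh_surface_area(trimmed128) / mesh_surface_area(trimmed64) - 1),
            0.005)
  expect_error(tessellate_patch(patch, 1), class = "cleftmorph_parameter_error")
})

test_that("trimming keeps the outline, never adds area, and respects the planar bound", {
  ctrl <- array(0, c(4, 4, 3))
  g <- seq(0, 10, length.out = 4)
  ctrl[, , 1] <- matrix(rep(g, 4), 4)
  ctrl[, , 2] <- matrix(rep(g, each = 4), 4)
  flat <- surface_patch(ctrl)
  tess <- tessellate_patch(flat, 64)

  # full-domain outline: identity up to the domain edge
  full <- trim_to_outline(tess, cbind(c(0.001, 0.999, 0.999, 0.001),
                                      c(0.001, 0.001, 0.999, 0.999)))
  expect_equal(mesh_surface_area(full), mesh_surface_area(tess), tolerance = 0.01)

  # centred 5 mm square on the 10 mm patch: 25 mm^2
  sq <- trim_to_outline(tess, cbind(c(0.25, 0.75, 0.75, 0.25),
                                    c(0.25, 0.25, 0.75, 0.75)))
  expect_lt(abs(mesh_surface_area(sq) / 25 - 1), 0.01)

  for (nm in c("curved_midline_5mm", "curved_midline_10mm")) {
    fill <- attr(cached_measurement(nm), "fills")[[1]]
    trimmed <- mesh_surface_area(fill$fill_mesh)
    expect_lte(trimmed, mesh_surface_area(fill$untrimmed_mesh))
    # a curved patch cannot beat the planar area of its outline projection
    pr <- fill$boundary$projected_area
    expect_gte(trimmed, 0.999 * pr)
  }

  bow <- cbind(c(0.2, 0.8, 0.2, 0.8), c(0.2, 0.8, 0.8, 0.2))
  expect_error(trim_to_outline(tess, bow), class = "cleftmorph_geometry_error")
})

test_that("identical inputs give bitwise-identical fill results", {
  ph <- cached_phantom("curved_midline_2mm")
  run_once <- function() {
    mask <- largest_component(threshold_mask(ph$volume))
    mesh <- extract_isosurface(mask)
    sheet <- oral_surface_sheet(mesh)
    lp <- detect_defect_boundary(mesh,
                                 wall_mesh = extract_isosurface(mask, smooth_iterations = 3))[[1]]
    fill_defect(sheet, lp)
  }
  f1 <- run_once()
  f2 <- run_once()
  expect_identical(f1$patch$control, f2$patch$control)
  expect_identical(f1$fill_mesh$vertices, f2$fill_mesh$vertices)
  expect_identical(f1$rms_fit, f2$rms_fit)
})

test_that("tidy and glance summarise fill results", {
  fill <- attr(cached_measurement("curved_midline_5mm"), "fills")[[1]]
  td <- tidy(fill)
  expect_s3_class(td, "tbl_df")
  expect_true(td$fill_area_mm2 <= td$untrimmed_area_mm2)
  gl <- glance(fill)
  expect_identical(gl$n_control_u, 8L)
  expect_identical(gl$degree_u, 3L)
})
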