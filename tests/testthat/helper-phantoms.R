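# Shared fixtures. Pipeline runs on the phantom suite are expensive, so
# they are generated once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cached_phantom <- function(name, noise_sd = 0) {
  key <- paste0("ph_", name, "_", noise_sd)
  memo(key, {
    spec <- standard_suite()[[name]]
    spec$noise_sd <- noise_sd
    generate_phantom(spec)
  })
}

cached_measurement <- function(name, noise_sd = 0) {
  key <- paste0("meas_", name, "_", noise_sd)
  memo(key, {
    ph <- cached_phantom(name, noise_sd)
    run_pipeline(ph$volume, animal_id = name)
  })
}

# oral-sheet area of the cleft-free twin of a suite phantom
cached_intact_twin_area <- function(name) {
  key <- paste0("twin_", name)
  memo(key, {
    spec <- standard_suite()[[name]]
    spec$cleft_outlines <- list()
    spec$suture_slits <- list()
    ph <- generate_phantom(spec)
    mesh <- extract_isosurface(largest_component(threshold_mask(ph$volume)))
    mesh_surface_area(oral_surface_sheet(mesh))
  })
}

# binary voxelised solid, cell-centred grid
voxelise_solid <- function(inside_fn, spacing, lim = 12,
                           hu_in = 700, hu_out = -1000) {
  g <- seq(-lim + spacing / 2, lim, by = spacing)
  n <- length(g)
  zz <- rep(g, times = n * n)
  yy <- rep(rep(g, each = n), times = n)
  xx <- rep(g, each = n * n)
  hu <- ifelse(inside_fn(xx, yy, zz), hu_in, hu_out)
  ct_volume(array(hu, c(n, n, n)), spacing = rep(spacing, 3),
            origin = rep(g[1], 3))
}

voxel_sphere <- function(radius = 10, spacing = 0.5) {
  voxelise_solid(function(x, y, z) x^2 + y^2 + z^2 <= radius^2, spacing)
}

voxel_cube <- function(half = 10, spacing = 0.5) {
  voxelise_solid(function(x, y, z) {
    abs(x) <= half & abs(y) <= half & abs(z) <= half
  }, spacing)
}

# regular open sheet mesh z = f(x, y) on a grid, for patch-fitting tests
grid_sheet_mesh <- function(f, xs, ys) {
  pts <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)))
  v <- cbind(pts, f(pts[, 1], pts[, 2]))
  nx <- length(xs)
  idx <- function(i, j) i + (j - 1L) * nx
  i <- rep(seq_len(nx - 1L), length(ys) - 1L)
  j <- rep(seq_len(length(ys) - 1L), each = nx - 1L)
  tri_mesh(v, rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                    cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))))
}

ellipse_loop3d <- function(f, cx = 0, cy = 10, rx = 4, ry = 6, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(cx + rx * cos(th), cy + ry * sin(th))
  boundary_loop(cbind(xy, f(xy[, 1], xy[, 2])))
}

rect_poly_for_tests <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

unit_square_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}
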