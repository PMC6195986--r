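#' Specification of a synthetic palate CT phantom
#'
#' The phantom emulates the imaging substrate of a neonatal hard palate: a
#' thin bony shell of thickness `thickness` following the parabolic cylinder
#' `z = a * x^2` over the domain `(x, y) in [-X, X] x [0, Y]` (x transverse,
#' y rostro-caudal, z dorsal), embedded in a soft-tissue margin with air
#' beyond. Clefts are simple polygons in the `(x, y)` plane removed through
#' the full shell thickness; unfused sutures are narrow through-gaps along a
#' line segment (capsule shape of the given width). Bone sits well above the
#' 140 HU segmentation cut-off, soft tissue well below, so thresholding is
#' separable by construction; optional additive Gaussian noise exercises
#' robustness.
#'
#' @param name Label for the phantom.
#' @param a Shell curvature in 1/mm (`0` gives a flat sheet).
#' @param X Half-extent of the shell in x (mm).
#' @param Y Extent of the shell in y (mm).
#' @param thickness Shell thickness in mm (> 0).
#' @param cleft_outlines List of simple polygons (`n x 2` matrices of
#'   `(x, y)` mm) strictly inside the sheet domain.
#' @param suture_slits List of `list(p0 =, p1 =, width =)` line-segment gaps
#'   (mm).
#' @param hu_bone,hu_soft,hu_air Tissue HU values; `hu_bone >= 140 > hu_soft`
#'   is required so the threshold separates bone.
#' @param spacing Isotropic voxel size in mm.
#' @param noise_sd Additive Gaussian noise SD in HU (0 = noise free).
#' @param seed Integer seed controlling the noise realisation.
#' @param margin_soft,margin_air Soft-tissue and air padding in mm.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(name = "phantom", a = 0.015, X = 10, Y = 24,
                         thickness = 1.6, cleft_outlines = list(),
                         suture_slits = list(), hu_bone = 700, hu_soft = 40,
                         hu_air = -1000, spacing = 0.5, noise_sd = 0,
                         seed = 1L, margin_soft = 2, margin_air = 1.5) {
  if (thickness <= 0) {
    abort_cleftmorph("shell thickness must be > 0", "cleftmorph_spec_error")
  }
  if (!(hu_bone >= 140 && hu_soft < 140)) {
    abort_cleftmorph("need hu_bone >= 140 > hu_soft for threshold separability",
                     "cleftmorph_spec_error")
  }
  if (spacing <= 0) abort_cleftmorph("spacing must be > 0", "cleftmorph_spec_error")
  cleft_outlines <- lapply(cleft_outlines, function(p) {
    p <- matrix(as.numeric(p), ncol = 2)
    if (nrow(p) < 3) abort_cleftmorph("cleft polygon needs >= 3 points",
                                      "cleftmorph_spec_error")
    if (any(p[, 1] < -X) || any(p[, 1] > X) || any(p[, 2] < 0) || any(p[, 2] > Y)) {
      abort_cleftmorph("cleft polygon outside the sheet domain",
                       "cleftmorph_spec_error")
    }
    if (!is_simple_polygon(p)) {
      abort_cleftmorph("cleft polygon must be simple (non-self-intersecting)",
                       "cleftmorph_spec_error")
    }
    p
  })
  structure(
    list(name = name, a = a, X = X, Y = Y, thickness = thickness,
         cleft_outlines = cleft_outlines, suture_slits = suture_slits,
         hu_bone = hu_bone, hu_soft = hu_soft, hu_air = hu_air,
         spacing = spacing, noise_sd = noise_sd, seed = as.integer(seed),
         margin_soft = margin_soft, margin_air = margin_air),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': a=%g/mm, %gx%g mm, t=%g mm, %d cleft(s), %d suture slit(s), spacing %g mm, noise %g HU\n",
              x$name, x$a, 2 * x$X, x$Y, x$thickness, length(x$cleft_outlines),
              length(x$suture_slits), x$spacing, x$noise_sd))
  invisible(x)
}

# segment-intersection based simplicity check for small polygons
is_simple_polygon <- function(p) {
  is.null(polygon_find_crossing(p))
}

# first pair of properly crossing (non-adjacent) edges, or NULL
polygon_find_crossing <- function(p) {
  n <- nrow(p)
  if (n < 3) return(c(1L, 1L))
  p2 <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  ax <- p[, 1]; ay <- p[, 2]; bx <- p2[, 1]; by <- p2[, 2]
  cross2 <- function(ox, oy, axx, ayy, bxx, byy) {
    (axx - ox) * (byy - oy) - (ayy - oy) * (bxx - ox)
  }
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)] # adjacent around the wrap
    if (!length(j)) next
    d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
    d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
    d3 <- cross2(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
    d4 <- cross2(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
    hit <- ((d1 > 0) != (d2 > 0)) & ((d3 > 0) != (d4 > 0))
    if (any(hit)) return(c(i, j[which(hit)[1]]))
  }
  NULL
}

point_in_polygon <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

dist_point_segment <- function(x, y, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - p0[1]) * vx + (y - p0[2]) * vy) / len2))
  sqrt((x - (p0[1] + t * vx))^2 + (y - (p0[2] + t * vy))^2)
}

#' Generate a CT phantom volume with ground truth
#'
#' Voxel membership uses the voxel-centre rule: a voxel is bone iff its
#' centre lies inside the thickened shell and outside every cleft polygon
#' and suture slit; voxels within the soft margin of the shell's bounding
#' box are soft tissue and everything else is air. Gaussian noise (if any)
#' is generated from the spec's seed, so identical specs give bitwise
#' identical volumes; the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()]), `truth` (a
#'   `ground_truth` list: `cleft_area_true`, `palate_area_true`,
#'   `percentage_true`, `widths_true`, `lengths_true`, `bone_voxel_count`,
#'   `palate_box`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$margin_soft + spec$margin_air
  sp <- spec$spacing
  zmax_shell <- spec$a * spec$X^2 + spec$thickness
  xr <- c(-spec$X - m, spec$X + m)
  yr <- c(-m, spec$Y + m)
  zr <- c(-m, zmax_shell + m)
  # cell-centred grid: voxel centres sit half a voxel inside the range ends,
  # so phantom feature edges never coincide exactly with voxel centres
  xs <- seq(xr[1] + sp / 2, xr[2], by = sp)
  ys <- seq(yr[1] + sp / 2, yr[2], by = sp)
  zs <- seq(zr[1] + sp / 2, zr[2], by = sp)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  # flat (z,y,x) index grids of voxel-centre coordinates
  zz <- rep(zs, times = ny * nx)
  yy <- rep(rep(ys, each = nz), times = nx)
  xx <- rep(xs, each = nz * ny)

  zsurf <- spec$a * xx^2
  in_shell <- xx >= -spec$X & xx <= spec$X & yy >= 0 & yy <= spec$Y &
    zz >= zsurf & zz <= zsurf + spec$thickness
  in_gap <- rep(FALSE, length(xx))
  for (poly in spec$cleft_outlines) {
    in_gap <- in_gap | point_in_polygon(xx, yy, poly)
  }
  for (sl in spec$suture_slits) {
    in_gap <- in_gap | (dist_point_segment(xx, yy, sl$p0, sl$p1) <= sl$width / 2)
  }
  bone <- in_shell & !in_gap

  soft_box <- xx >= -spec$X - spec$margin_soft & xx <= spec$X + spec$margin_soft &
    yy >= -spec$margin_soft & yy <= spec$Y + spec$margin_soft &
    zz >= -spec$margin_soft & zz <= zmax_shell + spec$margin_soft

  hu <- rep(spec$hu_air, length(xx))
  hu[soft_box] <- spec$hu_soft
  hu[bone] <- spec$hu_bone
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), sd = spec$noise_sd)
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  vol <- ct_volume(array(hu, c(nz, ny, nx)), spacing = c(sp, sp, sp),
                   origin = c(zs[1], ys[1], xs[1]))

  cleft_area_true <- vapply(spec$cleft_outlines, function(poly) {
    true_surface_area(spec, poly)
  }, numeric(1))
  palate_area_true <- true_surface_area(spec)
  widths_true <- lapply(spec$cleft_outlines, polygon_width_range)
  lengths_true <- vapply(spec$cleft_outlines, function(p) diff(range(p[, 2])),
                         numeric(1))
  truth <- list(
    cleft_area_true = cleft_area_true,
    palate_area_true = palate_area_true,
    percentage_true = if (length(cleft_area_true)) {
      cleft_percentage(sum(cleft_area_true), palate_area_true)
    } else 0L,
    widths_true = widths_true,
    lengths_true = lengths_true,
    bone_voxel_count = sum(bone),
    palate_box = list(xlim = c(-spec$X, spec$X), ylim = c(0, spec$Y),
                      zlim = c(0, zmax_shell))
  )
  list(volume = vol, truth = truth, spec = spec)
}

# min/max transverse (x) width of a polygon over y stations
polygon_width_range <- function(poly, n_stations = 200) {
  yr <- range(poly[, 2])
  ys <- seq(yr[1] + 1e-9, yr[2] - 1e-9, length.out = n_stations)
  widths <- vapply(ys, function(y) {
    xs <- polygon_scanline(poly, y)
    if (length(xs) < 2) return(NA_real_)
    diff(range(xs))
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  c(min = min(widths), max = max(widths))
}

# x coordinates where the horizontal line at y crosses polygon edges
polygon_scanline <- function(poly, y) {
  n <- nrow(poly)
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  hits <- numeric(0)
  for (i in seq_len(n)) {
    y1 <- poly[i, 2]; y2 <- p2[i, 2]
    if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
      t <- (y - y1) / (y2 - y1)
      hits <- c(hits, poly[i, 1] + t * (p2[i, 1] - poly[i, 1]))
    }
  }
  sort(hits)
}

#' Curved-surface area oracle for the parabolic sheet
#'
#' Computes the true area of the phantom's oral surface over a region:
#' `integral of sqrt(1 + 4 a^2 x^2) dx dy`. The y-extent of the region at
#' each x is resolved exactly by polygon scanlines, and the remaining 1-D
#' integral is evaluated by composite Simpson quadrature with successive
#' refinement until two refinements agree to `tol` relative.
#'
#' @param spec A [phantom_spec()] (supplies curvature and domain).
#' @param region `n x 2` polygon in `(x, y)` mm, or `NULL` for the full
#'   sheet domain.
#' @param tol Relative refinement tolerance (default 1e-8).
#' @return Area in mm^2.
#' @export
true_surface_area <- function(spec, region = NULL, tol = 1e-8) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$a
  g <- function(x) sqrt(1 + 4 * a^2 * x^2)
  if (is.null(region)) {
    # closed-form-free path: chord length is constant Y
    h <- function(x) rep(spec$Y, length(x))
    xr <- c(-spec$X, spec$X)
  } else {
    region <- matrix(as.numeric(region), ncol = 2)
    if (!is_simple_polygon(region)) {
      abort_cleftmorph("region polygon must be simple", "cleftmorph_geometry_error")
    }
    h <- function(x) {
      vapply(x, function(xi) {
        ys <- polygon_scanline(region[, 2:1, drop = FALSE], xi) # scan in x
        if (length(ys) < 2) return(0)
        sum(ys[seq(2, length(ys), by = 2)] - ys[seq(1, length(ys) - 1, by = 2)])
      }, numeric(1))
    }
    xr <- range(region[, 1])
  }
  f <- function(x) g(x) * h(x)
  # nudge the end nodes inside the region so scanlines never run exactly
  # along a polygon edge (where the chord is ill-defined)
  eps <- 1e-9 * max(diff(xr), 1)
  simpson <- function(n) {
    xs <- seq(xr[1], xr[2], length.out = n + 1)
    xs[1] <- xs[1] + eps
    xs[n + 1] <- xs[n + 1] - eps
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f(xs)) * (xr[2] - xr[1]) / (3 * n)
  }
  prev <- simpson(64)
  n <- 128
  repeat {
    cur <- simpson(n)
    if (abs(cur - prev) <= tol * max(abs(cur), 1e-12) || n >= 2^16) break
    prev <- cur
    n <- n * 2
  }
  cur
}

#' Closed-form area of a parabolic strip
#'
#' Antiderivative check for the quadrature oracle: the area of
#' `z = a x^2` over `[x0, x1] x [0, width]` is
#' `width * [x sqrt(1 + 4 a^2 x^2) / 2 + asinh(2 a x) / (4 a)]` evaluated at
#' the strip ends (flat limit `width * (x1 - x0)` as `a -> 0`).
#'
#' @param a Curvature (1/mm).
#' @param x0,x1 Strip extent in x (mm).
#' @param width Strip extent in y (mm).
#' @return Area in mm^2.
#' @export
parabolic_strip_area <- function(a, x0, x1, width) {
  if (a == 0) return(width * (x1 - x0))
  F <- function(x) x * sqrt(1 + 4 * a^2 * x^2) / 2 + asinh(2 * a * x) / (4 * a)
  width * (F(x1) - F(x0))
}

rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Deterministic phantom fixture suite
#'
#' A fixed set of phantoms spanning the study conditions: flat and curved
#' shells; cleft widths 2, 5 and 10 mm (bracketing the 2.1-9.6 mm range
#' reported for real clefts); unilateral, bilateral and midline outlines; an
#' intact control carrying only sub-millimetre suture slits; and voxel
#' spacings 0.5 mm (the scanner's slice thickness) and 1.0 mm. Every member
#' regenerates identically from its stored seed.
#'
#' @return Named list of [phantom_spec()] objects.
#' @export
standard_suite <- function() {
  long_rect <- function(w, x_mid = 0) rect_poly(x_mid - w / 2, x_mid + w / 2, 4, 20)
  specs <- list(
    phantom_spec("flat_midline_5mm", a = 0,
                 cleft_outlines = list(long_rect(5)), seed = 101L),
    phantom_spec("curved_midline_5mm", a = 0.015,
                 cleft_outlines = list(long_rect(5)), seed = 102L),
    phantom_spec("curved_midline_2mm", a = 0.015,
                 cleft_outlines = list(long_rect(2)), seed = 103L),
    phantom_spec("curved_midline_10mm", a = 0.015,
                 cleft_outlines = list(long_rect(10)), seed = 104L),
    phantom_spec("curved_unilateral_5mm", a = 0.015,
                 cleft_outlines = list(long_rect(5, x_mid = 4.5)), seed = 105L),
    phantom_spec("curved_bilateral_4_3mm", a = 0.015,
                 cleft_outlines = list(long_rect(4, x_mid = -5),
                                       long_rect(3, x_mid = 5)), seed = 106L),
    phantom_spec("intact_control_sutures", a = 0.015,
                 suture_slits = list(
                   list(p0 = c(0, 5), p1 = c(0, 19), width = 0.5),
                   list(p0 = c(-8, 12), p1 = c(-3, 12), width = 0.5)),
                 seed = 107L),
    phantom_spec("curved_midline_5mm_coarse", a = 0.015, thickness = 2.4,
                 cleft_outlines = list(long_rect(5)), spacing = 1.0,
                 seed = 108L)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
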