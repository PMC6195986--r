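#' Tensor-product spline surface patch
#'
#' A rational tensor-product B-spline (NURBS) surface: a grid of 3-D
#' control points with positive weights, clamped knot vectors, and a degree
#' per parametric direction. With all weights equal to 1 (the default, and
#' what the automated fit produces) the surface is an ordinary B-spline
#' patch; the rational form is kept in the type so weighted control nets
#' evaluate correctly.
#'
#' @param control `nu x nv x 3` array of control points (mm).
#' @param degree Length-2 integer degrees `(u, v)`.
#' @param weights `nu x nv` matrix of positive weights (default all 1).
#' @param knots_u,knots_v Clamped knot vectors; default open-uniform on
#'   `[0, 1]`.
#' @return A `surface_patch` object.
#' @export
surface_patch <- function(control, degree = c(3, 3), weights = NULL,
                          knots_u = NULL, knots_v = NULL) {
  stopifnot(length(dim(control)) == 3L, dim(control)[3] == 3L)
  nu <- dim(control)[1]; nv <- dim(control)[2]
  degree <- rep_len(as.integer(degree), 2L)
  if (any(degree < 1L) || nu < degree[1] + 1L || nv < degree[2] + 1L) {
    abort_cleftmorph("control grid too small for the requested degree",
                     "cleftmorph_parameter_error")
  }
  if (is.null(knots_u)) knots_u <- clamped_knots(nu, degree[1])
  if (is.null(knots_v)) knots_v <- clamped_knots(nv, degree[2])
  check_knots(knots_u, nu, degree[1], "u")
  check_knots(knots_v, nv, degree[2], "v")
  if (is.null(weights)) weights <- matrix(1, nu, nv)
  if (any(weights <= 0)) {
    abort_cleftmorph("NURBS weights must be positive", "cleftmorph_parameter_error")
  }
  structure(list(control = control, degree = degree, weights = weights,
                 knots_u = knots_u, knots_v = knots_v),
            class = "surface_patch")
}

clamped_knots <- function(n_ctrl, degree) {
  n_int <- n_ctrl - degree - 1L
  c(rep(0, degree + 1L),
    if (n_int > 0) seq_len(n_int) / (n_int + 1L),
    rep(1, degree + 1L))
}

check_knots <- function(knots, n_ctrl, degree, dir) {
  if (length(knots) != n_ctrl + degree + 1L) {
    abort_cleftmorph(sprintf("knot vector %s has wrong length", dir),
                     "cleftmorph_parameter_error")
  }
  if (any(diff(knots) < 0)) {
    abort_cleftmorph(sprintf("knot vector %s must be non-decreasing", dir),
                     "cleftmorph_parameter_error")
  }
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> degree (%d,%d), %d x %d control points%s\n",
              x$degree[1], x$degree[2], dim(x$control)[1], dim(x$control)[2],
              if (!is.null(attr(x, "rms_fit"))) {
                sprintf(", rms_fit %.4f mm", attr(x, "rms_fit"))
              } else ""))
  invisible(x)
}

bspline_basis <- function(x, knots, degree, deriv = 0L) {
  x <- pmin(pmax(x, knots[1]), knots[length(knots)])
  # splineDesign rejects x exactly at the right end unless nudged inside
  eps <- 1e-12 * max(1, abs(knots[length(knots)]))
  x[x >= knots[length(knots)]] <- knots[length(knots)] - eps
  splines::splineDesign(knots, x, ord = degree + 1L,
                        derivs = rep(deriv, length(x)))
}

#' Evaluate a surface patch at scattered parameters
#'
#' @param patch A [surface_patch()].
#' @param uv `n x 2` matrix of parameters in `[0, 1]^2`.
#' @param derivs If TRUE also return first partials.
#' @return `n x 3` matrix of points, or a list `S`, `Su`, `Sv`.
#' @export
eval_patch <- function(patch, uv, derivs = FALSE) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  Bu <- bspline_basis(uv[, 1], patch$knots_u, patch$degree[1])
  Bv <- bspline_basis(uv[, 2], patch$knots_v, patch$degree[2])
  W <- patch$weights
  den <- rowSums((Bu %*% W) * Bv)
  S <- matrix(0, nrow(uv), 3)
  num <- vector("list", 3)
  for (d in 1:3) {
    num[[d]] <- rowSums((Bu %*% (W * patch$control[, , d])) * Bv)
    S[, d] <- num[[d]] / den
  }
  if (!derivs) return(S)
  dBu <- bspline_basis(uv[, 1], patch$knots_u, patch$degree[1], deriv = 1L)
  dBv <- bspline_basis(uv[, 2], patch$knots_v, patch$degree[2], deriv = 1L)
  den_u <- rowSums((dBu %*% W) * Bv)
  den_v <- rowSums((Bu %*% W) * dBv)
  Su <- Sv <- matrix(0, nrow(uv), 3)
  for (d in 1:3) {
    num_u <- rowSums((dBu %*% (W * patch$control[, , d])) * Bv)
    num_v <- rowSums((Bu %*% (W * patch$control[, , d])) * dBv)
    Su[, d] <- (num_u * den - num[[d]] * den_u) / den^2
    Sv[, d] <- (num_v * den - num[[d]] * den_v) / den^2
  }
  list(S = S, Su = Su, Sv = Sv)
}

# tensor collocation matrix for scattered (u,v): n x (nu*nv), u index fastest
tensor_basis <- function(patch_like, uv) {
  Bu <- bspline_basis(uv[, 1], patch_like$knots_u, patch_like$degree[1])
  Bv <- bspline_basis(uv[, 2], patch_like$knots_v, patch_like$degree[2])
  nu <- ncol(Bu); nv <- ncol(Bv)
  Bu[, rep(seq_len(nu), nv), drop = FALSE] *
    Bv[, rep(seq_len(nv), each = nu), drop = FALSE]
}

# Third-order smoothness penalty on the control net, the discrete analogue
# of penalizing all third partial derivatives. Each windowed difference row
# is constructed to annihilate the exact B-spline control vectors of
# polynomials below its order, so any surface quadratic in the parameters
# lies exactly in the penalty null space and is reproduced unchanged at any
# penalty weight, while higher-frequency wiggle is damped strongly.

# exact control vector of x -> x^p in the given spline space
ctrl_of_poly <- function(knots, degree, p) {
  n <- length(knots) - degree - 1L
  xs <- seq(knots[1], knots[length(knots)], length.out = max(4L * n, 40L))
  B <- bspline_basis(xs, knots, degree)
  qr.solve(crossprod(B), crossprod(B, xs^p))
}

poly_annihilator <- function(knots, degree, k) {
  n <- length(knots) - degree - 1L
  if (n <= k) return(matrix(0, 0, n))
  basis_ctrl <- vapply(0:k, function(p) ctrl_of_poly(knots, degree, p),
                       numeric(n)) # n x (k+1); last column scales the rows
  D <- matrix(0, n - k, n)
  for (j in seq_len(n - k)) {
    A <- t(basis_ctrl[j:(j + k), 1:k, drop = FALSE]) # k x (k+1)
    v <- svd(A, nu = 0, nv = k + 1)$v[, k + 1]
    sc <- sum(v * basis_ctrl[j:(j + k), k + 1])
    if (abs(sc) > 1e-12) v <- v / sc # normalize like a divided difference
    D[j, j:(j + k)] <- v
  }
  D
}

smoothness_penalty <- function(knots_u, knots_v, degree_u, degree_v) {
  nu <- length(knots_u) - degree_u - 1L
  nv <- length(knots_v) - degree_v - 1L
  Du <- lapply(1:3, function(k) poly_annihilator(knots_u, degree_u, k))
  Dv <- lapply(1:3, function(k) poly_annihilator(knots_v, degree_v, k))
  kronecker(diag(nv), crossprod(Du[[3]])) +
    3 * kronecker(crossprod(Dv[[1]]), crossprod(Du[[2]])) +
    3 * kronecker(crossprod(Dv[[2]]), crossprod(Du[[1]])) +
    kronecker(crossprod(Dv[[3]]), diag(nu))
}

# local frame + affine parameterization used by the fit
make_fit_frame <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; e3 <- sv$v[, 3]
  p1 <- drop(sweep(pts, 2, ctr) %*% e1)
  p2 <- drop(sweep(pts, 2, ctr) %*% e2)
  pad1 <- 0.02 * diff(range(p1)); pad2 <- 0.02 * diff(range(p2))
  list(center = ctr, e1 = e1, e2 = e2, e3 = e3,
       o1 = min(p1) - pad1, s1 = diff(range(p1)) + 2 * pad1,
       o2 = min(p2) - pad2, s2 = diff(range(p2)) + 2 * pad2)
}

frame_uv <- function(frame, pts) {
  p1 <- drop(sweep(pts, 2, frame$center) %*% frame$e1)
  p2 <- drop(sweep(pts, 2, frame$center) %*% frame$e2)
  cbind((p1 - frame$o1) / frame$s1, (p2 - frame$o2) / frame$s2)
}

# two Newton steps of closest-point (foot-point) projection
footpoint_refine <- function(patch, pts, uv, steps = 2L) {
  for (s in seq_len(steps)) {
    ev <- eval_patch(patch, uv, derivs = TRUE)
    r <- ev$S - pts
    a11 <- rowSums(ev$Su^2); a22 <- rowSums(ev$Sv^2); a12 <- rowSums(ev$Su * ev$Sv)
    b1 <- -rowSums(r * ev$Su); b2 <- -rowSums(r * ev$Sv)
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-14] <- 1e-14
    du <- (b1 * a22 - b2 * a12) / det
    dv <- (b2 * a11 - b1 * a12) / det
    # damp steps to at most 1/4 of the domain to keep the update stable
    du <- pmin(pmax(du, -0.25), 0.25)
    dv <- pmin(pmax(dv, -0.25), 0.25)
    uv <- cbind(pmin(pmax(uv[, 1] + du, 0), 1), pmin(pmax(uv[, 2] + dv, 0), 1))
  }
  uv
}

#' Fit a spline patch that virtually fills a cleft
#'
#' Automated counterpart of interactive knot editing: a penalized
#' least-squares tensor-product spline surface is fitted to the palate
#' around the defect and iterated to convergence. The data are the oral
#' sheet vertices within `support_band_mm` of the defect outline plus the
#' outline itself (resampled and up-weighted until it is interpolated to
#' `rms_tol`); the objective adds a thin-plate smoothness penalty on the
#' control net, which also governs the smooth continuation across the
#' data-free hole interior. Each iteration re-parameterizes all data points
#' by closest-point projection onto the current surface and re-solves;
#' iteration stops when the fit RMS improves by less than 1% or after
#' `max_iter` iterations. The procedure is fully deterministic.
#'
#' @param palate_mesh A [tri_mesh()]: the oral-surface sheet, or a closed
#'   palate surface (the sheet is extracted automatically when the mesh has
#'   no boundary).
#' @param boundary A [boundary_loop()] on the sheet.
#' @param support_band_mm Width of the support band around the outline (mm).
#' @param degree Spline degree in both directions.
#' @param control_grid Control-net size `(nu, nv)`.
#' @param rms_tol Target boundary interpolation RMS (mm).
#' @param max_iter Maximum re-parameterization iterations.
#' @param lambda Relative smoothness-penalty weight (third-difference
#'   penalty; quadratic surfaces are reproduced exactly at any weight).
#' @param dorsal_axis,max_tilt_deg Passed to [oral_surface_sheet()] when the
#'   sheet must be extracted.
#' @return A [surface_patch()] with attributes `rms_fit` (mm),
#'   `boundary_rms` (mm), `iterations`, `frame` and `boundary_uv`.
#' @export
fit_fill_patch <- function(palate_mesh, boundary, support_band_mm = 3.0,
                           degree = 3, control_grid = c(8, 8), rms_tol = 0.2,
                           max_iter = 50, lambda = 1,
                           dorsal_axis = c(0, 0, 1), max_tilt_deg = 60) {
  stopifnot(inherits(palate_mesh, "tri_mesh"), inherits(boundary, "boundary_loop"))
  sheet <- if (nrow(cpp_boundary_edges(palate_mesh$faces)) == 0) {
    oral_surface_sheet(palate_mesh, dorsal_axis, max_tilt_deg)
  } else palate_mesh

  loop_pts <- boundary$points
  edge <- median_edge_length(sheet)
  loop_dense <- resample_closed_polyline(loop_pts,
                                         max(min(edge, support_band_mm / 4), 1e-3))
  # support band: sheet vertices within the band distance of the outline
  vd <- min_dist_to_points(sheet$vertices, loop_dense)
  support <- sheet$vertices[vd <= support_band_mm, , drop = FALSE]
  nu <- control_grid[1]; nv <- control_grid[2]
  if (nrow(support) < nu * nv) {
    abort_cleftmorph(sprintf("support band has %d points; need at least %d",
                             nrow(support), nu * nv),
                     "cleftmorph_insufficient_support_error")
  }
  # keep the caller's boundary samples when dense (resampling would replace
  # surface points by chord points); densify sparse loops
  loop_fit <- if (nrow(loop_pts) >= 100L) {
    loop_pts
  } else {
    resample_closed_polyline(loop_pts, polyline_length(loop_pts) / 100L)
  }

  pts <- rbind(support, loop_fit)
  is_loop <- c(rep(FALSE, nrow(support)), rep(TRUE, nrow(loop_fit)))
  frame <- make_fit_frame(pts)
  uv <- frame_uv(frame, pts)

  proto <- list(knots_u = clamped_knots(nu, degree),
                knots_v = clamped_knots(nv, degree),
                degree = rep(degree, 2L))
  P <- smoothness_penalty(proto$knots_u, proto$knots_v, degree, degree)
  boundary_weight <- 10
  w <- ifelse(is_loop, boundary_weight, 1)

  solve_patch <- function(uv, w, lam) {
    B <- tensor_basis(proto, uv)
    BtWB <- crossprod(B * sqrt(w))
    scale <- sum(diag(BtWB)) / max(sum(diag(P)), 1)
    M <- BtWB + (lam * scale) * P + 1e-10 * mean(diag(BtWB)) * diag(nu * nv)
    ctrl <- array(0, c(nu, nv, 3))
    for (d in 1:3) {
      rhs <- crossprod(B, w * pts[, d])
      ctrl[, , d] <- matrix(solve(M, rhs), nu, nv)
    }
    surface_patch(ctrl, degree = c(degree, degree),
                  knots_u = proto$knots_u, knots_v = proto$knots_v)
  }

  rms_of <- function(patch, uv, subset = TRUE) {
    r <- eval_patch(patch, uv) - pts
    sqrt(mean(rowSums(r^2)[subset]))
  }

  patch <- solve_patch(uv, w, lambda)
  rms <- rms_of(patch, uv)
  iterations <- 1L
  escalations <- 0L
  while (iterations < max_iter) {
    uv_new <- footpoint_refine(patch, pts, uv)
    patch_new <- solve_patch(uv_new, w, lambda)
    rms_new <- rms_of(patch_new, uv_new)
    improved <- (rms - rms_new) > 0.01 * rms
    if (rms_new <= rms) {
      uv <- uv_new; patch <- patch_new; rms <- rms_new
    }
    iterations <- iterations + 1L
    if (!improved) {
      brms <- rms_of(patch, uv, subset = is_loop)
      if (brms > rms_tol && escalations < 3L) {
        escalations <- escalations + 1L
        boundary_weight <- boundary_weight * 10
        w <- ifelse(is_loop, boundary_weight, 1)
        patch <- solve_patch(uv, w, lambda)
        rms <- rms_of(patch, uv)
        next
      }
      break
    }
  }
  boundary_rms <- rms_of(patch, uv, subset = is_loop)
  if (iterations >= max_iter && rms > 5 * rms_tol) {
    abort_cleftmorph(sprintf("patch fit did not converge: rms %.3f mm after %d iterations",
                             rms, iterations),
                     "cleftmorph_fit_failure_error")
  }
  # foot-point parameters of the original outline points, for trimming
  uv_loop <- footpoint_refine(patch, loop_pts, frame_uv(frame, loop_pts), steps = 3L)
  attr(patch, "rms_fit") <- rms
  attr(patch, "boundary_rms") <- boundary_rms
  attr(patch, "iterations") <- iterations
  attr(patch, "frame") <- frame
  attr(patch, "boundary_uv") <- uv_loop
  patch
}

polyline_length <- function(points) {
  closed <- rbind(points, points[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(closed)^2)))
}

min_dist_to_points <- function(pts, ref, chunk = 2048L) {
  out <- numeric(nrow(pts))
  rx <- ref[, 1]; ry <- ref[, 2]; rz <- ref[, 3]
  for (i0 in seq(1L, nrow(pts), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(pts))
    d2 <- outer(pts[i0:i1, 1], rx, "-")^2 +
      outer(pts[i0:i1, 2], ry, "-")^2 +
      outer(pts[i0:i1, 3], rz, "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Tessellate a surface patch into a triangle mesh
#'
#' Evaluates the patch on a regular `samples_per_direction` square grid of
#' the parametric domain and triangulates each cell. The returned mesh
#' carries the parameter coordinates (`$uv`) and the generating patch
#' (`$patch`) so it can be trimmed in parameter space.
#'
#' @param patch A [surface_patch()].
#' @param samples_per_direction Grid resolution (>= 2) per direction.
#' @return A [tri_mesh()] with extra fields `uv` and `patch`.
#' @export
tessellate_patch <- function(patch, samples_per_direction = 64) {
  stopifnot(inherits(patch, "surface_patch"))
  n <- as.integer(samples_per_direction)
  if (n < 2L) {
    abort_cleftmorph("samples_per_direction must be >= 2",
                     "cleftmorph_parameter_error")
  }
  g <- seq(0, 1, length.out = n)
  uv <- cbind(rep(g, times = n), rep(g, each = n)) # u fastest
  V <- eval_patch(patch, uv)
  idx <- function(i, j) i + (j - 1L) * n
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  mesh <- tri_mesh(V, rbind(f1, f2))
  mesh$uv <- uv
  mesh$patch <- patch
  mesh
}

#' Trim a tessellated fill patch to the defect outline
#'
#' Projects the outline into the patch's parametric domain by closest-point
#' projection and keeps the part of the tessellation inside it: fully
#' interior triangles are kept, fully exterior ones dropped, and triangles
#' straddling the outline are recursively subdivided (4-to-1, up to
#' `max_depth` levels) with leaf triangles kept by the centroid rule, so
#' the trimmed boundary tracks the outline to a fraction of a tessellation
#' edge. Trimming never adds area.
#'
#' @param fill_mesh A mesh from [tessellate_patch()] (carries `uv` and
#'   `patch`).
#' @param boundary A [boundary_loop()], or an `n x 2` matrix of parametric
#'   outline coordinates.
#' @param max_depth Subdivision depth for straddling triangles.
#' @return The trimmed [tri_mesh()].
#' @export
trim_to_outline <- function(fill_mesh, boundary, max_depth = 3) {
  stopifnot(inherits(fill_mesh, "tri_mesh"))
  if (is.null(fill_mesh$uv) || is.null(fill_mesh$patch)) {
    abort_cleftmorph("fill_mesh must come from tessellate_patch()",
                     "cleftmorph_parameter_error")
  }
  patch <- fill_mesh$patch
  if (inherits(boundary, "boundary_loop")) {
    uv0 <- attr(patch, "boundary_uv")
    outline <- if (!is.null(uv0) && nrow(uv0) == nrow(boundary$points)) {
      uv0
    } else {
      seed <- closest_grid_params(patch, boundary$points)
      footpoint_refine(patch, boundary$points, seed, steps = 3L)
    }
  } else {
    outline <- matrix(as.numeric(boundary), ncol = 2)
  }
  outline <- dedupe_polyline(outline)
  # voxel-scale jitter can introduce local self-crossings; untangle them by
  # dropping one endpoint of a crossing segment pair, then smoothing, and
  # only declare the outline invalid if crossings persist
  tries <- 0L
  repeat {
    cross_pair <- polygon_find_crossing(outline)
    if (is.null(cross_pair)) break
    if (tries >= 25L || nrow(outline) < 8L) {
      abort_cleftmorph("projected outline is self-intersecting",
                       "cleftmorph_geometry_error")
    }
    outline <- dedupe_polyline(outline[-cross_pair[2], , drop = FALSE])
    tries <- tries + 1L
  }
  uv <- fill_mesh$uv
  faces <- fill_mesh$faces
  inside <- point_in_polygon(uv[, 1], uv[, 2], outline)
  tri_uv <- list()
  emit <- function(p1, p2, p3) tri_uv[[length(tri_uv) + 1L]] <<- rbind(p1, p2, p3)
  subdivide <- function(p1, p2, p3, depth) {
    cen <- (p1 + p2 + p3) / 3
    ins <- point_in_polygon(c(p1[1], p2[1], p3[1], cen[1]),
                            c(p1[2], p2[2], p3[2], cen[2]), outline)
    if (all(ins)) { emit(p1, p2, p3); return(invisible()) }
    if (!any(ins)) return(invisible())
    if (depth >= max_depth) {
      if (ins[4]) emit(p1, p2, p3)
      return(invisible())
    }
    m12 <- (p1 + p2) / 2; m23 <- (p2 + p3) / 2; m31 <- (p3 + p1) / 2
    subdivide(p1, m12, m31, depth + 1L)
    subdivide(m12, p2, m23, depth + 1L)
    subdivide(m31, m23, p3, depth + 1L)
    subdivide(m12, m23, m31, depth + 1L)
  }
  for (fi in seq_len(nrow(faces))) {
    v <- faces[fi, ]
    ins <- inside[v]
    if (all(ins)) {
      emit(uv[v[1], ], uv[v[2], ], uv[v[3], ])
    } else {
      subdivide(uv[v[1], ], uv[v[2], ], uv[v[3], ], 0L)
    }
  }
  if (!length(tri_uv)) {
    abort_cleftmorph("outline retains no part of the patch",
                     "cleftmorph_empty_result_error")
  }
  alluv <- do.call(rbind, tri_uv)
  key <- paste(round(alluv[, 1], 10), round(alluv[, 2], 10))
  uid <- match(key, unique(key))
  uuv <- alluv[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  V <- eval_patch(patch, uuv)
  out <- tri_mesh(V, f[ok, , drop = FALSE])
  out$uv <- uuv
  out$patch <- patch
  out
}

closest_grid_params <- function(patch, pts, n_grid = 48L) {
  g <- seq(0, 1, length.out = n_grid)
  uvg <- cbind(rep(g, times = n_grid), rep(g, each = n_grid))
  S <- eval_patch(patch, uvg)
  idx <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (S[, 1] - pts[i, 1])^2 + (S[, 2] - pts[i, 2])^2 + (S[, 3] - pts[i, 3])^2
    idx[i] <- which.min(d2)
  }
  uvg[idx, , drop = FALSE]
}

dedupe_polyline <- function(p) {
  if (nrow(p) > 1) {
    d <- sqrt(rowSums((p - rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]))^2))
    p <- p[d > 1e-12, , drop = FALSE]
  }
  p
}

decimate_polyline <- function(p, n_max) {
  if (nrow(p) <= n_max) return(p)
  p[unique(round(seq(1, nrow(p), length.out = n_max))), , drop = FALSE]
}

#' Fill one detected defect
#'
#' Convenience wrapper chaining [fit_fill_patch()], [tessellate_patch()] and
#' [trim_to_outline()] for a single outline.
#'
#' @inheritParams fit_fill_patch
#' @param samples_per_direction Tessellation resolution.
#' @param ... Passed on to [fit_fill_patch()].
#' @return A `fill_result`: list with `patch`, `fill_mesh` (trimmed),
#'   `untrimmed_mesh`, `rms_fit` (mm), `iterations` and `boundary`.
#' @export
fill_defect <- function(palate_mesh, boundary, samples_per_direction = 64, ...) {
  patch <- fit_fill_patch(palate_mesh, boundary, ...)
  untrimmed <- tessellate_patch(patch, samples_per_direction)
  trimmed <- trim_to_outline(untrimmed, boundary)
  structure(
    list(patch = patch, fill_mesh = trimmed, untrimmed_mesh = untrimmed,
         rms_fit = attr(patch, "rms_fit"), iterations = attr(patch, "iterations"),
         boundary = boundary),
    class = "fill_result"
  )
}

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf("<fill_result> fill area %.2f mm^2, rms_fit %.4f mm, %d iterations\n",
              mesh_surface_area(x$fill_mesh), x$rms_fit, x$iterations))
  invisible(x)
}

#' @export
tidy.fill_result <- function(x, ...) {
  tibble::tibble(
    fill_area_mm2 = mesh_surface_area(x$fill_mesh),
    untrimmed_area_mm2 = mesh_surface_area(x$untrimmed_mesh),
    boundary_points = nrow(x$boundary$points),
    rms_fit_mm = x$rms_fit,
    boundary_rms_mm = attr(x$patch, "boundary_rms"),
    iterations = x$iterations
  )
}

#' @export
glance.fill_result <- function(x, ...) {
  tibble::tibble(
    degree_u = x$patch$degree[1],
    degree_v = x$patch$degree[2],
    n_control_u = dim(x$patch$control)[1],
    n_control_v = dim(x$patch$control)[2],
    rms_fit_mm = x$rms_fit,
    iterations = x$iterations
  )
}

#' Export a surface patch as a JSON control-net document
#'
#' @param patch A [surface_patch()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_patch_json <- function(patch, path) {
  stopifnot(inherits(patch, "surface_patch"))
  doc <- list(
    degree = patch$degree,
    knots_u = patch$knots_u,
    knots_v = patch$knots_v,
    weights = patch$weights,
    control = lapply(1:3, function(d) patch$control[, , d])
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
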