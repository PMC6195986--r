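#' Regions of interest for mesh cropping
#'
#' Three ROI flavours are supported by [crop_mesh()]: an axis-aligned box in
#' world mm, a set of cutting half-spaces (keep the side each normal points
#' to; faces straddling a plane are split at it), or an explicit face-index
#' set.
#'
#' @param xlim,ylim,zlim Length-2 numeric ranges (mm) with positive extent.
#' @return An ROI object.
#' @export
roi_box <- function(xlim, ylim, zlim) {
  if (diff(xlim) <= 0 || diff(ylim) <= 0 || diff(zlim) <= 0) {
    abort_cleftmorph("ROI box must have positive extent in all axes",
                     "cleftmorph_parameter_error")
  }
  structure(list(xlim = xlim, ylim = ylim, zlim = zlim),
            class = c("roi_box", "roi"))
}

#' @rdname roi_box
#' @param planes List of `list(point =, normal =)` half-spaces; a face is
#'   kept where `dot(x - point, normal) >= 0`.
#' @export
roi_planes <- function(planes) {
  for (pl in planes) {
    if (sqrt(sum(pl$normal^2)) <= 0) {
      abort_cleftmorph("plane normal must be non-zero", "cleftmorph_parameter_error")
    }
  }
  structure(list(planes = planes), class = c("roi_planes", "roi"))
}

#' @rdname roi_box
#' @param face_indices Integer vector of faces to keep.
#' @export
roi_faces <- function(face_indices) {
  structure(list(face_indices = as.integer(face_indices)),
            class = c("roi_faces", "roi"))
}

#' Crop a mesh to a region of interest
#'
#' The automated counterpart of interactive knife-and-select trimming: box
#' and face-set ROIs keep faces whose centroid lies inside; cutting-plane
#' ROIs additionally split straddling triangles exactly at each plane.
#'
#' @param mesh A [tri_mesh()].
#' @param roi An ROI from [roi_box()], [roi_planes()] or [roi_faces()].
#' @return The cropped [tri_mesh()].
#' @export
crop_mesh <- function(mesh, roi) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0) {
    abort_cleftmorph("mesh is empty", "cleftmorph_empty_result_error")
  }
  out <- if (inherits(roi, "roi_box")) {
    cen <- face_centroids(mesh)
    keep <- cen[, 1] >= roi$xlim[1] & cen[, 1] <= roi$xlim[2] &
      cen[, 2] >= roi$ylim[1] & cen[, 2] <= roi$ylim[2] &
      cen[, 3] >= roi$zlim[1] & cen[, 3] <= roi$zlim[2]
    subset_faces(mesh, keep)
  } else if (inherits(roi, "roi_planes")) {
    m <- mesh
    for (pl in roi$planes) m <- clip_mesh_halfspace(m, pl$point, pl$normal)
    m
  } else if (inherits(roi, "roi_faces")) {
    keep <- rep(FALSE, nrow(mesh$faces))
    keep[roi$face_indices] <- TRUE
    subset_faces(mesh, keep)
  } else {
    abort_cleftmorph("unknown ROI type", "cleftmorph_parameter_error")
  }
  if (nrow(out$faces) == 0) {
    abort_cleftmorph("ROI retains no faces", "cleftmorph_empty_result_error")
  }
  out
}

# Sutherland-Hodgman clip of every triangle against one half-space
clip_mesh_halfspace <- function(mesh, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  d <- drop(sweep(mesh$vertices, 2, point) %*% normal)
  verts <- list()
  faces <- list()
  nf <- nrow(mesh$faces)
  vcount <- 0L
  add_vert <- function(p) {
    vcount <<- vcount + 1L
    verts[[vcount]] <<- p
    vcount
  }
  for (i in seq_len(nf)) {
    idx <- mesh$faces[i, ]
    di <- d[idx]
    if (all(di >= 0)) {
      faces[[length(faces) + 1L]] <- rbind(mesh$vertices[idx[1], ],
                                           mesh$vertices[idx[2], ],
                                           mesh$vertices[idx[3], ])
      next
    }
    if (all(di < 0)) next
    poly <- mesh$vertices[idx, , drop = FALSE]
    dd <- di
    out_poly <- list()
    np <- 3L
    for (e in seq_len(np)) {
      a <- poly[e, ]; b <- poly[e %% np + 1, ]
      da <- dd[e]; db <- dd[e %% np + 1]
      if (da >= 0) out_poly[[length(out_poly) + 1L]] <- a
      if ((da >= 0) != (db >= 0)) {
        t <- da / (da - db)
        out_poly[[length(out_poly) + 1L]] <- a + t * (b - a)
      }
    }
    if (length(out_poly) >= 3) {
      pm <- do.call(rbind, out_poly)
      for (k in 2:(nrow(pm) - 1)) {
        faces[[length(faces) + 1L]] <- pm[c(1, k, k + 1), , drop = FALSE]
      }
    }
  }
  if (!length(faces)) return(tri_mesh(matrix(numeric(0), ncol = 3),
                                      matrix(integer(0), ncol = 3)))
  allv <- do.call(rbind, faces)
  key <- paste(signif(allv[, 1], 12), signif(allv[, 2], 12), signif(allv[, 3], 12))
  uid <- match(key, unique(key))
  uverts <- allv[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  tri_mesh(uverts, f[ok, , drop = FALSE])
}

#' Extract the oral (ventral) surface sheet of a palate mesh
#'
#' Areas are measured on the oral side of the bony palate. Faces whose
#' outward normal points sufficiently ventrally (within `max_tilt_deg` of
#' the negative dorsal axis, default 60 degrees) are kept, and the largest
#' connected sheet of such faces (by area) is returned. The cap excludes
#' the near-vertical walls of cleft margins and cut borders while keeping
#' the curved palatal surface itself.
#'
#' @param mesh A [tri_mesh()] (typically the cropped bone surface).
#' @param dorsal_axis Unit vector pointing dorsally; default `(0, 0, 1)`.
#' @param max_tilt_deg Maximum tilt from the ventral direction, degrees.
#' @return A [tri_mesh()] of the oral sheet.
#' @export
oral_surface_sheet <- function(mesh, dorsal_axis = c(0, 0, 1), max_tilt_deg = 60) {
  stopifnot(inherits(mesh, "tri_mesh"))
  dorsal_axis <- dorsal_axis / sqrt(sum(dorsal_axis^2))
  nrm <- face_normals(mesh)
  keep <- drop(nrm %*% dorsal_axis) < -cos(max_tilt_deg * pi / 180)
  if (!any(keep)) {
    abort_cleftmorph("no ventral-facing faces found", "cleftmorph_empty_result_error")
  }
  sub <- subset_faces(mesh, keep)
  comp <- cpp_face_components(sub$faces, nrow(sub$vertices))
  areas <- face_areas(sub)
  by_comp <- tapply(areas, comp, sum)
  best <- as.integer(names(by_comp)[which.max(by_comp)])
  subset_faces(sub, comp == best)
}

#' Boundary loops of an open mesh
#'
#' Chains the mesh's boundary edges (edges used by exactly one face) into
#' closed vertex cycles, following the faces' winding.
#'
#' @param mesh A [tri_mesh()].
#' @return List of integer vertex-index cycles.
#' @export
boundary_loops <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  be <- cpp_boundary_edges(mesh$faces)
  if (nrow(be) == 0) return(list())
  nxt <- split(be[, 2], be[, 1])
  used <- rep(FALSE, nrow(be))
  edge_id <- split(seq_len(nrow(be)), be[, 1])
  loops <- list()
  for (start_edge in seq_len(nrow(be))) {
    if (used[start_edge]) next
    loop <- integer(0)
    a <- be[start_edge, 1]
    cur_edge <- start_edge
    repeat {
      used[cur_edge] <- TRUE
      loop <- c(loop, a)
      b <- be[cur_edge, 2]
      cand <- edge_id[[as.character(b)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur_edge <- cand[1]
      a <- b
    }
    if (length(loop) >= 3) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Closed boundary polyline
#'
#' An ordered, implicitly closed 3-D polyline (first point is not repeated
#' at the end) with at least 3 points and no consecutive duplicates, plus
#' its signed area when projected perpendicular to the dorsal axis.
#'
#' @param points `n x 3` matrix of mm coordinates.
#' @param dorsal_axis Dorsal direction used for the projected area.
#' @return A `boundary_loop` object.
#' @export
boundary_loop <- function(points, dorsal_axis = c(0, 0, 1)) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) > 1 &&
      sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-12) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) >= 2) {
    d <- sqrt(rowSums((points - rbind(points[-1, , drop = FALSE],
                                      points[1, , drop = FALSE]))^2))
    points <- points[d > 1e-12, , drop = FALSE]
  }
  if (nrow(points) < 3) {
    abort_cleftmorph("boundary loop needs >= 3 distinct points",
                     "cleftmorph_geometry_error")
  }
  pr <- project_perp(points, dorsal_axis)
  area <- polygon_signed_area(pr)
  structure(list(points = points, projected_area = abs(area),
                 ccw = area > 0, dorsal_axis = dorsal_axis),
            class = "boundary_loop")
}

#' @export
print.boundary_loop <- function(x, ...) {
  cat(sprintf("<boundary_loop> %d points, projected area %.2f mm^2\n",
              nrow(x$points), x$projected_area))
  invisible(x)
}

project_perp <- function(points, axis) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal complement of the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cbind(points %*% u, points %*% w)
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# circular componentwise 3-point median: removes single-point spikes from
# snapping without moving straight runs
median_filter_loop <- function(points) {
  n <- nrow(points)
  if (n < 5) return(points)
  prv <- points[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- points[c(2:n, 1), , drop = FALSE]
  out <- points
  for (d in seq_len(ncol(points))) {
    out[, d] <- pmax(pmin(pmax(prv[, d], points[, d]),
                          pmax(points[, d], nxt[, d])),
                     pmin(prv[, d], nxt[, d]))
  }
  out
}

# remove local self-crossings (snap jitter near corners can reorder a few
# points): 2-opt style - reverse the subpath between the two crossing
# edges, which uncrosses them without discarding geometry; drop a point
# only if reversal cannot fix it
untangle_loop <- function(points, dorsal_axis, max_fix = 50L) {
  for (k in seq_len(max_fix)) {
    n <- nrow(points)
    if (n < 6) break
    cr <- polygon_find_crossing(project_perp(points, dorsal_axis))
    if (is.null(cr)) break
    i <- cr[1]; j <- cr[2] # edges (i, i+1) and (j, j+1), i < j
    seg <- (i + 1L):j
    if (length(seg) <= n - 2L) {
      points[seg, ] <- points[rev(seg), , drop = FALSE]
    } else {
      points <- points[-(i + 1L), , drop = FALSE]
    }
    # if the same crossing persists (degenerate geometry), drop a point
    cr2 <- polygon_find_crossing(project_perp(points, dorsal_axis))
    if (!is.null(cr2) && identical(cr2, cr)) {
      points <- points[-(i + 1L), , drop = FALSE]
    }
  }
  points
}

smooth_closed_polyline <- function(points, iterations = 3, factor = 0.5) {
  n <- nrow(points)
  if (n < 4) return(points)
  for (i in seq_len(iterations)) {
    prev <- points[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- points[c(2:n, 1), , drop = FALSE]
    points <- points + factor * ((prev + nxt) / 2 - points)
  }
  points
}

resample_closed_polyline <- function(points, spacing) {
  closed <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_out <- max(8L, ceiling(total / spacing))
  ts <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  idx <- findInterval(ts, s, rightmost.closed = TRUE)
  idx[idx >= nrow(closed)] <- nrow(closed) - 1L
  frac <- (ts - s[idx]) / pmax(seg[idx], 1e-12)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

# transverse width profile of a loop: PCA long axis in the projection
# plane, polygon scanline extent at each station
loop_width_profile <- function(points2d, n_stations = 60L) {
  ctr <- colMeans(points2d)
  pc <- svd(sweep(points2d, 2, ctr))$v
  st <- sweep(points2d, 2, ctr) %*% pc # (s, t) coordinates
  len <- diff(range(st[, 1]))
  if (len <= 0) return(list(widths = 0, length = 0))
  # keep stations off the extreme tips, where any outline degenerates to a
  # point and the transverse width is trivially zero
  trim <- 0.05 * len
  stations <- seq(min(st[, 1]) + trim, max(st[, 1]) - trim,
                  length.out = n_stations)
  widths <- vapply(stations, function(s) {
    hits <- polygon_scanline(st[, 2:1, drop = FALSE], s) # scan across t at s
    if (length(hits) < 2) return(NA_real_)
    diff(range(hits))
  }, numeric(1))
  list(widths = widths[!is.na(widths)], length = len)
}

#' Detect cleft outlines on the palate, bridging sutures
#'
#' Extracts the oral-surface sheet, chains its boundary into closed loops,
#' discards the sheet's outer border, and keeps interior hole outlines whose
#' minimum transverse width is at least `min_gap_mm`. Narrower gaps - the
#' radiolucent unfused sutures normal in neonates - are thereby bridged and
#' excluded, while true clefts (reported as narrow as about 2 mm) are
#' retained.
#'
#' Because smoothing rounds the corner between the oral surface and the
#' near-vertical cleft wall, the sheet's raw hole boundary sits a fraction
#' of a millimetre outside the true bone margin. When the full (closed)
#' palate surface is supplied, each outline point is therefore snapped onto
#' the locally fitted vertical wall plane, with its height re-estimated
#' from the adjacent oral surface; outlines are also lightly smoothed to
#' suppress voxel-scale jitter. Loops are returned largest projected area
#' first.
#'
#' @param mesh A [tri_mesh()]: the cropped palate surface (closed bone
#'   surface, or an already-extracted oral sheet with
#'   `extract_sheet = FALSE`).
#' @param min_gap_mm Minimum transverse gap width regarded as a defect (mm).
#' @param dorsal_axis Dorsal direction.
#' @param max_tilt_deg Oral-sheet tilt cap, degrees (see
#'   [oral_surface_sheet()]).
#' @param extract_sheet Extract the oral sheet first (default TRUE).
#' @param snap_to_wall Refine outline points onto the local cleft wall
#'   (requires the full mesh, i.e. `extract_sheet = TRUE`).
#' @param wall_mesh Optional mesh to take the wall faces from (e.g. a less
#'   smoothed extraction of the same segmentation, whose walls are not
#'   displaced by mesh smoothing); defaults to `mesh`.
#' @param loop_smooth_iterations Laplacian smoothing passes applied to each
#'   outline.
#' @return List of [boundary_loop()] objects, possibly empty.
#' @export
detect_defect_boundary <- function(mesh, min_gap_mm = 1.0,
                                   dorsal_axis = c(0, 0, 1), max_tilt_deg = 60,
                                   extract_sheet = TRUE, snap_to_wall = TRUE,
                                   wall_mesh = NULL,
                                   loop_smooth_iterations = 3) {
  sheet <- if (extract_sheet) {
    oral_surface_sheet(mesh, dorsal_axis, max_tilt_deg)
  } else mesh
  cycles <- boundary_loops(sheet)
  if (length(cycles) <= 1) return(list())
  loops <- lapply(cycles, function(cyc) sheet$vertices[cyc, , drop = FALSE])
  proj_area <- vapply(loops, function(p) {
    abs(polygon_signed_area(project_perp(p, dorsal_axis)))
  }, numeric(1))
  outer <- which.max(proj_area)
  keep <- setdiff(seq_along(loops), outer)
  wall <- if (snap_to_wall && extract_sheet) {
    w <- wall_face_centroids(if (is.null(wall_mesh)) mesh else wall_mesh,
                             dorsal_axis)
    if (nrow(w$centroids) > 0) w else NULL
  } else NULL
  out <- list()
  for (i in keep) {
    pts <- smooth_closed_polyline(loops[[i]], loop_smooth_iterations)
    if (nrow(pts) < 6) next
    # snap first: gap widths are then physical wall-to-wall distances, so
    # sub-millimetre sutures separate cleanly from true clefts. Smoothing
    # between two snap passes removes voxel jitter without the inward
    # shrink a plain curvature flow would cause.
    if (!is.null(wall)) {
      pts <- snap_loop_to_wall(pts, wall, sheet, dorsal_axis)
      pts <- smooth_closed_polyline(pts, 1)
      pts <- snap_loop_to_wall(pts, wall, sheet, dorsal_axis)
      pts <- median_filter_loop(pts)
      pts <- untangle_loop(pts, dorsal_axis)
    }
    wp <- loop_width_profile(project_perp(pts, dorsal_axis))
    # 10th percentile: a robust minimum that ignores voxel-scale zigzag
    # tongues at jagged outline ends
    if (!length(wp$widths) ||
        stats::quantile(wp$widths, 0.1, names = FALSE) < min_gap_mm) next
    out[[length(out) + 1L]] <- boundary_loop(pts, dorsal_axis)
  }
  if (!length(out)) return(list())
  out[order(vapply(out, `[[`, numeric(1), "projected_area"), decreasing = TRUE)]
}

# centroids (and normals) of near-vertical faces: candidate cleft walls
wall_face_centroids <- function(mesh, dorsal_axis) {
  dorsal_axis <- dorsal_axis / sqrt(sum(dorsal_axis^2))
  nrm <- face_normals(mesh)
  steep <- abs(drop(nrm %*% dorsal_axis)) < 0.5
  list(centroids = face_centroids(mesh)[steep, , drop = FALSE],
       normals = nrm[steep, , drop = FALSE],
       dorsal_cos = drop(nrm[steep, , drop = FALSE] %*% dorsal_axis))
}

# Snap each outline point onto the locally fitted wall plane (horizontal
# move), then restore its height from a local plane fit of the adjacent
# oral surface on the bone side. Points without enough wall support are
# left unchanged.
snap_loop_to_wall <- function(pts, wall, sheet, dorsal_axis,
                              search_mm = 1.2, band_mm = c(0.5, 2.5)) {
  axis <- dorsal_axis / sqrt(sum(dorsal_axis^2))
  h_pts <- project_perp(pts, axis)
  h_wall <- project_perp(wall$centroids, axis)
  n_wall <- project_perp(wall$normals, axis) # horizontal normal components
  nw_len <- sqrt(rowSums(n_wall^2))
  nw_len[nw_len == 0] <- 1
  n_wall <- n_wall / nw_len
  h_sheet <- project_perp(sheet$vertices, axis)
  z_pts <- drop(pts %*% axis)
  z_wall <- drop(wall$centroids %*% axis)
  steep_cos <- wall$dorsal_cos
  z_sheet <- drop(sheet$vertices %*% axis)
  ctr <- colMeans(h_pts)
  # basis to lift horizontal coordinates back to 3-D
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  out <- pts
  n_pts <- nrow(pts)
  # local inward normals from the polygon orientation
  orient <- sign(polygon_signed_area(h_pts))
  if (orient == 0) orient <- 1
  nxt_i <- c(2:n_pts, 1)
  prv_i <- c(n_pts, 1:(n_pts - 1))
  tangents <- h_pts[nxt_i, , drop = FALSE] - h_pts[prv_i, , drop = FALSE]
  inward_all <- cbind(-tangents[, 2], tangents[, 1]) * orient
  ilen <- sqrt(rowSums(inward_all^2))
  ilen[ilen == 0] <- 1
  inward_all <- inward_all / ilen
  for (i in seq_len(n_pts)) {
    p <- h_pts[i, ]
    inward <- inward_all[i, ]
    near <- which(abs(h_wall[, 1] - p[1]) <= search_mm &
                    abs(h_wall[, 2] - p[2]) <= search_mm &
                    abs(z_wall - z_pts[i]) <= 2.5 &
                    (n_wall %*% inward) > 0.5)
    # prefer the most vertical faces: they sit on the mid-wall, clear of
    # the rounded corner transitions whose centroids are biased into bone
    strict <- near[abs(steep_cos[near]) < 0.25]
    if (length(strict) >= 3) near <- strict
    p_new <- p
    if (length(near) >= 4) {
      # near an outline corner the candidates split into two wall
      # orientations; reconstruct the corner as the intersection of the
      # two fitted wall lines instead of blending them
      d2p <- rowSums(sweep(h_wall[near, , drop = FALSE], 2, p)^2)
      n_ref <- n_wall[near[which.min(d2p)], ]
      align <- drop(n_wall[near, , drop = FALSE] %*% n_ref)
      grpA <- near[align > 0.7071]
      grpB <- near[align <= 0.7071]
      fit_line <- function(idx) {
        wpts <- h_wall[idx, , drop = FALSE]
        wc <- colMeans(wpts)
        dirv <- svd(sweep(wpts, 2, wc))$v[, 1]
        list(c = wc, n = c(-dirv[2], dirv[1]))
      }
      if (length(grpA) >= 3 && length(grpB) >= 3) {
        lA <- fit_line(grpA); lB <- fit_line(grpB)
        A <- rbind(lA$n, lB$n)
        det2 <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
        if (abs(det2) > 0.3) {
          b <- c(sum(lA$n * lA$c), sum(lB$n * lB$c))
          cand <- solve(A, b)
          # accept only a nearby corner; otherwise fall through to the
          # single-wall projection
          if (sum((cand - p)^2) < search_mm^2) p_new <- cand
        }
      }
      if (all(p_new == p)) {
        lp_fit <- fit_line(near)
        p_new <- p + sum((lp_fit$c - p) * lp_fit$n) * lp_fit$n
      }
    }
    # height from the oral surface just outside the outline
    outward <- -inward
    z_new <- z_pts[i]
    {
      rel <- sweep(h_sheet, 2, p_new)
      t_out <- rel %*% outward
      d2 <- rowSums(rel^2)
      sel <- which(t_out > band_mm[1] & t_out < band_mm[2] & d2 < band_mm[2]^2)
      if (length(sel) >= 6) {
        A <- cbind(1, h_sheet[sel, 1] - p_new[1], h_sheet[sel, 2] - p_new[2])
        cf <- tryCatch(qr.solve(A, z_sheet[sel]), error = function(e) NULL)
        if (!is.null(cf)) z_new <- cf[1]
      }
    }
    out[i, ] <- p_new[1] * u + p_new[2] * w + z_new * axis
  }
  out
}
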