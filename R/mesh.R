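#' Triangle mesh container
#'
#' A `tri_mesh` is an indexed triangle surface in world millimetres:
#' `vertices` is an `n x 3` matrix of `(x, y, z)` coordinates and `faces` an
#' `m x 3` integer matrix of 1-based vertex indices. Faces with repeated
#' vertex indices are rejected; zero-area (collinear) faces are allowed and
#' contribute nothing to the surface area.
#'
#' @param vertices Numeric `n x 3` matrix (mm).
#' @param faces Integer `m x 3` matrix of vertex indices.
#' @return A `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(!is.finite(vertices))) {
    abort_cleftmorph("mesh vertices must be finite", "cleftmorph_geometry_error")
  }
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      abort_cleftmorph("face indices out of range", "cleftmorph_geometry_error")
    }
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(dup)) {
      abort_cleftmorph("faces with repeated vertices are not allowed",
                       "cleftmorph_geometry_error")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, area %.3f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_surface_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' Sums `0.5 * ||(v1 - v0) x (v2 - v0)||` over all faces. Degenerate
#' (collinear) faces contribute zero; an empty mesh has area 0. The measure
#' is invariant under rigid motion and scales with the square of any uniform
#' scale factor.
#'
#' @param mesh A [tri_mesh()].
#' @return Surface area in mm^2.
#' @export
#' @examples
#' sq <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                rbind(c(1, 2, 3), c(1, 3, 4)))
#' mesh_surface_area(sq)
mesh_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(numeric(0))
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh A [tri_mesh()].
#' @param rotation 3x3 matrix applied to vertex coordinates.
#' @param translation Length-3 vector added after rotation (mm).
#' @return The transformed [tri_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  tri_mesh(sweep(mesh$vertices %*% t(rotation), 2, -translation),
           mesh$faces)
}

#' Drop degenerate faces from a mesh
#'
#' Removes faces whose area is below `tol` and vertices left unreferenced.
#'
#' @param mesh A [tri_mesh()].
#' @param tol Area threshold in mm^2.
#' @return A cleaned [tri_mesh()].
#' @export
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  keep <- face_areas(mesh) > tol
  subset_faces(mesh, keep)
}

subset_faces <- function(mesh, keep) {
  faces <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3))
}

#' Icosphere test mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere; a standard
#' closed test surface whose area converges to `4 * pi * r^2`.
#'
#' @param radius Sphere radius in mm.
#' @param subdivisions Number of 4-to-1 subdivision rounds.
#' @param center Sphere centre (mm).
#' @return A [tri_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, -center), f)
}

#' Write a mesh to STL
#'
#' Emits binary (default) or ASCII STL in millimetres. STL stores each
#' triangle independently, so vertex indexing is not preserved; coordinates
#' survive at 32-bit float precision in the binary dialect and at the printed
#' precision in ASCII.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header <- charToRaw(sprintf("%-80s", "cleftmorph binary STL (mm)"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- cbind(n,
                 v[f[, 1], , drop = FALSE],
                 v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    raw_floats <- writeBin(as.vector(t(tri)), raw(), size = 4L, endian = "little")
    chunk <- matrix(raw_floats, nrow = 48L)
    out <- rbind(chunk, matrix(as.raw(0), nrow = 2L, ncol = ncol(chunk)))
    writeBin(as.vector(out), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("solid cleftmorph", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                v[f[i, c(1, 2, 3)], 1], v[f[i, c(1, 2, 3)], 2], v[f[i, c(1, 2, 3)], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid cleftmorph", con)
  }
  invisible(path)
}

#' Read a mesh from STL
#'
#' Detects the dialect automatically. Duplicated vertices (inherent to the
#' triangle-soup STL layout) are welded back by exact coordinate match.
#'
#' @param path STL file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) {
    abort_cleftmorph(sprintf("file not found: %s", path), "cleftmorph_io_error")
  }
  con <- file(path, "rb")
  head_bytes <- readBin(con, "raw", n = 80L)
  is_ascii <- grepl("^solid", rawToChar(head_bytes[1:5]))
  if (!is_ascii) {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    body <- readBin(con, "raw", n = 50L * ntri)
    close(con)
    if (length(body) < 50L * ntri) {
      abort_cleftmorph("binary STL truncated", "cleftmorph_format_error")
    }
    mat <- matrix(body, nrow = 50L)
    coords <- readBin(as.vector(mat[1:48, ]), "double", n = 12L * ntri,
                      size = 4L, endian = "little")
    coords <- matrix(coords, ncol = 12, byrow = TRUE)
    verts <- rbind(coords[, 4:6, drop = FALSE],
                   coords[, 7:9, drop = FALSE],
                   coords[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      abort_cleftmorph("malformed ASCII STL", "cleftmorph_format_error")
    }
    verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    if (any(!is.finite(verts))) {
      abort_cleftmorph("malformed ASCII STL vertex", "cleftmorph_format_error")
    }
  }
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  tri_mesh(uverts, faces[ok, , drop = FALSE])
}
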