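#' Percentage of the hard palate occupied by the cleft
#'
#' `100 * cleft_area / total_area`, rounded half away from zero to an
#' integer percent (so 55.5 -> 56), the convention that reproduces the
#' integer percentages printed in clinical case reports from their raw
#' areas.
#'
#' @param cleft_area Cleft surface area in mm^2 (possibly vector).
#' @param total_area Total hard-palate area in mm^2.
#' @return Integer percent.
#' @export
#' @examples
#' cleft_percentage(62, 572)  # 11
#' cleft_percentage(213, 331) # 64
cleft_percentage <- function(cleft_area, total_area) {
  if (any(!is.finite(total_area)) || any(total_area <= 0)) {
    abort_cleftmorph("total_area must be > 0", "cleftmorph_parameter_error")
  }
  if (any(cleft_area < 0) || any(cleft_area > total_area)) {
    abort_cleftmorph("need 0 <= cleft_area <= total_area",
                     "cleftmorph_consistency_error")
  }
  p <- 100 * cleft_area / total_area
  as.integer(floor(p + 0.5)) # round half away from zero (areas are >= 0)
}

#' Total palate area of the virtually repaired palate
#'
#' The residual oral-surface sheet plus every trimmed fill patch: the area
#' the intact palate would have had. Defining the total this way keeps the
#' percentage well defined even for wide clefts and makes intact area =
#' residual + fill a testable conservation property.
#'
#' @param residual_palate_mesh [tri_mesh()] of the residual oral sheet.
#' @param fill_meshes List of trimmed fill [tri_mesh()] objects (possibly
#'   empty).
#' @return Area in mm^2.
#' @export
total_palate_area <- function(residual_palate_mesh, fill_meshes = list()) {
  if (inherits(fill_meshes, "tri_mesh")) fill_meshes <- list(fill_meshes)
  mesh_surface_area(residual_palate_mesh) +
    sum(vapply(fill_meshes, mesh_surface_area, numeric(1)))
}

#' Length and width of a defect
#'
#' Projects the fill mesh onto the rostro-caudal axis to obtain the defect
#' length, then measures the transverse extent of cross-sections
#' perpendicular to that axis (the radiological "width in a transverse
#' plane"). The transverse direction is the axis orthogonal to both
#' `long_axis` and `dorsal_axis`. Cross-sections are sampled in slabs at
#' roughly the mesh's own tessellation resolution.
#'
#' @param fill_mesh A [tri_mesh()], typically a trimmed fill patch.
#' @param long_axis Unit vector of the rostro-caudal direction (default
#'   `(0, 1, 0)`).
#' @param dorsal_axis Unit vector of the dorsal direction (default
#'   `(0, 0, 1)`).
#' @param n_stations Number of cross-section slabs; default adapts to the
#'   mesh resolution.
#' @return Named numeric: `length`, `width_min`, `width_max` (mm).
#' @export
measure_cleft_extent <- function(fill_mesh, long_axis = c(0, 1, 0),
                                 dorsal_axis = c(0, 0, 1), n_stations = NULL) {
  stopifnot(inherits(fill_mesh, "tri_mesh"))
  if (nrow(fill_mesh$vertices) < 3) {
    abort_cleftmorph("fill mesh is empty", "cleftmorph_degenerate_geometry_error")
  }
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  dorsal_axis <- dorsal_axis / sqrt(sum(dorsal_axis^2))
  trans <- c(dorsal_axis[2] * long_axis[3] - dorsal_axis[3] * long_axis[2],
             dorsal_axis[3] * long_axis[1] - dorsal_axis[1] * long_axis[3],
             dorsal_axis[1] * long_axis[2] - dorsal_axis[2] * long_axis[1])
  tl <- sqrt(sum(trans^2))
  if (tl < 1e-9) {
    abort_cleftmorph("long_axis and dorsal_axis must not be parallel",
                     "cleftmorph_parameter_error")
  }
  trans <- trans / tl
  s <- drop(fill_mesh$vertices %*% long_axis)
  t <- drop(fill_mesh$vertices %*% trans)
  len <- diff(range(s))
  if (len <= 0 || !is.finite(len)) {
    abort_cleftmorph("mesh has zero extent along the long axis",
                     "cleftmorph_degenerate_geometry_error")
  }
  if (is.null(n_stations)) {
    edge <- median_edge_length(fill_mesh)
    n_stations <- max(8L, min(200L, ceiling(len / max(edge, 1e-6))))
  }
  # true cross-sections: intersect the mesh edges with planes perpendicular
  # to the long axis and take the transverse extent of the crossings;
  # stations stay off the extreme tips, where any outline narrows to a
  # point and the extent is not meaningful
  f <- fill_mesh$faces
  e1 <- c(f[, 1], f[, 2], f[, 3])
  e2 <- c(f[, 2], f[, 3], f[, 1])
  s1 <- s[e1]; s2 <- s[e2]; t1 <- t[e1]; t2 <- t[e2]
  trim <- 0.05 * len
  stations <- seq(min(s) + trim, max(s) - trim, length.out = n_stations)
  widths <- vapply(stations, function(s0) {
    hit <- (s1 <= s0 & s2 > s0) | (s2 <= s0 & s1 > s0)
    if (sum(hit) < 2) return(NA_real_)
    frac <- (s0 - s1[hit]) / (s2[hit] - s1[hit])
    diff(range(t1[hit] + frac * (t2[hit] - t1[hit])))
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  if (!length(widths)) {
    abort_cleftmorph("no usable cross-sections", "cleftmorph_degenerate_geometry_error")
  }
  c(length = len, width_min = min(widths), width_max = max(widths))
}

median_edge_length <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  v <- mesh$vertices
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  stats::median(sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2)))
}

#' Assemble a per-animal cleft measurement record
#'
#' @param animal_id,breed Labels.
#' @param cleft_area,total_palate_area Areas in mm^2.
#' @param length,width_min,width_max Defect extent in mm (NA when no defect).
#' @param n_loops Number of detected defect outlines.
#' @param diagnostic_code Optional classification code string (see
#'   [encode_cleft_code()]).
#' @return A one-row tibble of class `cleft_measurement`.
#' @export
cleft_measurement <- function(animal_id, breed = NA_character_,
                              cleft_area, total_palate_area,
                              length = NA_real_, width_min = NA_real_,
                              width_max = NA_real_, n_loops = 0L,
                              diagnostic_code = NA_character_) {
  if (cleft_area < 0 || total_palate_area < 0 || cleft_area > total_palate_area) {
    abort_cleftmorph("need 0 <= cleft_area <= total_palate_area",
                     "cleftmorph_consistency_error")
  }
  if (!is.na(width_min) && !is.na(width_max) && width_min > width_max) {
    abort_cleftmorph("width_min must be <= width_max",
                     "cleftmorph_consistency_error")
  }
  out <- tibble::tibble(
    animal_id = as.character(animal_id),
    breed = as.character(breed),
    total_area_mm2 = total_palate_area,
    cleft_area_mm2 = cleft_area,
    percentage = cleft_percentage(cleft_area, total_palate_area),
    length_mm = length,
    width_min_mm = width_min,
    width_max_mm = width_max,
    n_loops = as.integer(n_loops),
    diagnostic_code = as.character(diagnostic_code)
  )
  class(out) <- c("cleft_measurement", class(out))
  out
}

#' Write the per-animal report CSV
#'
#' Mirrors the layout of a clinical case table: one row per animal with the
#' total hard-palate area, cleft area and integer percentage, ordered by
#' `dog_no`. Percentages are recomputed from the stored areas so the CSV is
#' self-consistent.
#'
#' @param measurements A tibble of measurement rows (e.g. built by
#'   [cleft_measurement()] / [run_pipeline()]), or a list of them.
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
build_report <- function(measurements, path) {
  if (is.list(measurements) && !inherits(measurements, "data.frame")) {
    measurements <- dplyr::bind_rows(measurements)
  }
  cols <- c("animal_id", "breed", "total_area_mm2", "cleft_area_mm2")
  if (nrow(measurements) == 0) {
    report <- tibble::tibble(dog_no = character(0), breed = character(0),
                             total_area_mm2 = numeric(0),
                             cleft_area_mm2 = numeric(0),
                             percentage = integer(0),
                             diagnostic_code = character(0))
  } else {
    missing_cols <- setdiff(cols, names(measurements))
    if (length(missing_cols)) {
      abort_cleftmorph(paste("missing columns:", paste(missing_cols, collapse = ", ")),
                       "cleftmorph_parameter_error")
    }
    report <- measurements |>
      dplyr::mutate(
        dog_no = .data$animal_id,
        percentage = cleft_percentage(.data$cleft_area_mm2, .data$total_area_mm2)
      ) |>
      dplyr::arrange(order(order(suppressWarnings(as.numeric(.data$dog_no)),
                                 .data$dog_no))) |>
      dplyr::select(dplyr::all_of(c("dog_no", "breed", "total_area_mm2",
                                    "cleft_area_mm2", "percentage")),
                    dplyr::any_of("diagnostic_code"))
  }
  readr::write_csv(report, path)
  invisible(report)
}
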