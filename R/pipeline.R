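#' Default pipeline configuration
#'
#' All stage parameters in one document. The values mirror the package
#' defaults: 140 HU bone cut-off, 1 mm suture-bridging gap, dorsal axis
#' `+z`, rostro-caudal axis `+y`, cubic 8x8 fill patches with 0.2 mm
#' boundary tolerance, 64-sample tessellation.
#'
#' @return A named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    threshold_hu = 140,
    connectivity = 26L,
    presmooth = 0.4,
    taubin_iterations = 50L,
    min_gap_mm = 1.0,
    dorsal_axis = c(0, 0, 1),
    long_axis = c(0, 1, 0),
    max_tilt_deg = 60,
    roi = NULL,
    patch = list(degree = 3L, control_grid = c(8L, 8L), rms_tol = 0.2,
                 max_iter = 50L, support_band_mm = 3.0, lambda = 1),
    tessellation_samples = 64L,
    output_dir = NULL,
    seed = 1L,
    log_level = "info"
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_cleftmorph(sprintf("cannot parse config: %s", conditionMessage(e)),
                     "cleftmorph_format_error")
  })
  cfg <- default_config()
  unknown <- setdiff(names(doc), c(names(cfg), "patch"))
  if (length(unknown)) {
    abort_cleftmorph(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                     "cleftmorph_format_error")
  }
  for (k in setdiff(names(doc), "patch")) cfg[[k]] <- doc[[k]]
  if (!is.null(doc$patch)) for (k in names(doc$patch)) cfg$patch[[k]] <- doc$patch[[k]]
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns human-readable findings (empty when the configuration is usable);
#' never mutates the configuration. Hard range violations and plausibility
#' warnings are both reported.
#'
#' @param config A `run_config` list.
#' @return Character vector of findings.
#' @export
validate_config <- function(config) {
  findings <- character(0)
  say <- function(...) findings <<- c(findings, sprintf(...))
  if (!is.numeric(config$threshold_hu) ||
      config$threshold_hu < -1000 || config$threshold_hu > 3000) {
    say("threshold_hu %s outside the plausible HU range [-1000, 3000]",
        format(config$threshold_hu))
  }
  if (!config$connectivity %in% c(6, 26)) {
    say("connectivity must be 6 or 26, got %s", format(config$connectivity))
  }
  if (!is.numeric(config$min_gap_mm) || config$min_gap_mm <= 0) {
    say("min_gap_mm must be > 0")
  } else if (config$min_gap_mm > 20) {
    say("min_gap_mm = %g mm is implausibly large for a neonatal palate",
        config$min_gap_mm)
  }
  for (ax in c("dorsal_axis", "long_axis")) {
    v <- config[[ax]]
    if (!is.numeric(v) || length(v) != 3 || sqrt(sum(v^2)) < 1e-9) {
      say("%s must be a non-zero length-3 vector", ax)
    }
  }
  if (config$max_tilt_deg <= 0 || config$max_tilt_deg >= 90) {
    say("max_tilt_deg must lie in (0, 90)")
  }
  p <- config$patch
  if (p$degree < 1 || any(p$control_grid < p$degree + 1)) {
    say("patch control grid too small for degree %d", p$degree)
  }
  if (p$rms_tol <= 0) say("patch rms_tol must be > 0")
  if (p$max_iter < 1) say("patch max_iter must be >= 1")
  if (p$support_band_mm <= 0) say("patch support_band_mm must be > 0")
  if (config$tessellation_samples < 2) say("tessellation_samples must be >= 2")
  if (config$presmooth < 0) say("presmooth must be >= 0")
  findings
}

#' Run the full cleft quantification pipeline
#'
#' Volume to report in one configured, logged pass: threshold segmentation,
#' largest-component cleanup, iso-surface extraction, optional ROI crop,
#' oral-sheet isolation, defect detection with suture bridging, spline fill
#' of every defect, trimming, and morphometry. When `config$output_dir` is
#' set, the stage artifacts (bone/palate/fill STL meshes, measurement JSON,
#' report CSV, structured log with the fully resolved configuration) are
#' written there; every number in the report can be recomputed from those
#' artifacts with the package's module functions alone.
#'
#' A volume with no detected defect is a valid result (cleft area 0, empty
#' diagnostic fields), distinguished from stage failures, which raise
#' classed errors naming the stage.
#'
#' @param input A [ct_volume()] or a path readable by [read_volume()].
#' @param config A `run_config`; see [default_config()].
#' @param animal_id,breed Labels for the report row.
#' @param diagnostic_code Optional classification code string (validated via
#'   [parse_cleft_code()] when supplied).
#' @return A [cleft_measurement()] tibble row; artifacts and details are
#'   attached as attributes `fills`, `residual_sheet`, `bone_mesh`.
#' @export
run_pipeline <- function(input, config = default_config(), animal_id = "animal",
                         breed = NA_character_, diagnostic_code = NA_character_) {
  findings <- validate_config(config)
  if (length(findings)) {
    abort_cleftmorph(paste0("invalid config: ", paste(findings, collapse = "; ")),
                     "cleftmorph_parameter_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed for '%s': %s",
                           name, animal_id, conditionMessage(e)),
                   class = c("cleftmorph_stage_error", "cleftmorph_error"),
                   parent = e)
    })
  }
  volume <- if (inherits(input, "ct_volume")) input else {
    stage("read_volume", read_volume(input))
  }
  if (!is.na(diagnostic_code)) {
    stage("diagnostic_code", parse_cleft_code(diagnostic_code))
  }
  mask <- stage("threshold", threshold_mask(volume, config$threshold_hu))
  mask <- stage("largest_component", largest_component(mask, config$connectivity))
  bone_mesh <- stage("isosurface",
                     extract_isosurface(mask, presmooth = config$presmooth,
                                        smooth_iterations = config$taubin_iterations))
  # minimally smoothed companion surface for wall localisation: a few
  # smoothing passes remove staircase riser faces that masquerade as
  # walls, while heavy smoothing would displace narrow-slot walls
  wall_mesh <- stage("isosurface",
                     extract_isosurface(mask, presmooth = config$presmooth,
                                        smooth_iterations = min(3L, config$taubin_iterations)))
  palate_mesh <- if (!is.null(config$roi)) {
    stage("crop", crop_mesh(bone_mesh, as_roi(config$roi)))
  } else bone_mesh
  sheet <- stage("oral_sheet",
                 oral_surface_sheet(palate_mesh, config$dorsal_axis,
                                    config$max_tilt_deg))
  loops <- stage("detect_boundary",
                 detect_defect_boundary(palate_mesh, config$min_gap_mm,
                                        config$dorsal_axis, config$max_tilt_deg,
                                        wall_mesh = if (is.null(config$roi)) wall_mesh))
  fills <- lapply(loops, function(lp) {
    stage("fill_defect",
          fill_defect(sheet, lp,
                      samples_per_direction = config$tessellation_samples,
                      support_band_mm = config$patch$support_band_mm,
                      degree = config$patch$degree,
                      control_grid = config$patch$control_grid,
                      rms_tol = config$patch$rms_tol,
                      max_iter = config$patch$max_iter,
                      lambda = config$patch$lambda,
                      dorsal_axis = config$dorsal_axis,
                      max_tilt_deg = config$max_tilt_deg))
  })
  fill_meshes <- lapply(fills, `[[`, "fill_mesh")
  cleft_area <- sum(vapply(fill_meshes, mesh_surface_area, numeric(1)))
  total_area <- stage("morphometry", total_palate_area(sheet, fill_meshes))
  if (length(fills)) {
    extents <- lapply(fill_meshes, measure_cleft_extent,
                      long_axis = config$long_axis,
                      dorsal_axis = config$dorsal_axis)
    len <- max(vapply(extents, `[[`, numeric(1), "length"))
    wmin <- min(vapply(extents, `[[`, numeric(1), "width_min"))
    wmax <- max(vapply(extents, `[[`, numeric(1), "width_max"))
  } else {
    len <- wmin <- wmax <- NA_real_
  }
  measurement <- cleft_measurement(
    animal_id = animal_id, breed = breed,
    cleft_area = cleft_area, total_palate_area = total_area,
    length = len, width_min = wmin, width_max = wmax,
    n_loops = length(fills),
    diagnostic_code = if (length(fills)) diagnostic_code else NA_character_
  )
  if (!is.null(config$output_dir)) {
    stage("artifacts",
          write_run_artifacts(config$output_dir, animal_id, config, bone_mesh,
                              sheet, fills, measurement))
  }
  attr(measurement, "fills") <- fills
  attr(measurement, "residual_sheet") <- sheet
  attr(measurement, "bone_mesh") <- bone_mesh
  measurement
}

as_roi <- function(roi) {
  if (inherits(roi, "roi")) return(roi)
  if (is.list(roi) && all(c("xlim", "ylim", "zlim") %in% names(roi))) {
    return(roi_box(roi$xlim, roi$ylim, roi$zlim))
  }
  abort_cleftmorph("cannot interpret config$roi", "cleftmorph_parameter_error")
}

write_run_artifacts <- function(dir, animal_id, config, bone_mesh, sheet,
                                fills, measurement) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe_id <- gsub("[^A-Za-z0-9_.-]", "_", animal_id)
  write_stl(bone_mesh, file.path(dir, paste0(safe_id, "_bone.stl")))
  write_stl(sheet, file.path(dir, paste0(safe_id, "_palate_sheet.stl")))
  for (i in seq_along(fills)) {
    write_stl(fills[[i]]$fill_mesh,
              file.path(dir, sprintf("%s_fill_%02d.stl", safe_id, i)))
    write_patch_json(fills[[i]]$patch,
                     file.path(dir, sprintf("%s_patch_%02d.json", safe_id, i)))
  }
  jsonlite::write_json(as.list(measurement),
                       file.path(dir, paste0(safe_id, "_measurement.json")),
                       digits = NA, auto_unbox = TRUE)
  build_report(measurement, file.path(dir, paste0(safe_id, "_report.csv")))
  log <- list(
    package = "cleftmorph",
    package_version = as.character(utils::packageVersion("cleftmorph")),
    r_version = R.version.string,
    animal_id = animal_id,
    config = rapply(unclass(config), identity, how = "list"),
    n_defects = measurement$n_loops
  )
  jsonlite::write_json(log, file.path(dir, paste0(safe_id, "_log.json")),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}
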