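#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of Hounsfield units (HU) together with its
#' physical geometry. Axes follow a fixed `(z, y, x)` order: `data[iz, iy, ix]`
#' is the voxel whose centre sits at `origin + (iz - 1, iy - 1, ix - 1) *
#' spacing` in world millimetres. All meshes derived from a volume live in the
#' same world-mm frame, so surface areas are physical areas regardless of
#' voxel anisotropy.
#'
#' @param data 3-D numeric array of HU values, dimensions `(nz, ny, nx)`.
#' @param spacing Numeric length-3 vector, voxel size in mm per axis
#'   `(z, y, x)`; all components must be positive.
#' @param origin Numeric length-3 vector, world position (mm) of voxel
#'   `[1, 1, 1]` in `(z, y, x)` order.
#'
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `origin` and `axis_labels = c("z", "y", "x")`.
#' @export
#' @examples
#' vol <- ct_volume(array(-1000, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' dim(vol$data)
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_cleftmorph("`data` must be a 3-D array", "cleftmorph_metadata_error")
  }
  if (any(dim(data) < 2L)) {
    abort_cleftmorph("volume must have at least 2 voxels along every axis",
                     "cleftmorph_metadata_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_cleftmorph("`spacing` must be 3 positive finite values (mm)",
                     "cleftmorph_metadata_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort_cleftmorph("`origin` must be 3 finite values (mm)",
                     "cleftmorph_metadata_error")
  }
  if (any(!is.finite(data))) {
    abort_cleftmorph("volume data must be finite", "cleftmorph_metadata_error")
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         axis_labels = c("z", "y", "x")),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Display window setting
#'
#' A radiological display window: a clamped linear ramp centred at `level`
#' with total range `width`, mapping HU to normalised gray in `[0, 1]`.
#' Presets [bone_window()] (level 300, width 1500) and [soft_tissue_window()]
#' (level 40, width 350) match routine neonatal head review settings.
#'
#' @param level Window centre in HU.
#' @param width Window width in HU, must be positive.
#' @param name Label for the window.
#' @return A `window_setting` object.
#' @export
window_setting <- function(level, width, name = "custom") {
  if (!is.finite(width) || width <= 0) {
    abort_cleftmorph("window `width` must be > 0 HU", "cleftmorph_parameter_error")
  }
  structure(list(level = as.numeric(level), width = as.numeric(width),
                 name = as.character(name)),
            class = "window_setting")
}

#' @rdname window_setting
#' @export
bone_window <- function() window_setting(300, 1500, "bone")

#' @rdname window_setting
#' @export
soft_tissue_window <- function() window_setting(40, 350, "soft_tissue")

#' Apply a display window to a volume
#'
#' Maps HU linearly to `[0, 1]` with the window's half-width edges:
#' `clip((HU - (level - width/2)) / width, 0, 1)`. The level maps to 0.5,
#' values at or below `level - width/2` to 0 and at or above
#' `level + width/2` to 1. The map is monotone non-decreasing in HU.
#'
#' @param volume A [ct_volume()].
#' @param window A [window_setting()].
#' @return A numeric array with the same dimensions as `volume$data`, values
#'   in `[0, 1]`.
#' @export
#' @examples
#' v <- ct_volume(array(c(-450, 300, 1050, 40), c(2, 2, 2))[, , 1:2, drop = FALSE],
#'                spacing = c(1, 1, 1))
#' range(window_transform(v, bone_window()))
window_transform <- function(volume, window) {
  stopifnot(inherits(volume, "ct_volume"), inherits(window, "window_setting"))
  lo <- window$level - window$width / 2
  out <- (volume$data - lo) / window$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Read a CT volume from NRRD or NIfTI
#'
#' Axis order is normalised to the package's `(z, y, x)` contract. NIfTI
#' files (read via RNifti) store data `(x, y, z)` and are permuted; NRRD
#' files are read by the bundled minimal NRRD0004 reader and interpreted with
#' their fastest axis first, i.e. written `sizes` in `(z, y, x)` when produced
#' by [write_volume()].
#'
#' @param path File path.
#' @param format `"nrrd"` or `"nifti"`; default guesses from the extension.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (!file.exists(path)) {
    abort_cleftmorph(sprintf("file not found: %s", path), "cleftmorph_io_error")
  }
  if (format == "nrrd") {
    nr <- read_nrrd(path)
    ct_volume(nr$data, spacing = nr$spacing, origin = nr$origin)
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) {
      abort_cleftmorph("NIfTI volume must be 3-D", "cleftmorph_format_error")
    }
    pd <- RNifti::pixdim(img) # (x, y, z)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
      abort_cleftmorph("NIfTI pixdim missing or non-positive",
                       "cleftmorph_metadata_error")
    }
    # NIfTI round trips carry data and spacing; world origin is kept only by
    # the NRRD container and defaults to zero here
    ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]))
  }
}

#' Write a CT volume to NRRD or NIfTI
#'
#' Round trips through [read_volume()] preserve the HU payload bit-exactly
#' (double precision in NRRD, the array's own storage in NIfTI) and spacing
#' to full precision.
#'
#' @param volume A [ct_volume()].
#' @param path Output path.
#' @param format `"nrrd"` or `"nifti"`; default guesses from the extension.
#' @param encoding NRRD payload encoding, `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nrrd", "nifti"),
                         encoding = c("raw", "gzip")) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  encoding <- match.arg(encoding)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (format == "nrrd") {
    write_nrrd(volume$data, path, spacing = volume$spacing,
               origin = volume$origin, encoding = encoding)
  } else {
    arr <- aperm(volume$data, c(3, 2, 1)) # back to (x, y, z)
    attr(arr, "pixdim") <- rev(volume$spacing)
    img <- RNifti::asNifti(arr, datatype = "double")
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Export a windowed QC slice as 8-bit PNG
#'
#' Writes one axial (constant-z) slice of the windowed volume as an 8-bit
#' grayscale PNG for visual quality control.
#'
#' @param volume A [ct_volume()].
#' @param path Output PNG path.
#' @param slice Axial slice index (1-based along z).
#' @param window A [window_setting()]; defaults to the bone window.
#' @return `path`, invisibly.
#' @export
write_qc_slice <- function(volume, path, slice = NULL, window = bone_window()) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_cleftmorph("the 'png' package is required for QC export",
                     "cleftmorph_io_error")
  }
  w <- window_transform(volume, window)
  if (is.null(slice)) slice <- ceiling(dim(w)[1] / 2)
  img <- w[slice, , ]
  png::writePNG(img, path)
  invisible(path)
}
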