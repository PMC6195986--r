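#' Plot a windowed CT slice
#'
#' Renders one axial slice through the display window as a gray raster,
#' with physical axes in mm.
#'
#' @param volume A [ct_volume()].
#' @param slice Axial (z) slice index; default mid-volume.
#' @param window A [window_setting()].
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice = NULL, window = bone_window()) {
  w <- window_transform(volume, window)
  if (is.null(slice)) slice <- ceiling(dim(w)[1] / 2)
  img <- w[slice, , ]
  df <- expand.grid(
    y = volume$origin[2] + (seq_len(nrow(img)) - 1) * volume$spacing[2],
    x = volume$origin[3] + (seq_len(ncol(img)) - 1) * volume$spacing[3]
  )
  df$gray <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = window$name,
                  title = sprintf("%s window (level %g, width %g HU), slice %d",
                                  window$name, window$level, window$width, slice)) +
    ggplot2::theme_minimal()
}

#' Plot cleft percentages from a report
#'
#' Bar chart of the percentage of the hard palate occupied by the cleft,
#' per animal.
#'
#' @param report A tibble with `dog_no`/`animal_id` and `percentage`
#'   columns (e.g. from [build_report()]).
#' @return A ggplot object.
#' @export
plot_report <- function(report) {
  id_col <- intersect(c("dog_no", "animal_id"), names(report))[1]
  ggplot2::ggplot(report,
                  ggplot2::aes(x = factor(.data[[id_col]]), y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "animal", y = "cleft area (% of hard palate)") +
    ggplot2::theme_minimal()
}
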