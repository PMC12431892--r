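#' Plot microstate topographies
#'
#' Sensor-space view of each map: one facet per map, sensors colored by
#' loading on a diverging scale. Needs the sensor layout for coordinates.
#'
#' @param object A [mapset()].
#' @param layout A [sensor_layout()] matching the map channels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapset <- function(object, layout, ...) {
  df <- tidy(object, layout = layout)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_gradient2(low = "#2166AC", mid = "white",
                                   high = "#B2182B") +
    ggplot2::facet_wrap(~map) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Microstate maps", color = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation as a label raster
#'
#' Epochs stacked vertically, time left to right, colored by the active map.
#'
#' @param object A `segmentation`.
#' @param max_epochs Show at most this many epochs (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation <- function(object, max_epochs = 20L, ...) {
  d <- dim(object$labels)
  ne <- min(d[1L], max_epochs)
  df <- tibble::tibble(
    epoch = rep(seq_len(ne), times = d[2L]),
    time_ms = rep((seq_len(d[2L]) - 1L) * 1000 / object$sfreq, each = ne),
    map = factor(as.vector(object$labels[seq_len(ne), ]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$epoch,
                                   fill = .data$map)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "time (ms)", y = "epoch",
                  title = "Microstate segmentation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Marker distributions by group
#'
#' Box-and-jitter plots of one or more markers across groups, one facet per
#' marker — the standard view for cohort-level microstate comparisons.
#'
#' @param markers Marker tibble (one row per participant, `group` column).
#' @param marker_cols Marker columns to show (defaults to
#'   `coverage_entropy`, `gev_total`, `mmd`, `mdv`, `ep` where present).
#' @param group_order Optional ordering of the group factor.
#' @return A ggplot object.
#' @export
plot_markers <- function(markers, marker_cols = NULL, group_order = NULL) {
  if (is.null(marker_cols)) {
    marker_cols <- intersect(c("coverage_entropy", "gev_total", "mmd",
                               "mdv", "ep"), names(markers))
  }
  df <- markers |>
    dplyr::select(dplyr::all_of(c("group", marker_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(marker_cols),
                        names_to = "marker", values_to = "value")
  if (!is.null(group_order)) {
    df$group <- factor(df$group, levels = group_order)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
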