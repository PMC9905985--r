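#' Error map over the workspace
#'
#' Log-scaled contour/raster map of a reaching error over the rectangular
#' target grid, with the workspace boundary overlaid.  Out-of-workspace
#' targets are plotted (they are only excluded from aggregate statistics).
#'
#' @param metrics Metrics tibble from [run_target_set()] on the `rect_grid`
#'   set.
#' @param field Error column to map, `"e_h"` or `"e_mv"` (mm).
#' @param boundary Optional [estimate_workspace()] polygon to overlay.
#' @param floor_mm Errors below this are clipped for the log scale.
#' @return A ggplot object.
#' @export
plot_error_map <- function(metrics, field = "e_h", boundary = NULL,
                           floor_mm = 1e-3) {
  stopifnot(field %in% names(metrics))
  df <- dplyr::mutate(metrics,
                      log_err = log10(pmax(.data[[field]], floor_mm)))
  # require a (near-)uniform rectangular lattice
  ux <- sort(unique(round(df$x, 9)))
  if (length(ux) > 1) {
    dx <- diff(ux)
    if (max(dx) - min(dx) > 1e-6) {
      stop("`metrics` must come from a rectangular target grid", call. = FALSE)
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$log_err)) +
    ggplot2::scale_fill_viridis_c(name = bquote(log[10] ~ .(field) ~ "(mm)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  if (!is.null(boundary)) {
    p <- p + ggplot2::geom_path(data = boundary, linetype = "dashed",
                                colour = "black")
  }
  p
}

#' Write the gridded error values behind an error map
#'
#' @inheritParams plot_error_map
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_error_grid_csv <- function(metrics, path, field = "e_h") {
  write.csv(metrics[, c("target_id", "x", "y", "in_workspace", field)],
            path, row.names = FALSE)
  invisible(path)
}

#' Co-activation distribution heatmap across scenarios
#'
#' Bins the per-target co-activation level of one joint and shows, for each
#' scenario row, the fraction of in-workspace targets per bin on a log
#' colour scale.  Rows are ordered by scenario severity, with re-tuned
#' variants (if present in `control` column) marked `"rt"`.
#'
#' @param metrics A combined metrics tibble with a `scenario` column (and
#'   optionally `control`) over the rectangular grid.
#' @param joint `"shoulder"`, `"elbow"` or `"wrist"`.
#' @param bins Bin edges for the co-activation level.
#' @return A ggplot object; the binned fractions are in its `data`.
#' @export
plot_coactivation_heatmap <- function(metrics, joint = "shoulder",
                                      bins = seq(0, 0.5, by = 0.025)) {
  col <- paste0("coact_", joint)
  stopifnot(col %in% names(metrics), "scenario" %in% names(metrics))
  df <- metrics
  if (!"control" %in% names(df)) df$control <- "baseline"
  df$row_label <- ifelse(df$control == "retuned",
                         paste0(df$scenario, " rt"), df$scenario)
  if ("in_workspace" %in% names(df)) df <- df[df$in_workspace, ]
  df$bin <- cut(pmin(df[[col]], max(bins)), breaks = bins,
                include.lowest = TRUE)
  binned <- df |>
    dplyr::count(.data$row_label, .data$bin) |>
    dplyr::group_by(.data$row_label) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$row_label,
                                       fill = log10(.data$fraction))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 fraction") +
    ggplot2::labs(x = sprintf("average %s co-activation", joint),
                  y = "scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot one reach: endpoint path and distance to target
#'
#' @param object A [simulate_reach()] result with series.
#' @param ... Unused.
#' @return A ggplot object of the spatial endpoint path against the planned
#'   reference, with the target marked.
#' @export
autoplot.reach_result <- function(object, ...) {
  ser <- tidy(object)
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(x = .data$x_ref, y = .data$y_ref),
                       linetype = "dotted", colour = "grey50") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::annotate("point", x = object$target[1], y = object$target[2],
                      shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  subtitle = sprintf("e_h = %.3g mm, e_mv = %.3g mm (%s)",
                                     object$e_h, object$e_mv,
                                     object$failure)) +
    ggplot2::theme_minimal()
}
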