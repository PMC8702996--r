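# Shared phasor-plot scaffolding: universal semicircle + axis labels.
semicircle_df <- function(n = 361L) {
  th <- seq(0, pi, length.out = n)
  data.frame(g = 0.5 + 0.5 * cos(th), s = 0.5 * sin(th))
}

cursor_circle_df <- function(palette, n = 121L) {
  th <- seq(0, 2 * pi, length.out = n)
  do.call(rbind, lapply(seq_len(nrow(palette)), function(i) {
    data.frame(label = palette$label[i],
               g = palette$g[i] + palette$radius[i] * cos(th),
               s = palette$s[i] + palette$radius[i] * sin(th))
  }))
}

state_colors <- c(unclassified = "black", open = "#19A7A7", compact = "#D7301F")

#' Phasor plot of a FLIM image
#'
#' 2-D density of the per-pixel phasors over the standard plot window, with
#' the universal semicircle and, optionally, the cursor palette and a FRET
#' trajectory superimposed.
#'
#' @param object A `phasor_image`.
#' @param palette Optional `cursor_palette` to draw.
#' @param trajectory Optional `fret_trajectory` to draw.
#' @param bins Number of density bins per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_image <- function(object, palette = NULL, trajectory = NULL,
                                  bins = 200L, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$g), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(name = "pixels") +
    ggplot2::geom_path(data = semicircle_df(), linewidth = 0.3,
                       colour = "grey30") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "g", y = "s") +
    ggplot2::theme_minimal()
  if (!is.null(trajectory)) {
    p <- p + ggplot2::geom_path(data = as.data.frame(trajectory),
                                colour = "black", linewidth = 0.5)
  }
  if (!is.null(palette)) {
    p <- p + ggplot2::geom_path(
      data = cursor_circle_df(validate_palette(palette)),
      ggplot2::aes(group = .data$label, colour = .data$label), linewidth = 0.6) +
      ggplot2::scale_colour_manual(values = state_colors, name = "cursor")
  }
  p
}

#' Pseudo-colored chromatin-state map
#'
#' The reciprocal-mode image: open pixels teal, compact pixels red,
#' unclassified pixels black, mirroring published FLIM-map pseudo-coloring.
#'
#' @param object A [classify_pixels()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatin_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = state_colors, name = "state") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' FRET trajectory in the phasor plot
#'
#' @param object A [build_fret_trajectory()] result.
#' @param palette Optional `cursor_palette` to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_trajectory <- function(object, palette = NULL, ...) {
  df <- as.data.frame(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_path(data = semicircle_df(), linewidth = 0.3,
                       colour = "grey30") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$E), linewidth = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "E") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "g", y = "s") +
    ggplot2::theme_minimal()
  if (!is.null(palette)) {
    p <- p + ggplot2::geom_path(
      data = cursor_circle_df(validate_palette(palette)),
      ggplot2::aes(group = .data$label), colour = "grey10", linewidth = 0.5)
  }
  p
}

#' Histogram of compact-chromatin particle areas
#'
#' @param object A `foci_table` (or list pooled via [area_histogram()]).
#' @param bin_edges Passed to [area_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foci_table <- function(object, bin_edges = NULL, ...) {
  h <- area_histogram(object, bin_edges)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo) * 0.9, fill = "#D7301F") +
    ggplot2::labs(x = expression("particle area (" * mu * m^2 * ")"),
                  y = "particles") +
    ggplot2::theme_minimal()
}
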