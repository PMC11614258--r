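# ggplot2 display methods for the main result types.

#' Plot a band image
#'
#' @param x A `band_image` from [slice_band()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot band_image
#' @export
autoplot.band_image <- function(x, ...) {
  df <- expand.grid(row = seq_len(nrow(x$values)),
                    col = seq_len(ncol(x$values)))
  df$value <- as.vector(x$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%.1f nm", x$wavelength), fill = "value")
}

#' Plot a 2-D spectral embedding
#'
#' @param x A mapped `spectral_embedding` (after [manifold_embed()]).
#' @param colour Metadata column to colour by (default `"patch"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectral_embedding
#' @export
autoplot.spectral_embedding <- function(x, colour = "patch", ...) {
  sc <- x$scores
  if (!"x" %in% names(sc)) {
    abort("embedding has no 2-D map yet; run manifold_embed() first",
          class = "avicube_error_value")
  }
  if (!colour %in% names(sc)) colour <- NULL
  ggplot2::ggplot(sc, ggplot2::aes(.data$x, .data$y)) +
    (if (is.null(colour)) ggplot2::geom_point(alpha = 0.6, size = 0.8)
     else ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                              alpha = 0.6, size = 0.8)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2")
}

#' Plot highest-density-region contours
#'
#' Draws each group's HDR contour (at its stored level) over the embedding
#' grid.
#'
#' @param x A `density_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_field
#' @export
autoplot.density_field <- function(x, ...) {
  dfs <- lapply(names(x$density), function(g) {
    cl <- grDevices::contourLines(x$x, x$y, x$density[[g]],
                                  levels = x$levels[[g]])
    if (!length(cl)) return(NULL)
    dplyr::bind_rows(lapply(seq_along(cl), function(i) {
      tibble(group = g, piece = i, x = cl[[i]]$x, y = cl[[i]]$y)
    }))
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group,
                                   group = interaction(.data$group,
                                                       .data$piece))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = x$modes,
                        ggplot2::aes(.data$x, .data$y, colour = .data$group),
                        inherit.aes = FALSE, shape = 4, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2",
                  title = sprintf("%.0f%% highest-density regions",
                                  100 * x$mass))
}

#' Plot median +/- MAD spectra (mode spectra or pitch bins)
#'
#' @param spectra Long tibble with `wavelength`, `median`, `mad` and a
#'   grouping column.
#' @param group Grouping column name (default `"group"`).
#' @return A ggplot.
#' @export
plot_spectra_summary <- function(spectra, group = "group") {
  ggplot2::ggplot(spectra,
                  ggplot2::aes(.data$wavelength, .data$median,
                               colour = .data[[group]],
                               fill = .data[[group]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median - .data$mad,
                                      ymax = .data$median + .data$mad),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
}

#' Plot a surface-normal map
#'
#' @param x A `normal_map`.
#' @param component `"pitch"` (default) or `"roll"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot normal_map
#' @export
autoplot.normal_map <- function(x, component = c("pitch", "roll"), ...) {
  component <- match.arg(component)
  v <- x[[component]]
  df <- expand.grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$angle <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$angle)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-pi, pi), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = component)
}
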