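#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 1D profile
#'
#' @param object A `ppt_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppt_profile
#' @export
autoplot.ppt_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_col(width = attr(object, "bin_mm"), fill = "grey60") +
    ggplot2::labs(x = sprintf("%s (mm)", attr(object, "coord")),
                  y = if (attr(object, "normalized")) "normalized counts"
                      else "counts") +
    ggplot2::theme_minimal()
}

#' Plot a profile fit over its histogram
#'
#' @param object A `ppt_profile_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppt_profile_fit
#' @export
autoplot.ppt_profile_fit <- function(object, ...) {
  pr <- object$profile
  xf <- seq(min(pr$x), max(pr$x), length.out = 800)
  yf <- object$A / (1 + (xf / object$sigma)^2) +
    object$B * exp(-object$C * abs(xf))
  autoplot(pr) +
    ggplot2::geom_line(data = tibble::tibble(x = xf, value = yf),
                       ggplot2::aes(x = .data$x, y = .data$value),
                       color = "red") +
    ggplot2::labs(subtitle = sprintf("FWHM (Lorentzian component) = %.2f mm",
                                     object$fwhm))
}

#' Plot a central slice of a reconstructed image
#'
#' @param object A `ppt_image3d`.
#' @param plane `"xy"` or `"xz"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppt_image3d
#' @export
autoplot.ppt_image3d <- function(object, plane = c("xy", "xz"), ...) {
  plane <- match.arg(plane)
  d <- dim(object)
  sl <- if (plane == "xy") object[, , ceiling(d[3] / 2)]
        else object[, ceiling(d[2] / 2), ]
  v <- attr(object, "voxel_mm")
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  s2 <- if (plane == "xy") v[2] else v[3]
  df$u <- (df$i - nrow(sl) / 2 - 0.5) * v[1]
  df$w <- (df$j - ncol(sl) / 2 - 0.5) * s2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$w,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = if (plane == "xy") "y (mm)" else "z (mm)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a 2D event density map
#'
#' @param events A data frame with `x`, `y`, `z` (mm), e.g. `log$pairs`.
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @param bin_mm Bin width in mm.
#' @return A ggplot.
#' @export
plot_event_map <- function(events, plane = "xz", bin_mm = 2) {
  m <- event_map(events, plane, bin_mm)
  ax <- names(m)[1:2]
  ggplot2::ggplot(m, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                  fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(mm)"), y = paste(ax[2], "(mm)")) +
    ggplot2::theme_minimal()
}
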