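# ggplot2 views of the pipeline objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_raster facet_wrap labs scale_fill_viridis_c coord_fixed
#'   geom_hline theme_minimal
NULL

#' Plot a transaxial slice of a volume
#'
#' @param x A `spect_phantom` (activity), `recon_volume`, or 3-D array.
#' @param slice Slice index; default the central slice.
#' @param what For phantoms: `"activity"`, `"mu"` or `"labels"`.
#' @return A ggplot object.
#' @export
plot_slice <- function(x, slice = NULL, what = "activity") {
  vals <- if (inherits(x, "spect_phantom")) {
    x[[what]]
  } else if (inherits(x, "recon_volume")) {
    x$values
  } else x
  if (is.null(slice)) slice <- ceiling(dim(vals)[3] / 2)
  m <- vals[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = NULL) +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = sprintf("slice %d", slice)) +
    theme_minimal()
}

#' @method autoplot spect_phantom
#' @export
autoplot.spect_phantom <- function(object, ...) plot_slice(object, ...)

#' @method autoplot recon_volume
#' @export
autoplot.recon_volume <- function(object, ...) plot_slice(object, ...)

#' Recovery-coefficient plot of a quantification result
#'
#' RC per sphere diameter, with the 100% line (perfect recovery).
#'
#' @param object A `quant_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quant_result
#' @export
autoplot.quant_result <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$sphere_mm,
                                levels = sort(unique(.data$sphere_mm))),
                     y = .data$rc)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 100, linetype = "dashed") +
    labs(x = "sphere diameter (mm)", y = "recovery coefficient (%)") +
    theme_minimal()
}

#' Sweep curves: RC versus the swept parameter
#'
#' One line per sphere, faceted by T/B ratio; multiple seeds are drawn as
#' points.
#'
#' @param object A `sweep_result`.
#' @param metric Column to plot (default `"rc"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, metric = "rc", ...) {
  param <- attr(object, "param")
  df <- sweep_mean(object, metric)
  p <- ggplot(df, aes(x = .data$value, y = .data$m,
                      colour = factor(.data$sphere_mm),
                      group = factor(.data$sphere_mm)))
  p <- if (is.numeric(df$value)) p + geom_line() + geom_point() else
    p + geom_point()
  p +
    facet_wrap(~tb_ratio, labeller = ggplot2::label_both) +
    labs(x = param, y = sprintf("%s (%%)", toupper(metric)),
         colour = "sphere (mm)") +
    theme_minimal()
}
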