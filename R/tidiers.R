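# broom-style accessors for the fitted-statistics and volume objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sweep-statistics object
#'
#' One row per (T/B ratio, sphere): correlation, p-value and regression
#' coefficients of RC against the swept parameter.
#'
#' @param x A `sweep_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sweep_stats
#' @export
tidy.sweep_stats <- function(x, ...) {
  out <- as_tibble(x)
  out$parameter <- attr(x, "param") %||% NA_character_
  out
}

#' Summarise a sweep-statistics object
#'
#' @param x A `sweep_stats` object.
#' @param ... Unused.
#' @return One-row tibble: swept parameter, group count, range of r and of
#'   the regression slope (the span the benchmark tables report).
#' @method glance sweep_stats
#' @export
glance.sweep_stats <- function(x, ...) {
  tibble(parameter = attr(x, "param") %||% NA_character_,
         groups = nrow(x),
         r_min = min(x$r), r_max = max(x$r),
         slope_min = min(x$slope), slope_max = max(x$slope))
}

#' Tidy a quantification result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return The metric columns per sphere as a plain tibble.
#' @method tidy quant_result
#' @export
tidy.quant_result <- function(x, ...) {
  as_tibble(x)[, c("sphere_mm", "rc", "contrast", "cov", "mean", "sd")]
}

#' Summarise a reconstructed volume
#'
#' @param x A `recon_volume`.
#' @param ... Unused.
#' @return One-row tibble with the reconstruction settings and the total
#'   reconstructed activity (MBq).
#' @method glance recon_volume
#' @export
glance.recon_volume <- function(x, ...) {
  tibble(iterations = x$config$iterations,
         subsets = x$config$subsets,
         corrections = paste(x$config$corrections, collapse = "+"),
         post_filter_fwhm = x$config$post_filter_fwhm %||% NA_real_,
         total_mbq = sum(x$values) * prod(x$voxel) / 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
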