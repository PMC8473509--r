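# Statistical engines used by the parameter sweeps: product-moment
# correlation, least-squares regression, paired t-tests and RC-curve
# convergence detection. Thin wrappers over stats:: so p-values and degrees
# of freedom follow the standard implementations.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from `t = r sqrt((n-2)/(1-r^2))` on n-2
#' degrees of freedom (as `stats::cor.test`).
#'
#' @param x,y Numeric vectors, length >= 3, both non-constant.
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Least-squares linear regression
#'
#' @param x,y Numeric vectors, length >= 2; x non-constant.
#' @return Tibble: `slope` (the regression coefficient), `intercept`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 observations")
  if (sd(x) == 0) abort("x must not be constant")
  fit <- lm(y ~ x)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Paired t-test
#'
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `n - 1` degrees of freedom,
#' two-sided.
#'
#' @param a,b Paired numeric vectors of equal length n >= 2 whose
#'   differences have nonzero variance.
#' @return Tibble: `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  if (length(a) < 2) abort("need at least 2 pairs")
  if (sd(a - b) == 0) {
    abort("degenerate test: paired differences have zero variance")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Detect convergence of an RC-versus-iteration curve
#'
#' The study never defines "converged"; here the convergence iteration is
#' the smallest n such that RC gains less than `tol` percentage points over
#' the next `window` iterations: `max(rc[n..n+window]) - rc[n] < tol`.
#'
#' @param rc_curve RC values at iterations 1, 2, ... (percent).
#' @param window Look-ahead window in iterations (default 10).
#' @param tol Tolerated gain in percentage points (default 1).
#' @return The convergence iteration, or `NA_integer_` if never reached.
#' @export
convergence_iteration <- function(rc_curve, window = 10L, tol = 1) {
  n <- length(rc_curve)
  if (n < window + 1) abort("curve shorter than window + 1")
  for (i in seq_len(n - window)) {
    seg <- rc_curve[i:(i + window)]
    if (max(seg) - rc_curve[i] < tol) return(i)
  }
  NA_integer_
}

#' Early/late segment statistics of an iteration sweep
#'
#' Correlation and regression of RC against iteration number, computed
#' separately for iterations `1..boundary` and `boundary..max` (the boundary
#' iteration belongs to both segments, mirroring the overlapping printed
#' ranges), per T/B ratio and sphere.
#'
#' @param sweep A `sweep_result` from an `"iterations"` sweep.
#' @param boundary Segment boundary iteration (default 35).
#' @return Tibble with columns `tb_ratio`, `sphere_mm`, `segment`, `r`,
#'   `p_value`, `slope`, `intercept`.
#' @export
segmented_iteration_stats <- function(sweep, boundary = 35) {
  stopifnot(is.data.frame(sweep), "value" %in% names(sweep))
  if (!any(sweep$value <= boundary) || !any(sweep$value >= boundary)) {
    abort("sweep does not cover both segments")
  }
  segs <- list(early = c(-Inf, boundary), late = c(boundary, Inf))
  out <- list()
  for (sn in names(segs)) {
    dat <- sweep %>%
      filter(.data$value >= segs[[sn]][1], .data$value <= segs[[sn]][2]) %>%
      group_by(.data$tb_ratio, .data$sphere_mm) %>%
      summarise(
        stats = list(dplyr::bind_cols(
          # a perfectly flat curve has slope 0 but no defined correlation
          tryCatch(pearson_correlation(.data$value, .data$rc),
                   error = function(e) tibble(r = NA_real_,
                                              p_value = NA_real_,
                                              n = dplyr::n())),
          linear_regression(.data$value, .data$rc))),
        .groups = "drop") %>%
      tidyr::unnest("stats") %>%
      mutate(segment = sn)
    out[[sn]] <- dat
  }
  bind_rows(out) %>%
    select(all_of(c("tb_ratio", "sphere_mm", "segment", "r", "p_value",
                    "slope", "intercept")))
}
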