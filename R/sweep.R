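# Parameter-sweep drivers reproducing the sequential optimization protocol:
# iterations -> subsets -> post-filter FWHM -> correction combination ->
# energy window -> acquisition time, each sweep run through
# simulate -> reconstruct -> quantify with shared projections cached.

#' Study sphere concentration for a target-to-background ratio
#'
#' The four study ratios use measured sphere concentrations 0.20, 0.11,
#' 0.06 and 0.03 MBq/ml (32:1, 16:1, 8:1, 4:1). Other ratios fall back to a
#' constant background of 0.00625 MBq/ml.
#'
#' @param tb_ratio Target-to-background ratio.
#' @return Sphere activity concentration in MBq/ml.
#' @export
tb_concentration <- function(tb_ratio) {
  lut <- c("32" = 0.20, "16" = 0.11, "8" = 0.06, "4" = 0.03)
  key <- as.character(tb_ratio)
  ifelse(key %in% names(lut), unname(lut[key]), 0.00625 * tb_ratio)
}

#' Simulation-scale phantom specification
#'
#' The phantom used by the sweep drivers: full IEC geometry on a
#' 64 x 64 x 36 grid at 5.5 mm voxels — coarse enough for desk-scale
#' reconstruction sweeps while keeping at least one voxel centre inside the
#' 10 mm sphere at any alignment.
#'
#' @param tb_ratio Target-to-background ratio.
#' @param sphere_conc Sphere concentration; default from
#'   [tb_concentration()].
#' @param voxel,grid Override the simulation grid.
#' @return A `phantom_spec`.
#' @export
sim_phantom_spec <- function(tb_ratio = 32,
                             sphere_conc = tb_concentration(tb_ratio),
                             voxel = 5.5, grid = c(64L, 64L, 36L)) {
  phantom_spec(tb_ratio = tb_ratio, sphere_conc = sphere_conc,
               voxel = voxel, grid = grid)
}

#' Fixed-parameter context of a sweep
#'
#' Defaults follow the sequential protocol's starting point: 35 iterations
#' (6 subsets while iterations themselves are swept, 20 after), no filter,
#' AC + SC + RR, 120 s/frame, 15% window.
#'
#' @param iterations,subsets,fwhm,corrections,width_pct,time Fixed values
#'   for the parameters not being swept.
#' @return A list used as the `base` argument of [run_sweep()].
#' @export
sweep_base <- function(iterations = 35L, subsets = 20L, fwhm = NULL,
                       corrections = c("AC", "SC", "RR"),
                       width_pct = 15, time = 120) {
  list(iterations = as.integer(iterations), subsets = as.integer(subsets),
       fwhm = fwhm, corrections = corrections, width_pct = width_pct,
       time = time)
}

parse_corrections <- function(value) strsplit(value, "\\+")[[1]]

#' Run a parameter sweep
#'
#' Executes simulate -> reconstruct -> quantify over a parameter grid.
#' Projections are shared wherever the swept parameter does not change the
#' acquisition (iterations, subsets, FWHM, corrections), intermediate OSEM
#' iterates are recorded in one pass for iteration sweeps, and post-filter
#' values reuse one unfiltered reconstruction.
#'
#' @param param One of `"iterations"`, `"subsets"`, `"fwhm"`,
#'   `"corrections"`, `"window"`, `"time"`.
#' @param grid_values The grid: integers for iterations/subsets, mm for
#'   fwhm, strings like `"AC+SC+RR"` for corrections, window percents
#'   (15, 20), or seconds per frame for time.
#' @param tb_ratios T/B ratios to run (any of 32, 16, 8, 4).
#' @param seeds Integer vector of noise seeds; one sweep per seed.
#' @param noise Poisson noise on? Noiseless runs are used for convergence
#'   and filter properties.
#' @param base Fixed-parameter context from [sweep_base()].
#' @param spec_fn Function `tb_ratio -> phantom_spec`; default
#'   [sim_phantom_spec()].
#' @return A `sweep_result` tibble: `tb_ratio`, `sphere_mm`, `param`,
#'   `value`, `rc`, `contrast`, `cov`, `mean`, `sd`, `seed`.
#' @export
run_sweep <- function(param = c("iterations", "subsets", "fwhm",
                                "corrections", "window", "time"),
                      grid_values,
                      tb_ratios = 32,
                      seeds = 1L,
                      noise = TRUE,
                      base = sweep_base(),
                      spec_fn = sim_phantom_spec) {
  param <- match.arg(param)
  if (length(grid_values) < 1) abort("empty sweep grid")
  if (param == "iterations") base$subsets <- min(base$subsets, 6L)

  rows <- list()
  add <- function(q, value, tb, seed) {
    rows[[length(rows) + 1L]] <<- q %>%
      mutate(param = param,
             value = value, seed = seed) %>%
      select(all_of(c("tb_ratio", "sphere_mm", "param", "value", "rc",
                      "contrast", "cov", "mean", "sd", "seed")))
  }

  for (tb in tb_ratios) {
    phant <- build_phantom(spec_fn(tb))
    rois <- place_background_rois(phant)
    for (seed in seeds) {
      acq <- function(width_pct = base$width_pct, time = base$time) {
        acquisition_config(time_per_frame = time,
                           window = energy_window(width_pct),
                           seed = child_seed(seed, "acq", tb, width_pct))
      }
      rc_cfg <- function(iterations = base$iterations,
                         subsets = base$subsets,
                         corrections = base$corrections,
                         fwhm = base$fwhm) {
        recon_config(iterations = iterations, subsets = subsets,
                     corrections = corrections, post_filter_fwhm = fwhm)
      }

      if (param == "iterations") {
        ps <- simulate_projections(phant, acq(), noise = noise)
        vol <- osem_reconstruct(ps, phant$mu,
                                rc_cfg(iterations = max(grid_values)),
                                record_iterations = grid_values)
        for (it in grid_values) {
          v <- vol; v$values <- vol$iterates[[as.character(it)]]
          add(quantify(v, phant, rois), it, tb, seed)
        }
      } else if (param == "subsets") {
        ps <- simulate_projections(phant, acq(), noise = noise)
        for (S in grid_values) {
          vol <- osem_reconstruct(ps, phant$mu, rc_cfg(subsets = S))
          add(quantify(vol, phant, rois), S, tb, seed)
        }
      } else if (param == "fwhm") {
        ps <- simulate_projections(phant, acq(), noise = noise)
        vol <- osem_reconstruct(ps, phant$mu, rc_cfg(fwhm = NULL))
        for (f in grid_values) {
          vf <- if (f > 0) gaussian_postfilter(vol, f) else vol
          add(quantify(vf, phant, rois), f, tb, seed)
        }
      } else if (param == "corrections") {
        ps <- simulate_projections(phant, acq(), noise = noise)
        for (combo in grid_values) {
          vol <- osem_reconstruct(
            ps, phant$mu, rc_cfg(corrections = parse_corrections(combo)))
          add(quantify(vol, phant, rois), combo, tb, seed)
        }
      } else if (param == "window") {
        for (w in grid_values) {
          ps <- simulate_projections(phant, acq(width_pct = w),
                                     noise = noise)
          vol <- osem_reconstruct(ps, phant$mu, rc_cfg())
          add(quantify(vol, phant, rois), w, tb, seed)
        }
      } else if (param == "time") {
        full <- max(grid_values, base$time)
        ps <- simulate_projections(phant, acq(time = full), noise = noise)
        for (tt in sort(grid_values, decreasing = TRUE)) {
          pst <- if (tt < full) {
            rebin_time(ps, tt, seed = child_seed(seed, "rebin", tb, tt))
          } else ps
          vol <- osem_reconstruct(pst, phant$mu, rc_cfg())
          add(quantify(vol, phant, rois), tt, tb, seed)
        }
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "param") <- param
  attr(out, "base") <- base
  class(out) <- c("sweep_result", class(out))
  out
}

#' Correlation and regression statistics of a numeric sweep
#'
#' Pearson correlation and least-squares regression of RC against the swept
#' value, per T/B ratio and sphere (the Table-1-style summary).
#'
#' @param sweep A `sweep_result` with numeric `value`.
#' @return A `sweep_stats` tibble: `tb_ratio`, `sphere_mm`, `r`, `p_value`,
#'   `slope`, `intercept`, `n`.
#' @export
sweep_stats <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  if (!is.numeric(sweep$value)) {
    abort("sweep_stats requires a numeric swept parameter")
  }
  out <- sweep %>%
    group_by(.data$tb_ratio, .data$sphere_mm) %>%
    summarise(
      stats = list(dplyr::bind_cols(
        pearson_correlation(.data$value, .data$rc),
        linear_regression(.data$value, .data$rc))),
      .groups = "drop") %>%
    tidyr::unnest("stats") %>%
    arrange(.data$tb_ratio, dplyr::desc(.data$sphere_mm))
  attr(out, "param") <- attr(sweep, "param")
  class(out) <- c("sweep_stats", class(out))
  out
}

# Mean metric per (ratio, sphere, value) across seeds, wide by value.
sweep_mean <- function(sweep, metric = "rc") {
  sweep %>%
    group_by(.data$tb_ratio, .data$sphere_mm, .data$value) %>%
    summarise(m = mean(.data[[metric]]), .groups = "drop")
}

#' Paired comparison of two sweep settings
#'
#' Paired t-test across the six spheres of the seed-averaged metric at two
#' values of the swept parameter (how the printed tables compare correction
#' combinations, windows and frame times).
#'
#' @param sweep A `sweep_result`.
#' @param value_a,value_b The two settings to compare.
#' @param metric `"rc"`, `"contrast"` or `"cov"`.
#' @return Tibble with `tb_ratio`, `t`, `df`, `p_value`.
#' @export
sweep_paired_test <- function(sweep, value_a, value_b, metric = "rc") {
  m <- sweep_mean(sweep, metric)
  out <- list()
  for (tb in unique(m$tb_ratio)) {
    a <- m %>% filter(.data$tb_ratio == tb, .data$value == value_a) %>%
      arrange(.data$sphere_mm)
    b <- m %>% filter(.data$tb_ratio == tb, .data$value == value_b) %>%
      arrange(.data$sphere_mm)
    out[[length(out) + 1L]] <- paired_t_test(a$m, b$m) %>%
      mutate(tb_ratio = tb, a = value_a, b = value_b)
  }
  bind_rows(out) %>%
    select(all_of(c("tb_ratio", "a", "b", "t", "df", "p_value")))
}

#' Write the report bundle of a sweep set
#'
#' Emits the printed-table layouts as CSV: per-parameter correlation and
#' regression rows, metric-by-correction-combination tables with paired
#' p-values, and RC-by-window / RC-by-time tables.
#'
#' @param sweeps Named list of `sweep_result` objects (names are the swept
#'   parameters).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, name, precision = NULL) {
    p <- file.path(dir, name)
    write_tables(df, p, precision = precision)
    paths <<- c(paths, p)
  }

  stats_rows <- list()
  for (nm in names(sweeps)) {
    sw <- sweeps[[nm]]
    if (is.numeric(sw$value) && length(unique(sw$value)) >= 3) {
      if (identical(attr(sw, "param"), "iterations")) {
        seg <- segmented_iteration_stats(sw,
          boundary = min(35, max(sw$value)))
        stats_rows[[nm]] <- seg %>%
          mutate(parameter = paste0(nm, " (", .data$segment, ")")) %>%
          select(-all_of("segment"))
      } else {
        stats_rows[[nm]] <- sweep_stats(sw) %>%
          mutate(parameter = nm) %>%
          select(-all_of("n"))
      }
    }
  }
  if (length(stats_rows) > 0) {
    emit(bind_rows(stats_rows), "parameter_stats.csv")
  }

  wide <- function(sw, metric) {
    sweep_mean(sw, metric) %>%
      tidyr::pivot_wider(names_from = "sphere_mm", values_from = "m",
                         names_prefix = "sphere_")
  }
  if ("corrections" %in% names(sweeps)) {
    sw <- sweeps$corrections
    ref <- "AC+SC+RR"
    others <- setdiff(unique(sw$value), ref)
    for (metric in c("rc", "contrast", "cov")) {
      tabs <- wide(sw, metric)
      ps <- bind_rows(lapply(others, function(o) {
        sweep_paired_test(sw, ref, o, metric)
      }))
      emit(tabs, sprintf("corrections_%s.csv", metric))
      emit(ps, sprintf("corrections_%s_tests.csv", metric),
           precision = c(p_value = 3))
    }
  }
  for (nm in intersect(c("window", "time"), names(sweeps))) {
    emit(wide(sweeps[[nm]], "rc"), sprintf("%s_rc.csv", nm))
    vv <- sort(unique(sweeps[[nm]]$value))
    if (length(vv) >= 2) {
      emit(sweep_paired_test(sweeps[[nm]], vv[1], vv[length(vv)]),
           sprintf("%s_rc_tests.csv", nm), precision = c(p_value = 3))
    }
  }
  invisible(paths)
}
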