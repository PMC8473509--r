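# Sweep bookkeeping and reporting on miniature configurations (the heavy
# scientific properties of the sweeps live in the acceptance tests).

mini_spec <- function(tb) sim_phantom_spec(tb)

test_that("a one-point sweep yields one record per ratio and sphere", {
  sw <- run_sweep("fwhm", 4.0, tb_ratios = 32, seeds = 1, noise = FALSE,
                  base = sweep_base(iterations = 2, subsets = 6),
                  spec_fn = mini_spec)
  expect_equal(nrow(sw), 6)
  expect_setequal(sw$sphere_mm, c(37, 28, 22, 17, 13, 10))
  expect_true(all(is.finite(sw$rc)))
  expect_error(run_sweep("fwhm", numeric(0)), "empty")
})

test_that("sweeps are reproducible from their seeds", {
  base <- sweep_base(iterations = 2, subsets = 6)
  a <- run_sweep("corrections", c("AC+SC", "AC+SC+RR"), tb_ratios = 32,
                 seeds = 7, base = base, spec_fn = mini_spec)
  b <- run_sweep("corrections", c("AC+SC", "AC+SC+RR"), tb_ratios = 32,
                 seeds = 7, base = base, spec_fn = mini_spec)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("sweep statistics reproduce the per-group engine results", {
  set.seed(31)
  sw <- tidyr::expand_grid(tb_ratio = c(32, 4), sphere_mm = c(37, 10),
                           value = c(1, 2, 5, 10, 20), seed = 1)
  sw$rc <- 50 + 2 * sw$value + rnorm(nrow(sw))
  sw$contrast <- sw$rc; sw$cov <- 10; sw$mean <- 1; sw$sd <- 0.1
  sw$param <- "iterations"
  attr(sw, "param") <- "iterations"
  class(sw) <- c("sweep_result", class(sw))
  st <- sweep_stats(sw)
  expect_equal(nrow(st), 4)
  one <- sw[sw$tb_ratio == 32 & sw$sphere_mm == 37, ]
  expect_equal(st$r[st$tb_ratio == 32 & st$sphere_mm == 37],
               pearson_correlation(one$value, one$rc)$r, tolerance = 1e-12)
  expect_equal(st$slope[st$tb_ratio == 32 & st$sphere_mm == 37],
               linear_regression(one$value, one$rc)$slope,
               tolerance = 1e-12)
  td <- tidy(st)
  expect_equal(td$parameter, rep("iterations", 4))
  gl <- glance(st)
  expect_equal(gl$groups, 4)
})

test_that("paired sweep comparisons recompute from the emitted rows", {
  sw <- tidyr::expand_grid(tb_ratio = 32, sphere_mm = c(37, 28, 22, 17, 13, 10),
                           value = c(15, 20), seed = 1)
  set.seed(5)
  sw$rc <- 70 + 10 * (sw$value == 15) * runif(nrow(sw)) + rnorm(nrow(sw))
  sw$contrast <- sw$rc; sw$cov <- 10; sw$mean <- 1; sw$sd <- 0.1
  sw$param <- "window"
  attr(sw, "param") <- "window"
  class(sw) <- c("sweep_result", class(sw))
  cmp <- sweep_paired_test(sw, 15, 20)
  a <- sw$rc[sw$value == 15][order(sw$sphere_mm[sw$value == 15])]
  b <- sw$rc[sw$value == 20][order(sw$sphere_mm[sw$value == 20])]
  direct <- paired_t_test(a, b)
  expect_equal(cmp$p_value, direct$p_value, tolerance = 1e-12)
  expect_equal(cmp$df, 5)
})

test_that("report bundles contain the expected table files", {
  dir <- withr::local_tempdir()
  sw <- run_sweep("corrections", c("AC+SC+RR", "AC+SC"), tb_ratios = 32,
                  seeds = 1, base = sweep_base(iterations = 2, subsets = 6),
                  spec_fn = mini_spec)
  paths <- report_tables(list(corrections = sw), dir)
  expect_true(file.exists(file.path(dir, "corrections_rc.csv")))
  expect_true(file.exists(file.path(dir, "corrections_rc_tests.csv")))
  rc <- utils::read.csv(file.path(dir, "corrections_rc.csv"))
  expect_equal(nrow(rc), 2)                # one row per combination
  expect_equal(ncol(rc), 8)                # ratio + value + six spheres
})

test_that("the sequential study driver completes a miniature protocol", {
  cfg <- study_config(
    tb_ratios = 32, seed = 3,
    grids = list(corrections = c("AC+SC+RR", "AC+SC"), window = NULL,
                 iterations = NULL, subsets = NULL, fwhm = NULL,
                 time = NULL),
    base = sweep_base(iterations = 2, subsets = 6),
    out_dir = NULL)
  res <- run_study(cfg)
  expect_true("corrections" %in% res$chosen$step)
  expect_s3_class(res$sweeps$corrections, "sweep_result")
})
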