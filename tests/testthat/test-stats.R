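# Statistical engines against independent closed-form oracles, and the
# convergence detector against exhaustive scanning.

closed_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  c(r = r, p = p)
}

closed_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  c(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

test_that("pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(3, 10)), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("linear regression matches the normal equations", {
  x <- 0:19
  expect_equal(linear_regression(x, 3 * x)$slope, 3)
  expect_equal(linear_regression(x, 3 * x)$intercept, 0)
  fit2 <- linear_regression(c(0, 1), c(1, 4))
  expect_equal(fit2$slope, 3)
  expect_equal(fit2$intercept, 1)
  set.seed(8)
  y <- 2.5 * x + rnorm(20)
  fit <- linear_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})

test_that("statistical engines agree with closed forms on 1000 instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    pc <- pearson_correlation(x, y)
    or <- closed_pearson(x, y)
    expect_equal(pc$r, unname(or["r"]), tolerance = 1e-10)
    expect_equal(pc$p_value, unname(or["p"]), tolerance = 1e-10)
    tt <- paired_t_test(x, y)
    ot <- closed_paired_t(x, y)
    expect_equal(tt$t, unname(ot["t"]), tolerance = 1e-10)
    expect_equal(tt$df, unname(ot["df"]))
    expect_equal(tt$p_value, unname(ot["p"]), tolerance = 1e-10)
  }
})

test_that("paired t-test rejects degenerate input", {
  a <- c(1, 2, 3)
  expect_error(paired_t_test(a, a), "degenerate")
  expect_error(paired_t_test(a, a + 2), "degenerate")  # constant shift
  expect_error(paired_t_test(a, 1:2), "equal length")
})

test_that("convergence detection matches an exhaustive scan", {
  expect_equal(convergence_iteration(rep(50, 20)), 1)
  rising <- seq(0, 90, by = 2)            # gains 20 pp per 10-it window
  expect_true(is.na(convergence_iteration(rising)))
  curve <- 100 * (1 - exp(-(1:60) / 10))
  brute <- NA_integer_
  for (n in 1:(60 - 10)) {
    if (max(curve[n:(n + 10)]) - curve[n] < 1) { brute <- n; break }
  }
  expect_equal(convergence_iteration(curve, 10, 1), brute)
  expect_error(convergence_iteration(1:5, window = 10), "shorter")
})

test_that("segmented iteration statistics split at the boundary", {
  its <- 1:90
  sat <- tibble::tibble(tb_ratio = 32, sphere_mm = 37, param = "iterations",
                        value = its, rc = 100 * (1 - exp(-its / 15)))
  seg <- segmented_iteration_stats(sat)
  expect_gt(seg$slope[seg$segment == "early"],
            seg$slope[seg$segment == "late"])
  lin <- sat; lin$rc <- 0.5 * its + 3
  seg2 <- segmented_iteration_stats(lin)
  expect_equal(seg2$slope, c(0.5, 0.5), tolerance = 1e-10)
  flat <- sat; flat$rc <- 70 + 0
  seg3 <- segmented_iteration_stats(flat)
  expect_equal(seg3$slope, c(0, 0))
  expect_true(all(is.na(seg3$r)))
})
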