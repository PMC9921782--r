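# Benchmark error statistics and their bootstrap uncertainties.

test_that("error statistics reproduce hand arithmetic", {
  s <- error_stats(c(1, 2), c(0, 4))
  expect_equal(s$mue, 1.5)
  expect_equal(s$mse, -0.5)
  expect_equal(s$rmse, sqrt(2.5))
  expect_equal(s$max_error, 2)

  identical_case <- error_stats(c(-3, -7, -1), c(-3, -7, -1))
  expect_equal(identical_case$mue, 0)
  expect_equal(identical_case$rmse, 0)
  expect_equal(identical_case$r2, 1)
  expect_equal(identical_case$slope, 1)

  affine <- error_stats(2 * c(-3, -7, -1) + 3, c(-3, -7, -1))
  expect_equal(affine$r2, 1)
  expect_equal(affine$slope, 2)
})

test_that("degenerate stats inputs are explicit errors", {
  expect_error(error_stats(1:3, 1:2), "equal length")
  expect_error(error_stats(c(1, 2), c(3, 3)), "zero variance")
  expect_error(pearson_r2(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r2(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("pearson_r2 matches known values and affine invariance", {
  expect_equal(pearson_r2(1:5, 2 * (1:5) - 7), 1.0)
  expect_equal(pearson_r2(c(1, 2, 3), c(1, -2, 1)), 0.0)
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  base <- pearson_r2(x, y)
  expect_equal(pearson_r2(3.7 * x - 2, y), base, tolerance = 1e-12)
  expect_equal(pearson_r2(x, 0.01 * y + 5), base, tolerance = 1e-12)
})

test_that("statistic ordering invariants hold on random inputs", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    pred <- rnorm(n, -5, 4)
    exp_ <- rnorm(n, -5, 4)
    s <- error_stats(pred, exp_)
    expect_lte(s$mue, s$rmse)
    expect_lte(s$rmse, s$max_error)
    expect_lte(abs(s$mse), s$mue)
    expect_gte(s$r2, 0)
    expect_lte(s$r2, 1)
  }
})

test_that("relative error filters on the experimental cutoff", {
  expect_equal(relative_error(-12, -10), 0.2)
  expect_error(relative_error(-3, -4), "relative error undefined")
  # boundary: exactly -5 does not pass the strict < cutoff
  expect_error(relative_error(-5, -5), "undefined")
  expect_equal(relative_error(c(-12, -1), c(-10, -1)), 0.2)
  expect_equal(relative_error(c(-8, -9), c(-8, -9)), 0)
})

test_that("bootstrap is seeded, reproducible, and self-consistent", {
  set.seed(101)
  exp_ <- rnorm(60, -6, 3)
  pred <- exp_ + rnorm(60, 0, 1)
  s1 <- bootstrap_stats(pred, exp_, n_boot = 200, seed = 7)
  s2 <- bootstrap_stats(pred, exp_, n_boot = 200, seed = 7)
  expect_identical(attr(s1, "uncertainty"), attr(s2, "uncertainty"))
  s3 <- bootstrap_stats(pred, exp_, n_boot = 200, seed = 8)
  expect_false(identical(attr(s1, "uncertainty"), attr(s3, "uncertainty")))

  # point values come from the unresampled data
  expect_equal(unclass(s1)[c("mue", "rmse")],
               unclass(error_stats(pred, exp_))[c("mue", "rmse")])

  # degenerate but valid: pred == exp gives all-zero error uncertainties
  sd0 <- bootstrap_stats(exp_, exp_, n_boot = 50, seed = 1)
  expect_equal(attr(sd0, "uncertainty")$mue, 0)
  expect_equal(attr(sd0, "uncertainty")$rmse, 0)

  # MUE is linear in the resampled errors, so the bootstrap-mean MUE is an
  # unbiased estimate of the point MUE: the gap is pure Monte-Carlo error
  sbig <- bootstrap_stats(pred, exp_, n_boot = 2000, seed = 42)
  gap <- abs(attr(sbig, "boot_mean")$mue - sbig$mue)
  expect_lt(gap, 3 * attr(sbig, "uncertainty")$mue / sqrt(2000))
})

test_that("evaluate_predictions pools and splits by group, order-invariantly", {
  sim <- simulate_molecules(n_molecules = 80, hfe_noise_sd = 0.5, seed = 3)
  recs <- sim$records
  recs$flexibility <- rep(c("rigid", "flexible"), length.out = 80)
  fit <- suppressWarnings(loo_fit(recs, "PMVECC"))
  res <- evaluate_predictions(recs, fit$loo_predictions,
                              group_by = "flexibility", n_boot = 100, seed = 5)
  expect_named(res, c("total", "flexible", "rigid"))
  expect_equal(res$total$n, 80L)
  expect_equal(res$rigid$n + res$flexible$n, 80L)
  # shuffling record order does not change the results
  perm <- sample(80)
  res2 <- evaluate_predictions(recs[perm, ], fit$loo_predictions,
                               group_by = "flexibility", n_boot = 100,
                               seed = 5)
  expect_equal(res$total$mue, res2$total$mue)
  expect_identical(attr(res$total, "uncertainty"),
                   attr(res2$total, "uncertainty"))
})
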