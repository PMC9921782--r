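# Energy traces, free energy estimators, and the rigid/flexible rule.

kB <- 0.0019872041

test_that("trace summaries give first-frame value and sample SD", {
  tr <- energy_trace("const", rep(-3.0, 100))
  s <- trace_summary(tr)
  expect_equal(s$dg_static, -3.0)
  expect_equal(s$sigma, 0.0)

  two <- trace_summary(energy_trace("two", c(0, 2)))
  expect_equal(two$dg_static, 0)
  expect_equal(two$sigma, sqrt(2))

  set.seed(33)
  big <- trace_summary(energy_trace("g", rnorm(1e5, -4, 0.4)))
  expect_lt(abs(big$sigma - 0.4) / 0.4, 0.01)

  expect_error(energy_trace("short", -1), "at least 2 frames")
})

test_that("BAR is zero for identical states and antisymmetric under swap", {
  expect_equal(bar_free_energy(rep(0, 50), rep(0, 50)), 0, tolerance = 1e-10)

  set.seed(71)
  f <- rnorm(400, 1.5, 1)
  r <- rnorm(300, -0.5, 1)
  dg <- bar_free_energy(f, r)
  expect_equal(bar_free_energy(r, f), -dg, tolerance = 1e-8)
})

test_that("BAR shift covariance: constant offsets move dG by that constant", {
  set.seed(77)
  f <- rnorm(200, 2, 1.2)
  r <- rnorm(200, -1, 1.2)
  dg <- bar_free_energy(f, r)
  for (C in c(-3.2, 0.7, 12)) {
    expect_equal(bar_free_energy(f + C, r - C), dg + C, tolerance = 1e-7)
  }
})

test_that("BAR recovers the Gaussian work-distribution closed form", {
  # forward work ~ N(mu, sigma^2) with sigma^2 = 2*kT*(mu - dG) implies a
  # Crooks-consistent reverse work ~ N(-(mu - 2*dG), sigma^2) and
  # dG = mu - sigma^2 / (2 kT)
  T <- 298.15
  mu <- 2.0
  sigma2 <- 2 * kB * T * 1.0
  dg_true <- mu - sigma2 / (2 * kB * T)
  n <- 1e5
  est <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    f <- rnorm(n, mu, sqrt(sigma2))
    r <- rnorm(n, -(mu - 2 * dg_true), sqrt(sigma2))
    bar_free_energy(f, r, temperature = T)
  }, numeric(1))
  mc_se <- sd(est)
  expect_lt(abs(est[1] - dg_true), 3 * mc_se)
  expect_lt(abs(mean(est) - dg_true), 3 * mc_se / sqrt(5))
})

test_that("BAR rejects non-overlapping ensembles", {
  # free energy gap far beyond the bracket: the ensembles share no overlap
  expect_error(bar_free_energy(rep(2e6, 10), rep(-2e6, 10)), "overlap")
})

test_that("exponential averaging matches constants and the Gaussian form", {
  expect_equal(exp_avg_free_energy(rep(3.5, 20)), 3.5)
  expect_equal(exp_avg_free_energy(5), 5)
  # dU ~ N(mu, sigma^2) gives dG = mu - beta*sigma^2/2 in the large-n limit
  T <- 298.15
  beta <- 1 / (kB * T)
  mu <- 1.0; sigma <- 0.3
  set.seed(55)
  est <- exp_avg_free_energy(rnorm(2e5, mu, sigma), temperature = T)
  expect_lt(abs(est - (mu - beta * sigma^2 / 2)), 0.01)
  # max-shift keeps very large gaps finite
  expect_true(is.finite(exp_avg_free_energy(c(5000, 5001))))
})

test_that("the rigid/flexible rule applies inclusive thresholds", {
  expect_identical(classify_flexibility(0.1, 0.0, 0.3), "rigid")
  expect_identical(classify_flexibility(0.1, 0.0, 0.41), "flexible")
  # both thresholds exactly at the boundary are still rigid (<= semantics)
  expect_identical(classify_flexibility(0.2, 0.0, 0.4), "rigid")
  expect_identical(classify_flexibility(0.21, 0.0, 0.4), "flexible")
  # the static-vs-trajectory difference is two-sided
  expect_identical(classify_flexibility(-0.2, 0.0, 0.1), "rigid")
  expect_identical(classify_flexibility(-0.3, 0.0, 0.1), "flexible")
})

test_that("classification is monotone in sigma and |difference|", {
  set.seed(91)
  for (rep in 1:25) {
    sigma <- runif(1, 0, 1)
    diff <- runif(1, -1, 1)
    lab <- classify_flexibility(diff, 0, sigma)
    worse <- classify_flexibility(diff * 1.5, 0, sigma + 0.2)
    if (lab == "flexible") expect_identical(worse, "flexible")
  }
})

test_that("classify_traces uses BAR when cross energies are present", {
  set.seed(61)
  frames <- rnorm(500, -4, 0.1)
  tr_plain <- energy_trace("plain", frames)
  res_plain <- classify_traces(tr_plain)
  expect_identical(res_plain$md_estimator, "frame_mean")
  expect_equal(res_plain$dg_md, mean(frames))

  tr_bar <- energy_trace("bar", frames,
                         u_cross = list(forward = rnorm(500, -4, 0.1),
                                        reverse = rnorm(500, 4, 0.1)))
  res_bar <- classify_traces(tr_bar)
  expect_identical(res_bar$md_estimator, "bar")
  expect_equal(res_bar$dg_md,
               bar_free_energy(tr_bar$u_cross$forward,
                               tr_bar$u_cross$reverse))
})

test_that("trace files round-trip, with and without cross-energy companions", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mol1.csv")
  writeLines(c("frame,u_aq,u_vac", "1,-10.5,-6.2", "2,-10.1,-6.0",
               "3,-10.4,-6.1"), path)
  tr <- read_energy_trace(path)
  expect_identical(tr$id, "mol1")
  expect_equal(tr$dg_frames, c(-4.3, -4.1, -4.3))

  # whitespace-separated, headerless variant
  path2 <- file.path(dir, "mol2.txt")
  writeLines(c("1 -10.5 -6.2", "2 -10.1 -6.0"), path2)
  expect_equal(read_energy_trace(path2)$dg_frames, c(-4.3, -4.1))

  cross <- file.path(dir, "mol1_vac.csv")
  writeLines(c("frame,u_aq,u_vac", "1,-9.9,-6.3", "2,-10.0,-6.2"), cross)
  tr2 <- read_energy_trace(path, cross_path = cross)
  expect_equal(tr2$u_cross$forward, c(-4.3, -4.1, -4.3))
  expect_equal(tr2$u_cross$reverse, c(-6.3 + 9.9, -6.2 + 10.0))

  expect_error(read_energy_trace(file.path(dir, "none.csv")), "no such file")
  bad <- file.path(dir, "bad.csv")
  writeLines(c("frame,u_aq", "1,-3"), bad)
  expect_error(read_energy_trace(bad), "needs columns")
})
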