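# OLS and the leave-one-out protocol. brute_force_loo() (helper-oracles.R)
# refits each fold from scratch via the normal equations, an independent
# route from the package's QR path.

model_coefficients_vec <- function(m) {
  c(a = m$a, b = m$b, m$c)
}

test_that("ols_fit solves exact and noisy systems deterministically", {
  expect_equal(ols_fit(matrix(c(1, 2), ncol = 1), c(2, 4)), 2.0)
  # random full-rank system with known coefficients, no noise
  set.seed(5)
  X <- matrix(rnorm(250), 50, 5, dimnames = list(NULL, letters[1:5]))
  beta <- rnorm(5)
  fit <- ols_fit(X, drop(X %*% beta))
  expect_equal(unname(fit), beta, tolerance = 1e-10)
  expect_identical(fit, ols_fit(X, drop(X %*% beta)))
})

test_that("rank-deficient designs name the dependent columns", {
  X <- matrix(1, 2, 2, dimnames = list(NULL, c("u", "v")))
  expect_error(ols_fit(X, c(1, 2)), "rank deficient")
  X2 <- cbind(a = rnorm(10), b = 0)
  expect_error(ols_fit(X2, rnorm(10)), "b")
  expect_error(ols_fit(matrix(rnorm(4), 1, 4), 1), "underdetermined")
})

test_that("three records, one parameter: mean of three hand-checkable folds", {
  recs <- molecule_table(c("a", "b", "c"),
                         counts = list(c(H = 1L), c(H = 2L), c(H = 3L)),
                         dg_method = 0, dg_exp = c(1.1, 1.9, 3.3))
  fit <- suppressWarnings(loo_fit(recs, "ECC"))
  # each fold is a no-intercept line through two points
  slope_without <- function(i) {
    h <- c(1, 2, 3)[-i]; y <- c(1.1, 1.9, 3.3)[-i]
    sum(h * y) / sum(h * h)
  }
  folds <- vapply(1:3, slope_without, numeric(1))
  expect_equal(unname(fit$per_fold_coefficients[, "H"]), folds)
  expect_equal(unname(coef(fit)), mean(folds))
  expect_equal(unname(fit$coeff_sd), sd(folds))
  expect_equal(unname(fit$coeff_sem), sd(folds) / sqrt(3))
})

test_that("production LOO matches the brute-force refit oracle", {
  sim <- simulate_molecules(n_molecules = 50, hfe_noise_sd = 0.5, seed = 17)
  fit <- suppressWarnings(loo_fit(sim$records, "PMVECC"))
  oracle <- brute_force_loo(sim$records, "PMVECC", fit$element_order)
  expect_equal(fit$loo_predictions, oracle$pred, tolerance = 1e-10)
  expect_equal(unname(fit$per_fold_coefficients), oracle$coefs,
               tolerance = 1e-10)
  # mean_coefficients are the column means of the fold matrix
  expect_equal(coef(fit), colMeans(fit$per_fold_coefficients))
  # every molecule has exactly one leave-out prediction
  expect_setequal(names(fit$loo_predictions), sim$records$id)
})

test_that("LOO refits agree with the closed-form leverage shortcut", {
  sim <- simulate_molecules(n_molecules = 60, hfe_noise_sd = 0.4, seed = 23)
  fit <- suppressWarnings(loo_fit(sim$records, "PMVECC"))
  X <- design_matrix("PMVECC", sim$records, fit$element_order)
  y <- sim$records$dg_exp - sim$records$dg_method
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  yhat <- drop(X %*% beta)
  h <- rowSums(qr.Q(qx)^2)
  r <- y - yhat
  shortcut <- yhat - h * r / (1 - h)
  expect_equal(unname(fit$loo_predictions - sim$records$dg_method),
               unname(shortcut), tolerance = 1e-8)
})

test_that("fold residuals are orthogonal to the fold design", {
  sim <- simulate_molecules(n_molecules = 40, hfe_noise_sd = 0.6, seed = 31)
  fit <- suppressWarnings(loo_fit(sim$records, "PMVECC"))
  X <- design_matrix("PMVECC", sim$records, fit$element_order)
  y <- sim$records$dg_exp - sim$records$dg_method
  for (i in c(1L, 13L, 40L)) {
    Xi <- X[-i, , drop = FALSE]
    ri <- y[-i] - drop(Xi %*% fit$per_fold_coefficients[i, ])
    expect_lt(max(abs(drop(t(Xi) %*% ri))), 1e-8)
  }
})

test_that("record order changes nothing but fold order", {
  sim <- simulate_molecules(n_molecules = 45, hfe_noise_sd = 0.5, seed = 41)
  fit1 <- suppressWarnings(loo_fit(sim$records, "PMVECC"))
  perm <- sample(nrow(sim$records))
  fit2 <- suppressWarnings(loo_fit(sim$records[perm, ], "PMVECC"))
  ids <- sort(sim$records$id)
  expect_equal(fit1$loo_predictions[ids], fit2$loo_predictions[ids],
               tolerance = 1e-12)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)
})

test_that("full_fit equals the LOO mean on noiseless data, approaches it at 1/n", {
  sim0 <- simulate_molecules(n_molecules = 80, hfe_noise_sd = 0, seed = 53)
  full <- suppressWarnings(full_fit(sim0$records, "PMVECC"))
  loo <- suppressWarnings(loo_fit(sim0$records, "PMVECC"))
  expect_model_equal(full, loo$mean_model, tol = 1e-8)

  # with noise the gap shrinks roughly like 1/n
  gap <- vapply(c(60L, 240L), function(n) {
    sim <- simulate_molecules(n_molecules = n, hfe_noise_sd = 0.5, seed = 67)
    f <- suppressWarnings(full_fit(sim$records, "PMVECC"))
    l <- suppressWarnings(loo_fit(sim$records, "PMVECC"))
    max(abs(model_coefficients_vec(f) - model_coefficients_vec(l$mean_model)))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("element support below the minimum is an error, low support warns", {
  recs <- tiny_records() # P appears in one molecule only
  expect_error(suppressWarnings(loo_fit(recs, "ECC", min_element_support = 2L)),
               "P \\(1\\)")
  expect_warning(try(loo_fit(recs, "ECC"), silent = TRUE), "fewer than 5")
  expect_error(suppressWarnings(loo_fit(tiny_records()[1:2, ], "PMVECC")),
               "at least")
})

test_that("records missing required fields are rejected by name", {
  recs <- tiny_records()
  recs$dg_exp[3] <- NA
  expect_error(loo_fit(recs, "PMVC"), "m3")
})

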