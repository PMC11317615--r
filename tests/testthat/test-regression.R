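test_that("identity-Gram and zero-target fits are exact", {
  set.seed(3)
  y <- rnorm(8)
  f <- gp_fit(diag(8), y, gamma = 1)
  expect_equal(f$z, y / 2)
  expect_equal(f$V_signal, sum(y^2) / 4)
  expect_equal(f$V_noise, sum(y^2) / 4)
  expect_equal(f$ratio, 0.5)
  f0 <- gp_fit(random_spd(8, 2), rep(0, 8), gamma = 0.5)
  expect_equal(f0$z, rep(0, 8))
  expect_equal(f0$V_signal, 0)
  expect_equal(f0$V_noise, 0)
  expect_equal(f0$ratio, 0)   # degenerate 0/0 convention: no signal
})

test_that("signal fraction handles degenerate and boundary input", {
  expect_equal(signal_to_noise(1, 1), 0.5)
  expect_equal(signal_to_noise(0, 0), 0)
  expect_equal(signal_to_noise(2, 0), 1)
  expect_error(signal_to_noise(-1, 0), "nonnegative")
})

test_that("closed-form coefficients minimize the regularized objective", {
  # brute-force oracle: objective at the solution beats random perturbations
  gram <- random_spd(12, seed = 9)
  set.seed(10)
  y <- rnorm(12)
  for (g in c(0.05, 1)) {
    f <- gp_fit(gram, y, g)
    obj <- gphyper:::.gp_objective(gram, y, g, f$z)
    for (i in 1:200) {
      z_pert <- f$z + rnorm(12, sd = 0.1 * sd(f$z) + 1e-3)
      expect_lte(obj, gphyper:::.gp_objective(gram, y, g, z_pert))
    }
  }
})

test_that("variance components satisfy the conservation identity", {
  for (s in 1:5) {
    gram <- random_spd(15, seed = s)
    set.seed(100 + s)
    y <- rnorm(15)
    g <- runif(1, 0.01, 2)
    f <- gp_fit(gram, y, g)
    expect_equal(f$V_signal + f$V_noise, sum(y * f$z),
                 tolerance = 1e-8)
    expect_gte(f$ratio, 0); expect_lte(f$ratio, 1)
    # V_noise as gamma*||z||^2 equals the residual form (1/g)*||Kz - y||^2
    expect_equal(f$V_noise, sum((drop(gram %*% f$z) - y)^2) / g,
                 tolerance = 1e-6)
  }
})

test_that("the ratio matches its Gram-eigenbasis spectral form", {
  gram <- random_spd(20, seed = 12)
  set.seed(13)
  y <- rnorm(20)
  eg <- eigen(gram, symmetric = TRUE)
  cc <- drop(crossprod(eg$vectors, y))
  for (g in c(0.02, 0.3, 2)) {
    f <- gp_fit(gram, y, g)
    v_n <- sum(cc^2 * g / (eg$values + g)^2)
    v_s <- sum(cc^2 * eg$values / (eg$values + g)^2)
    expect_equal(1 - f$ratio, v_n / (v_s + v_n), tolerance = 1e-8)
  }
  # limits: noise fraction vanishes as gamma -> 0 (full-rank Gram) and
  # tends to 1 as gamma -> infinity
  expect_lt(1 - gp_fit(gram, y, 1e-8)$ratio, 1e-4)
  expect_gt(1 - gp_fit(gram, y, 1e6)$ratio, 0.99)
})

test_that("training-row predictions obey the residual identity", {
  x <- random_rows(40, c("a", "b"), seed = 14)
  set.seed(15)
  y <- x[, "a"] - 2 * x[, "b"] + rnorm(40, sd = 0.1)
  d <- cbind(x, y = y)
  fit <- gp_regress(d, "y", c("a", "b"), family = "nonlinear", gamma = 0.3,
                    low_rank = FALSE)
  expect_equal(predict(fit, d), y - 0.3 * fit$z, tolerance = 1e-8)
  # zero coefficients predict zero everywhere
  fit0 <- fit; fit0$z <- rep(0, 40)
  expect_equal(predict(fit0, d), rep(0, 40))
})

test_that("the ridge interpolates noiseless linear data as gamma -> 0", {
  x <- random_rows(10, "a", seed = 16)
  y <- 3 * x[, "a"]
  spec <- kernel_spec("linear", "a")
  f <- gp_fit(kernel_matrix(spec, x), y, gamma = 1e-12)
  expect_lt(max(abs((drop(kernel_matrix(spec, x) %*% f$z)) - y)), 1e-6)
})

test_that("low-rank and full-Gram paths agree", {
  x <- random_rows(50, c("a", "b", "c", "d"), seed = 17)
  set.seed(18)
  y <- rnorm(50)
  spec <- kernel_spec("quadratic", colnames(x))
  full <- gp_fit(kernel_matrix(spec, x), y, gamma = 0.5)
  low <- gp_fit_features(feature_map(spec, x), y, gamma = 0.5)
  expect_equal(low$V_signal, full$V_signal, tolerance = 1e-6)
  expect_equal(low$V_noise, full$V_noise, tolerance = 1e-6)
  expect_equal(low$ratio, full$ratio, tolerance = 1e-6)
  expect_equal(low$z, full$z, tolerance = 1e-6)
  # zero targets give zero variance through the feature path too
  z0 <- gp_fit_features(feature_map(spec, x), rep(0, 50), gamma = 0.5)
  expect_equal(z0$V_signal + z0$V_noise, 0)
})

test_that("a hand-computable 3-point univariate fit matches both paths", {
  x <- matrix(c(-1, 0, 2), 3, 1, dimnames = list(NULL, "a"))
  y <- c(1, 0, -1)
  spec <- kernel_spec("linear", "a")
  k <- 1 + 0.1 * tcrossprod(x)            # direct formula
  z_direct <- solve(k + diag(0.7, 3), y)  # independent dense solve
  full <- gp_fit(kernel_matrix(spec, x), y, 0.7)
  low <- gp_fit_features(feature_map(spec, x), y, 0.7)
  # the solver adds a relative jitter of 1e-10 before factorizing
  expect_equal(full$z, z_direct, tolerance = 1e-7)
  expect_equal(low$ratio, full$ratio, tolerance = 1e-8)
})

test_that("linear-kernel predictions agree with explicit ridge regression", {
  # independent oracle: primal ridge on the explicit feature matrix
  x <- random_rows(60, c("a", "b", "c"), seed = 19)
  set.seed(20)
  y <- 0.5 * x[, "a"] - x[, "c"] + rnorm(60, sd = 0.2)
  d <- cbind(x, y = y)
  g <- 0.4
  fit <- gp_regress(d, "y", colnames(x), family = "linear", gamma = g)
  p <- cbind(1, sqrt(0.1) * x)
  w <- solve(crossprod(p) + diag(g, 4), crossprod(p, y))
  expect_equal(unname(predict(fit, d)), unname(drop(p %*% w)),
               tolerance = 1e-8)
})

test_that("invalid regression input is rejected", {
  expect_error(gp_fit(diag(3), 1:3, gamma = 0), "positive")
  expect_error(gp_fit(matrix(1:9, 3), rnorm(3), 1), "symmetric")
  ns <- matrix(c(1, 2, 2, -8), 2)   # symmetric but indefinite
  expect_error(gp_fit(ns, c(1, 1), 1e-6), "positive semidefinite")
  expect_error(gp_fit(diag(3), c(1, NA, 2), 1), "finite")
})
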