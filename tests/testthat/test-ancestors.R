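test_that("contribution shares decompose the signal variance", {
  vars <- c("a", "b", "c")
  x <- random_rows(40, vars, seed = 21)
  set.seed(22)
  y <- rnorm(40)
  for (fam in c("linear", "quadratic", "nonlinear")) {
    spec <- kernel_spec(fam, vars)
    gram <- kernel_matrix(spec, x)
    f <- gp_fit(gram, y, 0.1)
    k2s <- lapply(setNames(vars, vars), function(v)
      split_matrices(kernel_split(spec, v), x)$k2)
    shares <- signal_contributions(f$z, k2s, gram)
    expect_true(all(shares >= 0 & shares <= 1))
    for (v in vars) {
      m <- split_matrices(kernel_split(spec, v), x)
      q1 <- sum(f$z * drop(m$k1 %*% f$z))
      q2 <- sum(f$z * drop(m$k2 %*% f$z))
      expect_equal(q1 + q2, sum(f$z * drop(gram %*% f$z)),
                   tolerance = 1e-8)
    }
  }
  # zero coefficients give all-zero shares by convention
  z0 <- signal_contributions(rep(0, 40),
                             lapply(setNames(vars, vars), function(v)
                               diag(40)), diag(40))
  expect_equal(unname(z0), rep(0, 3))
})

test_that("a copied candidate dominates the contribution shares", {
  d <- copy_plus_noise(n = 500, seed = 4)
  vars <- c("w1", "n1", "n2", "n3")
  x <- hg_values(d)[, vars]
  spec <- kernel_spec("linear", vars)
  f <- gp_fit(kernel_matrix(spec, x), hg_values(d)[, "y"], gamma = 0.01)
  k2s <- lapply(setNames(vars, vars), function(v)
    split_matrices(kernel_split(spec, v), x)$k2)
  shares <- signal_contributions(f$z, k2s, kernel_matrix(spec, x))
  expect_gt(shares["w1"], 0.9)
  expect_true(all(shares[c("n1", "n2", "n3")] < 0.05))
})

test_that("engine shares agree with the explicit split-matrix route", {
  # the pruning engine evaluates z'K2z in closed form; cross-check it
  # against the direct Gram computation for every family
  vars <- c("a", "b", "c", "d")
  x <- random_rows(35, vars, seed = 23)
  set.seed(24)
  y <- rnorm(35)
  for (fam in c("linear", "quadratic", "nonlinear")) {
    env <- gphyper:::.prune_engine(x, y, vars, fam, 0.1, 0.1, 0.1,
                                   "gaussian", 0.05)
    fit <- gphyper:::.engine_fit(env)
    eng <- gphyper:::.engine_shares(env, fit)
    spec <- kernel_spec(fam, vars)
    gram <- kernel_matrix(spec, x)
    k2s <- lapply(setNames(vars, vars), function(v)
      split_matrices(kernel_split(spec, v), x)$k2)
    ref <- signal_contributions(fit$z, k2s, gram)
    expect_equal(eng[vars], ref[vars], tolerance = 1e-6)
  }
})

test_that("pruning keeps an exact ancestor to the end of the path", {
  d <- copy_plus_noise(n = 500, seed = 4)
  tr <- prune_path(d, "y", c("w1", "n1", "n2", "n3"), family = "linear")
  df <- as.data.frame(tr)
  expect_equal(df$size, 4:1)
  expect_identical(tr$steps[[4]]$ancestors, "w1")   # survives to the end
  expect_false("w1" %in% df$removed)
  expect_true(all(df$noise_ratio >= 0 & df$noise_ratio <= 1))
  expect_identical(select_inflection(tr), "w1")
  expect_identical(select_threshold(tr), "w1")
  # step records agree with an independent refit on the same ancestor set
  s2 <- tr$steps[[2]]
  ref <- gp_regress(d, "y", s2$ancestors, family = "linear", gamma = 0.02)
  expect_equal(s2$V_signal, ref$V_signal, tolerance = 1e-6)
  expect_equal(s2$V_noise, ref$V_noise, tolerance = 1e-6)
})

test_that("single-candidate traces have one step and no removal", {
  d <- copy_plus_noise(n = 200, seed = 5)
  tr <- prune_path(d, "y", "w1", family = "linear")
  expect_length(tr$steps, 1)
  expect_true(is.na(tr$steps[[1]]$removed))
  expect_identical(select_inflection(tr), "w1")
  expect_error(prune_path(d, "y", character()), "empty candidate")
  expect_error(prune_path(d, "y", c("y", "w1")), "own candidate")
})

test_that("threshold rule returns the smallest set above half signal", {
  tr <- fake_trace(c(0.1, 0.15, 0.2, 0.8), sizes = 4:1)
  expect_length(select_threshold(tr), 2)
  expect_length(select_threshold(fake_trace(c(0.6, 0.7, 0.9), 3:1)), 0)
  expect_length(select_threshold(fake_trace(c(0.1, 0.2, 0.3), 3:1)), 1)
})

test_that("inflection rule picks the set before the largest surge", {
  tr <- fake_trace(c(0.10, 0.12, 0.25, 0.99), sizes = 5:2)
  expect_length(select_inflection(tr), 3)
  # flat path with no terminal information: earliest maximal increment,
  # i.e. the set before the first removal
  flat <- fake_trace(c(0.2, 0.2, 0.2), sizes = 3:1)
  expect_length(select_inflection(flat), 3)
  # flat path whose terminal ratio reveals the last candidate matters
  flat2 <- fake_trace(c(0.02, 0.02, 0.02), sizes = 3:1, terminal = 0.99)
  expect_length(select_inflection(flat2), 1)
  expect_length(select_inflection(fake_trace(0.3, 1)), 1)
})

test_that("the kernel ladder selects the simplest adequate family", {
  set.seed(26)
  n <- 400
  w <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("w1", "w2", "w3")))
  lin <- hg_normalize(hg_data(cbind(w, y = w[, "w1"])))
  expect_identical(
    choose_kernel(lin, "y", c("w1", "w2", "w3"))$family, "linear")
  quad <- hg_normalize(hg_data(cbind(w, y = w[, "w1"]^2 + 1 + 0.1 * w[, "w2"])))
  expect_identical(
    choose_kernel(quad, "y", c("w1", "w2", "w3"))$family, "quadratic")
  nl <- hg_normalize(hg_data(cbind(w, y = w[, "w2"] * sin(w[, "w3"]))))
  expect_identical(
    choose_kernel(nl, "y", c("w1", "w2", "w3"))$family, "nonlinear")
  noise <- hg_normalize(hg_data(cbind(w, y = rnorm(n))))
  expect_null(choose_kernel(noise, "y", c("w1", "w2", "w3"))$family)
})

test_that("bootstrap null summaries are ordered and reproducible", {
  gram <- kernel_matrix(kernel_spec("nonlinear", c("a", "b")),
                        random_rows(60, c("a", "b"), seed = 27))
  null <- bootstrap_null(gram, gamma = 0.02, n_boot = 50, seed = 3)
  expect_lte(null$q05, null$mean)
  expect_lte(null$mean, null$q95)
  expect_equal(noise_z_score(null$mean, null), 0)
  again <- bootstrap_null(gram, gamma = 0.02, n_boot = 50, seed = 3)
  expect_identical(null$ratios, again$ratios)
  # the eigenbasis evaluation matches a direct fit for a fresh target
  set.seed(4)
  y <- rnorm(60)
  direct <- 1 - gp_fit(gram, y, 0.02)$ratio
  eg <- eigen(gram, symmetric = TRUE)
  cc <- drop(crossprod(eg$vectors, y))
  lam <- pmax(eg$values, 0)
  expect_equal(direct,
               sum(cc^2 * 0.02 / (lam + 0.02)^2) /
                 sum(cc^2 / (lam + 0.02)), tolerance = 1e-6)
  expect_error(bootstrap_null(gram, 0.02, n_boot = 1), "at least 2")
  degen <- structure(list(mean = 0.5, sd = 0, q05 = 0.5, q95 = 0.5,
                          ratios = rep(0.5, 3), n_boot = 3),
                     class = "hg_null")
  expect_warning(z <- noise_z_score(0.7, degen), "infinite")
  expect_identical(z, Inf)
})
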