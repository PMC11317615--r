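test_that("independent noise columns yield an empty graph", {
  set.seed(30)
  d <- hg_normalize(hg_data(matrix(rnorm(800), 400, 2,
                                   dimnames = list(NULL, c("u", "v")))))
  gr <- discover_graph(d, hg_config(n_boot = 10))
  expect_identical(nrow(gr$edges), 0L)
  expect_false(gr$reports$u$has_ancestors)
})

test_that("discovery is deterministic and order-independent", {
  set.seed(31)
  n <- 300
  w <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("w1", "w2", "w3")))
  vals <- cbind(w, y = w[, "w1"] + 0.5 * w[, "w2"])
  d <- hg_normalize(hg_data(vals))
  cfg <- hg_config(seed = 9, n_boot = 20)
  g1 <- discover_graph(d, cfg)
  g2 <- discover_graph(d, cfg)
  expect_identical(g1$edges, g2$edges)
  # permuting the column order must not change the edge set
  d_perm <- hg_normalize(hg_data(vals[, c("y", "w3", "w1", "w2")]))
  g3 <- discover_graph(d_perm, cfg)
  canon <- function(e) e[order(e$source, e$target),
                         c("source", "target", "family")]
  expect_equal(canon(g1$edges), canon(g3$edges), ignore_attr = TRUE)
})

test_that("singleton clusters reproduce unmerged discovery", {
  set.seed(32)
  n <- 300
  w <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("w1", "w2")))
  vals <- cbind(w, y = w[, "w1"])
  d <- hg_normalize(hg_data(vals))
  cfg <- hg_config(seed = 2, n_boot = 10)
  plain <- discover_graph(d, cfg)
  merged <- discover_graph(
    merge_clusters(d, list(w1 = "w1", w2 = "w2", y = "y")), cfg)
  canon <- function(e) e[order(e$source, e$target),
                         c("source", "target", "family")]
  expect_equal(canon(plain$edges), canon(merged$edges), ignore_attr = TRUE)
})

test_that("merging collinear variables leaves downstream ancestors intact", {
  set.seed(33)
  n <- 400
  a <- rnorm(n)
  vals <- cbind(a1 = a, a2 = 2 * a, b = rnorm(n),
                y = a + 0.01 * rnorm(n))
  d <- hg_normalize(hg_data(vals))
  cfg <- hg_config(seed = 3, n_boot = 0)
  merged <- discover_graph(merge_clusters(d, list(A = c("a1", "a2"))), cfg)
  expect_identical(merged$reports$y$ancestors, "A")
  # against discovery using either copy alone
  solo <- discover_graph(hg_normalize(hg_data(vals[, c("a1", "b", "y")])),
                         cfg)
  expect_identical(solo$reports$y$ancestors, "a1")
})

test_that("merging everything but the target reduces to one has-ancestors test", {
  set.seed(34)
  n <- 300
  w <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("w1", "w2", "w3")))
  vals <- cbind(w, y = w[, "w1"] * w[, "w2"])
  d <- merge_clusters(hg_normalize(hg_data(vals)),
                      list(rest = c("w1", "w2", "w3")))
  gr <- discover_graph(d, hg_config(seed = 5, n_boot = 0))
  expect_true(gr$reports$y$has_ancestors)
  expect_identical(gr$reports$y$ancestors, "rest")
  tr <- gr$reports$y$trace
  expect_length(tr$steps, 1)   # a single joint candidate: nothing to prune
})

test_that("cluster constraints are validated", {
  d <- hg_data(matrix(rnorm(40), 10, 4,
                      dimnames = list(NULL, c("a", "b", "c", "e"))))
  expect_error(merge_clusters(d, list(g1 = c("a", "b"), g2 = c("b", "c"))),
               "disjoint")
  expect_error(merge_clusters(d, list(c("a", "b"))), "named")
  expect_error(merge_clusters(d, list(g = c("a", "zz"))), "unknown")
})

test_that("recovery metrics follow the printed formulas", {
  nodes <- c("a", "b", "c", "d")
  pred <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"))
  truth <- data.frame(source = c("a", "b", "d"), target = c("b", "c", "a"))
  m <- compare_graphs(pred, truth, direction_sensitive = TRUE, nodes = nodes)
  expect_identical(c(m$TP, m$FP, m$FN), c(2L, 1L, 1L))
  expect_identical(m$TN, 4L * 3L - 4L)
  expect_equal(m$TPR, 2 / 3)
  expect_equal(m$FDR, 1 / 3)
  expect_equal(m$FPR, 1 / 9)
  # direction-insensitive counting collapses reversed pairs
  mi <- compare_graphs(data.frame(source = "b", target = "a"),
                       data.frame(source = "a", target = "b"),
                       direction_sensitive = FALSE, nodes = nodes)
  expect_identical(mi$TP, 1L)
  expect_identical(mi$FP, 0L)
  expect_equal(mi$FDR, 0)
  # undefined denominators are NaN, never 0
  m0 <- compare_graphs(data.frame(source = character(),
                                  target = character()),
                       data.frame(source = character(),
                                  target = character()),
                       nodes = nodes)
  expect_true(is.nan(m0$TPR))
  expect_true(is.nan(m0$FDR))
  expect_equal(m0$FPR, 0)
  expect_error(compare_graphs(pred, data.frame(source = "zz", target = "a"),
                              nodes = nodes), "unknown node")
})

test_that("metric identities hold on randomized edge sets", {
  set.seed(35)
  nodes <- paste0("n", 1:6)
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  for (rep in 1:20) {
    pred <- pairs[runif(nrow(pairs)) < 0.2, ]
    truth <- pairs[runif(nrow(pairs)) < 0.2, ]
    m <- compare_graphs(pred, truth, nodes = nodes)
    expect_identical(m$TP + m$FN, nrow(unique(truth)))
    expect_identical(m$TP + m$FP, nrow(unique(pred)))
    expect_identical(m$TP + m$FP + m$FN + m$TN, 30L)
    if (!is.nan(m$TPR)) expect_equal(m$TPR, m$TP / (m$TP + m$FN))
    if (!is.nan(m$FPR)) expect_equal(m$FPR, m$FP / (m$FP + m$TN))
    if (!is.nan(m$FDR)) expect_equal(m$FDR, m$FP / (m$TP + m$FP))
  }
})
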