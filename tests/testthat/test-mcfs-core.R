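test_that("entropy matches direct evaluation of -sum p log2 p", {
  expect_equal(entropy(c(10, 0)), 0)
  expect_equal(entropy(c(5, 5)), 1)
  expect_equal(entropy(c(3, 1)), 0.811278124459133, tolerance = 1e-12)
  expect_error(entropy(c(0, 0)), "positive sum")
})

test_that("information gain and variance reduction follow their formulas", {
  y <- rep(c("a", "b"), each = 5)
  expect_equal(information_gain(y, y[1:5], y[6:10]), 1)
  # children distributed as the parent -> zero gain
  expect_equal(information_gain(y, y[c(1:2, 6:7)], y[c(3:5, 8:10)]), 0,
    tolerance = 1e-12
  )
  expect_equal(
    variance_reduction(c(0, 0, 4, 4), list(c(0, 0), c(4, 4))), 4
  )
  expect_error(information_gain(y, y[1:3], y[1:3]), "partition")
})

test_that("weighted accuracy is the mean of per-class accuracies", {
  y <- rep(c("a", "b"), c(90, 10))
  expect_equal(weighted_accuracy(y, y), 1)
  expect_equal(weighted_accuracy(y, rep("a", 100)), 0.5)
  # per-class accuracies 0.8 and 0.6 -> 0.7
  yt <- rep(c("a", "b"), each = 10)
  yp <- c(rep("a", 8), "b", "b", rep("b", 6), rep("a", 4))
  expect_equal(weighted_accuracy(yt, yp), 0.7)
})

test_that("tree root split matches exhaustive search over all splits", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- matrix(rnorm(12 * 3), 12, 3,
      dimnames = list(NULL, c("fa", "fb", "fc"))
    )
    y <- factor(sample(c("a", "b"), 12, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    tree <- build_tree(x, y, min_split = 2)
    oracle <- brute_force_best_split(x, y)
    if (is.na(oracle$feature)) {
      expect_true(is.na(tree$nodes$feature[1]))
    } else {
      expect_equal(tree$nodes$ig[1], oracle$gain, tolerance = 1e-10)
    }
    # regression mode against the same oracle
    yr <- rnorm(12)
    tr <- build_tree(x, yr, task = "regression", min_split = 2)
    orr <- brute_force_best_split(x, yr, task = "regression")
    expect_equal(tr$nodes$ig[1], orr$gain, tolerance = 1e-10)
  }
})

test_that("degenerate trees: pure target and constant features give leaves", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("fa", "fb")))
  tree <- build_tree(x, factor(rep("a", 10)))
  expect_equal(nrow(tree$nodes), 1)
  xc <- matrix(1, 10, 2, dimnames = list(NULL, c("fa", "fb")))
  tree2 <- build_tree(xc, factor(rep(c("a", "b"), 5)))
  expect_equal(nrow(tree2$nodes), 1)
  # perfectly separating feature -> depth-1 tree with root IG = H(parent)
  d <- separable_data(n = 30, p = 3)
  tr <- build_tree(d$x, d$y)
  expect_equal(tr$nodes$feature[1], "f001")
  expect_equal(tr$nodes$ig[1], entropy(table(d$y)), tolerance = 1e-9)
  expect_true(all(is.na(tr$nodes$feature[-1])))
})

test_that("RI accumulation reproduces the documented hand arithmetic", {
  # tree 1: q = 1.0, one node on g with IG 1.0, sample fraction 1.0
  t1 <- toy_tree_single_node(ig = 1, n = 10)
  # tree 2: q = 0.5, node on g with IG 0.5 at half the root samples
  t2 <- data.frame(
    feature = c("h", "g", NA, NA, NA), threshold = c(0, 0, NA, NA, NA),
    ig = c(0.3, 0.5, 0, 0, 0), n = c(20, 10, 10, 5, 5),
    left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
    parent = c(0, 1, 1, 2, 2), pred = NA, stringsAsFactors = FALSE
  )
  ri <- accumulate_ri(t1, q = 1)["g"] + accumulate_ri(t2, q = 0.5)["g"]
  expect_equal(unname(ri), 1.125)
})

test_that("ID edges take the child's IG weighted by its sample fraction", {
  # root on f1 (n = 100), child split node on f2 (n = 40, IG = 0.5)
  t <- data.frame(
    feature = c("f1", "f2", NA, NA, NA), threshold = c(0, 0, NA, NA, NA),
    ig = c(0.2, 0.5, 0, 0, 0), n = c(100, 40, 60, 20, 20),
    left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
    parent = c(0, 1, 1, 2, 2), pred = NA, stringsAsFactors = FALSE
  )
  e <- id_edges(t)
  expect_equal(nrow(e), 1)
  expect_equal(e$parent, "f1")
  expect_equal(e$child, "f2")
  expect_equal(e$weight, 0.5 * 0.4)
  # a forest of depth-1 trees has no parent/child split pairs
  expect_equal(nrow(compute_id_graph(list(toy_tree_single_node()))), 0)
  # duplicate structure doubles the edge weight
  g2 <- compute_id_graph(list(t, t))
  expect_equal(g2$weight, 0.4)
})

test_that("MCFS run is deterministic and recovers a planted perfect feature", {
  d <- separable_data(n = 50, p = 30, seed = 3)
  pr <- mcfs_params(m = 10, t = 3, n_perm = 5, seed = 11)
  f1 <- run_mcfs(d$x, d$y, pr)
  f2 <- run_mcfs(d$x, d$y, pr)
  expect_identical(f1$ranking, f2$ranking)
  expect_identical(f1$id_graph, f2$id_graph)
  expect_identical(f1$cutoff, f2$cutoff)
  expect_equal(f1$ranking$feature[1], "f001")
  expect_true(f1$ranking$significant[1])
  # ranks are a permutation; significant <=> RI above cutoff; RI >= 0
  expect_setequal(f1$ranking$rank, seq_len(ncol(d$x)))
  expect_equal(f1$ranking$significant, f1$ranking$ri > f1$cutoff)
  expect_true(all(f1$ranking$ri >= 0))
})

test_that("tree structures and RI are invariant to positive feature scaling", {
  d <- separable_data(n = 40, p = 12, seed = 5)
  pr <- mcfs_params(m = 6, t = 2, n_perm = 1, seed = 9)
  f1 <- run_mcfs(d$x, d$y, pr, compute_cutoff = FALSE)
  x2 <- d$x
  x2[, 4] <- x2[, 4] * 1000
  f2 <- run_mcfs(x2, d$y, pr, compute_cutoff = FALSE)
  expect_equal(f1$ranking, f2$ranking, tolerance = 1e-12)
  expect_equal(f1$id_graph, f2$id_graph, tolerance = 1e-12)
})

test_that("permutation cutoff of a single permutation is that run's max RI", {
  d <- separable_data(n = 30, p = 8, seed = 2)
  p1 <- mcfs_params(m = 4, t = 2, n_perm = 1, seed = 7)
  p2 <- p1
  p2$cutoff_quantile <- 0.5 # any quantile of a singleton is the value itself
  expect_equal(
    permutation_cutoff(d$x, d$y, p1), permutation_cutoff(d$x, d$y, p2)
  )
})

test_that("m larger than the feature count is clamped with a warning", {
  d <- separable_data(n = 30, p = 5, seed = 4)
  pr <- mcfs_params(m = 50, t = 2, n_perm = 1, seed = 1)
  expect_warning(f <- run_mcfs(d$x, d$y, pr), "clamped")
  expect_equal(f$ranking$feature[1], "f001")
})

test_that("idgraph_view keeps top nodes then top edges deterministically", {
  g <- data.frame(
    parent = c("a", "a", "b", "c", "d"), child = c("b", "c", "c", "d", "e"),
    weight = c(5, 4, 4, 2, 10), stringsAsFactors = FALSE
  )
  rk <- data.frame(
    feature = c("a", "b", "c", "d", "e"), ri = c(5, 4, 3, 2, 1)
  )
  expect_equal(nrow(idgraph_view(g, rk, 10, 10)), 5) # unchanged when large
  v1 <- idgraph_view(g, rk, 10, 1)
  expect_equal(v1$parent, "d") # single heaviest edge
  # top 3 nodes {a, b, c}: edge d->e excluded, then 2 strongest among them
  v2 <- idgraph_view(g, rk, 3, 2)
  expect_equal(v2$weight, c(5, 4))
  expect_equal(v2$parent, c("a", "a")) # tie at 4 broken lexicographically
})

test_that("mcfs params are validated", {
  expect_error(mcfs_params(m = 1), "m")
  expect_error(mcfs_params(train_fraction = 1), "train_fraction")
  expect_error(mcfs_params(n_perm = 0), "n_perm")
  expect_error(mcfs_params(mode = 3), "mode")
})
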