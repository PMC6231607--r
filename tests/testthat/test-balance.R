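test_that("balance score counts within-class negatives and cross-class positives", {
  bc <- balanced_two_clique_network(4, 4)
  expect_equal(balance_score(bc$network, bc$truth, 0.5)$r, 0)

  # move one node across: its positive edges to the old clique become
  # cross-class (3) and its negative edges into the new clique within (4)
  moved <- bc$truth
  moved["v01"] <- 2L
  sc <- balance_score(bc$network, moved, 0.5)
  expect_equal(sc$p_c, 3L)
  expect_equal(sc$n_c, 4L)
  expect_equal(sc$r, 0.5 * 4 + 0.5 * 3)

  # all-positive graph in one class: no violation possible
  allpos <- signed_net_from_edges(data.frame(u = c("a", "a"), v = c("b", "c"),
                                             sign = 1L))
  expect_equal(balance_score(allpos, stats::setNames(rep(1L, 3), allpos$nodes))$r, 0)
  expect_error(balance_score(allpos, c(a = 1L, b = 1L)), "lacks node")
})

test_that("the score is invariant under class relabeling and canonicalization works", {
  set.seed(5)
  net <- random_signed_network(9)
  cls <- stats::setNames(sample(1:3, 9, replace = TRUE), net$nodes)
  relab <- stats::setNames(c(3L, 1L, 2L)[cls], names(cls))
  expect_equal(balance_score(net, cls)$r, balance_score(net, relab)$r)
  canon <- tomonet:::canonical_partition
  expect_equal(canon(unname(cls)), canon(unname(relab)))
})

test_that("the exhaustive oracle solves closed-form instances", {
  # frustrated triad: one negative edge inside a triangle of positives
  tri <- signed_net_from_edges(data.frame(u = c("a", "a", "b"),
                                          v = c("b", "c", "c"),
                                          sign = c(1L, 1L, -1L)))
  opt <- exhaustive_optimum(tri, K = 2, min_size = 1, alpha_w = 0.5)
  expect_equal(opt$r, 0.5)

  # balanced 4-cycle (+,-,+,-): splitting at the negative edges scores 0
  cyc <- signed_net_from_edges(data.frame(u = c("a", "b", "c", "d"),
                                          v = c("b", "c", "d", "a"),
                                          sign = c(1L, -1L, 1L, -1L)))
  opt2 <- exhaustive_optimum(cyc, K = 2, min_size = 1)
  expect_equal(opt2$r, 0)

  allpos <- signed_net_from_edges(data.frame(u = "a", v = "b", sign = 1L))
  expect_equal(exhaustive_optimum(allpos, K = 1)$r, 0)
})

test_that("the relocation heuristic recovers a perfectly balanced bipartition uniquely", {
  bc <- balanced_two_clique_network(5, 5)
  tr <- optimize_partition(bc$network, K = 2, min_size = 3, repetitions = 20,
                           seed = 42)
  expect_equal(tr$r, 0)
  expect_true(tr$unique)
  part <- tr$partitions[[1]]
  expect_equal(mclust::adjustedRandIndex(part, bc$truth[names(part)]), 1)

  # all-negative graph with singleton classes removes every violation
  neg <- signed_net_from_edges(data.frame(u = c("a", "a", "b"),
                                          v = c("b", "c", "c"), sign = -1L))
  tr2 <- optimize_partition(neg, K = 3, min_size = 1, repetitions = 5, seed = 1)
  expect_equal(tr2$r, 0)
})

test_that("the heuristic matches the exhaustive oracle on random signed graphs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    net <- random_signed_network(n)
    K <- sample(2:3, 1)
    min_size <- sample(1:2, 1)
    oracle <- exhaustive_optimum(net, K, min_size = min_size)
    tr <- optimize_partition(net, K, min_size = min_size, repetitions = 30,
                             seed = i)
    expect_gte(tr$r, oracle$r - 1e-9)   # never better than the global optimum
    expect_equal(tr$r, oracle$r)
  }
})

test_that("optimization is deterministic given a seed and respects the size floor", {
  set.seed(8)
  net <- random_signed_network(12)
  t1 <- optimize_partition(net, K = 3, min_size = 3, repetitions = 10, seed = 99)
  t2 <- optimize_partition(net, K = 3, min_size = 3, repetitions = 10, seed = 99)
  expect_identical(t1$partitions, t2$partitions)
  expect_identical(t1$r, t2$r)
  for (p in t1$partitions) expect_true(all(tabulate(p, 3) >= 3))
  expect_error(optimize_partition(net, K = 7, min_size = 2), "infeasible")
})

test_that("sweeping classes on a planted network selects the planted count", {
  sim <- simulate_planted_reports(planted_config(n = 60, m = 60, k = 25, B = 5,
                                                 K_true = 3, seed = 13))
  rs <- sim$reports
  g <- estimate_gamma(rs)
  np <- null_params(rs$params$n, rs$params$m, rs$params$k, rs$params$B, g)
  th <- thresholds(np, 0.95)
  net <- infer_signed_network(tally_pair_evidence(rs), th$delta_plus, th$delta_minus)
  sw <- sweep_classes(net, K_range = 2:5, trials = 3, repetitions = 15,
                      min_size = 3, base_seed = 7)
  expect_equal(nrow(sw$results), 4 * 3)
  expect_equal(select_model(sw)$K, 3L)
})

test_that("model selection breaks median ties by outlier count then smaller K", {
  sweep <- structure(list(summary = data.frame(
    K = c(3L, 4L, 5L),
    median_r = c(10, 10, 12),
    min_r = c(10, 10, 12),
    n_outliers = c(2L, 0L, 0L),
    mean_solutions_outliers = c(5, 0, 0),
    median_smallest_class = c(3, 3, 3))), class = "balance_sweep")
  expect_equal(select_model(sweep)$K, 4L)
  sweep$summary$n_outliers <- c(0L, 0L, 0L)
  expect_equal(select_model(sweep)$K, 3L)
})
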