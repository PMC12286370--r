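test_that("row permutation preserves row sums and leaves full rows unchanged", {
  set.seed(1)
  for (i in 1:10) {
    m <- matrix(rbinom(6 * 9, 1, 0.4), 6, 9)
    p <- permute_rows(m)
    expect_equal(rowSums(p), rowSums(m))
    expect_equal(dim(p), dim(m))
  }
  full <- matrix(1L, 3, 4)
  expect_identical(permute_rows(full), full)
})

test_that("a single one lands in each position uniformly", {
  set.seed(42)
  hits <- replicate(10000, permute_rows(matrix(c(1L, 0L), 1, 2))[1, 1])
  # Binomial(10000, 0.5): 4 SDs is 0.02
  expect_lt(abs(mean(hits) - 0.5), 0.02)
})

test_that("tie gap matches hand computation and symmetry cases", {
  expect_equal(tie_gap(net_a(), "men_to_women"), -0.5)
  # equal standardized indegrees everywhere: gap 0 in both directions
  nodes <- data.frame(user_id = c("w1", "w2", "m1", "m2"),
                      gender = c("F", "F", "M", "M"))
  edges <- data.frame(s = c("m1", "m2", "w1", "w2"),
                      r = c("w1", "w2", "m1", "m2"))
  net <- swipe_network(edges, nodes)
  expect_equal(tie_gap(net, "men_to_women"), 0)
  expect_equal(tie_gap(net, "women_to_men"), 0)
  # no ties in a direction is an error
  net_one_way <- swipe_network(data.frame(s = "m1", r = "w1"),
                               nodes[c(1, 3), ])
  expect_error(tie_gap(net_one_way, "women_to_men"), "no ties")
})

test_that("weighted and unweighted gaps coincide under equal outdegrees, differ otherwise", {
  # all active senders have outdegree 1 in net_b
  expect_equal(tie_gap(net_b(), "men_to_women", weighted = TRUE),
               tie_gap(net_b(), "men_to_women", weighted = FALSE))
  net <- rand_net(6, 8, 0.4, seed = 11)
  w <- tie_gap(net, "men_to_women", weighted = TRUE)
  u <- tie_gap(net, "men_to_women", weighted = FALSE)
  # brute force the weighted statistic tie by tie
  edges <- edge_list_of(net)
  std_in <- c(bf_indegree(edges, net$women) / 8,
              bf_indegree(edges, net$men) / 6)
  sub <- edges[edges$sender %in% net$men, ]
  outdeg <- bf_outdegree(edges, net$men)
  wts <- 1 / outdeg[sub$sender]
  expect_equal(w, sum(wts * (std_in[sub$sender] - std_in[sub$receiver])) /
                 sum(wts))
  expect_false(isTRUE(all.equal(w, u)))
})

test_that("reciprocal gap averages man-minus-woman indegree over matches", {
  expect_equal(reciprocal_gap(net_a()), 0)  # only pair: both std indeg 1
  # a popular man matched with a woman receiving only his swipe:
  # positive gap
  nodes <- data.frame(user_id = c(paste0("w", 1:3), paste0("m", 1:3)),
                      gender = rep(c("F", "M"), each = 3))
  edges <- data.frame(
    s = c("w1", "w2", "w3", "m1", "m2"),
    r = c("m1", "m1", "m1", "w1", "w3"))
  net <- swipe_network(edges, nodes)
  # match: w1-m1. std(m1) = 3/3 = 1; std(w1) = 1/3
  expect_equal(reciprocal_gap(net), 1 - 1 / 3)
  # no matches -> undefined
  nomatch <- swipe_network(data.frame(s = "w1", r = "m2"), nodes)
  expect_error(reciprocal_gap(nomatch), "no reciprocated pairs")
})

test_that("empirical p-values count ties on both sides", {
  expect_equal(empirical_pvalues(0, c(-1, 0, 1)),
               c(p_le = 2 / 3, p_ge = 2 / 3))
  expect_equal(empirical_pvalues(-5, c(1, 2, 3)), c(p_le = 0, p_ge = 1))
  expect_equal(empirical_pvalues(5, c(1, 2, 3)), c(p_le = 1, p_ge = 0))
  expect_error(empirical_pvalues(1, numeric(0)), "no simulated")
  expect_error(empirical_pvalues(1, c(NA_real_, NA_real_)), "no simulated")
})

test_that("cug_test requires a seed and is bit-reproducible", {
  net <- net_b()
  expect_error(cug_test(net, "gap_mw", n_sims = 10), "seed")
  r1 <- cug_test(net, "gap_mw", n_sims = 200, seed = 3)
  r2 <- cug_test(net, "gap_mw", n_sims = 200, seed = 3)
  expect_identical(r1, r2)
  expect_error(cug_test(net, "no_such_stat", n_sims = 5, seed = 1),
               "unknown statistic")
})

test_that("a conserved statistic yields a degenerate null distribution", {
  net <- rand_net(4, 5, 0.5, seed = 2)
  res <- cug_test(net, "total_ties", n_sims = 50, seed = 9)
  expect_true(all(res$sim == res$observed))
  expect_equal(res$p_le, 1)
  expect_equal(res$p_ge, 1)
  # density is likewise conserved by row permutation
  res_d <- cug_test(net, "density", n_sims = 50, seed = 9)
  expect_true(all(res_d$sim == res_d$observed))
})

test_that("p_le + p_ge >= 1 and replicate count is honoured", {
  for (seed in 1:3) {
    net <- rand_net(5, 6, 0.4, seed = seed)
    res <- cug_test(net, "gap_mw", n_sims = 120, seed = seed + 100)
    expect_gte(res$p_le + res$p_ge, 1)
    expect_length(res$sim, 120)
    expect_equal(res$n_sims, 120L)
  }
})

test_that("missing replicates (no matches after permutation) are reported and excluded", {
  # sparse network with a single match: most permuted networks have none
  nodes <- data.frame(user_id = c(paste0("w", 1:4), paste0("m", 1:4)),
                      gender = rep(c("F", "M"), each = 4))
  edges <- data.frame(s = c("w1", "m1"), r = c("m1", "w1"))
  net <- swipe_network(edges, nodes)
  res <- cug_test(net, "reciprocal", n_sims = 300, seed = 17)
  expect_gt(res$n_missing, 0)
  expect_equal(sum(is.na(res$sim)), res$n_missing)
  expect_gte(res$p_le + res$p_ge, 1)
})

test_that("sampled CUG distribution matches exhaustive enumeration on a small network", {
  # 2 women x 2 men, each sender one tie: exactly 16 equally likely
  # row-permutation outcomes
  net <- net_b()
  exact <- enumerate_cug(net, bf_gap_mw_from_matrices)
  expect_length(exact, 16)
  res <- cug_test(net, "gap_mw", n_sims = 4000, seed = 31)
  support <- sort(unique(round(exact, 9)))
  p_exact <- as.numeric(table(factor(round(exact, 9), levels = support))) /
    length(exact)
  idx <- match_to_support(res$sim, support)
  counts <- tabulate(idx, nbins = length(support))
  gof <- suppressWarnings(stats::chisq.test(counts, p = p_exact))
  expect_gt(gof$p.value, 0.01)
})
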