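test_that("bootstrap contrast handles identical and shifted groups", {
  set.seed(10)
  x <- stats::rnorm(8)
  b0 <- bootstrap_group_difference(x, x, n_boot = 500)
  expect_equal(b0$observed, 0)
  expect_true(all(!b0$ci$excludes_zero))
  expect_identical(b0$stars, "")
  # nested intervals: wider at higher confidence
  expect_true(all(diff(b0$ci$upper - b0$ci$lower) >= 0))

  b1 <- bootstrap_group_difference(x + 10, x, n_boot = 500)
  expect_equal(b1$observed, 10)
  expect_true(b1$ci$excludes_zero[1])   # 95 % CI excludes 0 -> "*"
  expect_match(b1$stars, "^\\*")

  bdeg <- bootstrap_group_difference(rep(2, 5), rep(1, 5), n_boot = 100)
  expect_true(bdeg$degenerate)
  expect_equal(bdeg$ci$lower, rep(1, 3))
})

test_that("a clear shift is detected by the 95% interval in most replicate cohorts", {
  hits <- vapply(1:60, function(k) {
    set.seed(400 + k)
    a <- stats::rnorm(8, 10, 1)
    b <- stats::rnorm(8, 0, 1)
    bootstrap_group_difference(a, b, n_boot = 400)$ci$excludes_zero[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BCa reduces to the percentile interval for a symmetric bootstrap", {
  # a = (-1, 1) makes the jackknife deviations symmetric (acceleration = 0)
  # and the bootstrap distribution of the difference symmetric about 0
  set.seed(5)
  br <- bootstrap_group_difference(c(-1, 1), c(0, 0), n_boot = 4000)
  perc <- stats::quantile(br$boot, c(0.025, 0.975), names = FALSE)
  expect_equal(br$ci$lower[1], perc[1], tolerance = 0.02)
  expect_equal(br$ci$upper[1], perc[2], tolerance = 0.02)
})

test_that("BCa endpoints track boot::boot.ci on the same data", {
  skip_if_not_installed("boot")
  set.seed(21)
  a <- stats::rnorm(10, 2, 1.5)
  b <- stats::rnorm(10)
  br <- bootstrap_group_difference(a, b, n_boot = 4000)
  dat <- data.frame(x = c(a, b), g = rep(1:2, times = c(10, 10)))
  set.seed(22)
  bo <- boot::boot(dat, function(d, i)
    mean(d$x[i][d$g[i] == 1]) - mean(d$x[i][d$g[i] == 2]),
    R = 4000, strata = dat$g)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  width <- diff(ref)
  expect_lt(abs(br$ci$lower[1] - ref[1]), 0.15 * width)
  expect_lt(abs(br$ci$upper[1] - ref[2]), 0.15 * width)
})

test_that("rewiring preserves degree sequences and the edge-weight multiset", {
  set.seed(31)
  for (rep in 1:25) {
    a <- random_adjacency(10, 0.5)
    g <- graph_from_adj(a)
    if (igraph::ecount(g) < 2) next
    rw <- rewire_network(g)
    expect_identical(igraph::degree(g), igraph::degree(rw))
    expect_equal(sort(igraph::E(g)$weight), sort(igraph::E(rw)$weight))
    expect_false(igraph::any_multiple(rw))
    expect_false(any(igraph::which_loop(rw)))
  }
  expect_error(rewire_network(graph_from_adj(matrix(0, 3, 3))), "sparse")
})

test_that("identical networks give near-1 permutation p-values; the counting rule holds", {
  set.seed(17)
  a <- random_adjacency(8, 0.6)
  g <- graph_from_adj(a)
  pt <- rewire_permutation_test(g, g, n_perm = 99, seed = 4)
  expect_equal(pt$table$observed, rep(0, 8))
  expect_true(all(pt$table$p > 0.9))

  # p = (#{|null| >= |obs|} + 1) / (n_perm + 1), recomputed from the draws
  g2 <- rewire_network(g)
  pt2 <- rewire_permutation_test(g, g2, n_perm = 99, seed = 5)
  manual <- vapply(seq_len(ncol(pt2$null)), function(j)
    (sum(abs(pt2$null[, j]) >= abs(pt2$table$observed[j])) + 1) / 100,
    numeric(1))
  expect_equal(pt2$table$p, manual)
  expect_true(all(pt2$table$p > 0 & pt2$table$p <= 1))
})

test_that("permutation p-values are super-uniform under a null cohort contrast", {
  # no planted effect: rejections at alpha = 0.05 must not exceed alpha
  # beyond Monte-Carlo tolerance (the rewiring null is conservative)
  rej <- unlist(lapply(1:30, function(k) {
    nc <- null_cohort_networks(3000 + k)
    pt <- rewire_permutation_test(nc$consensus_rea, nc$consensus_ctl,
                                  n_perm = 99, seed = k)
    pt$table$p < 0.05
  }))
  expect_lte(mean(rej), 0.08)
})

test_that("hub-behaviour correlation recovers proportional and null relationships", {
  animals <- sprintf("m%02d", 1:12)
  hub <- do.call(rbind, lapply(c("A", "B"), function(nd)
    data.frame(animal_id = animals, node = nd,
               hub_score = seq(0.1, 1, length.out = 12))))
  beh <- data.frame(animal_id = animals,
                    percent_correct = 40 + 50 * seq(0.1, 1, length.out = 12))
  bc <- behavior_hub_correlation(hub, beh)
  expect_equal(bc$r, c(1, 1), tolerance = 1e-12)
  expect_equal(bc$n, c(12, 12))

  # hand-computed Pearson on a small pair
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  hub4 <- data.frame(animal_id = paste0("m", 1:4), node = "A", hub_score = x)
  beh4 <- data.frame(animal_id = paste0("m", 1:4), percent_correct = y)
  expect_equal(behavior_hub_correlation(hub4, beh4)$r, r_manual)

  # independence: mean correlation near zero over label permutations
  set.seed(61)
  rs <- vapply(1:200, function(i) {
    behp <- beh
    behp$percent_correct <- sample(beh$percent_correct)
    behavior_hub_correlation(hub[hub$node == "A", ], behp)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  expect_error(behavior_hub_correlation(hub4[1:2, ], beh4), "3 matched")
  beh_const <- beh4; beh_const$percent_correct <- 5
  expect_error(behavior_hub_correlation(hub4, beh_const), "zero-variance")
})
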