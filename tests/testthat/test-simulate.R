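test_that("range-dependent edge probabilities follow the distance decay", {
  # P(edge) = 0.9 * 0.3^(|i-j|-1): 0.9 at lag 1, 0.27 at lag 2
  hits1 <- hits2 <- 0; n1 <- n2 <- 0
  for (s in 1:150) {
    g <- make_graph("range_dependent", 8, seed = s)
    lag <- abs(outer(1:8, 1:8, "-"))
    up <- upper.tri(lag)
    hits1 <- hits1 + sum(g$edges[up & lag == 1]); n1 <- n1 + sum(up & lag == 1)
    hits2 <- hits2 + sum(g$edges[up & lag == 2]); n2 <- n2 + sum(up & lag == 2)
  }
  expect_equal(hits1 / n1, 0.9, tolerance = 0.05)
  expect_equal(hits2 / n2, 0.27, tolerance = 0.15)
})

test_that("precision matrices follow the diagonal rule and are positive definite", {
  for (model in c("small_world", "scale_free", "range_dependent")) {
    g <- make_graph(model, 12, seed = 3)
    expect_equal(unname(diag(g$precision)),
                 unname(rowSums(abs(g$precision)) - diag(abs(g$precision)) + 1))
    expect_true(min(eigen(g$precision, symmetric = TRUE)$values) > 0)
    expect_true(all(g$edges %in% c(0, 1)))
    expect_identical(g$edges, t(g$edges))
  }
  # isolated node: diagonal is exactly 1
  g <- make_graph("range_dependent", 20, seed = 11)
  iso <- which(rowSums(g$edges) == 0)
  if (length(iso) > 0)
    expect_equal(unname(diag(g$precision)[iso]), rep(1, length(iso)))
  expect_error(make_graph("foo", 10), "arg")
})

test_that("scale-free graphs have heavier degree tails than the ring lattice", {
  g <- make_graph("scale_free", 60, seed = 5)
  expect_gte(max(rowSums(g$edges)), 8)   # hubs emerge under preferential attachment
  sw <- make_graph("small_world", 60, seed = 5, p_rewire = 0)
  expect_equal(unname(rowSums(sw$edges)), rep(2, 60))  # pure degree-2 ring
})

test_that("simulation is reproducible and respects the count family", {
  g <- make_graph("small_world", 6, seed = 7)
  a <- simulate_counts(g, 15, seed = 9)
  b <- simulate_counts(g, 15, seed = 9)
  expect_identical(a$x, b$x)
  expect_true(all(a$x >= 0 & a$x == round(a$x)))
  d <- simulate_counts(g, 15, seed = 10)
  expect_false(identical(a$x, d$x))
  p <- simulate_counts(g, 15, family = "poisson", seed = 9)
  expect_false(identical(a$x, p$x))
})

test_that("marginal moments match the lognormal-mixture theory", {
  # independent taxa (empty graph edge case is disallowed by m>=3, so use a
  # graph whose precision is the identity: weight 0 edges)
  g <- make_graph("small_world", 5, seed = 13, weight = 0)
  expect_equal(unname(g$precision), diag(5))
  sim <- simulate_counts(g, 5000, mu = 3, gamma = 2, seed = 14)
  # E[X] = exp(mu + sigma^2/2) with sigma^2 = 1
  expect_equal(mean(colMeans(sim$x)), exp(3.5), tolerance = 0.05)
  # log-scale mean recovers mu
  lam_mean <- mean(log(colMeans(sim$x))) - 0.5
  expect_equal(lam_mean, 3, tolerance = 0.05)
})

test_that("negative binomial counts are overdispersed relative to Poisson", {
  g <- make_graph("small_world", 5, seed = 15, weight = 0)
  nb <- simulate_counts(g, 4000, gamma = 2, seed = 16)
  po <- simulate_counts(g, 4000, family = "poisson", seed = 16)
  vm_nb <- mean(apply(nb$x, 2, var) / colMeans(nb$x))
  vm_po <- mean(apply(po$x, 2, var) / colMeans(po$x))
  expect_gt(vm_nb, vm_po * 1.5)
  # large gamma approaches the Poisson variance/mean profile
  hi <- simulate_counts(g, 4000, gamma = 1e6, seed = 17)
  vm_hi <- mean(apply(hi$x, 2, var) / colMeans(hi$x))
  expect_equal(vm_hi, vm_po, tolerance = 0.1)
})

test_that("linked taxa are more rank-correlated than unlinked taxa", {
  g <- make_graph("small_world", 15, seed = 19, weight = -1)
  sim <- simulate_counts(g, 500, seed = 20)
  R <- abs(cor(sim$x, method = "spearman"))
  up <- upper.tri(R)
  linked <- R[up & g$edges == 1]
  unlinked <- R[up & g$edges == 0]
  expect_gt(mean(linked), mean(unlinked))
  expect_lt(wilcox.test(linked, unlinked, alternative = "greater")$p.value,
            1e-6)
})
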