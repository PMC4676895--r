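test_that("rank correlations match brute-force oracles, with and without ties", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(10, 4, 7, 1), c(8, 7, 3, 1)),
               oracle_spearman(c(10, 4, 7, 1), c(8, 7, 3, 1)))

  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 5, 7, 9)), 1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(9, 7, 5, 2)), -1)
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 3)),
               oracle_kendall(c(1, 1, 2), c(1, 2, 3)))

  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:5, 8, replace = TRUE)   # plenty of ties
    y <- sample(0:5, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(x, y), oracle_kendall(x, y), tolerance = 1e-12)
  }
})

test_that("rank correlations are invariant under strictly increasing transforms", {
  set.seed(3)
  x <- rpois(12, 9); y <- rpois(12, 9)
  expect_equal(spearman_rho(x, y), spearman_rho(exp(x / 3), y))
  expect_equal(kendall_tau(x, y), kendall_tau(x, y^3 + y))
})

test_that("degenerate rank inputs warn and return zero", {
  expect_warning(r <- spearman_rho(rep(2, 5), 1:5), "zero-variance")
  expect_equal(r, 0)
  expect_warning(t <- kendall_tau(1:5, rep(1, 5)), "tied")
  expect_equal(t, 0)
})

test_that("sin transform has the stated closed-form values and shape", {
  expect_equal(sin_transform(0), 0)
  expect_equal(sin_transform(1), 1)
  expect_equal(sin_transform(0.5), sqrt(2) / 2)
  r <- seq(-1, 1, by = 0.05)
  expect_equal(sin_transform(-r), -sin_transform(r))     # odd
  expect_true(all(diff(sin_transform(r)) > 0))           # strictly increasing
  expect_error(sin_transform(1.01), "\\[-1, 1\\]")
})

test_that("distances match their printed formulas on hand-computable cases", {
  expect_equal(hellinger_distance(c(3, 5, 2), c(3, 5, 2)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(hellinger_distance(c(2, 2), c(1, 3)),
               oracle_hellinger(c(2, 2), c(1, 3)))

  expect_equal(chi2_distance(c(4, 1), c(4, 1)), 0)
  expect_equal(chi2_distance(c(1, 0), c(0, 1)), 2)
  set.seed(5)
  a <- rpois(6, 8); b <- rpois(6, 8)
  expect_equal(chi2_distance(a, b), oracle_chi2(a, b))
  expect_equal(chi2_distance(a, b), chi2_distance(b, a))
  # a shared zero position is skipped, not NaN
  expect_equal(chi2_distance(c(1, 0, 2), c(3, 0, 1)),
               oracle_chi2(c(1, 0, 2), c(3, 0, 1)))

  expect_equal(braycurtis_dissimilarity(c(4, 1, 0), c(4, 1, 0)), 0)
  expect_equal(braycurtis_dissimilarity(c(1, 0), c(0, 5)), 1)
  expect_equal(braycurtis_dissimilarity(c(1, 1), c(1, 3)), 1 / 3)

  expect_error(hellinger_distance(c(0, 0), c(1, 2)), "zero total")
  expect_error(braycurtis_dissimilarity(c(0, 0), c(0, 0)), "zero total")
})

test_that("Hellinger distance ignores positive rescaling of a profile", {
  set.seed(7)
  a <- rpois(10, 6) + 1; b <- rpois(10, 6) + 1
  expect_equal(hellinger_distance(7 * a, b), hellinger_distance(a, b))
})

test_that("gaussian kernel maps distances to (0,1] and grows with sigma", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  S <- gaussian_kernel(D, 1)
  expect_equal(S[1, 2], exp(-1))
  expect_equal(diag(S), c(1, 1))
  S2 <- gaussian_kernel(D, 2)
  expect_true(S2[1, 2] > S[1, 2])
  expect_error(gaussian_kernel(D, 0), "positive")
})

test_that("similarity matrices are symmetric, unit-diagonal, and honour duplicates", {
  x <- fixture_counts(n = 12, m = 5, seed = 9)
  for (meas in c("spearman", "kendall", "hellinger", "chi2", "braycurtis")) {
    S <- similarity_matrix(x, meas)
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_equal(unname(diag(S)), rep(1, 5))
    if (meas %in% c("hellinger", "chi2", "braycurtis"))
      expect_true(all(S > 0 & S <= 1))
    else
      expect_true(all(S >= -1 & S <= 1))
    # duplicated taxon column: similarity exactly 1 under every family
    xd <- cbind(x, dup = x[, 1])
    Sd <- similarity_matrix(xd, meas)
    expect_equal(unname(Sd[1, ncol(xd)]), 1)
  }
})

test_that("kernel similarities agree with elementwise recomputation", {
  x <- fixture_counts(n = 10, m = 5, seed = 21)
  p <- relative_abundance(x)
  S <- similarity_matrix(x, "braycurtis")      # relative abundance default
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(S[i, j], exp(-oracle_braycurtis(p[, i], p[, j])^2),
                 tolerance = 1e-12)
  Sh <- similarity_matrix(x, "hellinger")
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(Sh[i, j], exp(-oracle_hellinger(p[, i], p[, j])^2),
                 tolerance = 1e-12)
})

test_that("psd repair floors the spectrum but leaves PSD matrices untouched", {
  set.seed(13)
  # indefinite symmetric matrix with unit diagonal
  M <- matrix(0.9, 3, 3); M[1, 2] <- M[2, 1] <- -0.9; diag(M) <- 1
  expect_true(min(eigen(M, symmetric = TRUE)$values) < 0)
  R <- psd_repair(M)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(R)), rep(1, 3))

  x <- fixture_counts(n = 30, m = 4, seed = 2)
  S <- similarity_matrix(x, "hellinger")   # Hellinger kernel is PSD
  expect_identical(psd_repair(S), S)
})
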