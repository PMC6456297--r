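test_that("fisher_exact reproduces worked examples and reports the sample OR", {
  expect_equal(round(fisher_exact(c(6, 16, 1, 24))$p_value, 3), 0.040)
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p_value, 1)
  # margins (3,3,3,3): the two extreme tables each have probability 1/20
  expect_equal(fisher_exact(c(3, 0, 0, 3))$p_value, 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact(c(6, 16, 1, 24))$odds_ratio, 6 * 24 / 16)
  expect_true(is.infinite(fisher_exact(c(10, 0, 0, 10))$odds_ratio))
  expect_error(fisher_exact(c(0, 0, 0, 0)), "all-zero")
})

test_that("fisher_exact is invariant under simultaneous row and column swaps", {
  set.seed(5)
  for (i in 1:25) {
    t <- sample.int(12, 4) - 1
    p1 <- fisher_exact(t)$p_value
    p2 <- fisher_exact(t[c(4, 3, 2, 1)])$p_value  # both rows and columns swapped
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("hypergeom_overlap matches printed counts and enumeration", {
  res <- hypergeom_overlap(263820, 4725, 3156, 299)
  expect_equal(res$expected, 4725 * 3156 / 263820)
  expect_equal(round(res$expected), 57)

  expect_equal(hypergeom_overlap(10, 0, 5, 0)$expected, 0)
  expect_equal(hypergeom_overlap(10, 0, 5, 0)$p_value, 1)

  res2 <- hypergeom_overlap(10, 4, 5, 3)
  expect_equal(res2$expected, 2)
  expect_equal(res2$p_value, 66 / 252, tolerance = 1e-12)

  # monotone non-increasing tail in k
  ps <- vapply(0:4, function(k) hypergeom_overlap(10, 4, 5, k)$p_value, 1)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_overlap(10, 4, 5, 6), "inconsistent")
})

test_that("mann_whitney_u handles exact and approximate branches", {
  x <- c(5, 1, 3, 9, 2, 8, 4, 7, 6, 0)
  res <- mann_whitney_u(x, x)
  expect_equal(res$u, 50)
  expect_gt(res$p_value, 0.95)

  res2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res2$u, 0)
  expect_equal(res2$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res2$method, "exact")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney branch agrees with rank-assignment enumeration", {
  set.seed(7)
  for (i in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- sample.int(1000, nx); y <- sample.int(1000, ny)  # no ties
    expect_equal(mann_whitney_u(x, y)$p_value, mwu_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney rejection rate is calibrated under the null", {
  set.seed(13)
  rej <- mean(replicate(1000, {
    mann_whitney_u(rnorm(200), rnorm(200))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("benjamini_hochberg applies the step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(1), 1)
  set.seed(17)
  p <- runif(200)^2
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # q is monotone in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # independent hand application of the step-up formula
  m <- length(p); o <- order(p)
  qhand <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(qhand, 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pearson_r recovers exact and tail behaviour", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")

  # |R| > 0.17 at n = 299 should be rare (about 0.3% under the null)
  set.seed(19)
  hits <- mean(replicate(1000, abs(pearson_r(rnorm(299), rnorm(299))$r) > 0.17))
  expect_lt(hits, 0.012)
})

test_that("one-sample proportion score test matches direct arithmetic", {
  expect_equal(one_sample_proportion_test(10, 40, 0.25)$p_value, 1)
  res <- one_sample_proportion_test(15, 40, 0.25)
  expect_equal(res$z, 1.825742, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0679, tolerance = 1e-3)
  res2 <- one_sample_proportion_test(0, 100, 0.5)
  expect_equal(res2$z, -10)
  expect_lt(res2$p_value, 1e-22)
  expect_error(one_sample_proportion_test(1, 0, 0.5), "positive")
})

test_that("count_ratio_test is exact, central and calibrated", {
  expect_equal(count_ratio_test(10, 10, 1), 1)
  expect_equal(count_ratio_test(20, 0, 1), 2 * 0.5^20, tolerance = 1e-9)
  expect_equal(count_ratio_test(0, 0, 1), 1)
  # matches binom.test tile by tile
  set.seed(23)
  for (i in 1:20) {
    a <- rpois(1, 30); b <- rpois(1, 10)
    if (a + b == 0) next
    expect_equal(count_ratio_test(a, b, 2),
                 binom.test(a, a + b, 2 / 3)$p.value, tolerance = 1e-9)
  }
  # null calibration: the exact test is discrete, hence sub-uniform — the
  # rejection rate never exceeds the nominal level at any threshold
  set.seed(29)
  a <- rpois(10000, 20); b <- rpois(10000, 20)
  p <- count_ratio_test(a, b, 1)
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 10000))
})
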