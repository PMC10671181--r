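test_that("all-same-sign cohorts give the closed-form exact p", {
  # n = 10: p = 2 / 2^10
  r10 <- wilcoxon_exact(seq(1, 10), rep(0, 10))
  expect_equal(r10$p_two_sided, 2 / 1024)
  expect_equal(r10$w_statistic, 0)
  expect_identical(r10$method, "exact")
  # n = 9: p = 2 / 2^9 = 0.00390625
  r9 <- wilcoxon_exact(seq(1, 9), rep(0, 9))
  expect_equal(r9$p_two_sided, 2 / 512)
  # printed-precision forms
  expect_equal(round(r10$p_two_sided, 3), 0.002)
  expect_equal(round(r9$p_two_sided, 4), 0.0039)
})

test_that("exact p matches full 2^n enumeration, with and without ties", {
  d5 <- c(1, 2, 3, 4, -5)
  expect_equal(wilcoxon_exact(d5)$p_two_sided, wilcoxon_enumeration_p(d5))
  set.seed(88)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))   # rounding induces ties/zeros
    if (all(d == 0)) next
    expect_equal(wilcoxon_exact(d)$p_two_sided, wilcoxon_enumeration_p(d),
                 tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when there are no ties", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_exact(x, y)
    want <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                         exact = TRUE))
    expect_equal(got$p_two_sided, want$p.value, tolerance = 1e-12)
  }
})

test_that("the signed-rank null is a proper distribution and the test is two-sided", {
  r <- rank(abs(c(0.3, -1.2, 2.5, 0.8, -0.1)))
  expect_equal(petbtv:::psignrank_multiset(sum(r), r), 1)
  expect_equal(petbtv:::psignrank_multiset(-1, r), 0)
  set.seed(10)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(wilcoxon_exact(x, y)$p_two_sided,
                 wilcoxon_exact(y, x)$p_two_sided)
  }
})

test_that("zero differences are dropped classically or kept under Pratt", {
  d <- c(0, 0, 1, 2, -3, 4)
  drop <- wilcoxon_exact(d)
  expect_equal(drop$n_effective, 4L)
  expect_equal(drop$p_two_sided, wilcoxon_enumeration_p(d))
  pratt <- wilcoxon_exact(d, zeros = "pratt")
  expect_equal(pratt$n_effective, 4L)
  # under Pratt the nonzero ranks are shifted up by the zero count
  expect_equal(pratt$rank_sum_positive + pratt$rank_sum_negative,
               sum(rank(abs(d))[d != 0]))
  expect_error(wilcoxon_exact(c(0, 0, 0)), "all differences are zero")
  expect_error(wilcoxon_exact(numeric(0)), "at least one pair")
})

test_that("large cohorts switch to the flagged normal approximation", {
  set.seed(2)
  x <- rnorm(40, 0.5); y <- rnorm(40)
  r <- wilcoxon_exact(x, y)
  expect_identical(r$method, "normal_approx")
  want <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
  expect_equal(r$p_two_sided, want$p.value, tolerance = 1e-6)
})

test_that("type-I error of the exact test is near nominal", {
  set.seed(314)
  reject <- logical(400)
  for (i in seq_along(reject))
    reject[i] <- wilcoxon_exact(rnorm(10))$p_two_sided <= 0.05
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("Pearson inference matches cor.test and handles degeneracy", {
  set.seed(6)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  got <- pearson_with_p(x, y)
  want <- cor.test(x, y)
  expect_equal(got$r, unname(want$estimate))
  expect_equal(got$p_two_sided, want$p.value, tolerance = 1e-12)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, x)$p_two_sided, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, rep(1, 50)), "constant")
  expect_error(pearson_with_p(1:2, 2:3), "n >= 3")
  # a moderate correlation at huge n is overwhelmingly significant
  n <- 1e5
  z <- rnorm(n); w <- 0.5 * z + sqrt(0.75) * rnorm(n)
  expect_lt(pearson_with_p(z, w)$p_two_sided, 1e-4)
})

test_that("descriptives match a sorting-based oracle", {
  d <- descriptives(c(15, 4, 6, 4, 13, 5, 3, 5, 5, 4))
  expect_equal(d$median, 5)
  expect_equal(d$min, 3)
  expect_equal(d$max, 15)
  expect_equal(descriptives(7)$mean, 7)
  expect_true(is.na(descriptives(7)$sd))
  expect_equal(descriptives(c(1, 2, 3, 4))$median, 2.5)
  set.seed(12)
  for (rep in 1:10) {
    v <- rnorm(sample(1:30, 1))
    d <- descriptives(v)
    s <- sort(v)
    n <- length(s)
    med <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(d$median, med)
    expect_equal(d$mean, sum(v) / n)
    expect_equal(d$min, s[1])
    expect_equal(d$max, s[n])
    if (n > 1) expect_equal(d$sd, sqrt(sum((v - mean(v))^2) / (n - 1)))
  }
  expect_error(descriptives(numeric(0)), "empty")
})
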