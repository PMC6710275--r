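test_that("complete separation at 4 vs 4 gives the minimal two-sided p", {
  cmp <- mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(cmp$p_two_sided, 2 / 70)
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$method, "exact")
  # symmetric under group exchange
  flip <- mann_whitney_exact(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(flip$p_two_sided, cmp$p_two_sided)
  expect_equal(flip$u_statistic, 16)
})

test_that("identical groups give the maximal p of 1", {
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
})

test_that("exact p equals the full-enumeration oracle, ties included", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      a <- sample(1:7, 5, replace = TRUE)  # replacement forces ties
      b <- sample(1:7, 4, replace = TRUE)
      expect_equal(mann_whitney_exact(a, b)$p_two_sided, brute_mw_p(a, b))
    }
    # and, tie-free, equals the classic exact distribution in wilcox.test
    for (rep in 1:5) {
      a <- runif(5); b <- runif(6)
      expect_equal(mann_whitney_exact(a, b)$p_two_sided,
                   wilcox.test(a, b, exact = TRUE)$p.value)
    }
  })
})

test_that("complete separation follows the closed form 2/C(n+m, n)", {
  for (n in 2:6) {
    for (m in 2:6) {
      p <- mann_whitney_exact(seq_len(n), n + seq_len(m))$p_two_sided
      expect_equal(p, 2 / choose(n + m, n))
    }
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  a <- c(1, 3, 4, 6, 8, 9, 11, 14, 15, 17, 18, 20, 21, 23, 24, 26)
  b <- c(2, 5, 7, 10, 12, 13)
  cmp <- mann_whitney_exact(a, b)
  expect_equal(cmp$method, "asymptotic")
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(cmp$p_two_sided, ref$p.value, tolerance = 1e-10)
  # forcing enumeration on the same data stays close to the approximation
  exact <- mann_whitney_exact(a, b, exact = TRUE)
  expect_lt(abs(exact$p_two_sided - cmp$p_two_sided), 0.05)
})

test_that("degenerate comparisons are rejected", {
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_exact(1:3, c(1, NA)), "finite")
})

test_that("pearson_r matches the closed-form t transform", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(2, 1, 5, 4, 8)
  ct <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_equal(ct$p_two_sided, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1)
})

test_that("pearson_r is affine-invariant and flips sign with the slope", {
  withr::with_seed(5, {
    x <- rnorm(30); y <- x + rnorm(30)
    r0 <- pearson_r(x, y)$r
    expect_equal(pearson_r(3 * x + 7, y)$r, r0, tolerance = 1e-12)
    expect_equal(pearson_r(x, -2 * y + 1)$r, -r0, tolerance = 1e-12)
    # independent draws decorrelate at root-n rate
    big <- pearson_r(rnorm(1e4), rnorm(1e4))
    expect_lt(abs(big$r), 0.05)
  })
  expect_error(pearson_r(1:5, rep(2, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("the 1.5 IQR fence removes only extreme values, single pass", {
  expect_equal(remove_extreme_outliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  expect_equal(remove_extreme_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_warning(out <- remove_extreme_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, c(1, 2, 3))
  # vacuous fences: data within quartiles +/- 1.5 IQR survive untouched
  withr::with_seed(9, {
    for (rep in 1:10) {
      v <- runif(20)
      q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      fence_ok <- max(v) <= q[2] + 1.5 * diff(q) &&
        min(v) >= q[1] - 1.5 * diff(q)
      if (fence_ok) expect_equal(remove_extreme_outliers(v), v)
    }
  })
})
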