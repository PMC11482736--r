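test_that("percent agreement is the diagonal fraction", {
  expect_equal(percent_agreement(contingency_2x2(16, 36, 8, 24)), 40 / 84)
  expect_equal(percent_agreement(contingency_2x2(10, 0, 0, 0)), 1)
  expect_equal(percent_agreement(contingency_2x2(0, 5, 5, 0)), 0)
  expect_error(contingency_2x2(0, 0, 0, 0), "empty")
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("kappa follows the hand formula and its degenerate cases", {
  k <- cohens_kappa(contingency_2x2(16, 36, 8, 24))
  expect_equal(k$po, 40 / 84)
  expect_equal(k$pe, 3168 / 7056)
  expect_equal(k$kappa, 4 / 81, tolerance = 1e-12)

  expect_equal(cohens_kappa(contingency_2x2(7, 0, 0, 13))$kappa, 1)
  # po == pe by construction: independent margins
  expect_equal(cohens_kappa(contingency_2x2(1, 1, 1, 1))$kappa, 0)
  # both raters constant: chance agreement is 1, kappa undefined
  expect_error(cohens_kappa(contingency_2x2(5, 0, 0, 0)), "undefined")
})

test_that("kappa is invariant under transposing rater roles and bounded by 1", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      cells <- sample(0:30, 4, replace = TRUE)
      if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
          sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
      t1 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      t2 <- contingency_2x2(cells[1], cells[3], cells[2], cells[4])
      k1 <- tryCatch(cohens_kappa(t1), error = function(e) NULL)
      if (is.null(k1)) next
      expect_equal(k1$kappa, cohens_kappa(t2)$kappa)
      expect_lte(k1$kappa, 1)
      expect_equal(k1$kappa == 1, cells[2] == 0 && cells[3] == 0)
    }
  })
})

test_that("kappa standard errors agree with a direct hand computation", {
  # worked 2x2: cells 20/5/10/15, n = 50
  tab <- contingency_2x2(20, 5, 10, 15)
  k <- cohens_kappa(tab)
  p <- matrix(c(20, 5, 10, 15), 2, byrow = TRUE) / 50
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  kap <- (po - pe) / (1 - pe)
  expect_equal(k$kappa, kap)
  se0 <- sqrt((pe + pe^2 - sum(rowSums(p) * colSums(p) *
                                 (rowSums(p) + colSums(p)))) / 50) / (1 - pe)
  expect_equal(k$se0, se0)
  expect_equal(k$p_value, 2 * pnorm(-abs(kap / se0)))
  expect_equal(k$ci_high - k$ci_low, 2 * qnorm(0.975) * k$se)
})

test_that("exact Mann-Whitney matches enumeration on small instances", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 2 / 6)

  same <- mann_whitney_u(c(5, 1, 3), c(3, 5, 1), mode = "exact")
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact mode equals the pair-counting enumeration oracle with ties", {
  withr::with_seed(17, {
    for (rep in 1:40) {
      n_a <- sample(2:5, 1)
      n_b <- sample(2:5, 1)
      a <- sample(1:6, n_a, replace = TRUE)   # heavy ties
      b <- sample(1:6, n_b, replace = TRUE)
      got <- mann_whitney_u(a, b, mode = "exact")
      expect_equal(got$p_value, brute_mw_exact(a, b), tolerance = 1e-12)
    }
  })
})

test_that("exact mode agrees with the classical null distribution when tie-free", {
  withr::with_seed(19, {
    for (rep in 1:15) {
      a <- round(rnorm(4, 0, 10), 3)
      b <- round(rnorm(5, 1, 10), 3)
      got <- mann_whitney_u(a, b, mode = "exact")
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(got$u_statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("normal approximation tracks the exact p at n = 10 per group", {
  withr::with_seed(29, {
    for (rep in 1:40) {
      a <- rnorm(10, 0, 1)
      b <- rnorm(10, stats::runif(1, 0, 1.5), 1)
      got <- mann_whitney_u(a, b, mode = "approx")
      u <- got$u_statistic
      p_exact <- min(1, 2 * min(stats::pwilcox(u, 10, 10),
                                1 - stats::pwilcox(u - 1, 10, 10)))
      expect_lt(abs(got$p_value - p_exact), 0.02)
    }
  })
})

test_that("U and mean ranks satisfy the rank-sum identities", {
  withr::with_seed(37, {
    for (rep in 1:20) {
      a <- sample(1:40, sample(3:12, 1), replace = TRUE)
      b <- sample(1:40, sample(3:12, 1), replace = TRUE)
      mw <- mann_whitney_u(a, b, mode = "approx")
      n <- mw$n_a + mw$n_b
      expect_gte(mw$u_statistic, 0)
      expect_lte(mw$u_statistic, mw$n_a * mw$n_b)
      expect_equal(mw$mean_rank_a * mw$n_a + mw$mean_rank_b * mw$n_b,
                   n * (n + 1) / 2)
    }
  })
})

test_that("rate and median/IQR follow the documented conventions", {
  expect_equal(rate(3, 139), 3 / 139)
  expect_equal(round(100 * rate(3, 139)), 2)
  expect_equal(rate(0, 100), 0)
  expect_equal(rate(17, 50), 0.34)
  expect_error(rate(1, 0), "positive")

  expect_equal(median_iqr(1:5), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  withr::with_seed(3, {
    x <- rnorm(31)
    expect_equal(median_iqr(x), median_iqr(sample(x)))
  })
})
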