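test_that("Cohen's kappa matches hand computation and chance behaviour", {
  # p_o = p_e = 0.5 -> kappa = 0
  k <- cohen_kappa(c("W", "W", "N2", "N2"), c("W", "N2", "W", "N2"))
  expect_equal(k$p_o, 0.5)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$estimate, 0)

  # perfect agreement
  h <- random_hypnogram(500, seed = 20)
  expect_equal(cohen_kappa(h, h)$estimate, 1)

  # independent uniform labels: near zero at n = 10,000
  set.seed(21)
  a <- sample(c("W", "N1", "N2", "N3", "REM"), 10000, replace = TRUE)
  b <- sample(c("W", "N1", "N2", "N3", "REM"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$estimate), 0.05)

  # both raters constant and equal: undefined
  expect_true(is.na(cohen_kappa(rep("N2", 10), rep("N2", 10))$estimate))

  # missing epochs dropped pairwise, recorded in n
  a2 <- c("W", NA, "N2", "N3"); b2 <- c("W", "N1", NA, "N3")
  expect_equal(cohen_kappa(a2, b2)$n, 2L)
})

test_that("kappa is invariant under consistent stage relabeling", {
  set.seed(22)
  stages <- c("W", "N1", "N2", "N3", "REM")
  a <- sample(stages, 400, replace = TRUE, prob = c(0.1, 0.1, 0.4, 0.2, 0.2))
  b <- ifelse(runif(400) < 0.7, a, sample(stages, 400, replace = TRUE))
  k1 <- cohen_kappa(a, b)$estimate
  perm <- setNames(c("N3", "REM", "W", "N1", "N2"), stages)
  k2 <- cohen_kappa(unname(perm[a]), unname(perm[b]))$estimate
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("kappa confusion matrix is oriented rows = a, columns = b", {
  k <- cohen_kappa(c("W", "W", "N2"), c("N2", "W", "N2"))
  expect_equal(unname(k$confusion["W", "N2"]), 1)
  expect_equal(unname(k$confusion["W", "W"]), 1)
  expect_equal(unname(k$confusion["N2", "N2"]), 1)
  expect_equal(unname(rowSums(k$confusion_row_norm)[c("W", "N2")]),
               c(1, 1))
})

test_that("ICC(3,1) matches its defining formula and known structure", {
  set.seed(23)
  for (i in 1:20) {
    m <- matrix(rnorm(30), ncol = 3) + rnorm(10)
    expect_equal(icc_consistency(m)$estimate, icc31_bruteforce(m),
                 tolerance = 1e-10)
  }
  # identical columns, and columns differing by a constant -> ICC = 1
  a <- rnorm(10)
  expect_equal(icc_consistency(cbind(a, a))$estimate, 1)
  expect_equal(icc_consistency(cbind(a, a + 5))$estimate, 1)
  # rater-specific constants never change the consistency ICC
  m <- matrix(rnorm(24), ncol = 2)
  expect_equal(icc_consistency(m)$estimate,
               icc_consistency(m + rep(c(0, 7), each = 12))$estimate,
               tolerance = 1e-9)
  expect_error(icc_consistency(matrix(1:4, 2)), "3 subjects")
})

test_that("interpretation bands follow the conventional cutpoints", {
  expect_equal(interpret_icc(0.49), "poor")
  expect_equal(interpret_icc(0.5), "moderate")
  expect_equal(interpret_icc(0.75), "good")
  expect_equal(interpret_icc(0.89), "good")
  expect_equal(interpret_icc(0.9), "excellent")
  expect_equal(interpret_icc(0.95), "excellent")
  expect_error(interpret_icc(1.2), "exceed")
})

test_that("Mann-Whitney U handles ties, separation and exact enumeration", {
  # identical multisets: U = n^2/2 under tie handling, p near 1
  x <- c(1, 2, 3, 4)
  mw <- mann_whitney_u(x, x)
  expect_equal(mw$U, 8)
  expect_gt(mw$p, 0.9)
  # full separation
  expect_equal(mann_whitney_u(1:5, 6:10)$U, 0)

  # exact p equals exhaustive enumeration over all C(10,5) labelings
  set.seed(24)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5, mean = runif(1, -1, 1))
    mw <- mann_whitney_u(y, x)
    expect_equal(mw$p, mw_enumeration_p(y, x), tolerance = 1e-12)
  }
})

test_that("pooled t-test matches the closed form", {
  tt <- independent_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -sqrt(1.5), tolerance = 1e-4)
  expect_equal(tt$df, 4)
  # t = 0 for identical samples; scale invariance
  expect_equal(independent_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  set.seed(25)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(independent_t(3 * x, 3 * y)$t, independent_t(x, y)$t,
               tolerance = 1e-12)
})

test_that("repeated-measures ANOVA agrees with the sums-of-squares oracle", {
  set.seed(26)
  for (i in 1:100) {
    m <- matrix(rnorm(5 * 3), ncol = 3) + rnorm(5)
    res <- rm_anova(m)
    expect_equal(res$F, rm_anova_bruteforce(m), tolerance = 1e-10)
    expect_equal(res$df1, 2)
    expect_equal(res$df2, 8)
  }
  # per-subject constants leave F unchanged
  m <- matrix(rnorm(12), ncol = 3)
  expect_equal(rm_anova(m)$F, rm_anova(m + (1:4) * 10)$F, tolerance = 1e-9)
  # all conditions identical within subject -> F = 0
  m0 <- matrix(rep(rnorm(4), 3), ncol = 3)
  expect_equal(rm_anova(m0)$F, 0)
})
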