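test_that("Spearman rho and p follow the rank/t-approximation contract", {
  r <- spearman_test(1:4, 1:4)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 0)
  r2 <- spearman_test(1:4, 4:1)
  expect_equal(r2$rho, -1)
  expect_equal(r2$p, 0)
  # rho by 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  r3 <- spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$rho, 0.6, tolerance = 1e-12)
  # n = 3 is below the minimum for a meaningful test
  expect_false(spearman_test(1:3, 1:3)$computable)
  expect_false(spearman_test(1:5, rep(2, 5))$computable)
})

test_that("analytic Spearman p approximates the exact permutation p at tiny n", {
  # the worked n = 4 case: t-approximation p vs exact 10/24
  expect_lt(abs(spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))$p -
                  perm_spearman_p(c(1, 2, 3, 4), c(2, 1, 4, 3))), 0.02)
  # from n = 6 the t approximation is within 0.05 of the permutation null
  # everywhere (worst case 0.048 at n = 6, 0.027 at n = 7, by enumeration)
  set.seed(71)
  for (n in 6:7) {
    for (rep in 1:5) {
      x <- rnorm(n)
      y <- rnorm(n) + 0.6 * x
      r <- spearman_test(x, y)
      expect_lt(abs(r$p - perm_spearman_p(x, y)), 0.05)
    }
  }
})

test_that("Spearman test agrees with cor.test and is antisymmetric in y", {
  set.seed(72)
  for (rep in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15) + 0.3 * x
    if (rep %% 2 == 0) y <- round(y)  # induce ties
    r <- spearman_test(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p, ct$p.value, tolerance = 1e-12)
    rneg <- spearman_test(x, -y)
    expect_equal(rneg$rho, -r$rho, tolerance = 1e-12)
  }
  # incomplete pairs are dropped pairwise
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 1, 3, NA, 6, 5)
  expect_equal(spearman_test(x, y)$n, 4)
})

test_that("Mann-Whitney U and p follow the rank-sum contract", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2/20 assignments as extreme
  # identical multisets: U = n_a * n_b / 2 by symmetry
  a <- c(1, 2, 2, 5)
  expect_equal(mann_whitney_test(a, a)$U, 8)
  expect_false(mann_whitney_test(numeric(0), 1:3)$computable)
  expect_false(mann_whitney_test(rep(1, 3), rep(1, 4))$computable)
})

test_that("U_a + U_b = n_a * n_b and the approximation tracks enumeration", {
  set.seed(73)
  # tie-free continuous groups: approximation within 0.02 of enumeration
  # (the tie-free worst case over all U at sizes 5/6 is 0.0173)
  for (rep in 1:10) {
    a <- rnorm(5)
    b <- rnorm(6)
    ra <- mann_whitney_test(a, b)
    rb <- mann_whitney_test(b, a)
    expect_equal(ra$U + rb$U, length(a) * length(b))
    expect_lt(abs(ra$p - enum_mwu_p(a, b)), 0.02)
    expect_equal(enum_mwu_p(a, b), mann_whitney_test(a, b, exact = TRUE)$p,
                 tolerance = 1e-12)
  }
  # heavily tied integer groups: the tie-corrected approximation still
  # tracks enumeration (more coarsely) and matches wilcox.test exactly
  for (rep in 1:10) {
    a <- sample(0:8, 5, TRUE)
    b <- sample(0:8, 6, TRUE)
    ra <- mann_whitney_test(a, b)
    rb <- mann_whitney_test(b, a)
    expect_equal(ra$U + rb$U, length(a) * length(b))
    expect_lt(abs(ra$p - enum_mwu_p(a, b)), 0.05)
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(ra$U, unname(w$statistic))
    expect_equal(ra$p, w$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_test(1:7, 1:7, exact = TRUE), "<= 12")
})

test_that("BH plain dialect reproduces the published corrected values", {
  ref <- published_screen_pvalues()
  q <- bh_adjust(ref$p, m = 25, mode = "plain")
  # smallest p 0.00032 at rank 1 of 25 -> 0.0080
  expect_equal(q[ref$variable == "any_suppressor"], 0.0080,
               tolerance = 1e-12)
  # second smallest 0.001 at rank 2 -> 0.0125 (printed as 0.013)
  expect_equal(q[ref$variable == "hcq_use"], 0.0125, tolerance = 1e-12)
  expect_true(is.na(q[ref$variable == "mtx_use"]))
})

test_that("BH modes obey their definitions and relate by suffix minimization", {
  expect_equal(bh_adjust(0.04, m = 1, mode = "plain"), 0.04)
  expect_equal(bh_adjust(0.04, m = 1, mode = "monotone"), 0.04)
  expect_error(bh_adjust(c(0.1, 0.2, 0.3), m = 2), "configuration error")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(74)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding makes ties
    m <- n + sample(0:3, 1)
    plain <- bh_adjust(p, m = m, mode = "plain")
    mono <- bh_adjust(p, m = m, mode = "monotone")
    # definitional step-up oracle on sorted positions:
    # q_(i) = min(1, min_{j >= i} p_(j) * m / j)
    o <- order(p)
    ps <- p[o]
    qs <- vapply(seq_len(n), function(i) {
      min(1, min(ps[i:n] * m / (i:n)))
    }, numeric(1))
    oracle <- numeric(n)
    oracle[o] <- qs
    expect_equal(mono, oracle, tolerance = 1e-12)
    expect_true(all(mono <= plain + 1e-12))
    # plain mode never adjusts below the raw p when ranks <= m
    expect_true(all(plain >= p - 1e-12))
  }
})
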