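test_that("split_half produces disjoint complementary halves of floor/ceil size", {
  set.seed(30)
  sp <- split_half(182)
  expect_length(sp$set1, 91)
  expect_length(sp$set2, 91)
  expect_length(intersect(sp$set1, sp$set2), 0)
  expect_setequal(c(sp$set1, sp$set2), 1:182)
  sp9 <- split_half(9)
  expect_length(sp9$set1, 4)
  expect_length(sp9$set2, 5)
  expect_error(split_half(5), "refusing")
})

test_that("split_half samples bipartitions uniformly", {
  # n = 6 (guard lowered): 10 unordered {3,3} bipartitions, keyed by the
  # half containing index 1
  set.seed(31)
  n_draws <- 10000
  keys <- replicate(n_draws, {
    sp <- split_half(6, min_n = 2)
    half <- if (1 %in% sp$set1) sp$set1 else sp$set2
    paste(half, collapse = "-")
  })
  freq <- table(keys)
  expect_length(freq, 10)
  se <- sqrt(0.1 * 0.9 / n_draws)
  expect_true(all(abs(freq / n_draws - 0.1) < 3 * se))
})

test_that("stability screen counts are reproducible and partition n_iter", {
  fx <- null_cohort_fixture(n = 60, seed = 33)
  st1 <- stability_screen(fx$scores, fx$cohort, fx$spec,
                          n_iter = 40, seed = 9)
  st2 <- stability_screen(fx$scores, fx$cohort, fx$spec,
                          n_iter = 40, seed = 9)
  expect_identical(st1, st2)
  expect_equal(st1$count_both + st1$count_one + st1$count_neither,
               rep(40L, 4), ignore_attr = TRUE)
  expect_true(all(st1$median_p_set1 >= 0 & st1$median_p_set1 <= 1))

  st3 <- stability_screen(fx$scores, fx$cohort, fx$spec,
                          n_iter = 40, seed = 10)
  expect_false(identical(st1$count_both, st3$count_both) &&
                 identical(st1$median_p_set1, st3$median_p_set1))

  # n_iter = 1: a one-hot triple per variable
  st4 <- stability_screen(fx$scores, fx$cohort, fx$spec,
                          n_iter = 1, seed = 11)
  expect_true(all(st4$count_both + st4$count_one + st4$count_neither == 1))
})

test_that("a constant score makes every half-set test not computable", {
  fx <- null_cohort_fixture(n = 30, seed = 34)
  const <- structure(setNames(rep(1.3, 30), names(fx$scores)),
                     class = "ifn_score")
  expect_message(
    st <- stability_screen(const, fx$cohort, fx$spec, n_iter = 12,
                           seed = 2),
    "not computable")
  expect_equal(st$count_neither, rep(12L, 4), ignore_attr = TRUE)
  expect_equal(st$n_not_computable, rep(24L, 4), ignore_attr = TRUE)
})

test_that("stability screen matches an independent plain-loop reimplementation", {
  fx <- null_cohort_fixture(n = 62, seed = 35)
  n_iter <- 100
  alpha <- 0.05
  seed <- 77
  st <- stability_screen(fx$scores, fx$cohort, fx$spec,
                         n_iter = n_iter, alpha = alpha, seed = seed)

  # independent loop: same seed policy (one stream, one sample.int(n) per
  # iteration, first floor(n/2) indices = set 1), tests via stats::
  dat <- as.data.frame(fx$cohort)
  s <- as.numeric(fx$scores[dat$patient_id])
  n <- nrow(dat)
  k <- n %/% 2
  pmat <- array(NA_real_, c(n_iter, 4, 2))
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    perm <- sample.int(n)
    halves <- list(sort(perm[1:k]), sort(perm[(k + 1):n]))
    for (j in 1:4) {
      v <- dat[[fx$spec$variable[j]]]
      for (h in 1:2) {
        idx <- halves[[h]]
        pmat[i, j, h] <- if (fx$spec$test[j] == "spearman") {
          suppressWarnings(cor.test(v[idx], s[idx], method = "spearman",
                                    exact = FALSE)$p.value)
        } else {
          suppressWarnings(wilcox.test(s[idx][v[idx] == 1],
                                       s[idx][v[idx] == 0],
                                       exact = FALSE)$p.value)
        }
      }
    }
  }
  sig <- pmat < alpha
  expect_equal(st$count_both, colSums(sig[, , 1] & sig[, , 2]),
               ignore_attr = TRUE)
  expect_equal(st$count_one, colSums(xor(sig[, , 1], sig[, , 2])),
               ignore_attr = TRUE)
  expect_equal(st$median_p_set1, apply(pmat[, , 1], 2, median),
               tolerance = 1e-12)
  expect_equal(st$median_p_set2, apply(pmat[, , 2], 2, median),
               tolerance = 1e-12)
})

test_that("summarize_stability is a pure field-by-field mapping", {
  expect_equal(nrow(summarize_stability(NULL)), 0)
  fake <- data.frame(variable = c("v1", "v2"), test = "spearman",
                     count_both = c(521L, 3L), count_one = c(479L, 99L),
                     count_neither = c(0L, 898L),
                     median_p_set1 = c(0.015, 0.66),
                     median_p_set2 = c(0.015, 0.65),
                     median_statistic = c(-0.18, 0.01),
                     n_not_computable = c(0L, 0L))
  out <- summarize_stability(fake)
  expect_equal(out$variable, fake$variable)
  expect_equal(out$both, fake$count_both)
  expect_equal(out$one, fake$count_one)
  expect_equal(out$neither, fake$count_neither)
  expect_equal(out$median_p_set1, fake$median_p_set1)
  expect_equal(out$median_statistic, fake$median_statistic)
})
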