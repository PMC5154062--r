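test_that("full-cohort screen composes the single-test operations", {
  fx <- null_cohort_fixture(n = 80, seed = 17)
  res <- screen_cohort(fx$scores, fx$cohort, fx$spec)
  expect_equal(res$variable, fx$spec$variable)
  s <- as.numeric(fx$scores)
  dat <- as.data.frame(fx$cohort)
  # per-variable recomputation via the single-test operations
  r1 <- spearman_test(dat$cont_a, s)
  expect_equal(res$statistic[1], r1$rho)
  expect_equal(res$p[1], r1$p)
  r3 <- mann_whitney_test(s[dat$bin_a == 1], s[dat$bin_a == 0])
  expect_equal(res$statistic[3], r3$U)
  expect_equal(res$p[3], r3$p)
  # BH applied across the whole spec with default m = 4
  expect_equal(res$q, bh_adjust(res$p, m = 4, mode = "monotone"))
})

test_that("screen handles perfect association, missingness and the m contract", {
  fx <- null_cohort_fixture(n = 40, seed = 18)
  cohort <- fx$cohort
  cohort$self <- as.numeric(fx$scores[cohort$patient_id])
  cohort$dead <- NA_real_
  attr(cohort, "types") <- c(attr(fx$cohort, "types"),
                             self = "continuous", dead = "continuous")
  spec <- rbind(fx$spec,
                data.frame(variable = c("self", "dead"),
                           test = "spearman"))
  res <- screen_cohort(fx$scores, cohort, spec, m = 25)
  expect_equal(res$statistic[res$variable == "self"], 1)
  expect_equal(res$p[res$variable == "self"], 0)
  expect_false(res$computable[res$variable == "dead"])
  expect_true(is.na(res$q[res$variable == "dead"]))
  # BH used m = 25 despite only 5 computable p values
  expect_equal(res$q, bh_adjust(res$p, m = 25, mode = "monotone"))
  expect_error(screen_cohort(fx$scores, fx$cohort,
                             data.frame(variable = "ghost",
                                        test = "spearman")),
               "ghost")
})

test_that("screen p values are invariant to patient row order", {
  fx <- null_cohort_fixture(n = 50, seed = 19)
  res1 <- screen_cohort(fx$scores, fx$cohort, fx$spec)
  set.seed(20)
  shuffled <- fx$cohort[sample(nrow(fx$cohort)), ]
  res2 <- screen_cohort(fx$scores, shuffled, fx$spec)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-12)
})

test_that("subgroup filter retains exactly the fully untreated patients", {
  cfg <- synthetic_cohort_config(seed = 23)
  cohort <- generate_clinical(cfg)
  sub <- subgroup_filter(cohort)
  flags <- as.data.frame(cohort)[, c("predn_use", "hcq_use", "ssz_use")]
  keep_oracle <- !apply(is.na(flags), 1, any) & rowSums(flags) == 0
  expect_equal(nrow(sub), sum(keep_oracle))
  expect_setequal(sub$patient_id, cohort$patient_id[keep_oracle])

  # identity when everyone is untreated; empty (with warning) when all treated
  all0 <- cohort
  all0$predn_use <- all0$hcq_use <- all0$ssz_use <- 0
  expect_equal(nrow(subgroup_filter(all0)), nrow(cohort))
  all1 <- cohort
  all1$predn_use <- 1
  expect_warning(empty <- subgroup_filter(all1, "predn_use"), "no patients")
  expect_equal(nrow(empty), 0)

  # patients with unknown treatment status cannot be classified
  miss <- cohort
  miss$hcq_use[1:4] <- NA
  expect_message(submiss <- subgroup_filter(miss), "4 patient")
  expect_false(any(miss$patient_id[1:4] %in% submiss$patient_id))
})

test_that("group comparison stratifies by agent count and tests pairs", {
  syn <- generate_cohort(synthetic_cohort_config(seed = 24))
  scores <- compute_ifn_score(syn$expr)
  gc <- group_compare(scores, syn$cohort)
  flags <- as.data.frame(syn$cohort)[, c("predn_use", "hcq_use", "ssz_use")]
  counts <- rowSums(flags)
  expect_equal(gc$strata$n,
               c(sum(counts == 0), sum(counts == 1), sum(counts >= 2)))
  expect_equal(gc$strata$median[1],
               median(as.numeric(scores)[counts == 0]))
  expect_equal(nrow(gc$tests), 3)

  # all untreated: single occupied stratum, comparisons not computable
  all0 <- syn$cohort
  all0$predn_use <- all0$hcq_use <- all0$ssz_use <- 0
  gc0 <- group_compare(scores, all0)
  expect_equal(gc0$strata$n, c(nrow(all0), 0, 0))
  expect_false(any(gc0$tests$computable))
})

test_that("derived variables are recomputed from parents", {
  df <- data.frame(patient_id = c("a", "b", "c", "d"),
                   esr = c(10, 25, NA, 20),
                   crp = c(5, 10, 12, NA),
                   acpa_titer = c(100, 2000, NA, 1049),
                   rf_pos = c(1, 0, 1, NA),
                   acpa_pos = c(1, 1, 0, 0),
                   predn_use = c(0, 1, 0, 0),
                   hcq_use = c(0, 0, 1, 0),
                   ssz_use = c(0, 0, 0, 0))
  cohort <- add_derived_variables(
    clinical_cohort(df, c(esr = "continuous", crp = "continuous",
                          acpa_titer = "continuous", rf_pos = "dichotomous",
                          acpa_pos = "dichotomous",
                          predn_use = "dichotomous", hcq_use = "dichotomous",
                          ssz_use = "dichotomous")),
    acpa_cutoff = 350)
  expect_equal(cohort$esr_gt20, c(0, 1, NA, 0))   # strict >
  expect_equal(cohort$crp_ge10, c(0, 1, 1, NA))   # >=
  expect_equal(cohort$acpa_high, c(0, 1, NA, 0))  # >= 3 * 350 = 1050
  expect_equal(cohort$rf_acpa_pos, c(1, 0, 0, NA))
  expect_equal(cohort$rf_acpa_neg, c(0, 0, 0, NA))
  expect_equal(cohort$any_suppressor, c(0, 1, 1, 0))
  expect_identical(unname(variable_types(cohort)[["any_suppressor"]]),
                   "dichotomous")
})
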