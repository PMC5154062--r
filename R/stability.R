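#' Draw one random bipartition of a cohort into equal halves
#'
#' Splits indices `1..n` uniformly at random into two disjoint sets of sizes
#' `floor(n/2)` and `ceiling(n/2)`. Consumes the current RNG stream (set a
#' seed upstream for reproducibility); [stability_screen()] draws one such
#' bipartition per iteration, shared across all variables.
#'
#' @param n cohort size; splits of fewer than `min_n` patients are refused
#'   because half-set tests are not meaningful (default 8).
#' @param min_n guard threshold; lower only for simulation studies of the
#'   splitter itself.
#' @return list with integer index vectors `set1` (size floor(n/2)) and
#'   `set2` (size ceiling(n/2)).
#' @export
split_half <- function(n, min_n = 8) {
  if (n < min_n) {
    stop("refusing to split n = ", n, " patients (< ", min_n,
         "); half-set tests would not be meaningful")
  }
  perm <- sample.int(n)
  k <- n %/% 2
  list(set1 = sort(perm[seq_len(k)]), set2 = sort(perm[(k + 1):n]))
}

#' Split-half stability screen
#'
#' The internal cross-validation of the association screen: the cohort is
#' randomized `n_iter` times into two equally sized sets and each variable's
#' test is run on both halves of every bipartition. For each variable the
#' procedure tabulates in how many iterations the test reached `p < alpha`
#' in both sets, exactly one set, or neither set, along with the median p
#' value per set and (for continuous variables) the median Spearman rho
#' pooled over all `2 * n_iter` half-set fits. Associations that replicate
#' across random halves are considered stable; a single lucky full-cohort
#' p value is not.
#'
#' A half in which a test is not computable (for example an empty treatment
#' group in that half) counts as not-significant for that set; such
#' occurrences are tallied in the `n_not_computable` column.
#'
#' @param scores an `ifn_score` vector (named by patient id).
#' @param cohort a `clinical_cohort`.
#' @param variable_spec data frame with `variable` and `test` columns;
#'   default [default_variable_spec()].
#' @param n_iter number of random bipartitions, default 1000.
#' @param alpha per-test significance level, default 0.05.
#' @param seed integer seed; one root seed drives the whole run, iteration
#'   i's bipartition being the i-th draw of the stream, so identical inputs
#'   give byte-identical results.
#' @return data frame of class `stability_result`, one row per variable:
#'   `variable`, `test`, `count_both`, `count_one`, `count_neither`
#'   (summing to `n_iter`), `median_p_set1`, `median_p_set2`,
#'   `median_statistic`, `n_not_computable`. Attributes record `n_iter`,
#'   `alpha` and `seed`.
#' @export
stability_screen <- function(scores, cohort,
                             variable_spec = default_variable_spec(),
                             n_iter = 1000, alpha = 0.05, seed = 1) {
  stopifnot(n_iter >= 1, alpha > 0, alpha < 1)
  dat <- .align_scores(scores, cohort)
  n <- nrow(dat)
  nv <- nrow(variable_spec)
  missing_vars <- setdiff(variable_spec$variable, names(dat))
  if (length(missing_vars)) {
    stop("configuration error: variable(s) not found in cohort: ",
         paste(missing_vars, collapse = ", "))
  }
  score <- dat$.score
  vals <- lapply(variable_spec$variable, function(v) as.numeric(dat[[v]]))
  is_sp <- variable_spec$test == "spearman"
  bad_test <- variable_spec$test[!variable_spec$test %in%
                                   c("spearman", "mann_whitney")]
  if (length(bad_test)) stop("unknown test '", bad_test[1], "'")

  p1 <- matrix(NA_real_, n_iter, nv)
  p2 <- matrix(NA_real_, n_iter, nv)
  stat_pool <- matrix(NA_real_, 2 * n_iter, nv)

  half_p <- function(idx, j) {
    s <- score[idx]; v <- vals[[j]][idx]
    if (is_sp[j]) {
      r <- spearman_test(v, s)
      c(r$p, r$rho)
    } else {
      ok <- is.finite(v) & is.finite(s)
      r <- mann_whitney_test(s[ok & v == 1], s[ok & v == 0])
      c(r$p, NA_real_)
    }
  }

  set.seed(seed)
  for (i in seq_len(n_iter)) {
    sp <- split_half(n)
    for (j in seq_len(nv)) {
      r1 <- half_p(sp$set1, j)
      r2 <- half_p(sp$set2, j)
      p1[i, j] <- r1[1]
      p2[i, j] <- r2[1]
      stat_pool[2 * i - 1, j] <- r1[2]
      stat_pool[2 * i, j] <- r2[2]
    }
  }

  sig1 <- !is.na(p1) & p1 < alpha
  sig2 <- !is.na(p2) & p2 < alpha
  res <- data.frame(
    variable = variable_spec$variable,
    test = variable_spec$test,
    count_both = colSums(sig1 & sig2),
    count_one = colSums(xor(sig1, sig2)),
    count_neither = colSums(!sig1 & !sig2),
    median_p_set1 = apply(p1, 2, stats::median, na.rm = TRUE),
    median_p_set2 = apply(p2, 2, stats::median, na.rm = TRUE),
    median_statistic = ifelse(
      is_sp, apply(stat_pool, 2, stats::median, na.rm = TRUE), NA_real_),
    n_not_computable = colSums(is.na(p1)) + colSums(is.na(p2)),
    stringsAsFactors = FALSE
  )
  if (any(res$n_not_computable > 0)) {
    message("some half-set tests were not computable (counted ",
            "not-significant): ",
            paste0(res$variable[res$n_not_computable > 0], " (",
                   res$n_not_computable[res$n_not_computable > 0], ")",
                   collapse = ", "))
  }
  attr(res, "n_iter") <- n_iter
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  class(res) <- c("stability_result", "data.frame")
  res
}

#' Tabulate stability results
#'
#' Formats a list of stability results into report rows, in input order,
#' without recomputation: variable, both/one/neither counts and per-set
#' median p values (plus the pooled median statistic for continuous
#' variables).
#'
#' @param results a `stability_result` data frame (or anything coercible
#'   with the same columns).
#' @return data frame with columns `variable`, `both`, `one`, `neither`,
#'   `median_p_set1`, `median_p_set2`, `median_statistic`.
#' @export
summarize_stability <- function(results) {
  cols <- c("variable", "count_both", "count_one", "count_neither",
            "median_p_set1", "median_p_set2", "median_statistic")
  if (NROW(results) == 0) {
    out <- data.frame(variable = character(), both = integer(),
                      one = integer(), neither = integer(),
                      median_p_set1 = numeric(), median_p_set2 = numeric(),
                      median_statistic = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  df <- as.data.frame(results)[, cols]
  names(df) <- c("variable", "both", "one", "neither",
                 "median_p_set1", "median_p_set2", "median_statistic")
  rownames(df) <- NULL
  df
}
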