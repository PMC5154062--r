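#' Screen the IFN score against clinical variables in the full cohort
#'
#' Runs one association test per variable in the specification: Spearman
#' correlation of score vs. variable for continuous variables, Mann-Whitney U
#' comparing scores between the two levels for dichotomous variables
#' (U reported for the `1` group). Each test uses pairwise-complete cases;
#' patients missing a variable drop out of that test only. Benjamini-Hochberg
#' correction is applied across the whole specification, with
#' `m = nrow(variable_spec)` by default so that variables whose test is not
#' computable still count toward the correction.
#'
#' @param scores an `ifn_score` vector (named by patient id).
#' @param cohort a `clinical_cohort`; its `patient_id`s must overlap the
#'   score names. Patients present in only one of the two are dropped.
#' @param variable_spec data frame with columns `variable`, `test`
#'   (`"spearman"` / `"mann_whitney"`), in reporting order; defaults to
#'   [default_variable_spec()] restricted is NOT applied — every listed
#'   variable must exist in the cohort.
#' @param bh BH dialect passed to [bh_adjust()]: `"monotone"` (default) or
#'   `"plain"` (the replication dialect).
#' @param m total number of tests for the BH correction; default the number
#'   of rows of `variable_spec`.
#' @return data frame of class `association_result`, one row per variable,
#'   with columns `variable`, `test`, `n_used`, `statistic` (rho or U), `p`,
#'   `q`, `computable`.
#' @export
screen_cohort <- function(scores, cohort,
                          variable_spec = default_variable_spec(),
                          bh = c("monotone", "plain"), m = NULL) {
  bh <- match.arg(bh)
  stopifnot(nrow(variable_spec) > 0)
  if (is.null(m)) m <- nrow(variable_spec)
  dat <- .align_scores(scores, cohort)
  types <- variable_types(cohort)
  rows <- lapply(seq_len(nrow(variable_spec)), function(i) {
    v <- variable_spec$variable[i]
    test <- variable_spec$test[i]
    if (!v %in% names(dat)) {
      stop("configuration error: variable '", v, "' not found in cohort")
    }
    .test_one(dat$.score, dat[[v]], test, v, types[[v]])
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p, m = m, mode = bh)
  attr(res, "bh") <- list(mode = bh, m = m)
  class(res) <- c("association_result", "data.frame")
  res
}

.test_one <- function(score, values, test, variable, declared_type = NULL) {
  if (test == "spearman") {
    if (!is.null(declared_type) && declared_type != "continuous") {
      warning("Spearman requested for non-continuous variable '", variable,
              "'")
    }
    r <- spearman_test(values, score)
    data.frame(variable = variable, test = "spearman", n_used = r$n,
               statistic = r$rho, p = r$p, computable = r$computable,
               stringsAsFactors = FALSE)
  } else if (test == "mann_whitney") {
    if (!is.null(declared_type) && declared_type != "dichotomous") {
      warning("Mann-Whitney requested for non-dichotomous variable '",
              variable, "'")
    }
    ok <- is.finite(values) & is.finite(score)
    r <- mann_whitney_test(score[ok & values == 1], score[ok & values == 0])
    data.frame(variable = variable, test = "mann_whitney",
               n_used = r$n_a + r$n_b, statistic = r$U, p = r$p,
               computable = r$computable, stringsAsFactors = FALSE)
  } else {
    stop("unknown test '", test, "' for variable '", variable, "'")
  }
}

.align_scores <- function(scores, cohort) {
  ids <- intersect(cohort$patient_id, names(scores))
  if (length(ids) == 0) stop("no overlap between score and cohort patient ids")
  dat <- as.data.frame(cohort)[match(ids, cohort$patient_id), , drop = FALSE]
  dat$.score <- as.numeric(scores[ids])
  dat
}

#' Restrict a cohort to patients on none of the listed treatments
#'
#' Retains patients whose value is 0 for every listed (dichotomous) treatment
#' variable. Patients with a missing value in any listed variable cannot be
#' classified and are excluded, with a message giving the count. Used for
#' the untreated-subgroup reanalysis, which removes the masking effect of
#' score-suppressing agents.
#'
#' @param cohort a `clinical_cohort`.
#' @param exclude_if_any character vector of dichotomous treatment variables;
#'   default the three score-suppressing agents.
#' @return the filtered `clinical_cohort` (possibly empty, with a warning).
#' @export
subgroup_filter <- function(cohort,
                            exclude_if_any = c("predn_use", "hcq_use",
                                               "ssz_use")) {
  types <- variable_types(cohort)
  for (v in exclude_if_any) {
    if (!v %in% names(cohort)) stop("variable '", v, "' not in cohort")
    if (!identical(types[[v]], "dichotomous")) {
      stop("subgroup filter variable '", v, "' must be dichotomous")
    }
  }
  flags <- as.matrix(as.data.frame(cohort)[, exclude_if_any, drop = FALSE])
  unclassifiable <- apply(flags, 1, anyNA)
  keep <- !unclassifiable & rowSums(flags) == 0
  if (any(unclassifiable)) {
    message(sum(unclassifiable),
            " patient(s) excluded for missing treatment status")
  }
  if (!any(keep)) warning("subgroup filter retained no patients")
  cohort[keep, , drop = FALSE]
}

#' Compare IFN scores across strata of treatment burden
#'
#' Stratifies patients by how many of the listed agents they take (0, 1, or
#' 2 or more), summarizes the score per stratum and runs Mann-Whitney tests
#' between every pair of strata. Patients missing any agent flag are
#' excluded from stratification.
#'
#' @param scores an `ifn_score` vector.
#' @param cohort a `clinical_cohort`.
#' @param agents dichotomous treatment variables; default the three
#'   score-suppressing agents.
#' @return list of class `group_comparison` with `strata` (data frame:
#'   `stratum`, `n`, `median`, `q1`, `q3`) and `tests` (data frame:
#'   `stratum_a`, `stratum_b`, `U`, `p`, `computable`).
#' @export
group_compare <- function(scores, cohort,
                          agents = c("predn_use", "hcq_use", "ssz_use")) {
  types <- variable_types(cohort)
  for (v in agents) {
    if (!identical(types[[v]], "dichotomous")) {
      stop("agent variable '", v, "' must be dichotomous")
    }
  }
  dat <- .align_scores(scores, cohort)
  flags <- as.matrix(dat[, agents, drop = FALSE])
  n_agents <- rowSums(flags)
  dat <- dat[!is.na(n_agents), , drop = FALSE]
  n_agents <- n_agents[!is.na(n_agents)]
  stratum <- cut(n_agents, breaks = c(-0.5, 0.5, 1.5, Inf),
                 labels = c("0", "1", ">=2"))
  levs <- levels(stratum)
  strata <- do.call(rbind, lapply(levs, function(s) {
    x <- dat$.score[stratum == s]
    data.frame(stratum = s, n = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
               q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(levs, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- dat$.score[stratum == pairs[1, k]]
    b <- dat$.score[stratum == pairs[2, k]]
    r <- mann_whitney_test(a, b)
    data.frame(stratum_a = pairs[1, k], stratum_b = pairs[2, k],
               U = r$U, p = r$p, computable = r$computable,
               stringsAsFactors = FALSE)
  }))
  structure(list(strata = strata, tests = tests), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("IFN score by number of suppressing agents:\n")
  print(x$strata, row.names = FALSE)
  cat("Pairwise Mann-Whitney tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
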