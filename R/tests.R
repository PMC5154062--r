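# Rank-based association tests and Benjamini-Hochberg adjustment.
#
# These are the per-variable primitives the full-cohort screen and the
# split-half stability screen both call; their tie and continuity
# conventions are therefore fixed here, once.

#' Spearman rank correlation with t-approximation p value
#'
#' Computes Spearman's rho on average ranks (ties share their mean rank) over
#' pairwise-complete observations, with a two-sided p value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. A perfect monotone relation (|rho| = 1) gives p = 0.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with `rho`, `p`, `n` (complete pairs used) and `computable`.
#'   The result is flagged not-computable (`rho` and `p` NA) when fewer than
#'   4 complete pairs remain or either vector has zero variance.
#' @examples
#' spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, computable = FALSE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, computable = TRUE)
}

#' Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic for group `a`
#' (`U_a = R_a - n_a (n_a + 1) / 2`, with `R_a` the rank sum of group `a` in
#' the pooled average ranks). The default p value uses the normal
#' approximation with tie correction and a 0.5 continuity correction; with
#' `exact = TRUE` (available for `n_a + n_b <= 12`) the two-sided p value is
#' obtained by exhaustive enumeration of all equally likely group
#' assignments of the pooled values, which is also valid under ties.
#'
#' @param a,b numeric vectors for the two groups; NAs dropped per group.
#' @param exact use exact enumeration (small samples only).
#' @return list with `U` (for group `a`), `p`, `n_a`, `n_b`, `computable`.
#'   Flagged not-computable when either group is empty after NA removal or
#'   all pooled values are tied (no ordering information).
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)  # U = 0, p = 0.1
#' @export
mann_whitney_test <- function(a, b, exact = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) {
    return(list(U = NA_real_, p = NA_real_, n_a = n1, n_b = n2,
                computable = FALSE))
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(list(U = U, p = NA_real_, n_a = n1, n_b = n2, computable = FALSE))
  }
  if (exact) {
    if (n1 + n2 > 12) {
      stop("exact enumeration supported only for n_a + n_b <= 12")
    }
    p <- .mwu_exact_p(pooled, n1, U)
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    mu <- n1 * n2 / 2
    dev <- U - mu
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p, n_a = n1, n_b = n2, computable = TRUE)
}

# Exact two-sided p: enumerate all C(N, n1) assignments of the pooled values
# to group a; p = proportion of assignments whose U deviates from n1*n2/2 at
# least as much as observed (handles ties because ranks are recomputed on the
# fixed pooled multiset).
.mwu_exact_p <- function(pooled, n1, U_obs) {
  N <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (N - n1) / 2
  combos <- utils::combn(N, n1)
  U_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

#' Benjamini-Hochberg adjustment, in two dialects
#'
#' `mode = "monotone"` is the standard step-up procedure
#' (`q_i = min over j with p_j >= p_i of p_j * m / rank_j`, capped at 1),
#' delegated to [stats::p.adjust()]. `mode = "plain"` is the simpler dialect
#' `q_i = min(1, p_i * m / rank_i)` without monotonicity enforcement, with
#' tied p values sharing the smaller rank; some published analyses report
#' this form, and it is the package's replication default (see
#' [screen_cohort()]'s `bh` argument).
#'
#' The total number of tests `m` may exceed the number of supplied p values
#' when some of the m performed tests have no reported p value; those tests
#' still count in the correction.
#'
#' @param p numeric vector of p values in \[0, 1\] (NA allowed, returned NA).
#' @param m total number of tests; default `length(p)`. Must be >= the
#'   number of non-missing p values.
#' @param mode `"monotone"` (default) or `"plain"`.
#' @return numeric vector of adjusted p values, same order as input.
#' @examples
#' bh_adjust(c(0.00032, 0.001, 0.017), m = 25, mode = "plain")
#' @export
bh_adjust <- function(p, m = length(p), mode = c("monotone", "plain")) {
  mode <- match.arg(mode)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  if (m < sum(ok)) {
    stop("configuration error: m (", m, ") smaller than the number of ",
         "p values (", sum(ok), ")")
  }
  q <- rep(NA_real_, length(p))
  if (!any(ok)) return(q)
  if (mode == "monotone") {
    q[ok] <- stats::p.adjust(p[ok], method = "BH", n = m)
  } else {
    r <- rank(p[ok], ties.method = "min")
    q[ok] <- pmin(1, p[ok] * m / r)
  }
  q
}
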