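# Shared fixtures and small independent oracles.

# random expression matrix with named dims
rand_expr <- function(n = 10, g = 4, seed = 1, ref = NA_character_) {
  set.seed(seed)
  m <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("G%02d", seq_len(g))))
  expr_matrix(m, reference_gene = ref)
}

# all permutations of 1..n (tiny n only), one per column
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(k, sub + (sub >= k))
  }))
}

# exact two-sided permutation p value for Spearman's rho
perm_spearman_p <- function(x, y) {
  obs <- abs(cor(rank(x), rank(y)))
  perms <- all_perms(length(y))
  rho_all <- apply(perms, 2, function(idx) cor(rank(x), rank(y[idx])))
  mean(abs(rho_all) >= obs - 1e-12)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
enum_mwu_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  mu <- n1 * length(b) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  U_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# a small typed cohort where score is independent of everything
null_cohort_fixture <- function(n = 60, seed = 5) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cont_a = rnorm(n),
    cont_b = rexp(n),
    bin_a = rbinom(n, 1, 0.4),
    bin_b = rbinom(n, 1, 0.25),
    stringsAsFactors = FALSE
  )
  cohort <- clinical_cohort(df, c(cont_a = "continuous",
                                  cont_b = "continuous",
                                  bin_a = "dichotomous",
                                  bin_b = "dichotomous"))
  scores <- structure(setNames(rnorm(n), df$patient_id), class = "ifn_score")
  list(cohort = cohort, scores = scores,
       spec = data.frame(
         variable = c("cont_a", "cont_b", "bin_a", "bin_b"),
         test = c("spearman", "spearman", "mann_whitney", "mann_whitney"),
         stringsAsFactors = FALSE))
}
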