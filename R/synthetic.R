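#' Configuration for the synthetic RA cohort generator
#'
#' Bundles every distributional parameter of the generator. The defaults
#' emulate an established rheumatoid arthritis cohort of 182 patients with a
#' 19-gene interferon response panel: highly inter-correlated gene
#' expression (common-factor correlation `rho = 0.8`), an IFN score with
#' mean 0.26 and SD 1.01 on the log2 scale, clinical marginals typical of
#' active established RA, and optional treatment-linked suppression of the
#' score that adds up across agents.
#'
#' @param n_patients cohort size (default 182).
#' @param n_genes panel size (default 19).
#' @param rho common-factor inter-gene correlation, in \[0, 1) (default 0.8).
#' @param score_mean,score_sd target mean and SD of the panel-mean score in
#'   the unsuppressed population, log2 units (defaults 0.26 and 1.01).
#' @param suppression_delta named numeric vector of per-agent score shifts in
#'   units of `score_sd`, additive across agents a patient takes; names must
#'   be treatment flag variables. Default all 0 (a null cohort).
#' @param missingness named numeric vector of per-variable missing
#'   probabilities; the special names `rf` and `acpa` apply one shared mask
#'   to titer and positivity of that antibody, mirroring how assay results
#'   go missing jointly. Defaults: nodules 6/182, rf 21/182, acpa 7/182.
#' @param acpa_cutoff ACPA assay positivity cutoff (AU/ml) used for the
#'   derived high-positivity indicator (default 350).
#' @param marginals named list of per-variable marginal specifications; each
#'   entry is a list with `dist` one of `"normal"` (fields `mean`, `sd`,
#'   optional truncation `lower`/`upper`), `"lognormal_moments"` (fields
#'   `mean`, `sd` of the target arithmetic moments) or `"bernoulli"` (field
#'   `prev`), plus optional `dose_of` naming the use flag a dose belongs to
#'   (dose drawn for users, 0 otherwise). Entries given here override the
#'   defaults of [default_marginals()] entry-wise.
#' @param seed integer root seed.
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 182, n_genes = 19,
                                    rho = 0.8,
                                    score_mean = 0.26, score_sd = 1.01,
                                    suppression_delta = c(predn_use = 0,
                                                          hcq_use = 0,
                                                          ssz_use = 0),
                                    missingness = c(nodules = 6 / 182,
                                                    rf = 21 / 182,
                                                    acpa = 7 / 182),
                                    acpa_cutoff = 350,
                                    marginals = list(),
                                    seed = 1) {
  if (rho < 0 || rho >= 1) {
    stop("configuration error: rho must lie in [0, 1)")
  }
  stopifnot(score_sd > 0, n_patients >= 1, n_genes >= 1)
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness probabilities must lie in [0, 1]")
  }
  marg <- utils::modifyList(default_marginals(), marginals)
  for (m in marg) {
    if (m$dist == "bernoulli" && (m$prev < 0 || m$prev > 1)) {
      stop("prevalences must lie in [0, 1]")
    }
    if (m$dist != "bernoulli" && m$sd <= 0) stop("marginal sds must be > 0")
  }
  structure(
    list(n_patients = n_patients, n_genes = n_genes, rho = rho,
         score_mean = score_mean, score_sd = score_sd,
         suppression_delta = suppression_delta, missingness = missingness,
         acpa_cutoff = acpa_cutoff, marginals = marg, seed = seed),
    class = "synthetic_cohort_config"
  )
}

#' Default clinical marginal distributions
#'
#' One entry per generated clinical variable, in draw order. Continuous
#' measurements with mild skew use truncated normals; autoantibody titers,
#' whose SDs far exceed their means, use lognormals matched by arithmetic
#' moments (a normal draw would be mostly negative). Doses are drawn for
#' users of the corresponding drug and are 0 for non-users.
#'
#' @return named list of marginal specifications (see
#'   [synthetic_cohort_config()]).
#' @export
default_marginals <- function() {
  list(
    mtx_use   = list(dist = "bernoulli", prev = 0.84),
    predn_use = list(dist = "bernoulli", prev = 0.29),
    hcq_use   = list(dist = "bernoulli", prev = 0.19),
    ssz_use   = list(dist = "bernoulli", prev = 0.15),
    mtx_dose   = list(dist = "normal", mean = 21.0, sd = 6.3, lower = 0,
                      dose_of = "mtx_use"),
    predn_dose = list(dist = "normal", mean = 7.2, sd = 3.5, lower = 0,
                      dose_of = "predn_use"),
    age = list(dist = "normal", mean = 54.2, sd = 11.8),
    female = list(dist = "bernoulli", prev = 0.75),
    disease_duration = list(dist = "normal", mean = 9.7, sd = 10.3,
                            lower = 0),
    das28 = list(dist = "normal", mean = 5.1, sd = 1.2, lower = 0,
                 upper = 9.4),
    tjc28 = list(dist = "normal", mean = 8, sd = 6, lower = 0, upper = 28),
    sjc28 = list(dist = "normal", mean = 6, sd = 5, lower = 0, upper = 28),
    vas = list(dist = "normal", mean = 50, sd = 25, lower = 0, upper = 100),
    erosions = list(dist = "bernoulli", prev = 0.72),
    nodules = list(dist = "bernoulli", prev = 0.24),
    esr = list(dist = "normal", mean = 24.5, sd = 18.0, lower = 0),
    crp = list(dist = "normal", mean = 17.8, sd = 22.1, lower = 0),
    rf_titer = list(dist = "lognormal_moments", mean = 124.7, sd = 279),
    rf_pos = list(dist = "bernoulli", prev = 0.59),
    acpa_titer = list(dist = "lognormal_moments", mean = 1563, sd = 2680),
    acpa_pos = list(dist = "bernoulli", prev = 0.75)
  )
}

# Truncated-normal draw by inverse-CDF so each variable consumes exactly n
# uniforms regardless of truncation.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

.rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

.draw_marginal <- function(spec, n) {
  switch(spec$dist,
    bernoulli = stats::rbinom(n, 1, spec$prev),
    normal = .rtruncnorm(n, spec$mean, spec$sd,
                         lower = if (is.null(spec$lower)) -Inf else spec$lower,
                         upper = if (is.null(spec$upper)) Inf else spec$upper),
    lognormal_moments = .rlnorm_moments(n, spec$mean, spec$sd),
    stop("unknown marginal distribution '", spec$dist, "'")
  )
}

#' Generate a synthetic clinical cohort table
#'
#' Draws every clinical variable independently from its configured marginal
#' (treatment flags first, so the expression generator can condition on
#' them), applies the configured missingness masks, and recomputes the
#' derived indicator variables from their parents.
#'
#' @param config a `synthetic_cohort_config`.
#' @param seed seed to set before drawing; `NULL` continues the current RNG
#'   stream (used by [generate_cohort()]). Defaults to `config$seed`.
#' @return a `clinical_cohort` with patient ids `P001, P002, ...`.
#' @export
generate_clinical <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  types <- character(0)
  for (v in names(config$marginals)) {
    spec <- config$marginals[[v]]
    x <- .draw_marginal(spec, n)
    if (!is.null(spec$dose_of)) x <- x * df[[spec$dose_of]]
    df[[v]] <- x
    types[[v]] <- if (spec$dist == "bernoulli") "dichotomous" else "continuous"
  }
  # shared mask per antibody: titer and positivity come from the same assay
  miss <- config$missingness
  mask_for <- function(p) stats::runif(n) < p
  for (mv in names(miss)) {
    targets <- switch(mv, rf = c("rf_titer", "rf_pos"),
                      acpa = c("acpa_titer", "acpa_pos"), mv)
    m <- mask_for(miss[[mv]])
    for (tv in targets) if (tv %in% names(df)) df[[tv]][m] <- NA
  }
  cohort <- clinical_cohort(df, types)
  add_derived_variables(cohort, acpa_cutoff = config$acpa_cutoff)
}

#' Generate a correlated expression matrix, optionally treatment-suppressed
#'
#' Common-factor model: gene g of patient j is
#' `x_gj = mu + sigma * (sqrt(rho) * f_j + sqrt(1 - rho) * e_gj)` with `f`
#' and `e` standard normal, so every gene pair shares correlation `rho`.
#' `mu` and `sigma` are set so that the panel-mean score has mean
#' `score_mean` and SD `score_sd`: since the score averages out the
#' idiosyncratic noise over G genes, `sigma = score_sd / sqrt(rho +
#' (1 - rho) / G)`. For each suppressing agent a patient takes,
#' `suppression_delta[agent] * score_sd` is subtracted from every panel
#' gene, shifting the score by the same amount (additive across agents).
#'
#' @param config a `synthetic_cohort_config`.
#' @param treatment_flags data frame or matrix of 0/1 agent flags with one
#'   row per patient and a column per name of `config$suppression_delta`
#'   (row names or a `patient_id` column give sample ids). `NULL` means no
#'   suppression (all deltas effectively 0).
#' @param seed as in [generate_clinical()].
#' @return an `expr_matrix` (`n_patients` x `n_genes`, genes `IRG01, ...`).
#' @export
generate_expression <- function(config, treatment_flags = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  G <- config$n_genes
  rho <- config$rho
  sigma <- config$score_sd / sqrt(rho + (1 - rho) / G)
  mu <- config$score_mean
  f <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * G), n, G)
  x <- mu + sigma * (sqrt(rho) * f + sqrt(1 - rho) * e)
  ids <- sprintf("P%03d", seq_len(n))
  shift <- numeric(n)
  if (!is.null(treatment_flags)) {
    tf <- as.data.frame(treatment_flags)
    if ("patient_id" %in% names(tf)) {
      ids <- as.character(tf$patient_id)
    } else if (!is.null(rownames(treatment_flags))) {
      ids <- rownames(treatment_flags)
    }
    if (nrow(tf) != n) stop("treatment_flags must have one row per patient")
    agents <- names(config$suppression_delta)
    absent <- setdiff(agents, names(tf))
    if (length(absent)) {
      stop("treatment_flags lacks column(s): ", paste(absent, collapse = ", "))
    }
    fl <- as.matrix(tf[, agents, drop = FALSE])
    fl[is.na(fl)] <- 0  # unknown treatment status: no suppression applied
    shift <- as.numeric(fl %*% config$suppression_delta) * config$score_sd
  }
  x <- x - shift
  dimnames(x) <- list(ids, sprintf("IRG%02d", seq_len(G)))
  expr_matrix(x, reference_gene = "GAPDH")
}

#' Generate a full synthetic cohort (expression + clinical + ground truth)
#'
#' Draws the clinical table first (treatment flags included), then the
#' expression matrix conditioned on the treatment flags, from one root seed.
#' The returned ground-truth record carries every injected effect so that
#' recovery can be checked downstream: by construction, no clinical variable
#' except the treatment flags influences expression, so any other
#' association found by the screen is a false positive.
#'
#' @param config a `synthetic_cohort_config`.
#' @return list with `expr` (an `expr_matrix`), `cohort` (a
#'   `clinical_cohort`) and `truth` (list: `suppression_delta` in score-SD
#'   units, `rho`, `score_mean`, `score_sd`, `seed`).
#' @examples
#' cfg <- synthetic_cohort_config(seed = 42)
#' syn <- generate_cohort(cfg)
#' dim(syn$expr)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  cohort <- generate_clinical(config, seed = config$seed)
  flags <- as.data.frame(cohort)[, c("patient_id",
                                     names(config$suppression_delta))]
  expr <- generate_expression(config, treatment_flags = flags, seed = NULL)
  list(expr = expr, cohort = cohort,
       truth = list(suppression_delta = config$suppression_delta,
                    rho = config$rho, score_mean = config$score_mean,
                    score_sd = config$score_sd, seed = config$seed))
}
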