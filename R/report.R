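#' Fuse full-cohort and stability results into one report
#'
#' Left-joins the full-cohort association screen and the split-half
#' stability screen on the variable, preserving the specification order.
#' Pure assembly: no value is recomputed or rounded here; rounding happens
#' only at render time in [format_report()].
#'
#' @param assoc an `association_result` from [screen_cohort()].
#' @param stab a `stability_result` from [stability_screen()] over the same
#'   variable specification (same variables, same order).
#' @return data frame of class `screen_report` with columns `variable`,
#'   `test`, `n_used`, `statistic`, `p`, `q`, `both`, `one`, `neither`,
#'   `median_p_set1`, `median_p_set2`, `median_statistic`, and a
#'   `provenance` attribute (seed, n_iter, alpha, BH mode and m).
#' @export
build_report <- function(assoc, stab) {
  if (!identical(assoc$variable, stab$variable)) {
    off <- union(setdiff(assoc$variable, stab$variable),
                 setdiff(stab$variable, assoc$variable))
    if (length(off) == 0) off <- "(same variables, different order)"
    stop("association and stability results disagree on the variable ",
         "specification: ", paste(off, collapse = ", "))
  }
  st <- summarize_stability(stab)
  out <- data.frame(
    assoc[, c("variable", "test", "n_used", "statistic", "p", "q")],
    st[, c("both", "one", "neither", "median_p_set1", "median_p_set2",
           "median_statistic")],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    seed = attr(stab, "seed"), n_iter = attr(stab, "n_iter"),
    alpha = attr(stab, "alpha"), bh = attr(assoc, "bh"),
    version = as.character(utils::packageVersion("ifnstab")))
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Render a report for humans
#'
#' Rounds numeric columns to `digits` significant figures and substitutes
#' `missing_token` for not-computable cells. Stored report values are never
#' modified; write the JSON sidecar for full precision.
#'
#' @param report a `screen_report`.
#' @param digits significant figures, default 3.
#' @param missing_token string for missing cells, default `""`.
#' @return character data frame ready for printing or TSV export.
#' @export
format_report <- function(report, digits = 3, missing_token = "") {
  out <- as.data.frame(report)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      v <- signif(out[[cn]], digits)
      out[[cn]] <- ifelse(is.na(v), missing_token, format(v, trim = TRUE))
    }
  }
  out
}

#' @export
print.screen_report <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf(
    "IFN score association screen: %d variables; %d iterations, alpha = %g, BH %s (m = %d), seed = %s\n",
    nrow(x), prov$n_iter, prov$alpha, prov$bh$mode, prov$bh$m,
    format(prov$seed)))
  print(format_report(x), row.names = FALSE)
  invisible(x)
}

#' Write a report as TSV plus a full-precision JSON sidecar
#'
#' @param report a `screen_report`.
#' @param path TSV output path; the sidecar is written next to it as
#'   `<path>.json` with unrounded values and the provenance block.
#' @param digits,missing_token rendering options for the TSV (see
#'   [format_report()]).
#' @export
write_report <- function(report, path, digits = 3, missing_token = "NA") {
  utils::write.table(format_report(report, digits, missing_token), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(provenance = attr(report, "provenance"),
         rows = as.data.frame(report)),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full screening pipeline
#'
#' End-to-end driver: IFN score from the expression matrix, inter-gene
#' correlation QC (advisory), full-cohort association screen, split-half
#' stability screen, fused report. Optionally repeats the whole analysis on
#' the subgroup of patients taking none of the score-suppressing agents,
#' which removes their masking effect on other associations.
#'
#' @param expr an `expr_matrix` of log2 relative expression (use
#'   [normalize_and_log()] or [read_expression()] upstream when starting
#'   from Ct values).
#' @param cohort a `clinical_cohort`.
#' @param panel gene panel for the score; default all columns of `expr`.
#' @param variable_spec see [screen_cohort()].
#' @param n_iter,alpha,seed stability-screen settings (defaults 1000, 0.05).
#' @param bh,m BH settings passed to [screen_cohort()].
#' @param subgroup_exclude `NULL` (no subgroup pass) or a character vector
#'   of treatment flags; patients positive for any are excluded in a second
#'   pass whose BH correction uses the same m.
#' @param qc run [correlation_qc()] and attach its summary (default TRUE).
#' @return list with `report` (a `screen_report`), `scores`, `qc`
#'   (or NULL), `group_comparison` (strata of suppressing-agent burden, when
#'   the three agent flags are present), and `subgroup` (second
#'   `screen_report`, or NULL).
#' @export
run_pipeline <- function(expr, cohort, panel = NULL,
                         variable_spec = default_variable_spec(),
                         n_iter = 1000, alpha = 0.05, seed = 1,
                         bh = c("monotone", "plain"), m = NULL,
                         subgroup_exclude = NULL, qc = TRUE) {
  bh <- match.arg(bh)
  scores <- compute_ifn_score(expr, panel = panel)
  qc_res <- if (qc) correlation_qc(expr) else NULL
  assoc <- screen_cohort(scores, cohort, variable_spec, bh = bh, m = m)
  stab <- stability_screen(scores, cohort, variable_spec,
                           n_iter = n_iter, alpha = alpha, seed = seed)
  report <- build_report(assoc, stab)
  agents <- c("predn_use", "hcq_use", "ssz_use")
  gc_res <- if (all(agents %in% names(cohort))) {
    group_compare(scores, cohort, agents)
  }
  sub_report <- NULL
  if (!is.null(subgroup_exclude)) {
    sub_cohort <- subgroup_filter(cohort, subgroup_exclude)
    sub_spec <- variable_spec[!variable_spec$variable %in%
                                c(subgroup_exclude, "any_suppressor",
                                  paste0(sub("_use$", "_dose",
                                             subgroup_exclude))), ,
                              drop = FALSE]
    sub_assoc <- screen_cohort(scores, sub_cohort, sub_spec, bh = bh,
                               m = if (is.null(m)) nrow(sub_spec) else m)
    sub_stab <- stability_screen(scores, sub_cohort, sub_spec,
                                 n_iter = n_iter, alpha = alpha, seed = seed)
    sub_report <- build_report(sub_assoc, sub_stab)
  }
  list(report = report, scores = scores, qc = qc_res,
       group_comparison = gc_res, subgroup = sub_report)
}
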