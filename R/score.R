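#' Pairwise inter-gene correlation QC
#'
#' Before averaging a gene panel into a single score, the panel should behave
#' as one coherent signature: pairwise correlations between the log2
#' expression values of its genes should be high. This QC computes all
#' `n_genes * (n_genes - 1) / 2` pairwise correlations on pairwise-complete
#' observations and reports the fraction of pairs with `r >= threshold_r` and
#' `p <= threshold_p`. The check is advisory: a fraction below `warn_fraction`
#' raises a warning but never filters genes.
#'
#' @param expr an `expr_matrix` (samples x genes, log2 scale).
#' @param threshold_r correlation threshold, default 0.7.
#' @param threshold_p two-sided p-value threshold, default 0.002.
#' @param method `"pearson"` (default; the values are already log-transformed)
#'   or `"spearman"`.
#' @param warn_fraction warn when the passing fraction falls below this,
#'   default 0.9.
#' @return An object of class `correlation_summary`: list with `n_genes`,
#'   `n_pairs`, thresholds, `fraction_pairs_passing`, and `pairs`, a data
#'   frame with one row per gene pair (`gene_i`, `gene_j`, `n`, `r`, `p`).
#'   Pairs involving a zero-variance gene have `r = NA` and are excluded from
#'   the passing-fraction denominator (with a warning).
#' @export
correlation_qc <- function(expr, threshold_r = 0.7, threshold_p = 0.002,
                           method = c("pearson", "spearman"),
                           warn_fraction = 0.9) {
  method <- match.arg(method)
  x <- unclass(expr)
  genes <- colnames(x)
  g <- length(genes)
  if (g < 2) stop("correlation QC needs at least 2 panel genes")
  if (nrow(x) < 4) stop("correlation QC needs at least 4 samples")
  idx <- utils::combn(g, 2)
  n_pairs <- ncol(idx)
  res <- data.frame(gene_i = genes[idx[1, ]], gene_j = genes[idx[2, ]],
                    n = NA_integer_, r = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    xi <- x[, idx[1, k]]
    xj <- x[, idx[2, k]]
    ok <- is.finite(xi) & is.finite(xj)
    res$n[k] <- sum(ok)
    if (sum(ok) < 4 ||
        stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
    ct <- stats::cor.test(xi[ok], xj[ok], method = method, exact = FALSE)
    res$r[k] <- unname(ct$estimate)
    res$p[k] <- ct$p.value
  }
  undefined <- is.na(res$r)
  if (any(undefined)) {
    warning(sum(undefined), " gene pair(s) with undefined correlation ",
            "(zero variance or too few complete observations); ",
            "excluded from the passing fraction")
  }
  denom <- sum(!undefined)
  passing <- !undefined & res$r >= threshold_r & res$p <= threshold_p
  frac <- if (denom > 0) sum(passing) / denom else NA_real_
  if (!is.na(frac) && frac < warn_fraction) {
    warning(sprintf(
      "only %.1f%% of defined gene pairs reach r >= %g at p <= %g; the panel may not form a coherent signature",
      100 * frac, threshold_r, threshold_p))
  }
  structure(
    list(n_genes = g, n_pairs = n_pairs, threshold_r = threshold_r,
         threshold_p = threshold_p, fraction_pairs_passing = frac,
         pairs = res),
    class = "correlation_summary"
  )
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "Inter-gene correlation QC: %d genes, %d pairs; %.1f%% with r >= %g (p <= %g)\n",
    x$n_genes, x$n_pairs, 100 * x$fraction_pairs_passing,
    x$threshold_r, x$threshold_p))
  invisible(x)
}

#' Write the QC pair table as TSV
#'
#' @param qc a `correlation_summary`.
#' @param path output path; the pair table is written as TSV preceded by a
#'   one-line `#` summary comment.
#' @export
write_qc_report <- function(qc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# %d genes, %d pairs, fraction passing (r >= %g, p <= %g): %.4f",
    qc$n_genes, qc$n_pairs, qc$threshold_r, qc$threshold_p,
    qc$fraction_pairs_passing), con)
  utils::write.table(qc$pairs, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Compute the per-sample IFN score
#'
#' The IFN score of a sample is the arithmetic mean of its log2 relative
#' expression values over the panel genes. Samples with fewer than
#' `min_complete` (a fraction) of the panel genes present are omitted with a
#' message; the default of 1 requires all panel genes.
#'
#' @param expr an `expr_matrix`.
#' @param panel character vector of gene ids; defaults to every column of
#'   `expr`. Must be non-empty and a subset of the matrix genes.
#' @param min_complete minimum fraction of non-missing panel genes a sample
#'   needs for its score to be defined, in (0, 1]; default 1.
#' @return A named numeric vector (class `ifn_score`) of scores indexed by
#'   sample id, with attribute `panel`. Omitted samples are absent, not NA.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("S", 1:10), paste0("G", 1:4)))
#' compute_ifn_score(expr_matrix(m))
#' @export
compute_ifn_score <- function(expr, panel = NULL, min_complete = 1) {
  x <- unclass(expr)
  if (is.null(panel)) panel <- colnames(x)
  if (length(panel) == 0) stop("configuration error: empty gene panel")
  absent <- setdiff(panel, colnames(x))
  if (length(absent)) {
    stop("configuration error: panel gene(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  stopifnot(min_complete > 0, min_complete <= 1)
  sub <- x[, panel, drop = FALSE]
  frac_present <- rowMeans(is.finite(sub))
  keep <- frac_present >= min_complete
  if (any(!keep)) {
    message("omitting ", sum(!keep), " sample(s) with < ",
            round(100 * min_complete), "% of panel genes present: ",
            paste(rownames(sub)[!keep], collapse = ", "))
  }
  scores <- rowMeans(sub[keep, , drop = FALSE], na.rm = TRUE)
  structure(scores, panel = panel, class = "ifn_score")
}

#' @export
print.ifn_score <- function(x, ...) {
  cat("IFN scores for", length(x), "samples over a",
      length(attr(x, "panel")), "gene panel\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' @rdname compute_ifn_score
#' @param scores an `ifn_score` vector.
#' @param path output CSV path (columns `sample_id`, `ifn_score`).
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(
    data.frame(sample_id = names(scores), ifn_score = as.numeric(scores)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname compute_ifn_score
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(stats::setNames(df$ifn_score, df$sample_id),
            panel = NULL, class = "ifn_score")
}
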