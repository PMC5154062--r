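#' Fit a qPCR standard curve
#'
#' Fits the per-gene calibration line of the standard curve method,
#' `Ct = intercept + slope * log10(quantity)`, by ordinary least squares on a
#' dilution series. For an efficient reaction the slope is negative (more
#' template amplifies earlier); a slope of -1/log10(2) = -3.32 corresponds to
#' perfect doubling per cycle.
#'
#' @param dilution_points data frame with columns `quantity` (known relative
#'   quantity, > 0) and `ct` (observed threshold cycle), or a two-column
#'   matrix in that order. At least two distinct quantities are required.
#' @param gene_id optional gene label carried on the returned object.
#'
#' @return An object of class `standard_curve`: a list with `gene_id`,
#'   `intercept` (Ct at quantity 1), `slope` (Ct per log10 quantity),
#'   `efficiency` (implied amplification efficiency `10^(-1/slope)`), and
#'   `usable` (FALSE when the fitted slope is non-negative).
#'
#' @details The implied amplification efficiency is checked against the
#'   physically plausible range (1, 2.5]; values outside it trigger a warning
#'   but the curve is still returned (only a non-negative slope makes a curve
#'   unusable). Dilution points with missing Ct are dropped before fitting.
#'
#' @examples
#' pts <- data.frame(quantity = c(1, 10, 100), ct = c(20, 16.678, 13.356))
#' fit_standard_curve(pts, gene_id = "IFI44L")
#' @export
fit_standard_curve <- function(dilution_points, gene_id = NA_character_) {
  dp <- as.data.frame(dilution_points)
  if (!all(c("quantity", "ct") %in% names(dp))) {
    if (ncol(dp) >= 2) names(dp)[1:2] <- c("quantity", "ct")
    else stop("dilution_points must have columns 'quantity' and 'ct'")
  }
  dp <- dp[is.finite(dp$quantity) & is.finite(dp$ct), , drop = FALSE]
  if (any(dp$quantity <= 0)) stop("all known quantities must be > 0")
  if (length(unique(dp$quantity)) < 2) {
    stop("calibration error: need >= 2 distinct known quantities, got ",
         length(unique(dp$quantity)))
  }
  if (any(dp$ct <= 0)) stop("Ct values must be > 0")
  fit <- stats::lm(ct ~ log10(quantity), data = dp)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  usable <- slope < 0
  if (!usable) {
    warning("fitted slope is non-negative (", format(slope),
            "); curve for ", gene_id, " flagged unusable")
    efficiency <- NA_real_
  } else {
    efficiency <- 10^(-1 / slope)
    if (efficiency <= 1 || efficiency > 2.5) {
      warning("implied amplification efficiency ", format(efficiency),
              " outside (1, 2.5] for gene ", gene_id)
    }
  }
  structure(
    list(gene_id = gene_id, intercept = intercept, slope = slope,
         efficiency = efficiency, usable = usable),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve", if (!is.na(x$gene_id)) paste0("[", x$gene_id, "]"),
      "\n  Ct =", format(x$intercept), "+", format(x$slope),
      "* log10(quantity)\n  efficiency:", format(x$efficiency),
      if (!x$usable) " (UNUSABLE)", "\n")
  invisible(x)
}

#' Convert Ct values to relative quantities (and back)
#'
#' Inverts the fitted standard curve: `quantity = 10^((ct - intercept)/slope)`.
#' Missing Ct values (failed or undetermined wells) propagate as missing
#' quantities rather than zeros.
#'
#' @param ct numeric vector of threshold cycles; `NA` allowed.
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @return numeric vector of relative quantities (dimensionless, > 0).
#' @export
ct_to_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$usable) stop("curve is flagged unusable (slope >= 0)")
  10^((ct - curve$intercept) / curve$slope)
}

#' @rdname ct_to_quantity
#' @param quantity numeric vector of relative quantities.
#' @export
quantity_to_ct <- function(quantity, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$usable) stop("curve is flagged unusable (slope >= 0)")
  curve$intercept + curve$slope * log10(quantity)
}

#' Apply standard curves to a Ct table
#'
#' Maps a samples-by-genes grid of Ct values through per-gene standard curves.
#'
#' @param ct_table numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (colnames = gene ids); `NA` for non-amplified wells.
#' @param curves named list of `standard_curve` objects covering every column.
#' @return numeric matrix of relative quantities, same shape and dimnames.
#' @export
apply_standard_curves <- function(ct_table, curves) {
  ct_table <- as.matrix(ct_table)
  missing_curves <- setdiff(colnames(ct_table), names(curves))
  if (length(missing_curves)) {
    stop("no standard curve for gene(s): ",
         paste(missing_curves, collapse = ", "))
  }
  out <- ct_table
  for (g in colnames(ct_table)) {
    out[, g] <- ct_to_quantity(ct_table[, g], curves[[g]])
  }
  out
}

#' Reference-normalize quantities and log2-transform
#'
#' Divides each gene's relative quantity by the same sample's reference-gene
#' quantity (GAPDH in the original assay) and takes log2, producing the
#' expression matrix every downstream step consumes. Samples whose reference
#' quantity is missing cannot be normalized and are dropped with a message;
#' any non-positive quantity is set missing with a warning. The reference
#' gene is removed from the output columns.
#'
#' @param quantities numeric matrix of relative quantities, samples in rows,
#'   genes in columns (the reference gene must be one of them).
#' @param reference_gene column name of the reference gene.
#' @return An `expr_matrix`: a numeric matrix of log2 relative expression with
#'   attributes `panel` (remaining gene ids, in column order) and
#'   `reference_gene`.
#' @seealso [expr_matrix()] to wrap pre-computed log2 values directly.
#' @export
normalize_and_log <- function(quantities, reference_gene) {
  q <- as.matrix(quantities)
  if (!reference_gene %in% colnames(q)) {
    stop("reference gene '", reference_gene, "' not found in quantity matrix")
  }
  bad <- which(!is.na(q) & q <= 0)
  if (length(bad)) {
    warning(length(bad), " non-positive quantit",
            if (length(bad) == 1) "y" else "ies", " set to missing")
    q[bad] <- NA_real_
  }
  ref <- q[, reference_gene]
  drop_samples <- which(is.na(ref))
  if (length(drop_samples)) {
    message("dropping ", length(drop_samples),
            " sample(s) with missing reference gene: ",
            paste(rownames(q)[drop_samples], collapse = ", "))
    q <- q[-drop_samples, , drop = FALSE]
    ref <- ref[-drop_samples]
  }
  genes <- setdiff(colnames(q), reference_gene)
  out <- log2(q[, genes, drop = FALSE] / ref)
  expr_matrix(out, reference_gene = reference_gene)
}

#' Construct an expression matrix of log2 relative values
#'
#' Thin wrapper marking a samples-by-genes numeric matrix as reference-
#' normalized log2 relative expression. This is the bypass entry point when
#' log2 values are pre-computed upstream and no Ct-level data are available.
#'
#' @param x numeric matrix, samples in rows, genes in columns, both named.
#' @param reference_gene name of the reference gene the values were
#'   normalized to (recorded, not present among the columns).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(x, reference_gene = NA_character_) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs sample rownames and gene colnames")
  }
  if (!is.na(reference_gene) && reference_gene %in% colnames(x)) {
    stop("reference gene must not remain among the normalized columns")
  }
  if (any(is.infinite(x))) stop("expression matrix contains infinite values")
  structure(x, panel = colnames(x), reference_gene = reference_gene,
            class = c("expr_matrix", "matrix", "array"))
}

#' Read / write expression and Ct tables
#'
#' CSV/TSV layout: first column `sample_id`, remaining columns one per gene,
#' missing encoded as empty field or `NA`. The separator is inferred from the
#' file extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path file path.
#' @param reference_gene recorded on the returned `expr_matrix`.
#' @return `read_expression()` returns an `expr_matrix`; `read_ct_table()` a
#'   plain numeric matrix.
#' @export
read_expression <- function(path, reference_gene = NA_character_) {
  expr_matrix(.read_grid(path), reference_gene = reference_gene)
}

#' @rdname read_expression
#' @export
read_ct_table <- function(path) .read_grid(path)

#' @rdname read_expression
#' @param x matrix to write.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

.read_grid <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read per-gene dilution series and fit all curves
#'
#' @param path CSV with columns `gene_id`, `quantity`, `ct`.
#' @return named list of `standard_curve` objects.
#' @export
read_dilution_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "quantity", "ct") %in% names(df)))
  curves <- lapply(split(df, df$gene_id), function(d) {
    fit_standard_curve(d[, c("quantity", "ct")], gene_id = d$gene_id[1])
  })
  curves
}
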