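#' Construct a clinical cohort table
#'
#' A clinical cohort is a data frame with one row per patient, a `patient_id`
#' column, and clinical variables each declared either `continuous`
#' (real-valued) or `dichotomous` (coded 0/1). Missing values are permitted
#' in any cell; dichotomous columns may contain only 0, 1 and NA.
#'
#' @param data data frame with a `patient_id` column.
#' @param types named character vector mapping variable names to
#'   `"continuous"` or `"dichotomous"`; variables not named here are carried
#'   along untyped and cannot be screened.
#' @return A `clinical_cohort`: the data frame with a `types` attribute.
#' @export
clinical_cohort <- function(data, types) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(data)) stop("cohort needs a patient_id column")
  if (anyDuplicated(data$patient_id)) stop("duplicated patient ids")
  unknown <- setdiff(names(types), names(data))
  if (length(unknown)) {
    stop("typed variable(s) absent from data: ",
         paste(unknown, collapse = ", "))
  }
  bad_type <- types[!types %in% c("continuous", "dichotomous")]
  if (length(bad_type)) {
    stop("variable types must be 'continuous' or 'dichotomous'")
  }
  for (v in names(types)[types == "dichotomous"]) {
    vals <- data[[v]]
    if (!all(is.na(vals) | vals %in% c(0, 1))) {
      stop("dichotomous variable '", v, "' contains values outside {0, 1, NA}")
    }
  }
  structure(data, types = types,
            class = c("clinical_cohort", "data.frame"))
}

#' @export
print.clinical_cohort <- function(x, ...) {
  ty <- attr(x, "types")
  cat("Clinical cohort:", nrow(x), "patients,",
      sum(ty == "continuous"), "continuous and",
      sum(ty == "dichotomous"), "dichotomous variables\n")
  NextMethod()
}

#' @export
`[.clinical_cohort` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "types") <- attr(x, "types")[
      names(attr(x, "types")) %in% names(out)]
    class(out) <- c("clinical_cohort", "data.frame")
  }
  out
}

#' @rdname clinical_cohort
#' @param x a `clinical_cohort`.
#' @export
variable_types <- function(x) attr(x, "types")

#' Recompute derived clinical variables from their parents
#'
#' Several screened variables are deterministic functions of measured ones
#' and are never stored independently: dichotomized inflammation markers
#' (ESR > 20 mm/h, CRP >= 10 mg/L), ACPA high positivity (titer >= 3x the
#' assay cutoff), the RF/ACPA double-positive and double-negative indicators,
#' and the any-suppressor flag (prednisone, HCQ and/or SSZ). A derived value
#' is missing whenever any parent is missing.
#'
#' @param cohort a `clinical_cohort` containing the parent columns among
#'   `esr`, `crp`, `acpa_titer`, `rf_pos`, `acpa_pos`, `predn_use`,
#'   `hcq_use`, `ssz_use`; absent parents simply skip their derived column.
#' @param acpa_cutoff assay positivity cutoff in AU/ml for ACPA; high
#'   positivity is titer >= 3 * cutoff. Default 350.
#' @return The cohort with derived columns (re)computed and typed
#'   dichotomous: `esr_gt20`, `crp_ge10`, `acpa_high`, `rf_acpa_pos`,
#'   `rf_acpa_neg`, `any_suppressor`.
#' @export
add_derived_variables <- function(cohort, acpa_cutoff = 350) {
  ty <- attr(cohort, "types")
  put <- function(name, values) {
    cohort[[name]] <<- as.numeric(values)
    ty[[name]] <<- "dichotomous"
  }
  has <- function(...) all(c(...) %in% names(cohort))
  if (has("esr")) put("esr_gt20", cohort$esr > 20)
  if (has("crp")) put("crp_ge10", cohort$crp >= 10)
  if (has("acpa_titer")) {
    put("acpa_high", cohort$acpa_titer >= 3 * acpa_cutoff)
  }
  if (has("rf_pos", "acpa_pos")) {
    # NA whenever either parent is unknown (R's NA & FALSE would give FALSE)
    either_na <- is.na(cohort$rf_pos) | is.na(cohort$acpa_pos)
    both_pos <- cohort$rf_pos == 1 & cohort$acpa_pos == 1
    both_neg <- cohort$rf_pos == 0 & cohort$acpa_pos == 0
    both_pos[either_na] <- NA
    both_neg[either_na] <- NA
    put("rf_acpa_pos", both_pos)
    put("rf_acpa_neg", both_neg)
  }
  if (has("predn_use", "hcq_use", "ssz_use")) {
    put("any_suppressor",
        pmax(cohort$predn_use, cohort$hcq_use, cohort$ssz_use) == 1)
  }
  attr(cohort, "types") <- ty
  cohort
}

#' The default 25-variable screening specification
#'
#' The screen covers disease parameters (duration, DAS28 and its components,
#' erosions, nodules), laboratory parameters (ESR and CRP continuous and
#' dichotomized, RF and ACPA titers and positivity, combined autoantibody
#' status) and medication parameters (MTX, prednisone, HCQ, SSZ use and
#' doses, and the combined any-suppressor flag). Continuous variables are
#' tested by Spearman correlation, dichotomous ones by Mann-Whitney U.
#'
#' @return data frame with columns `variable` and `test`
#'   (`"spearman"`/`"mann_whitney"`), in reporting order.
#' @export
default_variable_spec <- function() {
  data.frame(
    variable = c("disease_duration", "das28", "tjc28", "sjc28", "vas",
                 "erosions", "nodules",
                 "esr", "esr_gt20", "crp", "crp_ge10",
                 "rf_titer", "rf_pos", "acpa_titer", "acpa_pos", "acpa_high",
                 "rf_acpa_pos", "rf_acpa_neg",
                 "mtx_use", "mtx_dose", "predn_use", "predn_dose",
                 "hcq_use", "ssz_use", "any_suppressor"),
    test = c("spearman", "spearman", "spearman", "spearman", "spearman",
             "mann_whitney", "mann_whitney",
             "spearman", "mann_whitney", "spearman", "mann_whitney",
             "spearman", "mann_whitney", "spearman", "mann_whitney",
             "mann_whitney", "mann_whitney", "mann_whitney",
             "mann_whitney", "spearman", "mann_whitney", "spearman",
             "mann_whitney", "mann_whitney", "mann_whitney"),
    stringsAsFactors = FALSE
  )
}

#' Read / write a clinical cohort
#'
#' @param path CSV/TSV file, one row per patient, first column `patient_id`.
#' @param types named character vector of variable types (see
#'   [clinical_cohort()]).
#' @export
read_cohort <- function(path, types) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  clinical_cohort(df, types)
}

#' @rdname read_cohort
#' @param cohort a `clinical_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
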