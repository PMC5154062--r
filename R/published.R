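#' Published complete-group screen p values
#'
#' The complete-group association p values reported by a published screen of
#' the peripheral-blood IFN score against 25 clinical variables in an
#' established RA cohort (n = 182), together with the reported
#' Benjamini-Hochberg-corrected values. The MTX-use p value was performed
#' but not reported (both columns NA); it still counts toward the total
#' number of tests, so the matching correction is `bh_adjust(p, m = 25,
#' mode = "plain")`. These values are the validation input for the
#' replication dialect of [bh_adjust()]; they are published summary
#' statistics, not patient-level data.
#'
#' @return data frame with columns `variable`, `p` (reported complete-group
#'   p value) and `q_published` (reported BH-corrected value, as printed).
#' @examples
#' ref <- published_screen_pvalues()
#' round(bh_adjust(ref$p, m = 25, mode = "plain"), 4)
#' @export
published_screen_pvalues <- function() {
  data.frame(
    variable = c("disease_duration", "das28", "tjc28", "sjc28", "vas",
                 "erosions", "nodules",
                 "esr", "esr_gt20", "crp", "crp_ge10",
                 "rf_titer", "rf_pos", "acpa_titer", "acpa_pos", "acpa_high",
                 "rf_acpa_pos", "rf_acpa_neg",
                 "mtx_use", "mtx_dose", "predn_use", "predn_dose",
                 "hcq_use", "ssz_use", "any_suppressor"),
    p = c(0.061, 0.18, 0.10, 0.61, 0.21,
          0.41, 0.24,
          0.86, 0.71, 0.14, 0.15,
          0.36, 0.96, 0.38, 0.86, 0.29,
          0.57, 0.13,
          NA, 0.57, 0.037, 0.017,
          0.001, 0.023, 0.00032),
    q_published = c(0.250, 0.41, 0.36, 0.76, 0.44,
                    0.60, 0.46,
                    0.98, 0.85, 0.39, 0.38,
                    0.60, 1.0, 0.59, 0.98, 0.52,
                    0.79, 0.41,
                    NA, 0.79, 0.19, 0.14,
                    0.013, 0.14, 0.0080),
    stringsAsFactors = FALSE
  )
}
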