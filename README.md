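# ifnstab

Association screening of a composite peripheral-blood interferon (IFN)
score against clinical variables, with internal split-half stability
cross-validation.

## The problem

In rheumatoid arthritis (and several other autoimmune diseases) a subset
of patients shows coordinated over-expression of type I interferon
response genes (IRGs) in whole blood — the *IFN signature*. Panels of
IRGs are measured by real-time qPCR, summarized into one number per
patient, and screened against clinical parameters: disease activity and
its components, inflammation labs, autoantibody titers and positivity,
erosions, nodules, and treatment. The statistical hazard is obvious — one
score, ~25 heterogeneous variables, a cohort of moderate size — so every
association is additionally put through a replication filter: randomize
the cohort 1000 times into two equally sized halves, run the test on both
halves each time, and count in how many iterations significance appeared
in **both**, **one**, or **neither** half. Associations that cannot
replicate across random halves of the same cohort do not deserve belief.

## What the package computes

* **Standard-curve quantification** (`fit_standard_curve()`,
  `ct_to_quantity()`, `normalize_and_log()`): per-gene OLS calibration
  `Ct = a + b·log10(Q)`, inversion to relative quantities,
  reference-gene (e.g. GAPDH) normalization, log2 transform. Pre-computed
  log2 values can enter directly via `expr_matrix()`.
* **IFN score** (`compute_ifn_score()`): per-sample arithmetic mean of
  log2 relative expression over the gene panel, with panel-coherence QC
  (`correlation_qc()`: fraction of gene pairs with r ≥ 0.7 at p ≤ 0.002).
* **Association screen** (`screen_cohort()`): Spearman correlation for
  continuous variables, Mann-Whitney U for dichotomous ones,
  pairwise-complete cases, Benjamini-Hochberg correction across the whole
  specification. Two BH dialects are provided (`bh_adjust()`): the
  standard monotone step-up (default) and the "plain" `q = p·m/rank`
  dialect that some published tables report, with `m` allowed to exceed
  the number of reported p values.
* **Split-half stability screen** (`stability_screen()`): the 1000×
  bipartition procedure above, fully seeded, with per-variable both /
  one / neither counts, per-set median p values, and median Spearman rho.
* **Synthetic cohorts** (`generate_cohort()`): a common-factor expression
  model (every gene pair at correlation ρ, default 0.8) calibrated so the
  panel-mean score has mean 0.26 and SD 1.01, plus clinical marginals of
  an established-RA cohort (n = 182), treatment-linked additive
  suppression of the score, and a ground-truth record — so calibration,
  power, and false-positive behaviour of the pipeline are testable
  without patient-level data.
* **Reporting** (`run_pipeline()`, `build_report()`, `write_report()`):
  one table fusing full-cohort and stability results, TSV plus
  full-precision JSON sidecar, optional second pass on the subgroup of
  patients taking none of the score-suppressing agents
  (`subgroup_filter()`), and score-by-treatment-burden strata
  (`group_compare()`).

## Worked example

Simulate a cohort in which prednisone, HCQ and SSZ suppress the score by
0.3, 0.6 and 0.3 score-SD units respectively (additive across agents),
then run the full pipeline:

```r
library(ifnstab)

cfg <- synthetic_cohort_config(
  seed = 42,
  suppression_delta = c(predn_use = 0.3, hcq_use = 0.6, ssz_use = 0.3))
syn    <- generate_cohort(cfg)
scores <- compute_ifn_score(syn$expr)

correlation_qc(syn$expr)
#> Inter-gene correlation QC: 19 genes, 171 pairs; 100.0% with r >= 0.7 (p <= 0.002)

res <- run_pipeline(syn$expr, syn$cohort, n_iter = 1000, seed = 7)
```

Selected rows of `res$report` (values rounded at render time by
`format_report()`):

```
       variable         test n_used statistic        p       q both one neither median_p_set1 median_p_set2
          das28     spearman    182  5.75e-02 0.440000 0.76000    0  50     950       0.52300       0.55000
     acpa_titer     spearman    177  5.51e-02 0.466000 0.76000    0  39     961       0.51000       0.55100
      predn_use mann_whitney    182  2.73e+03 0.094000 0.39200    0 275     725       0.22700       0.24800
        hcq_use mann_whitney    182  1.62e+03 0.000668 0.00835  506 494       0       0.01620       0.01770
        ssz_use mann_whitney    182  1.23e+03 0.023100 0.19200    0 592     408       0.11200       0.10400
 any_suppressor mann_whitney    182  2.80e+03 0.000166 0.00416  681 319       0       0.00827       0.00811
```

Read: the injected treatment effects surface exactly where they were
planted — HCQ use reaches p < 0.05 in both halves in 506 of 1000
bipartitions and never in neither, while disease activity (DAS28) and
ACPA titer, which by construction do not influence expression, replicate
in no iteration; their full-cohort p values (~0.44) are the false-positive
background the BH correction is there to absorb. The combined
any-suppressor flag is stronger than any single agent because suppression
adds up. Stratifying by treatment burden shows the additive ordering:

```
res$group_comparison
#> IFN score by number of suppressing agents:
#>  stratum  n     median         q1         q3
#>        0 91  0.4771508 -0.2405709  0.9760583
#>        1 76 -0.1124329 -0.6629440  0.5425846
#>      >=2 15 -0.5992043 -1.3888623 -0.2178856
```

A shell front end over the same functions lives at `inst/cli/ifnstab`
(subcommands `simulate`, `score`, `screen`, `stability`, `run`).

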