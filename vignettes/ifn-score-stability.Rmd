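---
title: "The IFN score and its split-half stability screen: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IFN score and its split-half stability screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnstab)
```

## The problem this package addresses

A subset of patients with rheumatoid arthritis (RA) shows elevated
peripheral-blood expression of type I interferon response genes (IRGs) — the
"IFN signature". Whether that signature tracks anything clinically useful
(disease activity, autoantibody status, treatment) is a question of
association screening: one continuous molecular score against a couple of
dozen heterogeneous clinical variables, in a cohort of moderate size, where
a single lucky p value is cheap and replication is everything.

`ifnstab` implements that screening pipeline end to end:

1. **quantify** — relative quantification of panel qPCR data by the
   standard-curve method, normalized to a reference gene and
   log2-transformed;
2. **score** — coherence QC of the gene panel and the per-sample IFN score;
3. **screen** — full-cohort rank-based association tests with
   Benjamini-Hochberg (BH) correction, in two dialects;
4. **stability** — internal cross-validation by repeated random bipartition
   of the cohort into two equally sized halves;
5. **synthetic data** — a generator producing cohorts with the statistical
   structure the analysis assumes, so the whole pipeline is testable
   without patient-level data (which, for the motivating study design, are
   not publicly available);
6. **report** — fusion of the full-cohort and stability results into one
   table plus a full-precision JSON sidecar.

## Quantification model

For each gene, a dilution series calibrates the line

$$C_t = a + b\,\log_{10}(Q),$$

fitted by ordinary least squares (`fit_standard_curve()`). The slope must
be negative; the implied amplification efficiency $10^{-1/b}$ is checked
against the physically plausible $(1, 2.5]$ and warned about outside it
(perfect doubling gives $b = -1/\log_{10} 2 \approx -3.32$, efficiency 2).
Inverting the curve gives the relative quantity $Q = 10^{(C_t - a)/b}$;
dividing by the same sample's reference-gene quantity (GAPDH in the
motivating assay) and taking log2 yields the expression matrix
(`normalize_and_log()`). Relative quantification makes any per-sample
preamplification factor cancel, so preamplification is not modeled.

Missing Ct values (failed or undetermined wells) propagate as missing
expression rather than zeros; a sample is dropped only when its reference
gene is missing, because nothing in it can be normalized. How the
motivating assay handled failed wells is not documented anywhere we know
of; propagation-as-missing is this package's choice, paired with
pairwise-complete analysis downstream. Most users will skip this module
entirely and enter at `expr_matrix()` with pre-computed log2 relative
values; every downstream test in this package does exactly that.

## The IFN score and panel coherence

The IFN score of a sample is the arithmetic mean of its log2 relative
expression over the panel genes (`compute_ifn_score()`). Averaging is only
meaningful if the panel moves as one signature, so `correlation_qc()`
computes all pairwise inter-gene correlations (Pearson by default — the
values are already log-transformed; Spearman by switch) and reports the
fraction of pairs with $r \ge 0.7$ at $p \le 0.002$. In the signature
regime this fraction is expected to reach about 0.9. The QC is advisory: a
low fraction warns but never drops genes, because gene selection is the
panel designer's decision, not the scoring function's.

By default a sample's score requires all panel genes present
(`min_complete = 1`); there is no principled imputation for a missing
signature gene, and silently averaging fewer genes would shift scores for
exactly the samples with assay problems. The threshold is exposed for
panels where partial missingness is routine.

The panel itself is a required input. The package hard-codes no gene list:
published IRG panels differ, and the score is defined relative to whatever
panel the assay measured. The score stays continuous throughout —
dichotomizing into IFN-high/IFN-low discards information and is
deliberately out of scope.

## The association screen

Each clinical variable is declared continuous or dichotomous. Continuous
variables are tested by Spearman correlation between variable and score;
dichotomous ones by the Mann-Whitney U test comparing scores between the
two levels. Conventions, fixed once in `spearman_test()` and
`mann_whitney_test()` and shared by the full-cohort and stability screens:

* Spearman's $\rho$ on average ranks (ties share their mean rank),
  two-sided p from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df;
  $|\rho| = 1$ gives $p = 0$; fewer than 4 complete pairs or zero variance
  flags the result not-computable.
* Mann-Whitney U for the "1" group, two-sided p from the normal
  approximation with tie correction and 0.5 continuity correction. These
  match the conventions of `stats::cor.test(exact = FALSE)` and
  `stats::wilcox.test(exact = FALSE, correct = TRUE)` bitwise (the test
  suite asserts this), but are implemented directly because they sit in the
  hot loop of the stability screen and their dialect is part of the
  replication contract. An exact-enumeration mode
  (`mann_whitney_test(exact = TRUE)`, $n_a + n_b \le 12$) enumerates all
  group assignments and is valid under ties.

How close are the approximations to exact enumeration? Enumerating every
possible U at group sizes 5 and 6 bounds the tie-free error of the MWU
normal approximation at 0.0173 anywhere in $[0,1]$; heavy ties roughly
double it. For Spearman, the t approximation's worst-case deviation from
the exact permutation null is 0.15 at $n = 4$, 0.048 at $n = 6$ and 0.027
at $n = 7$ — at half-cohort sizes (around 90) both approximations are far
inside anything that matters at $\alpha = 0.05$. The test suite asserts
exactly these enumerated bounds rather than an optimistic blanket figure.

Missing data are handled pairwise-complete per test, with no imputation:
a patient missing one lab value drops out of that test only, and `n_used`
records what remained.

### Benjamini-Hochberg dialects

`bh_adjust()` offers two dialects:

* **monotone** (package default): the standard step-up,
  $q_{(i)} = \min(1, \min_{j \ge i} p_{(j)}\,m/j)$, delegated to
  `stats::p.adjust(method = "BH", n = m)`.
* **plain** (replication default in published-table comparisons):
  $q_i = \min(1, p_i\,m/\mathrm{rank}_i)$ with tied p values sharing the
  smaller rank and no monotonicity enforcement. Several statistics
  packages have historically reported this form.

The two coincide whenever $p \cdot m/\mathrm{rank}$ is nondecreasing in
rank — in particular across the low ranks of the published 25-variable
screen this package replicates — and differ otherwise, with monotone
$\le$ plain elementwise. Replication against the published corrected
column requires `m = 25`: 24 reported p values plus one test (MTX use)
that was performed but whose p value was not printed. `m` may therefore
exceed the number of supplied p values, and the full-cohort screen counts
not-computable variables toward `m` for the same reason: a test that was
attempted is part of the multiplicity burden whether or not it produced a
number.

## The split-half stability screen

`stability_screen()` randomizes the cohort `n_iter` times (default 1000)
into two disjoint halves of sizes $\lfloor n/2 \rfloor$ and
$\lceil n/2 \rceil$, runs every variable's test on both halves of every
bipartition, and tabulates per variable how often $p < \alpha$ held in
both, exactly one, or neither half, together with per-set median p values
and, for continuous variables, the median Spearman $\rho$ pooled over all
$2\,n_\text{iter}$ half-set fits. An association worth believing should
replicate across random halves; one that owes its full-cohort p value to a
handful of influential patients will not.

Design choices that were genuinely open:

* **One bipartition per iteration, shared across all variables** — the
  procedure randomizes the patient group, not each test; this also keeps
  the door open for cross-variable concordance analyses.
* **Set labels are arbitrary.** Halves are exchangeable by construction;
  "set 1" is merely the $\lfloor n/2 \rfloor$-sized half. For odd $n$ the
  floor/ceil split is this package's extension.
* **Median coefficient pools both sets** (all $2\,n_\text{iter}$ fits)
  rather than reporting per-set medians; the halves are exchangeable, so
  per-set medians estimate the same quantity twice.
* **Not-computable halves count as not-significant** for that set (e.g. a
  treatment group empty in one half), and are tallied separately in
  `n_not_computable` so silent degradation is visible.
* **RNG policy:** one root seed, one stream; iteration $i$'s bipartition
  is the $i$-th draw (`sample.int(n)`, first $\lfloor n/2 \rfloor$ indices
  forming set 1). The policy is documented precisely so an independent
  reimplementation can mirror it — the test suite contains exactly such a
  plain-loop reimplementation built on `stats::cor.test()` /
  `stats::wilcox.test()` and requires identical counts.

## The synthetic cohort generator

`generate_cohort()` produces (expression, clinical, ground-truth) triples
emulating an established-RA cohort of 182 patients measured on a 19-gene
panel. It exists so that calibration, power and recovery claims about the
pipeline can be tested without patient-level data; its defaults are the
study conditions, not tuning knobs.

**Expression** follows a single-common-factor model: gene $g$ of patient
$j$ is

$$x_{gj} = \mu + \sigma\left(\sqrt{\rho}\,f_j +
\sqrt{1-\rho}\,e_{gj}\right), \qquad f_j, e_{gj} \sim N(0,1),$$

so every gene pair shares correlation $\rho$ (default 0.8, which at
$n = 182$ puts roughly 90% or more of the 171 pairs above $r = 0.7$ — the
signature-coherence regime). Averaging over $G$ genes shrinks the
idiosyncratic term, so $\sigma = s/\sqrt{\rho + (1-\rho)/G}$ and
$\mu = 0.26$, $s = 1.01$ put the panel-mean score at the reported cohort
mean and SD. For each score-suppressing agent a patient takes (prednisone,
HCQ, SSZ), `suppression_delta[agent] * s` is subtracted from every gene —
suppression is additive across agents on the log2 scale, directly encoding
the observation that two or more agents suppress more than one.

**Clinical variables** are drawn independently from marginals typical of
active established RA: truncated normals where skew is mild (age 54.2/11.8;
disease duration 9.7/10.3 truncated positive; DAS28 5.1/1.2 on [0, 9.4];
ESR 24.5/18.0; CRP 17.8/22.1; doses among users), lognormals matched by
arithmetic moments for autoantibody titers (RF 124.7/279, ACPA 1563/2680 —
their SDs dwarf their means, so normal draws would be mostly negative),
and Bernoulli prevalences for the binary variables (female 0.75, erosions
0.72, nodules 0.24, RF+ 0.59, ACPA+ 0.75, MTX 0.84, prednisone 0.29, HCQ
0.19, SSZ 0.15). DAS28 components are not published as cohort marginals,
so TJC28 (8/6 on [0, 28]), SJC28 (6/5 on [0, 28]) and VAS (50/25 on
[0, 100]) use values a rheumatologist would call realistic for a cohort
with mean DAS28 of 5.1; they were fixed once, before any calibration runs.
Note that for strongly truncated marginals (disease duration, CRP) the
realized mean exceeds the nominal normal mean — the tests compare against
the analytic truncated-normal moments, not naively against the config.

Details worth knowing:

* Doses are drawn for users and are 0 for non-users, so a dose variable
  screened as continuous carries the use/non-use contrast too.
* Missingness masks mirror typical assay dropout: nodules 6/182, RF
  21/182, ACPA 7/182, with titer and positivity of an antibody going
  missing jointly (one assay, one failure).
* Derived indicators — ESR > 20, CRP ≥ 10, ACPA high positivity
  (titer ≥ 3 × cutoff, default cutoff 350 AU/ml, set so about 40% of
  patients fall above 3 × cutoff), RF and ACPA double-positive/negative,
  any-suppressor — are always recomputed from parents
  (`add_derived_variables()`), never stored, and are missing whenever a
  parent is missing.
* Treatment flags are independent Bernoullis by default; the real joint
  distribution of the three suppressing agents is not published, and
  independence gives an expected untreated fraction
  $0.71 \times 0.81 \times 0.85 \approx 0.49$ (about 89 of 182, close to
  the 95 observed in the motivating cohort).
* By construction, **no clinical variable except the treatment flags
  influences expression**, so under `suppression_delta = 0` every
  association the screen finds is a false positive, and the ground-truth
  record suffices to recompute every injected effect.

What the generator does **not** emulate: correlations among clinical
variables (ESR, CRP and DAS28 are independent here; an effect detectable
through such correlations in real data has no synthetic counterpart),
longitudinal structure, plate/batch effects, and Ct-level noise. Passing
tests on synthetic cohorts therefore demonstrate that the *procedure* is
calibrated and powered under its own assumptions — not that any particular
real-world association exists.

## Calibration, power, and the shape of the both-set rate

Under the null, the two halves of a bipartition are disjoint subsets of
iid patients — independent samples — so the probability that a variable
reaches $p < \alpha$ in *both* halves is $\alpha^2 = 0.0025$ at
$\alpha = 0.05$. A 150,000-replicate direct simulation of independent
halves confirms both the per-half level (0.0502) and the product (0.00245
± 0.00013) for the MWU test at half-cohort sizes.

Estimating that rate from split-half runs needs care: *conditional on a
cohort*, the both-set rate is heavy-tailed. A null cohort whose chance
imbalance happens to be large replicates it in both halves in a
substantial fraction of bipartitions, and such cohorts — occurring with
probability of order $10^{-3}$ — carry much of the unconditional mean.
Averaging over few cohorts with many bipartitions each therefore
undersamples the tail and lands below $\alpha^2$ with a deceptively small
empirical standard error. The calibration check accordingly spreads its
budget over 4000 independent cohorts with 10 bipartitions each (40,000
bipartitions total): each cohort contributes an independent draw, the tail
is sampled, and the 3-standard-error band is honest.

Power behaves as construction dictates: with a suppression effect on one
agent at prevalence 0.19 and $n = 182$, the both-set rate rises from
$\approx \alpha^2$ at $\delta = 0$ through intermediate values to
$\ge 0.95$ at $\delta = 1.5$ score-SD units, where the median half-set p
value itself drops below 0.05. Because a single synthetic cohort is one
draw, the realized effect in any one cohort wobbles around $\delta$; the
monotonicity checks fix the cohort seed across the $\delta$ grid so the
comparison isolates the injected effect.

## Numerical and degenerate-input policy

* All stored results keep full double precision; rounding (3 significant
  figures by default, mirroring typical published precision) happens only
  in `format_report()` / `write_report()` at render time, with a JSON
  sidecar preserving exact values.
* Zero-variance inputs, empty groups, all-missing variables and $n < 4$
  are flagged not-computable rather than erroring mid-screen; the screen
  and stability results carry the flag so downstream consumers can
  distinguish "no association" from "no test".
* Ties: average ranks everywhere; BH plain mode gives tied p values the
  smaller rank.
* `split_half()` refuses cohorts below 8 patients (half-set tests would be
  noise); the guard is a parameter so the splitter itself can be studied
  at tiny $n$.
* Problem sizes used by the test suite and the acceptance script — cohorts
  of 182, 1000-iteration stability runs, 4000-cohort calibration sweeps,
  enumeration oracles up to $n = 12$ (MWU) and $n = 7$ (Spearman
  permutations) — complete in a few minutes on a single core; they were
  chosen as the smallest sizes at which each claim is actually
  discriminating.

## Known limitations

* The stability screen's counts for *real* cohorts depend on the real
  joint distribution of score and covariates; synthetic results bound what
  the procedure can do, not what any dataset will show.
* The BH "plain" dialect is intentionally non-monotone; when ranks invert
  it can report $q_i$ larger than a lower-ranked variable's. Use the
  monotone default for anything but replication of published tables.
* No multivariable/confounder adjustment is provided; the screen is
  univariate by design.
* The MWU normal approximation is used at all $n$ in the screens; exact
  enumeration is available only as a small-sample reference, which is the
  regime where the approximation is weakest and also the regime the
  screens never operate in.
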