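---
title: "Evaluating the ROMA index for preoperative adnexal-mass triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the ROMA index for preoperative adnexal-mass triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romadx)
library(dplyr)
```

## The clinical problem

A woman presenting with an adnexal mass should be referred to a
gynecologic-oncology centre *before* surgery if the mass is likely to be an
epithelial ovarian cancer (EOC): initial surgery by a specialist —
complete staging in early disease, optimal debulking in advanced disease —
is the single most consequential step in management. Serum CA125 alone
triages poorly: it is elevated in under half of early-stage cancers and in
many benign gynecologic conditions. The Risk of Ovarian Malignancy
Algorithm (ROMA) combines CA125 with HE4, a second serum marker that is
more specific for EOC, into a single probability-like percentage with
menopause-specific weights.

`romadx` implements the complete evaluation pipeline for this setting:
scoring, cutoff optimization, and a full diagnostic-test report, stratified
by menopausal status and by tumour stage, together with a calibrated
synthetic-cohort generator so the whole pipeline is testable without
patient-level data.

## The model

For each patient the predictive index (PI) is a linear combination of the
natural logarithms of the two markers, with coefficients depending on
menopausal status:

$$
PI_{\mathrm{pre}} = -12.0 + 2.38\,\ln(\mathrm{HE4}) + 0.0626\,\ln(\mathrm{CA125})
$$
$$
PI_{\mathrm{post}} = -8.09 + 1.04\,\ln(\mathrm{HE4}) + 0.732\,\ln(\mathrm{CA125})
$$

and the ROMA percentage is the logistic transform

$$
\mathrm{ROMA}(\%) = 100 \cdot \frac{e^{PI}}{1 + e^{PI}}.
$$

HE4 enters in pmol/L and CA125 in U/mL, exactly as the assays report them;
no unit conversion is applied. The pre-menopausal formula is dominated by
HE4 (coefficient 2.38 vs 0.0626), the post-menopausal one weights both
markers. `roma_percent()` evaluates the logistic in a piecewise form —
`100/(1 + exp(-pi))` for positive PI, `100*exp(pi)/(1 + exp(pi))`
otherwise — so `exp()` only ever sees non-positive arguments: extreme PI
saturates smoothly to 0 or 100 and never overflows to `NaN`. A practical
precision note: the percentage loses the ability to represent the distance
to 0 or 100 once $|PI|$ exceeds roughly 16, so a logit back-transform
recovers PI to $10^{-9}$ only inside that range. This is irrelevant
clinically (such patients are unambiguous) but matters if you round-trip
scores through files.

```{r score}
simulate_cohort(seed = 42) |>
  score_roma() |>
  select(id, menopausal_status, ca125, he4, pi, roma_percent) |>
  head(4)
```

## Cutoffs

Operating cutoffs are chosen by maximizing Youden's
$J = \mathrm{sensitivity} + \mathrm{specificity} - 1$ over the empirical
ROC curve. Candidate cutoffs are the midpoints between consecutive
distinct observed scores, plus $\pm\infty$ sentinels; a test call is
positive when the score is **greater than or equal to** the cutoff.
Midpoints are used because published cutoffs of this kind (22.5 U/mL for
CA125, 18.3% for ROMA) are interstitial values that do not occur in the
data. Ties in $J$ are broken towards higher specificity, then towards the
lower cutoff, making the optimizer fully deterministic. With all scores
identical the data carry no information and the sentinel cutoff with
$J = 0$ is returned.

The pipeline optimizes cutoffs *per stratum* by default, mirroring the
clinical practice of separate pre- and post-menopausal thresholds; a fixed
named set (`cutoffs = c(ca125 = 22.5, he4 = 73, roma = 18.3)`) can be
supplied instead, in which case the same cutoffs are applied in every
stratum and stratified confusion counts add up to the total ones.

## The metric suite

`evaluate_marker()` reports, from one confusion table: sensitivity,
specificity, PPV, NPV, diagnostic accuracy (all in percent), both
likelihood ratios, the diagnostic odds ratio, and unweighted Cohen's
kappa, each with a 95% confidence interval.

Interval choices, in order of how much they matter:

* **Proportions: Wilson score interval** ($z = 1.96$), obtained by
  inverting the score test. It behaves correctly at the boundaries (the
  interval for 9/9 is (70.1, 100), not a degenerate point), and it is the
  procedure that reproduces, to two decimals, the intervals printed in the
  clinical literature this package's test fixtures are drawn from.
* **Likelihood ratios: Simel log-transform interval**, with
  $\mathrm{SE}(\ln LR^+) = \sqrt{(1-\mathrm{sens})/tp + \mathrm{spec}/fp}$
  and the analogous expression for $LR^-$.
* **Diagnostic odds ratio: log method**, $\mathrm{SE} =
  \sqrt{1/tp + 1/fp + 1/fn + 1/tn}$.
* **Kappa: asymptotic interval**, $\kappa \pm 1.96\,
  \sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$.

Degenerate tables do not raise errors: a zero denominator yields a row
tagged `undefined (...)` in the `method` column (with $LR^+$ and DOR
reported as `+Inf` when $fp$ or $fn$ is zero), so stratified batch runs
always complete — post-menopausal subgroups with perfect specificity are
exactly where this happens in practice. An optional 0.5 continuity
correction for the DOR is available but off by default.

All computation is done on unrounded proportions; rounding to one decimal
happens only in report rendering (`metrics.tsv`), while `report.json`
carries full precision. On this point one published quirk is worth
documenting: a table in the source literature prints a diagnostic odds
ratio of 78.6 where the exact value of $(32 \cdot 54)/(2 \cdot 11)$ is
78.545; the package always reports the exact value.

```{r metrics}
as_confusion(tp = 32, fp = 2, fn = 11, tn = 54) |> sensitivity()
```

## ROC and AUC

The empirical ROC curve has one operating point per distinct observed
score plus the two trivial endpoints; tied scores across classes produce a
single point with a fractional step on both axes. The AUC is computed as
the Mann-Whitney U statistic divided by $n_1 n_0$ with ties counted one
half — identically the probability that a random malignant case outscores
a random benign one, and exactly the trapezoidal area under the curve.
The default confidence interval is Hanley–McNeil (closed form,
desk-checkable); a DeLong structural-component interval is available via
`ci = "delong"`. Paired AUC comparisons (`compare_auc()`) use the DeLong
test, with an optional seeded stratified-bootstrap percentile interval for
the difference. Both AUC and maximal $J$ are invariant under strictly
monotone transforms of the scores; cutoffs of course are not.

## Baseline group comparisons

`baseline_summary()` reproduces the usual "Table 1/Table 2" machinery:
Mann-Whitney for continuous or ordinal variables (exact null distribution
when there are no ties and $mn \le 400$, tie-corrected
continuity-corrected normal approximation otherwise), and for binary
flags an **uncorrected** Pearson chi-square, switching to the Fisher exact
test when any expected cell count falls below 5. The chi-square is
uncorrected by default deliberately: clinical papers in this literature
report uncorrected values (the abdominal-distension comparison used in the
tests prints p = 0.001, which only the uncorrected statistic reproduces;
Yates gives 0.002). Fisher's two-sided p sums the probabilities of all
tables no more probable than the observed one — the probability-mass rule;
the doubling rule, which some software uses, gives different values.
Displayed p-values are floored at "< 0.001" by `format_p()`.

## The synthetic cohort generator

No patient-level data accompany the study design this package targets, so
`simulate_cohort()` generates cohorts with the group-level structure the
analysis assumes. What it emulates, with defaults calibrated to the
published 99-patient series (56 benign / 43 malignant):

* **Marker marginals**: truncated log-normals per (marker, pathology)
  group. `meanlog = log(median)` reproduces the published group medians
  (CA125 17/121 U/mL, HE4 47/114 pmol/L) exactly as distribution medians —
  medians are prioritized over means/SDs because every downstream metric
  is rank-based, and a two-parameter family cannot match mean, SD and
  median of these heavily right-skewed data simultaneously.
  `sdlog = (log(max) - log(min))/4.5` places the published extremes at
  about $\pm 2.25$ SD, where the extremes of a sample of ~50 are expected;
  truncation is at $\pm 3$ SD in log space (the central 99.7% band). For
  benign HE4 the published median (47) sits far off-centre in the
  published range (5–97) on the log scale, so its `sdlog` is enlarged to
  the minimum that keeps the whole published range inside the truncation
  band.
* **Correlation**: one shared log-scale correlation `rho = 0.3` between
  the markers within each group — the source literature provides no
  correlation information, and a moderate positive value reflects that
  both markers rise with tumour burden. Out-of-band draws are rejected and
  redrawn, preserving the correlation structure.
* **Menopause**: Bernoulli per pathology group (9/56 benign, 22/43
  malignant), independent of the markers.
* **Stage** (malignant only): categorical with probabilities
  $(4, 8, 22, 9)/43$ over FIGO 1–4.
* **Age and symptom flags**: truncated normal ages (39 ± 14 benign,
  51 ± 16 malignant, bounded to 17–79) and independent Bernoulli symptom
  flags at the published group rates, for exercising the baseline module.

What it deliberately does **not** emulate: any dependence of the marker
distributions on menopausal status (only pathology-conditional marginals
are published), the true inter-marker correlation, or the patient-level
scores behind the published AUCs and Youden cutoffs. Consequently a
passing pipeline on synthetic data demonstrates that the machinery is
correct and that the default design is *consistent* with the published
discrimination (the replicate-mean ROMA AUC lands in a 0.80–0.97 band
around the published 0.907), not that it reproduces the published AUCs,
cutoff values, or the AUC-comparison p-value — those require the
unpublished raw data and are not asserted anywhere.

Monte-Carlo problem sizes used in the test suite are chosen to keep
tolerances honest: medians are checked at $10^4$ draws per group against
3–5 median-standard-error bands, log-normal parameter recovery at $10^5$
draws within 2% (the $\pm 3$ SD truncation itself shrinks the sample SD
by about 1.3%, inside that band), and the replicate study runs 200 seeded
cohorts at the published group sizes.

## The analysis driver

```{r pipeline}
report <- simulate_cohort(seed = 42) |>
  run_roma_analysis(seed = 42)
report$auc
```

`run_roma_analysis()` evaluates every marker in the total, pre- and
post-menopausal strata, and ROMA additionally in the early-stage (FIGO
1–2) and advanced-stage (FIGO 3–4) strata, where the malignant subset of
the requested stages is compared against **all** benign records as the
negative class, at the ROMA cutoff of the total stratum. Any failure is
re-raised with the stratum and marker attached. `write_report()`
serializes the bundle — unrounded JSON plus display-rounded TSVs with a
run log carrying the seed, a configuration hash and the package version,
and no timestamps — so identical inputs give byte-identical bundles; the
rounded `metrics.tsv` can be re-derived from `report.json` alone.

```{r tidy}
tidy(report) |> filter(stratum == "total", marker == "roma") |> head(5)
glance(report)
```

## Known limitations

* Single coefficient set as printed above; assay-specific ROMA
  recalibrations are out of scope.
* Binary outcome only (benign vs malignant EOC); borderline and
  non-epithelial pathology are assumed excluded upstream.
* Predictive values are at study prevalence; no adjustment to external
  prevalences.
* The HE4 unit is assumed pmol/L (standard for the HE4 EIA); the
  formulas are applied to values as entered.
* Published likelihood-ratio and kappa intervals in this literature do
  not always match the standard Simel/asymptotic formulas and the
  generating procedures are unnamed; this package's intervals are the
  standard ones, and only point estimates should be compared against such
  tables.
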