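---
title: "Circulating lncRNA panels and risk-score classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circulating lncRNA panels and risk-score classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaLncDx)
```

## The problem

Circulating long non-coding RNAs (lncRNAs) in plasma are candidate
non-invasive markers for hepatocellular carcinoma (HCC): a small panel of
transcripts elevated in patient plasma, falling after tumour resection, can
support diagnosis without biopsy, and a subset tracking metastatic disease
can flag progression risk. The canonical study design is multiphase:

1. **Screening** — a small microarray comparison (a handful of patients,
   sampled before and one month after resection, plus matched controls)
   reduces the transcriptome to a candidate list via differential tests and
   fold/intensity filters.
2. **Training** — qPCR measurement of the candidates in a fresh 20-case /
   20-control set reduces them to the final panel and fits a classifier.
3. **Validation** — the *frozen* classifier is applied to a larger
   independent set (here 147 cases vs 180 controls by default).
4. **Double-blind** — a further set (50 vs 50) is classified with analysts
   blinded to diagnosis; only accuracy is reported.
5. **Metastasis** — the same construction, retrained on metastatic vs
   non-metastatic patients for the metastasis-linked markers.
6. **Post-operative dynamics** — paired pre/post levels per patient; a
   *secondary increase* (post-operative level above pre-operative) is
   tested for association with metastasis.

`plasmaLncDx` implements every stage as an exported function and ties them
together in `runStudy()`, with a synthetic cohort generator so the whole
design is exercisable and testable without any external data.

## The risk score function

The classifier is deliberately simple and auditable. For each panel marker
$k$ a *positivity threshold* $t_k$ is placed at an upper percentile
(default the 95th) of the control expression distribution, and a
non-negative weight $w_k$ is fitted. A sample with levels $x_1, \dots,
x_K$ scores

$$ s(x) \;=\; \sum_{k=1}^{K} w_k \, \mathbf{1}[x_k > t_k], $$

so $s \in [0, \sum_k w_k]$, and the sample is called **high risk** when
$s$ exceeds a global cutoff $c$. Published panels of this family print
their score bins as $[0, c]$ / $[c, \sum w_k]$; with the midpoint rule
$c = \tfrac12 \sum_k w_k$ the two-marker bin boundary 3.214 of a 6.428
range is reproduced exactly (`chooseCutoff(method = "midpoint")`), and a
14.89 range halves to 7.445, consistent within rounding with a published
7.449. The default cutoff rule is instead data-driven: the Youden
criterion, maximising sensitivity + specificity over midpoints between
adjacent distinct observed scores.

Design choices that the published description leaves open are fixed and
documented here:

* **Weights.** Default: per-marker univariate logistic regression of class
  on the positivity indicator, floored at zero so the score stays monotone
  in positivity. Under complete separation (a zero cell in the 2×2
  indicator-by-class table, where the logistic MLE diverges — common when
  a marker is nearly perfect) the marker's weight falls back to its
  absolute mean log2 fold, with a warning and a provenance record.
  `"log2fc"` and `"unit"` weights are available; with unit weights the
  score is simply the count of positive markers.
* **Boundary.** A score exactly equal to the cutoff is **low** risk. The
  printed bins share the boundary value, so the rule must be fixed
  somewhere; classification is strict (`score > cutoff`) throughout.
* **Quantiles.** Thresholds interpolate linearly between order statistics
  (`stats::quantile` type 7). Quantile conventions differ across
  ecosystems; fixing one makes thresholds reproducible. The illustrative
  check: controls at levels $1..100$ give a 95th-percentile threshold of
  exactly 95.05.
* **Cutoff ties.** When several candidate cutoffs achieve the maximal
  Youden index (within $10^{-9}$, absorbing floating-point noise in the
  sensitivity/specificity sums), the smallest is returned.

## ROC conventions

`rocCurve()` sweeps the distinct observed scores from high to low, one
vertex per threshold, grouping tied scores into a single diagonal segment
(half credit). With that convention the trapezoidal area is *identically*
the Mann–Whitney pair-counting AUC — the probability a random case
outscores a random control, ties at half — which `aucMannWhitney()`
computes independently by brute-force pair enumeration. The test suite
asserts the identity to $10^{-12}$ on a thousand randomly tied instances;
`pROC` agrees on continuous scores and serves as an external cross-check.
Higher score = more case-like is fixed; per-marker ROC uses the raw
expression level as the score, the merged-panel ROC uses the risk score.

## Screening statistics

Differential tests are Student $t$ tests on log2 values (Welch optional):
unpaired for case vs control, paired on per-patient differences for
pre- vs post-operative comparisons, with orphaned patients rejected.
Fold change is $2^{|\Delta \text{mean log2}|}$ — the ratio of geometric
means — because the analysis scale is logarithmic; the same convention
defines the training filter's "mean fold change". No multiple-testing
correction is applied by default, matching the published procedure of
filtering at raw $p < 0.05$; this is statistically generous at the
screening stage, which is why the downstream qPCR training filter, the
frozen-model validation and the double-blind phase exist. The candidate
filter keeps transcripts with case-group mean log2 intensity ≥ 5 ("high
signal") and fold ≥ 2 in *every* comparison; the intensity criterion is
applied to the case group, the natural reading when markers are
case-elevated. Zero-variance degenerate inputs are handled explicitly: a
comparison with identical groups reports $p = 1$ and direction `none`; an
exactly constant non-zero difference reports $p = 0$ (below any
reportable floor). `-log10(p)` in `volcanoTable()` is capped at 300,
double precision's practical limit.

## The synthetic cohort generator

`generateCohort()` draws the statistical structure the analysis assumes —
it is the package's test bed, not a microarray simulator. On the log2
scale each transcript gets a background mean from
$N(\mu_0, \sigma_0^2)$ (defaults $\mu_0 = 6$, $\sigma_0 = 1.5$, typical
of log2 microarray intensity ranges) and each measurement adds
$N(0, \sigma^2)$ noise ($\sigma = 0.5$ by default, a realistic
plasma-qPCR replicate spread). The first `nMarkers` transcripts are the
planted biomarkers:

| parameter | default | meaning |
|---|---|---|
| `caseEffect` | 2 | log2 elevation, pre-op HCC vs control |
| `resectionEffect` | 2 | log2 drop, post-op vs pre-op (resolving patients) |
| `metastasisEffect` | 1.5 | extra log2 elevation in metastatic cases, metastasis-linked markers |
| `secondaryRiseFraction` | 0.8 | metastatic patients whose markers *rise* post-op |
| `riseEffect` | 1 | log2 magnitude of that rise |
| `metFraction` | 0.5 | metastatic share of HCC patients (fixed count per phase cell) |

The defaults are the study conditions: phase sizes replicate the design
(screening 3 HCC + 3 paired post-op + 3 controls; training 20/20;
validation 147/180; double-blind 50/50; metastasis splits 20/20 and
79/78 drawn from the pooled patients), `metFraction` reflects the roughly
half-and-half metastasis split of such cohorts, and 3 markers are planted
of which the last 2 carry the metastasis effect, mirroring a 3-marker
panel with 2 metastasis indicators. qPCR output is $2^{\text{log2}}$
(strictly positive linear relative levels, already normalised — the
published assays name no endogenous plasma reference, so normalisation is
left upstream of this package); array output stays on the log2 scale.

Choices worth flagging:

* **Screening patients are "resolved".** The discovery set emulates
  patients whose resection removed the tumour: metastasis status unknown,
  no secondary rise. A discovery comparison contaminated by rising
  post-operative levels would not have produced a down-after-resection
  candidate list in the first place.
* **Secondary rises** are confined to metastatic patients by default
  (`nonMetRiseFraction = 0` allows a leak), so the post-operative
  association is planted but, through `secondaryRiseFraction` < 1 and
  measurement noise, not forced to be perfect. The rise magnitude
  (`riseEffect = 1`) is the package's choice — large enough that a true
  riser is usually flagged at the default `riseMargin = 0`, small
  relative to `resectionEffect` so the two regimes are asymmetric, as
  observed dynamics are.
* **Metastasis counts are designed, not sampled**: each HCC phase cell
  gets exactly `round(metFraction · n)` metastatic patients, as in a
  designed case-control split, so requested metastasis training and
  validation splits are always satisfiable.
* Generation is a pure function of the configuration (seeded, with the
  caller's RNG stream restored), and the two platforms use disjoint seed
  streams.

What the generator does **not** emulate: probe-level array artefacts
(background, dye bias), qPCR amplification-efficiency variation,
between-patient effect-size heterogeneity, and correlated markers
(markers are conditionally independent given group). Passing tests
therefore show the *procedures* are correct and well calibrated under the
assumed signal structure — not that any particular panel will perform
comparably on real plasma.

## Patient-level aggregation in the post-operative analysis

A patient counts as a secondary-increase *riser* when at least
`minMarkers` (default 2 of the 3-marker panel) individual markers rose.
Marker-level flags use `log2(post/pre) > riseMargin` with
`riseMargin = 0` — any increase counts — because the published
description does not define the aggregation; the margin is configurable
since a strict > 0 rule is fragile under noise. The riser-by-metastasis
2×2 table is tested with both the Pearson chi-square (no continuity
correction) and Fisher's exact test; Fisher is authoritative at the small
counts involved, and the perfectly concordant 10+10 table reproduces the
hypergeometric value $2/\binom{20}{10}$ exactly.

## Problem sizes used in the checks

The package's own verification runs at the design sizes where those are
informative and at reduced sizes where a smaller problem demonstrates the
same property: the parameter-recovery surface runs 100 seeded cohorts at
the full phase sizes over the 13-candidate qPCR stage; null calibration
uses 1,500 null transcripts for the rejection-rate check and 50 seeded
cohorts for the chance-level AUC band; the screening-funnel property runs
at 10 patients per arm, because the 3-patient paired design has roughly
55% per-marker power at the simulated effect ($\delta = 2$,
$\sigma = 0.5$) and would demonstrate sample-size limitation rather than
funnel correctness — the 3/3/3 cell remains the default study design.
Oracle equivalences (trapezoid vs Mann–Whitney, Youden vs exhaustive
scan) run on 1,000 random instances each.

## Known limitations

* The published risk-score construction is described only by reference;
  the indicator-threshold-weight form implemented here is the standard
  construction of this literature and is consistent with the printed
  score ranges, but the original weights are unrecoverable, so published
  AUCs and contingency tables are reproduced structurally (bin
  arithmetic, predictive-value arithmetic), not numerically.
* Markers are treated univariately throughout (per-marker thresholds and
  weights); no joint logistic model, regularisation or survival analysis.
* The screening stage at 3 patients per arm is faithful to the design but
  statistically fragile; users simulating their own designs should expect
  partial candidate recovery there and treat the qPCR training filter as
  the effective selector.

## A worked run

```{r, eval = FALSE}
# qPCR phases over the 13 screened candidates, as in the study's
# training/validation/double-blind stages
gs <- subset(defaultGroupSizes(), phase != "screening")
cfg <- cohortConfig(nTranscripts = 13, groupSizes = gs, seed = 1)
report <- runStudy(studyConfig(cohort = cfg, seed = 1))
report
writeStudyReport(report, "study_report")
```
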