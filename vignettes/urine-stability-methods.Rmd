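---
title: "Methods: screening the urine metabolome for collection-condition instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening the urine metabolome for collection-condition instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urostab)
```

## The problem

Urine collected for metabolomics is rarely frozen the moment it leaves
the donor. During collection and bench storage two processes change its
composition: **bacterial overgrowth** (commensal skin and gut flora
carried by the urine stream metabolise sugars, amino acids and
nucleosides once the sample sits at room temperature) and **chemical
instability** (some metabolites, such as ascorbic acid, degrade in
solution regardless of microbial activity). The two have different
remedies — preservatives stop bacteria but not chemistry; cold slows
both — so a stability screen must not only find time-dependent
metabolites but attribute the dependence to one of the two mechanisms.

`urostab` implements an LC-MS screen for this attribution. The
experimental design it targets stores pooled urine (pooling removes
inter-individual variation) under three conditions — room temperature
(`RT`), 4 °C (`C4`), and room temperature with boric-acid preservative
(`Pres`) — sampled in triplicate between 0 and 72 h, in two independent
experiments measured in positive and negative electrospray mode, with a
pooled-urine quality-control (QC) sample injected every 10 study
injections and blanks at the start of each run.

The attribution logic is a significance pattern over conditions: a
metabolite whose intensity correlates with storage duration **only at
RT** is attributed to bacterial overgrowth (bacteria grow neither at
4 °C nor with preservative), whereas correlation at RT **and** at 4 °C
and/or with preservative indicates chemical instability.

## Pipeline stages

### Drift correction

Electrospray response decays over a run. For each feature a loess model
(local quadratic, tricube weights) of intensity versus injection order
is fitted to the QC injections only, and every injection's intensity is
divided by the model prediction at its order; corrected intensities are
then relative to the QC level (QC values average 1). Features whose QC
model produces a non-positive prediction fall back to division by the
feature median, and a whole block falls back when the QC model is
judged non-representative (the median QC CV fails to decrease, or more
than 10 % of features have non-positive predictions).

Numerical choices worth stating:

* **Span** defaults to 0.75 (the conventional loess default; the value
  is a free parameter of the method and is echoed in the report).
  Because the tricube weight of the farthest point in a window is
  exactly zero, the span is floored at `(degree + 3) / n_qc` so the
  local quadratic never becomes rank-deficient when a run contains few
  QCs.
* **Extrapolation** beyond the first/last QC order is clamped to the
  nearest QC-range prediction; the generator therefore anchors each run
  with a QC before the first and after the last study injection, which
  is also standard acquisition practice.
* Predictions use the direct (non-interpolated) loess surface, so an
  exactly quadratic drift is removed to machine precision — this is the
  package's primary correctness oracle.

With only 7–9 QCs per run the loess absorbs an appreciable share of the
QC noise itself; post-correction QC CVs are therefore optimistic, and
the per-feature correction error is a smooth function of order that the
downstream injection-order filter will flag in some features. Both
effects shrink as runs get longer (real studies have tens of QCs).

After correction the blocks (experiment × ion mode) are multiplied by a
**common factor**: the geometric mean of the block raw-intensity
medians. The alternative reading — per-block factors equalising the
medians — is available via `block_scale(mode = "per_block")`; the choice
is immaterial for every downstream statistic (rank tests and
unit-variance scaling are invariant to it), which is why a single
common factor, the more literal reading, is the default.

### Filtering

* **Injection-order filter**: features still Spearman-correlated with
  order after correction are discarded at BH `q < 0.05` (the threshold
  is a package choice; only the outcome, a few percent of features
  discarded, is reported by the original protocol).
* **Blank filter**: a feature is kept unless its *raw* QC mean is less
  than twice its raw blank mean (strict inequality at the boundary).
* **QC repeatability filter**: features with QC CV above 30 % on the
  corrected intensities are removed (strict inequality; sample-SD
  convention, fixed because QC counts are small). Whether the original
  protocol computed this on raw or corrected intensities is not stated;
  corrected is the default here and raw is a one-line change
  (`cv_filter` on the raw table).
* **Outlier observations**: the cited quantile-based outlier procedure
  is not fully specified in the protocol, so the package implements an
  explicit stand-in: per study injection, the deciles of its log10
  intensity distribution are compared by robust z-score (median/MAD) to
  the same deciles of the *other injections of the same condition*, the
  statistic is the maximum |z| over deciles, and the p-value is a
  Student-t tail (degrees of freedom = reference size, acknowledging
  the estimated MAD) Bonferroni-corrected over deciles, thresholded at
  10^-3. The within-condition reference matters: a preservative shifts
  the ionisation of a whole arm coherently, and against a pooled
  reference the entire arm would read as outliers.

### Univariate screen and onset times

Within each condition of each block, each feature's intensity is
correlated with storage duration by Spearman rank correlation
(replicates pooled; p from the t-approximation, with the exact
permutation bound `2/n!` when |rho| = 1), and BH-adjusted across the
features of that block × condition at FDR 0.01 — the family is per
condition because each condition is tested as its own hypothesis
family. A feature with zero rank variance is reported non-significant.

The **onset time** of a significant trend is the first time point at
which all replicates lie beyond the *full* T0 replicate range (above
the T0 maximum for positive trends, below the T0 minimum for negative
ones) — the strictest reading of "triplicates all above/below T0",
chosen because it is deterministic and conservative. A known blind
spot, inherited from the rank screen itself: a step-like change (a
metabolite falling to zero at the first sampled time point) produces
many ties and can fail the correlation test even though the change is
real; the screen documents rather than patches this.

### Multivariate modelling

Study intensities are log10-transformed (zeros replaced by half the
feature's smallest positive value), mean-centred and unit-variance
scaled. PCA (by SVD, explained variance per component = squared
singular value over total) gives the unsupervised overview; a
two-component PLS1 (NIPALS with deflation) regresses storage duration
on the matrix. Model quality is `Q2 = 1 - PRESS/TSS` under
venetian-blind 7-fold cross-validation (observations dealt into folds
in sorted-response order — deterministic, and standard in metabolomics
software since the response is a designed time variable); significance
comes from comparing the observed Q2 with the Q2 of `n_perm = 1000`
response-permuted models, with the +1-smoothed p-value
`(1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)`. Variable influence is
the standard VIP score (mean squared VIP = 1 by construction), and the
univariate/multivariate agreement is summarised as the overlap fraction
between the top-k VIPs and the k smallest RT p-values.

Sign conventions are fixed (each PCA loading's largest-magnitude
element is positive) so outputs are reproducible across platforms.
Within cross-validation folds the training submatrix is re-centred but
not re-scaled; the matrix is already globally unit-variance scaled and
re-scaling near-constant training columns would be numerically fragile.

### Robust selection and classification

Because two independent experiments are available, a metabolite enters
the final list only if its RT correlation is significant **with the
same sign in every experiment where it was measured** and its 4 °C
significance **status** (significant vs not — not the rho value, since
only the status is dichotomised downstream) agrees across experiments;
metabolites measured in a single experiment are judged on it alone, and
preservative-arm discordance never blocks selection (not every
experiment has that arm). Metabolites failing robustness but judged
interesting can only enter through an explicit allow-list — never
automatically.

Classification is then a pure function of the per-condition
significance pattern (2^3 patterns × signs, exhaustively tested):
RT-only → bacterial; RT plus C4 and/or Pres → chemical; everything
else → `stable_or_indeterminate` with an explicit reason. Conflicting
trend signs between conditions or experiments — a case the original
protocol does not discuss — are deliberately flagged indeterminate
rather than resolved by any precedence rule.

## The synthetic-data generator

No public feature tables accompany the design at desk scale, so the
package ships a generator (`simulate_study()`) whose defaults *are* the
study conditions, and a ground-truth ledger that every downstream test
reads back.

* **Design**: Exp. 1 = RT and 4 °C at 0, 4, 8, 12, 24, 36, 48, 60, 72 h;
  Exp. 2 = RT, 4 °C and Pres at 0, 12, 24, 36, 48, 60, 72 h; triplicates;
  one QC before every 10 study injections plus a closing QC; three
  leading blanks; two ionisation modes with independent feature panels
  (as in real acquisitions) shared across experiments (so per-metabolite
  evidence combines between experiments).
* **Intensities**: per-feature baselines log-uniform over three
  decades; m/z uniform in 75–1000 Th; retention times uniform over a
  19-minute gradient; multiplicative log-normal noise with CV 0.10 for
  study samples and half that for the pooled QC (a single vial
  re-injected is more repeatable than independently prepared aliquots).
* **Drift**: multiplicative, monotone quadratic-plus-linear in
  injection order with amplitude 0.20 (0.30 in the oracle tests). A
  quadratic truth makes the local-quadratic correction exactly
  attainable, which turns the corrector into a testable oracle rather
  than an approximation.
* **Planted effects**: 12 bacterial and 7 chemical metabolites per
  panel at a 3-fold 72-h RT effect with random direction. Bacterial
  effects ramp with the *normalised logistic growth curve* at RT only;
  chemical effects ramp linearly with time at RT and Pres and at half
  amplitude at 4 °C. Pres samples additionally carry a global ×0.8
  ionisation shift, emulating the effect of boric acid on electrospray
  yields.
* **Growth curves** (OD620): logistic, with invented parameters — the
  reference design reports growth only graphically. Exp. 1 uses
  midpoint 16 h / rate 0.15 h^-1, Exp. 2 midpoint 48 h / rate
  0.12 h^-1, so overgrowth is visible from ~12 h in Exp. 1 and delayed
  to ~48 h in Exp. 2. The rates are deliberately slow enough that the
  logistic rise spans several sampling points: a culture that saturates
  between two consecutive collections turns most of the time course
  into rank ties, which caps the Spearman correlation of genuinely
  affected metabolites near 0.8 regardless of effect size. This is a
  property of rank statistics on plateaued kinetics, not of the
  generator; with the chosen rates ≥ 90 % of planted features exceed
  rho 0.8 at the 2-fold/10 %-noise boundary.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: chromatographic peak
shapes and integration error, correlated features (adducts, isotopes,
in-source fragments of one metabolite), missing values, retention-time
drift, inter-batch effects beyond smooth intensity drift, matrix
effects that vary per metabolite, and step-like concentration changes.
Recovery rates on this generator are an upper bound for real studies.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a single CPU:
drift oracles run on 100-feature tables; statistical calibration uses
1000 random oracle instances, 100–300 null screens of 1000 features
each, and 200 permutation-test repetitions at 99 permutations; the
end-to-end recovery runs the full two-experiment design at 300 features
per panel with 999 permutations for the PLS significance test. The
same code scales to real peak-table sizes (10^3–10^4 features) with
runtimes dominated by the per-feature loess fits and the permutation
loop.

## Known limitations

* The spectral library shipped under `inst/extdata/` is synthetic
  (plausible metabolite names and approximate monoisotopic ion masses,
  invented retention times); it demonstrates the annotation machinery
  and must be replaced by a curated library for real use.
* The outlier-observation screen is a stand-in construction; it targets
  gross acquisition failures, not subtle multivariate outliers.
* Onset times inherit the conservatism of the strict min/max rule: one
  aberrant T0 replicate inflates the T0 range and delays every onset.
* With few QCs per run, drift correction both under-reports the
  post-correction QC CV and inflates the injection-order filter's
  discard rate; both effects are small for runs with ≥ 20 QCs.
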