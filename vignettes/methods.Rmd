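---
title: "Compositional analysis of 24-hour time use: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour time use: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## The problem

A day has exactly 1440 minutes. When children's time is partitioned into
activity-intensity behaviours (sedentary, light physical activity, MVPA,
sleep) or activity-type postures (sitting, standing, walking, running,
lying), the parts are not free to vary independently: more of one
behaviour necessarily means less of another. Treating such data with
ordinary multivariate statistics ignores this constant-sum constraint and
produces spurious negative correlations. `coda24` therefore works in
Aitchison geometry: a daily record is a *composition* — a vector carrying
only relative information, closed to the constant $\kappa = 1440$ min —
and every statistic is computed on log-ratio coordinates.

## Model and procedure

**Closure and log-ratios.** `closure(x, kappa)` rescales non-negative
minutes to sum to $\kappa$. The centred log-ratio is
$\mathrm{clr}(x) = \ln x - \overline{\ln x}$; the isometric log-ratio
(ilr) transform maps a $D$-part composition to $D-1$ orthonormal real
coordinates $z = \Psi^\top \mathrm{clr}(x)$, where $\Psi$ is a
$D \times (D-1)$ contrast matrix with orthonormal, zero-sum columns.
Because no conventional choice of $\Psi$ is singled out by the analysis —
all the test statistics used here are invariant to it, which the test
suite verifies to $10^{-9}$ — the package defaults to the standard pivot
(balance) basis from `pivot_basis()`, with parts in the order sedentary,
LPA, MVPA, sleep (intensity) and sitting, standing, walking, running,
lying (type).

**Descriptives.** The centre of a compositional sample is the closed
vector of per-part geometric means (`compositional_mean()`); dispersion
is the variation array (`variation_array()`): means and $n-1$ variances
of all pairwise log-ratios $\ln(x_i/x_j)$.

**Zero and missing imputation.** A day on which no 5-second epoch was
classified as running yields a structural-looking zero that is really a
rounded (left-censored) value. `lr_em_impute()` treats observed zeros as
censored below a per-part detection limit and missing entries as fully
missing, and runs expectation-maximisation on additive log-ratio
coordinates: the M-step re-estimates the mean and covariance of the alr
vector; the E-step replaces each missing coordinate by its conditional
Gaussian expectation given the row's observed coordinates, and each
censored coordinate by the corresponding truncated-normal expectation
(truncated above at the limit), so imputed zeros always land strictly
inside $(0, \delta)$. Observed parts are never altered except by the
final re-closure, so within-row ratios of observed parts are preserved.
Defaults: detection limit $\delta = 1/12$ min (one 5-s epoch), tolerance
$10^{-6}$ on successive imputed log values, at most 200 iterations, with
a warning (never silent acceptance) on non-convergence. Log arguments
below $10^{-12}$ raise an error rather than being clamped.

**Group comparison.** For each sociodemographic factor separately (no
covariate adjustment), the ilr coordinates enter a one-factor MANOVA;
`compositional_manova()` reports Pillai's trace, its standard F
approximation with hypothesis/error degrees of freedom, the p-value, and
partial eta squared defined as $\eta_p^2 = \mathrm{Pillai}/s$ with
$s = \min(\text{levels}-1, D-1)$ — for a two-level factor this makes
$\eta_p^2$ equal Pillai's trace exactly. Factors with more than two
levels get pairwise two-sample Hotelling $T^2$ post-hocs
(`pairwise_hotelling()`) using the pooled covariance,

$$T^2 = \frac{n_1 n_2}{n_1+n_2}\, \bar d^\top S_p^{-1} \bar d, \qquad
F = \frac{n_1+n_2-p-1}{(n_1+n_2-2)\,p}\, T^2,$$

with Holm's step-down adjustment across the pairs of that factor (stable
ordering on raw p, then pair name).

**Per-part contrasts.** `per_part_contrast()` estimates, for each part,
the log-ratio of the comparison group's compositional-mean share to the
reference group's, with percentile bootstrap confidence intervals
obtained by resampling children with replacement within each group, and
back-transforms to percentages via $(\,e^{d}-1)\times 100$. Defaults
`n_boot = 2000`, 95% intervals, child as the resampling unit, and a
mandatory seed: the bootstrap design is not dictated by the analysis
itself, so these are declared package choices.

**Guideline adherence.** `classify_guidelines()` applies the 24-h
Movement Guidelines for 5–13-year-olds: MVPA $\geq 60$ min (the "60+"
phrasing is read inclusively), screen time $< 120$ min (strict, "less
than 2 h"), sleep in $[540, 660]$ min (the "9–11 h" range read with
inclusive bounds; the guideline text does not state boundary handling,
so all three thresholds are configurable). Daily screen time is the
plain average of the reported weekday and weekend values and is missing
if either report is missing; children missing screen time are excluded
listwise from screen and combined analyses, with denominators always
reported explicitly. Associations use Pearson chi-square without
continuity correction — the uncorrected statistic is what reproduces the
published gender-by-MVPA effect size ($V = 0.11$); Fisher's exact test
supplies the p-value whenever an expected cell count drops below 5,
while Cramér's $V = \sqrt{\chi^2 / (n\,(\min(r,c)-1))}$ is always
derived from the Pearson statistic.

## The synthetic cohort generator

The individual-level cohort data behind this kind of study are
restricted, so `generate_cohort()` draws cohorts with the statistical
structure the analysis assumes, making every downstream stage testable:

* **Logistic-normal compositions.** A child's mean composition is the
  reference composition (defaults: the published compositional-mean
  minutes, 448/321/98/573 intensity and 479/155/106/7/694 type)
  perturbed by factor-level effects, plus a Gaussian deviation on ilr
  coordinates; each valid day adds day-level ilr noise and closes to
  1440 exactly. The logistic-normal is the canonical simplex
  distribution and matches the pipeline's own geometry, so
  parameter-recovery tests are directly interpretable.
* **Dispersion.** Between-child covariance is specified through per-part
  clr standard deviations (defaults 0.10/0.12/0.30/0.07 for
  sedentary/LPA/MVPA/sleep; 0.12/0.18/0.18/0.45/0.07 for
  sitting/standing/walking/running/lying): sleep is tightly regulated in
  relative terms while MVPA and running vary several-fold between
  children. The magnitudes were fixed once so that cohort-level
  adherence comes out near the reported rates (~90% of children above
  60 min MVPA, ~60-70% inside the 9-11 h sleep band). Day-to-day noise
  uses the same correlation structure scaled by 1.5 — days vary more
  than child means; no published within-child variance was available,
  so this multiplier is a declared choice recorded here.
* **Planted effects.** By default only gender carries an effect — girls'
  MVPA share multiplied by 0.82 and LPA by 1.06 (intensity), standing
  ×1.20 and running ×0.80 (type) — mirroring the reported −18% MVPA /
  +6% LPA gender contrast. The generator returns the exact per-part
  log-share effects (`truth`) for recovery tests.
* **Valid-day structure.** Seven protocol days, each valid with
  probability 0.7: about 4.9 valid days and 1.4 weekend days per child,
  the cohort's reported wear pattern. Children with no valid day are
  kept in the records and dropped (and counted) by `filter_valid()`.
* **Zeros.** With probability 0.05 per valid day the running part
  records no epochs and rounds to zero (the value falls below the
  1/12-min detection limit), and the day is re-closed — rounding, not
  structural absence.
* **Screen time.** Child-level correlated lognormals for weekday and
  weekend minutes (medians 210 and 250, log-SD 0.6, correlation 0.7 —
  mean daily screen time ≈ 270 min and ≈ 15% of children under 2 h,
  matching the survey's scale), missing entirely for 25% of children.
* **Sociodemographics.** Nine factors with level frequencies matching
  the published cohort description.

What the generator does **not** emulate: raw accelerometer signal
processing (epochs, counts, cut-points, sleep algorithms, wear
detection), classification error in the activity-type model,
non-lognormal screen-time reporting artefacts (digit preference,
censoring at zero), and correlation between sociodemographic factors.
Passing tests therefore demonstrate that the statistical pipeline is
correct under its own model assumptions, not that those assumptions hold
for any particular real cohort.

## Numerical and design notes

* All statistics are computed at full precision; integer minutes and
  one-decimal percentages appear only at the presentation layer (a
  published minutes row summing to 1441 is evidence of exactly this
  convention, and `closure()` re-closes such rows).
* Intensity and type compositions are processed as two independent
  tables throughout; their child sets may differ.
* The ternary-plot confidence region is the $\chi^2_2$ 0.95-quantile
  ellipse of a bivariate normal fitted to the 2-D ilr coordinates of the
  3-part subcomposition, mapped back through the inverse ilr as a
  100-vertex polygon; the construction is a declared choice.
* Plot *data* functions (`gmean_barplot_data()`,
  `ternary_coordinates()`) are the tested surface; rendered figures are
  best-effort because images are not bit-reproducible across backends.
* Simulation-based checks in the test suite use deliberately scaled
  designs chosen once as part of the test design: 1000 null replicates
  at 100 children per group (3 valid days each) for the type-I-error
  calibration of the MANOVA, and 100 replicates at n = 300 with 500
  bootstrap draws for CI coverage of a planted effect.

## Known limitations

* The MANOVA is one factor at a time with no covariate adjustment, and
  no multiplicity adjustment is applied across the many guideline
  contingency tests — both deliberate mirrors of the analysis this
  package operationalises, preserved as-is.
* `lr_em_impute()` requires at least one fully observed part to anchor
  the alr coordinates and at least two observed positive parts per row.
* Percentile bootstrap intervals can undercover for very small groups;
  the coverage property is verified at n = 300.
* Isotemporal substitution, mixed-effects extensions, and Bayesian or
  robust imputation variants are out of scope.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_children = 600, seed = 7)
ch <- generate_cohort(spec)
write_cohort(ch, "cohort_csvs")
files <- read_cohort_files("cohort_csvs")
cohort <- build_cohort(files$profiles, files$intensity_days,
                       files$type_days)

descriptive_table(cohort, "gender")
compositional_manova(cohort, "gender")
per_part_contrast(cohort, "gender", "boy", "girl", n_boot = 2000,
                  seed = 1)
st <- classify_guidelines(cohort)
association_test(st, cohort$gender, "mvpa")
```

The same pipeline is available from a shell through the bundled wrapper:
`Rscript $(Rscript -e 'cat(system.file("cli", "coda24.R", package = "coda24"))') simulate --seed 7 --out-dir out`,
followed by the `describe`, `compare`, `guidelines` and `report`
subcommands.
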