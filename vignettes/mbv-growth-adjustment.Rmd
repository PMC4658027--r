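---
title: "Genomic adjustment of net-energy growth predictions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic adjustment of net-energy growth predictions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(mbvgrowth)
```

## The problem

Feedlot managers group cattle so that a pen reaches a common carcass
composition - in the United States, the USDA low Choice grade, conventionally
identified with 28 % empty body fat (EBF) - after a common time on feed.
Getting that right requires predicting, per animal, the shrunk body weight at
the target fatness (the *adjusted final shrunk body weight*, AFSBW), the days
on feed (DOF) needed to reach it, and the feed the animal will consume on the
way. Body composition is the weak link: the composition of gain varies among
animals in ways that standard animal/diet/environment inputs do not capture.

Commercial SNP panels summarize part of that animal-to-animal genetic
variation as *molecular breeding values* (MBV) - summed allele-substitution
effects trained on a trait (marbling, ribeye area, ADG, carcass weight,
residual feed intake). Two leptin-gene SNPs (UASMS2 and E2FB) carry related
information: the T allele is associated with fatter, the C allele with leaner
carcasses. `mbvgrowth` implements a pipeline that (i) predicts AFSBW by two
routes, (ii) projects growth with a net-energy model, (iii) forms the
differences between the routes, and (iv) asks how much of those differences
the genomic scores explain - together with the model-adequacy and
cross-validation machinery needed to judge the answer, and a calibrated
synthetic-cohort generator so the whole pipeline is testable without the
proprietary feedyard data it emulates.

## Two routes to the weight at target fatness

**Hip-height route** (available at feedyard entry). Hip height HH (cm) and
age (d) give a continuous frame score FS through the Beef Improvement
Federation polynomials (valid between 5 and 21 months of age; the male form
is used for steers), and FS maps linearly to AFSBW:

$$\mathrm{AFSBW_{HH}} = \begin{cases}
40.0\,\mathrm{FS} + 440.0 & \text{bulls}\\
33.4\,\mathrm{FS} + 366.6 & \text{steers}\\
26.7\,\mathrm{FS} + 293.2 & \text{heifers.}
\end{cases}$$

FS is deliberately not clamped to its nominal 1-9 scale: the AFSBW lines are
linear and tolerate out-of-range scores, and clamping would distort the tails
of a population; out-of-range scores are reported once per call instead.

**Carcass-trait route** (available at slaughter, treated as the more accurate
estimate). Fat thickness FT (cm), hot carcass weight HCW (kg), marbling score
MS (2-9) and, when measured, ribeye area REA (cm²) give empty body fat;
`ebf_from_carcass()` selects the richer equation when REA is present and
records which was used. Empty body weight follows from HCW
(EBW = 1.316 HCW + 32.39), and

$$\mathrm{AFSBW_{CT}} = \frac{\mathrm{EBW} + 14.26\,(28 - \mathrm{EBF})}{0.891},$$

where 14.26 kg/% is the weight equivalent of a percentage point of EBF and
0.891 converts empty to shrunk body weight. The 28 % endpoint is a
configurable parameter (`target_ebf`), because the fat content at low Choice
varies with sex and breed type.

```{r}
afsbw_from_carcass(ft_cm = 1.14, hcw_kg = 356, marbling = 4.51,
                   rea_cm2 = 88.3)
```

## The net-energy growth engine

The projection engine is a standard net-energy growth model with a daily
(Euler) step. Its components, each an exported function:

* **Diet energy.** Metabolizable energy ME (Mcal/kg, default 3.2 for a
  high-grain finishing diet) is converted to net energy for maintenance and
  gain by the usual cubic forms; at ME = 3.2 these give NEm = 2.19 and
  NEg = 1.51 Mcal/kg, the conventional anchors for such diets.
* **Maintenance.** NEm required = 0.077 SBW^0.75 Mcal/d, times an exposed
  multiplicative `maintenance_factor` (default 1). Environmental adjustments
  (weather, mud) are deliberately out of scope; the factor is the hook for
  them.
* **Retained energy.** Animals are size-scaled through the equivalent shrunk
  body weight EQSBW = SBW·SRW/AFSBW (standard reference weight SRW = 478 kg
  at 28 % EBF), and RE = 0.0635 (0.891 EQSBW)^0.75 (0.956 ADG)^1.097 Mcal/d,
  with 0.956 converting shrunk to empty-body gain.
* **Gain from intake.** Intake above maintenance yields retained energy at
  NEg; gain is recovered by the *exact algebraic inverse* of the retained
  energy form. We invert analytically rather than using the conventional
  rounded inverse-gain coefficients (13.91, 0.9116, 0.6837) so that the
  forward and backward calculations are mutual inverses to machine precision
  - a property the test suite enforces at 1e-6 - while agreeing with the
  rounded constants to about 0.1 %.
* **Intake.** The default predictor is the empirical form
  DMI = SBW^0.75 (0.2435 NEm − 0.0466 NEm² − 0.0869)/NEm; any function of
  `(sbw, diet)` can be plugged into the projection. An end-BW-driven stub
  (`dmi_end_bw()`, the same empirical form evaluated at final weight with
  NEm fixed at 2.2 Mcal/kg) stands in for intake equations driven by end
  weight.

Three derived quantities close the loop:

* `project_days_on_feed()` simulates forward from the initial shrunk weight
  until AFSBW is met (1-d steps, first day at or above target, 1000-d
  horizon) and reports the integer DOF with mean predicted DMI and ADG.
* `expected_dof()` is the deterministic identity
  eDOF = (AFSBW_CT − iSBW)/oADG using the *observed* gain - it removes
  intake- and gain-prediction error from the days-on-feed estimate.
* `dry_matter_required()` runs the engine backwards: reconstruct the daily
  weight trajectory from observed ADG, and charge each day its maintenance
  intake plus the intake supplying the retained energy of that day's gain.
  The mean daily DMR proxies intake for group-fed animals whose individual
  intake is never recorded. The decomposition
  DMR_day = NEm_req/NEm + RE/NEg holds exactly by construction.

## Difference variables and the genomic adjustment

Treating the carcass route as the accurate one, the per-animal differences

* ΔAFSBW = AFSBW_CT − AFSBW_HH,
* ΔADG = observed − predicted gain (per route),
* ΔDOF = eDOF − projected DOF (per route),
* ΔDMI = DMR − predicted intake (hip-height route)

are what the genomic scores are asked to explain (`add_deltas()`; missing
operands propagate to missing differences, never to zeros). Four adjustment
equations, with the sex indicator a = 0 for steers and 1 for heifers, are
built in as reference coefficient sets (`reference_adjustments()`) and can be
refitted to any cohort (`fit_adjustment()`):

$$\mathrm{AFSBW_{CT}} = (312.8 - 175.9a) + (0.5354 + 0.392a)\,\mathrm{AFSBW_{HH}} + 44.5\,\mathrm{MBV_{REA}}$$

a hip-height/initial-weight form with quadratic HH terms and both the Angus
marbling MBV (−0.257) and the ribeye MBV (39.04), and two dry-matter-required
forms on predicted intake (ribeye MBV effects −0.606 and −0.45 kg/d per
unit). The ribeye-area MBV is the workhorse: one unit is worth 44.5 kg of
AFSBW, which at the population's sex-mean gain of about 1.5 kg/d is roughly
30 extra days on feed for leaner cattle.

`stepwise_ols()` provides the classic forward-entry / backward-elimination
selection on partial-F p-values with entry/stay thresholds defaulting to
0.15/0.15 (the conventional statistical-package default; configurable). Ties
are broken by candidate list order, and mutually exclusive pairs - the
leptin class and the ribeye MBV, which share SNPs and would be collinear -
are enforced so that once one enters the other is never offered. Inference
is classical OLS t/F with no multiple-testing correction; classificatory
effects (sex, the nine-level leptin class) use fixed-effects least squares
with equally weighted least-squares means (`group_effects()`) - a deliberate
simplification of REML mixed models, since no random-effects structure is
required by the analysis.

## Adequacy evaluation and cross-validation

`adequacy()` scores predictions against observations with the mean square
error of prediction and its exact three-way partition

$$\mathrm{MSEP} = (\bar P - \bar O)^2 + (s_P - r\,s_O)^2 + (1 - r^2)\,s_O^2$$

(mean bias, systematic/slope bias, random error), the root RMSEP, Pearson
r², Lin's concordance correlation coefficient
CCC = 2 cov(O,P)/(s_O² + s_P² + (mean(O) − mean(P))²) and its accuracy component
Cb = CCC/r. Moments are population (divide-by-n) precisely so the three
components sum to MSEP exactly; the identities (partition; CCC = r·Cb;
|CCC| ≤ |r| ≤ 1) are fuzz-tested. Because "mean bias" is reported in the
literature both as a signed difference and as a squared component, both are
returned, labelled `mean_diff` and `mean_bias`.

`cross_validate()` repeats a random 2-fold split: a training half of
`train_n` rows (default half the cohort, e.g. 750 of 1499) and a testing
half; the model is fitted on each half and scored on the other, the two
folds averaged weighted by test-fold size - one value per replicate - and
the 2.5 %/97.5 % quantiles (type-7 linear interpolation, fixed) reported
over replicates. A single seed makes the whole stream reproducible;
replicates with singular fits are skipped and counted. The default replicate
count is 1000; the package's own tests and the acceptance script use 200,
which leaves the quantile estimates' Monte-Carlo error well below the width
of the intervals being checked.

## The synthetic cohort generator

The generator (`cohort_spec()`, `generate_cohort()`) emulates the commercial
feedyard population the analysis was designed around: 681 crossbred heifers
and 836 steers placed in spring, with per-sex means, SDs and ranges for
initial shrunk weight, hip height, final weight, days on feed, ADG, carcass
traits and the eleven MBV scores, plus per-sex leptin genotype frequencies.
Only means/SDs/ranges and a set of pairwise correlations are available for
that population, so a Gaussian copula with truncated-normal marginals is the
natural choice: correlated standard normals are transformed per sex to each
trait's truncated marginal; marbling is discretized to whole scores on its
observed 3-9 range; genotypes are drawn independently per SNP from the
per-sex frequencies.

Structural choices worth knowing:

* The MBV-phenotype correlation block is fully specified; among phenotypes
  only final BW-HCW (0.95) and fat thickness-marbling (0.35) are defaulted
  non-zero, because the source population's full phenotype correlation
  matrix is not published. The resulting default matrix is slightly
  non-positive-definite (smallest eigenvalue about −0.015) and is repaired
  by eigenvalue clipping with a warning; the repair and the truncation
  attenuate target correlations by a few hundredths (e.g. the REA-MBV_REA
  target of 0.370 realizes near 0.35).
* Final weight, gain and days on feed are drawn as marginals; the generator
  reproduces their distributions and correlations, *not* the accounting
  identity finalBW = iSBW + ADG·DOF. Tests passing on generated cohorts
  therefore validate the statistical machinery, not day-level bookkeeping of
  real pens.
* Genotypes are independent of the MBVs by default; an optional coupling
  (`leptin_coupling`) raises the ribeye MBV of the UASMS2-CC/E2FB-CC class,
  mimicking the association expected when the leptin SNPs sit inside the
  ribeye panel.
* A *generating truth* embeds one of the adjustment equations: the response
  is its mean function plus Normal noise (residual SD defaulting to the
  reference fit's RMSE, 51.3 kg for the AFSBW form), and hidden `truth_*`
  columns plus `truth_report()` expose the exact generating coefficients for
  parameter-recovery checks. For the intake-based truths, predicted intake
  is first produced by the engine's default intake model at mid-period
  weight (or the end-BW stub).
* `calibrate_total_sd` rescales the systematic part around its mean so the
  total response SD matches a known value. The AFSBW response's total SD is
  not published directly; back-solving from RMSE = 51.3 kg and r² = 0.39
  gives about 65.7 kg, and the rescaled part stays inside the span of the
  model terms, so the fitted r² reflects the systematic-to-total variance
  ratio (≈ (65.7² − 51.3²)/65.7² ≈ 0.39). This derived value is used only
  where a fit-statistic reproduction is wanted, never for parameter
  recovery.
* All randomness in one `generate_cohort()` call flows from a single seeded
  stream (one seed per cohort, not per-animal substreams); cohorts are
  generated whole, so this is fully reproducible.

At n = 10,000 the generated marginals pass a 3-standard-error mean check and
a 4-standard-error SD check against the *truncated-normal* expectations
(the correct reference: truncation shifts some means, e.g. days on feed by
almost two days, by more than the Monte-Carlo error).

## Numerical and design choices

* Age defaults to 365 d where unrecorded; it is an overridable input, and
  ages outside the 150-640 d validity window of the frame-score polynomials
  warn rather than fail.
* The bull AFSBW line is retained for completeness although feedlot cohorts
  contain none; steers use the male frame-score polynomial with the steer
  AFSBW line.
* EBF is not clamped before the AFSBW correction; implausible marbling
  scores (outside 2-9) are rejected at validation instead.
* The projection reports DOF as the first day the target is met; an
  infeasible projection (target at or below initial weight, or not reached
  within `max_days` = 1000) errors rather than returning a sentinel, and the
  cohort-level wrapper converts such animals to missing values with a
  warning.
* Intake at or below maintenance yields zero gain with a warning; weight
  loss is not modelled.
* The default candidate pool for stepwise selection over the difference
  variables is all eleven MBVs plus the leptin class, sex, sex interactions
  and quadratics; it is an argument, not a constant, because no canonical
  pool exists.
* Reference-coefficient application (`apply_adjustment()`) is pure
  arithmetic on a named design matrix - bit-stable across runs and platforms.
* Problem sizes in the shipped tests and acceptance script: recovery studies
  use 200 generated cohorts of n = 1499 (673 heifers + 826 steers, matching
  the complete-record count of the emulated population); cross-validation
  uses 200 replicates of 750/749 splits; generator calibration uses 10,000
  heifers. These sizes leave Monte-Carlo error comfortably inside every
  interval checked.

## Known limitations

* The engine is a documented NRC-style core: it omits the weather-driven
  maintenance adjustment and the exponential-decay gain-composition
  adjustment of the commercial system it stands in for; a constant
  environment is assumed.
* MBV construction (SNP discovery, allele-substitution selection) is out of
  scope; MBVs enter only as given scores.
* The two leptin SNPs are drawn independently (no linkage), and MBV-MBV
  correlations default to zero.
* Fixed-effects least squares throughout; no pedigree, kinship or random
  effects.
* The generator's fidelity is to printed summary statistics; higher moments,
  nonlinear dependence and pen-level structure of real feedyard data are not
  emulated, which bounds what passing tests can claim about real data.
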