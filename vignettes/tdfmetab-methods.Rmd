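---
title: "Methods: from oxygen traces and tissue isotopes to SMR and TDF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces and tissue isotopes to SMR and TDF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfmetab)
```

## What this package computes

`tdfmetab` implements the computational chain used in feeding experiments
that relate a fish's standard metabolic rate (SMR) to its trophic
discrimination factors (TDF): intermittent-flow respirometry traces are
turned into per-fish SMR estimates; tissue δ¹³C and δ¹⁵N values are
lipid-normalized and referenced to the diet to give Δ¹³C and Δ¹⁵N; and the
statistical layer (ANCOVA across weight classes with Bonferroni pairwise
comparisons, TDF-on-SMR regressions, a littoral-vs-pelagic Welch t-test)
reproduces the study-style analysis. A synthetic-data generator with full
ground truth makes every stage testable without any animal data.

## Respirometry model

Intermittent-flow respirometry alternates *flush* (chamber re-aerated),
*wait* (sealed, excluded from fitting) and *measure* phases. Trial loops
are 180 s / 30 s / 210 s; background (blank chamber) loops use a 900 s
measurement phase. During each sealed measurement phase dissolved O₂
declines approximately linearly, and the fitted slope gives one oxygen
consumption estimate:

\[
\dot M_{O_2} = -b \,(V_\mathrm{chamber} - m/\rho), \qquad \rho = 1\ \mathrm{g\,cm^{-3}},
\]

where \(b\) is the OLS slope of concentration on time (mg O₂ L⁻¹ hr⁻¹)
and the effective volume subtracts the fish's volume. The instrument
convention of which volume enters this conversion is rarely stated in
papers; the chamber-minus-fish rule used here is the standard one and is
applied uniformly to trials and blanks (a blank has \(m = 0\)).

Background (microbial) respiration is estimated per chamber by regressing
all pre- and post-trial blank MO₂ values on absolute experiment time,
after excluding blank fits with R² ≤ 0.1. Pooling across trials (rather
than interpolating within each trial) is deliberate: it allows the R²
filter to discard uninformative blanks while retaining chamber-specific
calibration. The fitted background at each measurement's midpoint time is
subtracted, the result divided by fish mass (kg), and:

* measurements with phase-fit R² < 0.95 are removed;
* measurements that go non-positive after background subtraction are
  **excluded, not clamped** — clamping to zero would bias the lowest-decile
  statistic downward;
* SMR is the mean of the lowest 10 % of the surviving mass-specific
  values, with \(k = \max(1, \lfloor 0.10\,n \rfloor)\) and ties broken by
  loop order, so the statistic is defined for any \(n \ge 1\).

Both R² thresholds follow the fitting conventions of the AutoResp-style
workflow: retention at R² ≥ 0.95 (inclusive), background inclusion at
R² > 0.1 (strict), and R² is the ordinary coefficient of determination of
concentration on time. A zero-variance phase is reported as slope 0 with
R² defined as 0, so constant traces are filtered rather than crashing.

The choice of *absolute experiment time* as the background regression
predictor (rather than trial index or within-trial time) matters when
benchmarking against other implementations; it is the reading most
consistent with pooling "all of the starting and ending background
values", and it is isolated in `fit_background_model()` so it can be
swapped.

## Lipid normalization and TDF

Lipid is depleted in ¹³C relative to protein, so lipid-rich tissues read
too negative. Per sample, lipid content is predicted from the C:N mass
ratio, \(L = -20.54 + 7.24\,\mathrm{C{:}N}\) (clamped to [0, 100] %), and
δ¹³C is corrected by

\[
\delta^{13}C' = \delta^{13}C + D\left(I + \frac{3.90}{1 + 287/L}\right),
\qquad D = 7.018,\ I = 0.048 .
\]

The correction is applied only when C:N exceeds 3.4 (strictly), per
sample rather than per tissue: typical muscle (C:N ≈ 3.2) passes through
unchanged while liver (C:N ≈ 4.4 ± 0.6) is corrected, which reproduces
the tissue-wholesale convention on realistic data while generalizing to
mixed samples. C:N is treated as the elemental-analyzer mass ratio; no
molar conversion is applied. All coefficients are `lipid_norm_params()`
fields and can be overridden, e.g. with refit D/I values.

TDFs are diet-mean offsets, \(\Delta X = \delta X_\mathrm{tissue} -
\overline{\delta X}_\mathrm{diet}\); the diet SD is carried for reporting
but never enters the subtraction. `compute_tdf()` refuses liver samples
that have not passed through `normalize_tissue()`, so an un-screened
δ¹³C cannot silently contaminate Δ¹³C.

Equilibrium gating assumes a consumer is at isotopic equilibrium after
4–5 tissue half-lives. The half-life model is log-linear in body mass
with per-tissue offsets. **No literature coefficients are shipped**: the
published turnover equations live in their own papers, and hard-coding
them here would present third-party regression coefficients as package
facts. `equilibrium_params()` therefore requires the user to supply the
coefficient set (citing its source in their configuration); the pipeline
logs the resulting window before reporting TDFs, or logs that the gate
was not evaluated.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions:

| parameter | default | rationale |
|---|---|---|
| trial duration | 71 000 s (~19 h 43 min) | minimum trial length of the emulated protocol |
| loop timing | 180/30/210 s; blanks 180/30/900 s | protocol values |
| O₂ saturation | 9.0 mg L⁻¹ | air saturation near 18 °C |
| sensor noise | 0.01 mg L⁻¹ at 1 Hz | fiber-optic optode precision; keeps clean loops above the R² ≥ 0.95 gate at realistic chamber sizing |
| activity bouts | Poisson onsets at 1 hr⁻¹, 600 s, MO₂ × 2 | the protocol does not model activity; this is the minimal mechanism that makes the lowest-decile statistic meaningful (~20 % of loops touched) |
| background | 0.3 mg O₂ hr⁻¹ + 0.01 hr⁻¹ per hour | slow microbial growth between bleachings; makes the chamber-specific drift correction consequential |
| chamber volumes | 0.5/0.6/0.8/0.9 L, size-matched | chambers size-matched to fish as in the protocol; ~15 mL per g fish keeps the per-loop O₂ drop well above the noise floor for every size class |
| diet | δ¹³C −30.6 ± 0.5 ‰, δ¹⁵N 14.0 ± 3.7 ‰, C:N 4.7 | measured diet distribution |
| tissue C:N | muscle 3.2 ± 0.01, liver 4.4 ± 0.6 | measured tissue values |
| instrument error | 0.2 ‰ (C), 0.3 ‰ (N) | stated analytical precision |

Activity bouts are a Poisson process in time with fixed duration and a
multiplicative MO₂ elevation. The flush phase relaxes exponentially to
saturation with a 30 s time constant; the wait phase carries the sealed
dynamics but is excluded from fitting, mirroring instrument convention.
Within sealed phases the decline is generated by left-Riemann integration
of the instantaneous rate, so a constant rate yields an exactly linear
trace — matching the downstream linear fitting model by construction
rather than by approximation.

The cohort side draws true mass-specific SMR from a power law of the
group's initial (weight-class) mass, `125.8 · m^-0.179` mg O₂ kg⁻¹ hr⁻¹
plus +10 for pelagic fish and a between-fish SD of 8, which places the
five group means near 98, 71, 81, 77 and 64. Muscle TDFs are linear in
true SMR (Δ¹³C: 6.2 − 0.035·SMR, Δ¹⁵N: −1.6 + 0.043·SMR, residual SD
0.25 ‰); liver TDFs are drawn independently of SMR (1.1 ± 0.35 ‰ and
1.0 ± 0.45 ‰). Liver δ¹³C is distorted by the *exact inverse* of the
normalization model before measurement error is added, so at zero noise
the normalization round-trip is exact to machine precision — a designed
closure property, not a numerical coincidence. Final masses are truncated
below at the group's initial mass (fish grew over the experiment); the
reported ±23 g spread of one group would otherwise produce near-zero-mass
fish.

What the generator does **not** emulate: temperature dynamics and
O₂-solubility changes, specific dynamic action after feeding, circadian
MO₂ rhythms, tank/shoal effects on growth, and isotopic turnover
trajectories (fish are generated *at* equilibrium). Passing tests
therefore demonstrate correctness of the processing chain under the
stated generative model, not robustness to those real-data features.

## Statistical layer

ANCOVAs are `response ~ weight-class-group + final weight` with
sum-to-zero contrasts and Type III (partial) F tests, matching the
default convention of the commercial software the emulated analyses were
run in; the sum-of-squares type is switchable (`ss_type = 1/2/3`) for
benchmarking against other conventions. The 20–30 g littoral and pelagic
fish are distinct factor levels. Adjusted means are evaluated at the
grand-mean covariate; pairwise contrasts use raw t-tests multiplied by
the number of pairs (capped at 1), and the compact letter display is
computed by a split-and-absorb algorithm so that levels sharing a letter
do not differ at α after adjustment. Normality (Shapiro–Wilk) and
variance homogeneity (Levene) are computed and reported but never gate a
fit. Degenerate designs are handled explicitly: a zero-variance response
reports F = 0, and perfect (zero-residual) fits fall back to a drop-term
RSS comparison, which coincides with Type III for this additive model.

The 2-sample habitat comparison uses Welch's unequal-variance t statistic
with Satterthwaite df — identifiable in reports by its fractional degrees
of freedom.

## Numerical choices and edge cases

* Phase midpoints (mean of measurement-phase sample times) are the time
  coordinate for MO₂, for background prediction and for truth records, so
  simulator and estimator agree on the convention and the drift
  correction is exact for linear drift.
* Background predictions are clamped at ≥ 0; with fewer than two
  surviving blank fits a chamber falls back to the mean of what survives,
  or to zero with a warning.
* Ties in the lowest-decile selection are broken by loop order, making
  the statistic deterministic.
* All simulation is seeded and restores the caller's RNG state; per-trial
  seeds are derived from the master seed by integer mixing within 32-bit
  range, so runs are byte-reproducible file-for-file.
* Configuration files are YAML (`read_pipeline_config()`), with CLI flags
  overriding file values; every run writes the resolved configuration
  next to its outputs.

## Problem sizes used by the test suite

The package's own checks run the full-length protocol (169-loop trials,
28-fish cohort) where the property under test demands it — SMR recovery
under activity bouts, the end-to-end run — and reduced sizes (15-loop
trials, 12-fish cohorts, 100–1000 Monte-Carlo replicates) for
distributional properties where the answer does not depend on trial
length. These sizes are the package's choice of a thorough-but-quick
default; all of them are set in the test files and scale up freely.

## Known limitations

* With realistic sensor noise the lowest-decile estimator carries a small
  negative bias (selecting loops with favorable noise); at the default
  noise level this stays within a couple of percent and is inherent to
  the quantile-based SMR definition, not to this implementation.
* Measurement error in estimated SMR attenuates TDF-on-SMR regression
  slopes toward zero; at default settings the attenuation is well under
  the between-fish SMR spread and the recovered slope remains within a
  few percent of the generated one.
* The liver "no SMR dependence" pattern is a null hypothesis: at α = 0.05
  roughly one cohort in twenty will show a spuriously significant liver
  slope, which is the expected behavior of a calibrated test, not a
  defect.
* The benchmark against the study's deposited per-fish data requires that
  external dataset; the stats module accepts any merged per-fish CSV for
  that purpose.
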