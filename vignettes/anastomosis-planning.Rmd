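---
title: "Scaling-law anastomosis planning for TAPVC repair: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling-law anastomosis planning for TAPVC repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapvcflow)
```

## The clinical problem and the model

In surgical repair of total anomalous pulmonary venous connection (TAPVC),
the pulmonary venous confluence (PVC) is opened along an incision of length
$L$ and sutured to the left atrium. Too small an anastomosis raises the
blood-flow velocity across it, a marker of postoperative pulmonary venous
obstruction risk; surgeons therefore want the incision sized to the
individual patient before the operation.

The model at the core of this package is a one-line scaling law. Cardiac
output scales with body weight $M$, and by continuity the peak velocity
across an orifice is flow divided by effective orifice area. Treating the
effective area as proportional to the product of the incision length $L$
and the PVC circumference $C$ gives

$$V \;=\; k\,\frac{M}{L\,C},$$

with $V$ in m/s, $M$ in kg, $L$ and $C$ in mm, and the calibration constant
$k = 163.48$ m·mm²·s⁻¹·kg⁻¹ (`default_k()`). Solving for $L$,

$$L \;=\; k\,\frac{M}{V\,C},$$

turns the predictor into a planning tool: given a tolerable target velocity
and the CTA-measured circumference, it returns the incision length
(`plan_incision_length()`). The two functions are exact algebraic inverses,
a property the test suite holds to 1e-9 relative error.

The competing predictor $M/L$, which ignores confluence size, is retained
in `fit_scaling_model(predictor = "m_l")` because the model comparison —
$M/(LC)$ explains ~99% of velocity variance across pooled simulation
sweeps, $M/L$ only ~28% — is the empirical argument for including $C$.

## Calibration

`fit_scaling_model()` pools all sweep points and fits ordinary least
squares of peak velocity on the chosen ratio. Design choices that matter:

* **Free intercept by default.** The constant is reported as the slope; the
  intercept is expected to be negligible and is reported so the user can
  verify that. A through-origin fit (slope $\sum xy / \sum x^2$) is
  available with `through_origin = TRUE` and is the natural estimator when
  data are known to be generated with no offset.
* **`ratio_source`.** The packaged sweep table carries the ratio columns
  exactly as published alongside each row's raw $M$, $L$, $C$. Thirteen
  printed $M/(LC)$ cells disagree with their own row arithmetic by more
  than 5e-5 (`audit_ratio_discrepancies()` lists them; the list is frozen
  as a regression test). The package default recomputes ratios from the raw
  columns — the defensible general-purpose choice — but
  `ratio_source = "printed"` reproduces the fit as published
  (slope 163.4824, $r$ = 0.9942, $r^2$ = 0.9885); with recomputed ratios
  the slope moves to 168.8. Neither column is silently "corrected".
* **Inference.** Pearson $r$ with a two-sided $p$ from the $t$-transform
  with $n-2$ degrees of freedom (`stats::cor.test()`); significance
  threshold 0.05. `check_normality()` (Shapiro–Wilk) is advisory and never
  blocks a fit.

## Validation and agreement statistics

`run_validation_pipeline()` applies the published exclusion rules —
sutureless repairs (no suture-line length exists) and cases without an
intraoperative length record — fills model velocities, and compares them
with postoperative Doppler-echo peak velocities. Conventions, each chosen
to reproduce the published summary statistics and stated explicitly in
reports:

* differences are **calculated − measured**;
* the standard deviation of differences uses the $n-1$ denominator;
* the 95% CI of the mean difference uses the $t$ quantile with $n-1$
  degrees of freedom;
* Bland–Altman limits of agreement are mean ± 1.96·sd (normal factor), by
  construction, not approximation;
* calculated velocities enter the aggregate statistics unrounded. The
  packaged validation table also keeps the calculated column as printed;
  one printed cell (case 06: 1.260 where its own $M$, $L$, $C$ give 1.284)
  is internally inconsistent, and the published aggregates correspond
  exactly to the printed column. `reproduce_study()` therefore reports the
  agreement statistics both ways; they differ by about 0.001 m/s. With
  zero-variance differences the paired $t$ is flagged degenerate rather
  than divided by zero.

## The reduced-order surrogate

Full fluid–structure-interaction (FSI) simulation of each candidate
geometry is not reproducible at desk scale, so synthetic data come from a
deliberately minimal pulsatile orifice model:

* **Inflow.** A rectified-sinusoid pulse whose cycle mean equals the
  weight-indexed cardiac output, default 200 mL·kg⁻¹·min⁻¹ — a typical
  neonatal requirement, configurable and never hard-coded into results.
  The waveform is normalised on the discrete time grid, so conservation of
  the prescribed output holds exactly per cycle (tested to 1e-9). The
  peak-to-mean ratio of the shape is ≈ π.
* **Orifice.** Continuity equation $V(t) = Q(t)/A_\mathrm{eff}$ with
  $A_\mathrm{eff} = \alpha L C$. This is the only area law consistent with
  the empirically validated $V \propto M/(LC)$; the slot area
  $L \times$ rim height (rim default 0.5 mm) would make velocity
  independent of $C$. The single dimensionless coefficient $\alpha$ is
  calibrated once against the scaling law (`calibrate_alpha()`); because
  peak flow is linear in $M$ and $A_\mathrm{eff}$ linear in $LC$, one
  calibration point aligns the surrogate with the law everywhere, and the
  sub-1% surrogate-vs-law consistency test passes by construction rather
  than by tuning.
* **Outlet pressure.** A raised cosine between 4 and 12 mmHg (the typical
  infant left-atrial range), period 60/heart rate (default 140 bpm). In a
  rigid-walled continuity model the outlet pressure cannot alter the
  velocity; the waveform exists so the configuration surface is complete
  if a compliant-wall extension is added later.
* **Walls are rigid.** Vessel elasticity is deliberately not modeled: the
  validated scaling law contains no elasticity term, and surrogate
  realism beyond the law's structure would add parameters the analysis
  never identifies.
* The reported peak is taken after discarding the first simulated cycle
  (default 3 cycles, dt = 1 ms) — a transient-settling convention kept
  from solver practice, though this surrogate has no transient.

## Synthetic cohorts: what they do and do not emulate

`generate_synthetic_cohort()` draws $M$, $C$, $L$ uniformly within bounds
spanning the study tables (defaults 1.9–4.9 kg, 14–31 mm, 5–19 mm) and
generates $V = k_\mathrm{true} M/(LC)\,e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma)$, $\sigma = 0.05$ by default —
multiplicative noise, since simulation and measurement errors scale with
velocity. `generate_validation_cohort()` adds a systematic offset and
additive measurement noise to stress the agreement module. Every stochastic
operation takes an explicit integer seed and restores the session RNG
state; same seed, same cohort, bit for bit.

What passing tests on these cohorts show: the estimators recover known
generating parameters at the study's noise scale and sample sizes. What
they do not show: anything about real hemodynamics beyond the scaling law's
structure — the generator has no secondary physiology (no subtype effect,
no correlation between weight and circumference, no velocity-dependent
measurement error), so agreement on synthetic data cannot certify clinical
accuracy. The clinical evidence in the package is the fixture-based
validation, whose 22 cases are the study's own.

A note on estimator behaviour found while verifying recovery: under
multiplicative noise the free-intercept OLS slope has a heavy-tailed
sampling distribution (relative sd ≈ 1.2% at $n = 200$, $\sigma = 0.05$;
occasional 3–4% excursions driven by high-leverage small-$LC$ points). The
through-origin refit, which matches the zero-intercept generating law,
concentrates within 2% on every seed tested. Parameter-recovery tests
therefore bound the through-origin slope per seed and the free-intercept
slope in expectation.

## Numerical and interface choices

* Printed-table comparisons round half-to-even at 3 decimals
  (`round_printed()`); internal values are never rounded. The source table
  itself is not uniform — at least one velocity cell is truncated rather
  than rounded — so cell-level tests allow ±0.001 after rounding.
* Lengths or circumferences below 1e-6 mm, and effective areas below
  1e-6 mm², are rejected as unit mistakes instead of returning enormous
  velocities.
* Fixture loaders verify row counts, case/subtype structure and frozen
  column sums, so silent edits to the packaged CSVs fail loudly.
* CSV writers serialise numerics at 17 significant digits; write/read
  round-trips are bit-exact.
* The command-line layer (`run_cli()`, wrapper in `inst/cli/tapvcflow.R`)
  prints machine-readable JSON to `--out` or stdout, human diagnostics to
  stderr, and a manifest (parameters, seeds, input MD5s, package version,
  timestamp) alongside every file it writes.
* Problem sizes in the test suite: the 42-point and 22-case fixtures for
  all published statistics; $n = 200$ cohorts over 100 seeds for slope
  recovery; $n = 10^4$ for shift/noise recovery in the agreement module.
  The whole suite runs in a few seconds.

## Known limitations

* The constant $k$ was calibrated on seven simulated infant geometries
  (1.95–4.8 kg); nothing supports extrapolation to older children.
* Velocity is treated as a continuous output; the package deliberately
  takes no position on a velocity threshold defining obstruction, since
  reported thresholds vary.
* The validation cohort is single-institution and excludes sutureless
  repairs, so the agreement statistics say nothing about that technique.
* The surrogate is rigid-walled and its inflow/pressure waveforms are
  stand-in shapes; it emulates the scaling law's structure for testing,
  not patient-specific hemodynamics.
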