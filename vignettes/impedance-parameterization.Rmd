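---
title: "Parameterizing RFA impedance curves: model, indices, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing RFA impedance curves: model, indices, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfacurve)
```

## The signal and its landmarks

During radiofrequency ablation (RFA) the generator drives an alternating
current through an electrode placed in the target tissue. The circuit
impedance it sees follows a characteristic trajectory: it falls while
Joule heating lowers the tissue's electrical resistivity, reaches a
minimum, and then rises — slowly at first, then abruptly — as desiccation
and carbonization electrically isolate the electrode. That abrupt rise is
the *roll-off*, and it is the usual stop criterion for the procedure.

`rfacurve` reduces one such curve $Z(t)$ to seven landmarks:

* $t_{end}$ — duration until the first roll-off, and $Z_{end}$, the
  impedance there;
* $t_{1/2} = t_{end}/2$, and $Z_{1/2} = Z(t_{1/2})$;
* $t_{min}$, $Z_{min}$ — the time and value of the global impedance
  minimum on $[0, t_{end}]$;
* $Z_{init}$ — the impedance at procedure start.

and to three dimensionless performance indices, all in percent:

$$\delta = \Big(\frac{t_{min}}{t_{1/2}} - 1\Big) \cdot 100,\qquad
  DR = \Big(1 - \frac{Z_{min}}{Z_{init}}\Big) \cdot 100,\qquad
  AR = \Big(\frac{Z_{end}}{Z_{min}} - 1\Big) \cdot 100.$$

$\delta$ measures the asymmetry of the curve ($\delta = 0$: the minimum
sits exactly at mid-procedure; $\delta > 0$: after it). $DR$ is the
percent drop from the initial impedance to the minimum, $AR$ the percent
rise from the minimum to the roll-off value. Because all three are
ratios, they are invariant to rescaling of the time axis and of the
impedance axis — a property the test suite checks directly.

A note on the sign of $DR$: the literal ratio
$(Z_{min}/Z_{init} - 1)\cdot 100$ is negative for any real drop. Reported
values in this field are positive drop magnitudes, so `drop_ratio()`
returns the positive `dr` and keeps the literal `dr_signed` alongside.

## Two definitions of roll-off

The package deliberately implements two roll-off definitions and stamps
the choice into every output record:

* **`log_end`** (default): the equipment stopped the procedure at the
  first roll-off, so the last logged sample *is* the event. This is the
  definition that produces ascent ratios of several hundred percent —
  final impedances around five times the minimum are typical for RF-only
  ablations.
* **`threshold`**: the conventional fixed stop level
  $Z_{end} = 1.5 \cdot Z_{init}$, located by linear interpolation at the
  earliest crossing after the curve minimum.

The two are not interchangeable. Under the threshold definition the
identity
$$AR = 100\Big(\frac{1.5}{1 - DR/100} - 1\Big)$$
holds *exactly* (it is algebra, and the suite verifies it to $10^{-9}$ on
every synthetic curve), which caps $AR$ near 100% for realistic drops. A
fixed 1.5x level therefore cannot produce the multi-hundred-percent
ascent ratios observed when the generator halts at the event itself; any
analysis mixing the two definitions would be internally inconsistent.
`log_end` is the default because it reproduces the magnitudes reported
for the reference ex vivo cohort.

Threshold crossings are searched only after the minimum, so initial
readings above the level (possible when `init_k > 1` averages several
leading samples into $Z_{init}$) cannot trigger a spurious detection. A
curve that never reaches the level raises a classed `no-rolloff` error
carrying the maximum impedance reached — the signature of an aborted or
failed ablation rather than a numerical accident.

## Numerical choices

* **Interpolation.** $Z_{1/2}$ and threshold crossings use linear
  interpolation between bracketing samples; sampling grids are not
  guaranteed to contain $t_{end}/2$ or the crossing time.
* **Ties.** The minimum search returns the *earliest* sample attaining
  the minimum; duplicating the minimum value later in the curve never
  moves $t_{min}$.
* **Time origin.** Landmark times are durations, so curves are rebased to
  $t[1] = 0$ on construction; a constant offset in the log changes
  nothing.
* **Cleaning.** Log rows with missing time, missing/negative voltage, or
  missing/non-positive current are dropped and counted (`dropped_rows`
  travels with the curve into every parameter record). These artifacts
  come from generator cut-outs; dropping is the least-assuming rule.
* **Smoothing.** Extraction is raw by default (`median_window = 0`). For
  noisy logs an odd-window running median is available; see below for
  why the package recommends `median_window = 9` there.

## The synthetic cohort generator

The generator exists so the full pipeline — including the statistical
battery — runs and is tested without laboratory data. It is
*index-faithful*, not biophysical: each curve is constructed to realize
prescribed $(\delta, DR, AR)$ exactly in the noise-free limit, via a
saturating-exponential decay $Z_{init} \to Z_{min}$ on $[0, t_{min}]$ and
a power-law rise $Z_{min} \to Z_{end}$ on $[t_{min}, t_{end}]$. This is
sufficient because every downstream computation consumes only landmarks
and indices; no claim is made that the curve between landmarks matches
tissue physics (no bioheat modelling, no temperature channel).

Defaults emulate the reference five-arm ex vivo bovine study (RF-only
control; 0.9% saline and deionized water, each at ambient and 5 °C;
ten ablations per arm):

* **Index means per arm** come from the published group estimates
  bundled in `ref_group_indices()`.
* **Standard deviations** are reconstructed from the published 95% CI
  half-widths as $(\mathrm{CI_{up}} - \bar{x})/1.96 \cdot \sqrt{10}$.
  This is an approximation, and a consequential one: the published
  intervals pool variance across arms, so every arm inherits the same
  (large) spread — see *Known limitations*.
* **Truncation.** DR targets are truncated to $[0, 99]$, AR to
  $[0, \infty)$, $\delta$ to $(-95, 95)$ (the construction needs the
  minimum strictly inside the procedure). Truncation is by redraw, i.e.
  the conditional (truncated-normal) distribution.
* **Initial impedance** is uniform on 66–117 Ω, the band observed in the
  reference cohort.
* **Durations** are uniform on 300–900 s at `dt` = 1 s. Roll-off times
  are not printed for the reference cohort; this range is typical of
  40 W expandable-electrode ex vivo ablations and is exposed in
  `cohort_spec()`.
* **Curve shape**: `decay_shape = 1.5` (mildly convex decay) and
  `rise_exponent = 3` (accelerating rise) were chosen once for
  qualitative resemblance to published curve families and are exposed in
  `curve_spec()`; printed values cannot calibrate them.
* **Volumes** are drawn per arm from the published mean/sd summaries,
  jointly with AR through a Gaussian copula whose normal-score
  correlation $2\sin(\pi\rho_s/6)$ attains the target Spearman $\rho_s$
  in expectation. Targets use the published per-arm coefficients where
  printed (0.72, 0.73, 0.78) and 0.50 for the two arms described as
  positively but not significantly correlated.
* **Noise**: additive Gaussian, 2 Ω by default, floored at 1 Ω so
  impedance stays positive.

### Noise handling and the median window

The impedance minimum is an extreme value, so with additive noise the
observed minimum is biased *low* — and DR correspondingly high — by
roughly $\sigma\sqrt{2\ln m}$, where $m$ is the number of samples within
one noise standard deviation of the true minimum. Long, gently curved
valleys make $m$ large: with 2 Ω noise and raw extraction the DR bias is
about +5 percentage points under the generator defaults. A running
median shrinks the effective $\sigma$ (the median of 9 Gaussians has
about 0.41 of their sd), and an order-statistics estimate — made before
any acceptance measurement, and confirmed by simulation afterwards —
puts the bias near 1.3 points at `median_window = 9`. That is the
package's recommended setting for noisy logs, and what the cohort-scale
tests use; noise-free analyses keep the raw default.

## The statistical battery

The battery mirrors the analysis plan of the reference study, at
$\alpha = 0.05$ throughout:

* Shapiro-Wilk normality (`stats::shapiro.test`) on the one-way model
  residuals, and Brown-Forsythe/Levene homogeneity
  (`car::leveneTest`, median-centered) across arms.
* One-way ANOVA across the five arms, Tukey HSD for pairwise contrasts
  (`stats::aov`, `stats::TukeyHSD`).
* A 2x2 factorial (solution x temperature, with interaction) on the four
  treated arms. The RF-only control carries neither factor, and an
  incomplete factorial with a phantom level is ill-posed, so the control
  is excluded from the factorial and reported as a standalone reference
  level in every marginal table, with control-vs-arm contrasts available
  through the one-way path.
* Estimated marginal means via **emmeans**. The pooled-variance t
  intervals of the one-way model reproduce the structure of the
  published tables (identical half-widths across a balanced design),
  which is why `ci_method = "parametric"` is the default for table
  reproduction; what procedure produced the published intervals is not
  stated, so neither option claims to be it.
* BCa bootstrap intervals (1000 resamples, 95% by default) for any
  statistic, implemented in the package: bias correction from the
  bootstrap distribution, acceleration from jackknife skewness, a
  seeded resampler for reproducibility, and a flagged percentile
  fallback when the bootstrap distribution degenerates. The
  implementation is cross-checked against `boot::boot.ci` and achieves
  93–97% empirical coverage for the mean of normal data in the
  acceptance suite.
* Spearman correlation between each index and the ablation volume, per
  arm. For $n \le 9$ the p-value is exact, by full enumeration of all
  $n!$ rank permutations (midranks for ties); beyond that the usual t
  approximation is used. The exact path is cross-checked against
  `stats::cor.test`.
* Tukey fences ($1.5 \cdot IQR$) flag outliers per arm and index.

No multiplicity control beyond Tukey HSD is applied, and no
nonparametric omnibus alternatives are offered — matching the reference
analysis plan.

## What passing tests do and do not show

The cohort-scale tests simulate the reference design (10 ablations x 5
arms, 20 replicate cohorts) and check that the full pipeline recovers
the published group structure: arm means inside the published 95% CIs
for at least 13 of the 15 arm-index cells in a majority of cohorts, and
the two published qualitative contrasts (saline-5 °C DR above the
RF-only control; saline-ambient AR lowest).

Because the generator is index-faithful, these tests validate the
*pipeline* — extraction, indices, statistics — under realistic sampling
variability. They do not validate the generator against real tissue:
real curves have correlated, non-Gaussian disturbances (infusion cycles,
electrode repositioning, multi-roll-off morphologies), none of which are
modelled. Reproduction of the published numbers from the deposited
laboratory workbook is a separate, opt-in path (see the README).

## Known limitations

* **Pooled-sd reconstruction compresses arm contrasts.** With the
  pooled AR spread (~249 in percent units) attached to every arm, the
  non-negativity truncation shifts the low-mean saline-ambient arm up by
  ~97 points but the next-lowest arm by only ~59, so "saline-ambient AR
  lowest" reproduces in roughly 65–85% of seeded cohorts rather than
  comfortably above 80%: the real cohort's per-arm spreads were
  evidently narrower than the pooled reconstruction (its printed
  saline-ambient minimum is 48.4%, far from 0). The package keeps the
  reconstruction rule rather than inventing per-arm spreads the source
  does not report.
* **One roll-off only.** The study design stops at the first roll-off;
  multi-roll-off segmentation is out of scope.
* **No temperature channel.** Thermocouple data enter none of the
  computations.
* **Volumes are inputs.** Thermal-damage volumes are consumed as given
  numbers; measuring them is a separate problem.
* **Deposited-workbook layout.** The reader auto-detects a per-sample
  (long) layout with precomputed index columns and falls back to raw-log
  ingestion otherwise; undocumented workbook layouts may need an
  explicit `column_map`.

## Problem sizes used by the test and acceptance runs

Cohort-scale checks use 20 replicate cohorts of 50 curves (durations
300–900 s at 1 s sampling); noise-bias checks use 500 replicate curves;
BCa coverage uses 1000 Monte-Carlo datasets of $n = 30$ with $B = 1000$
resamples; exact-permutation cross-checks run at $n \le 9$. These sizes
make the whole suite run in well under a minute on one core while
keeping Monte-Carlo error comfortably below every asserted margin.
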