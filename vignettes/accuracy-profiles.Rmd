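---
title: "Total-error validation with accuracy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-error validation with accuracy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(accuprofile)
library(dplyr)
```

## The decision problem

A quantitative analytical method (here, the motivating case is an automated
flow assay quantifying a drug in dissolution samples) is *valid* over a
concentration range when an individual future measurement can be expected to
fall within a pre-set acceptance limit $\pm\lambda$ of the true value — for
dissolution assays of finished products, $\lambda = 10\%$ relative error is
the usual choice. The total-error approach judges this directly: rather than
testing bias and precision separately, it combines both into a per-level
**$\beta$-expectation tolerance interval** ($\beta$-ETI) on the relative
error and asks whether that interval lies inside $(-\lambda, +\lambda)$.
Plotting the intervals across concentration levels gives the **accuracy
profile**, a graphical decision tool on which the limits of quantification
can be read off.

## The model

The validation experiment is a balanced one-way random-effects design:
$p$ series (typically days) of $n$ independent replicates at each of $m$
concentration levels. For the back-calculated concentrations $x_{ij}$ of one
level with true value $\mu_T$:

* $\hat\mu$ — grand mean; relative bias $\;b = 100(\hat\mu-\mu_T)/\mu_T$;
* $\hat\sigma^2_W = MS_W$ and $\hat\sigma^2_B = \max\{0, (MS_B - MS_W)/n\}$,
  the within- and between-series variance components from the ANOVA mean
  squares (the between component is truncated at zero);
* repeatability RSD $s_r = 100\,\hat\sigma_W/\hat\mu$ and
  intermediate-precision RSD
  $s_R = 100\sqrt{\hat\sigma^2_W+\hat\sigma^2_B}/\hat\mu$.

The interval on the relative-error scale is

$$
b \;\pm\; Q_t\!\left(\nu,\tfrac{1+\beta}{2}\right)
\sqrt{1+\frac{1}{p\,n\,B^2}}\; s_R ,
\qquad
B^2 = \frac{R+1}{nR+1},\quad R = \hat\sigma^2_B/\hat\sigma^2_W ,
$$

with $\nu$ the Satterthwaite effective degrees of freedom of
$\hat\sigma^2_B+\hat\sigma^2_W$:

$$
\nu = \frac{(R+1)^2}
{\dfrac{(R+1/n)^2}{p-1} + \dfrac{1-1/n}{p\,n}} .
$$

Two algebraically equivalent forms of $\nu$ (the ratio form above and the
mean-squares form used by `satterthwaite_dof_ms()`) are implemented and
cross-checked against each other in the test suite; they agree to $10^{-10}$
on randomised designs. The multiplier of the coverage factor is the
intermediate-precision RSD, i.e. the standard deviation of a *future single
measurement* from a new series — using the repeatability RSD instead would
understate the interval whenever a between-series component exists.

```{r}
d <- validation_design(p = 3, n = 3, m = 7, lambda_pct = 10, beta = 0.95)
satterthwaite_dof(0, p = 3, n = 3)     # no between-series component
tolerance_factor(satterthwaite_dof(0, 3, 3), 0.95, 3, 3, b2 = 1)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p`, `n`, `m` | 3, 3, 7 | series, replicates/series, levels — the usual three-day triplicate design |
| `lambda_pct` | 10 % | acceptance limit on relative error |
| `beta` | 0.95 | proportion of future results the interval must be expected to contain |
| `rsd_reference` | `"mu_hat"` | RSDs normalised by the estimated mean; switch to `"mu_t"` to normalise by the true value |

The seven default levels (5, 10, 25, 50, 75, 100, 120 % of nominal) span the
working range of a dissolution assay; the nominal 100 % level is the
concentration reached when the full label dose dissolves in the vessel
(`percent_to_concentration(100)` = 55.56 µg/mL for 50 mg in 900 mL).

## LLOQ, ULOQ and the profile decision

A level is valid when its interval is strictly inside $(-\lambda,\lambda)$.
The LLOQ is the lowest valid level, or — when lower levels fail — the point
where the violating bound crosses the acceptance limit, interpolated
linearly in level % between the last failing and first passing level; the
ULOQ mirrors this from the top. The piecewise-linear interpolation matches
how the profile is drawn; it is a convention, not an inference, and is the
natural reading of a piecewise-linear accuracy profile. A profile with no
valid level is reported as invalid (`lloq_pct = NA`), not as an error.

```{r}
iv <- tibble::tibble(level_pct = c(5, 10, 25),
                     eti_low_pct = c(-20, -5, -3),
                     eti_high_pct = c(5, 5, 3))
glance(profile_from_intervals(iv, validation_design(m = 3)))
```

## What the synthetic-data generator emulates

`simulate_validation()` draws, per level, the measured quantity
$\mu_T(1+\text{bias}/100)(1+\delta_i+\varepsilon_{ij})$ with
$\delta_i \sim N(0,\sigma_B/100)$ one between-series effect per series per
level and $\varepsilon_{ij} \sim N(0,\sigma_W/100)$ replicate noise — exactly
the one-way random-effects structure the estimators assume, with noise
specified as a percent RSD of the noise-free value (relative noise matches
the roughly level-independent RSDs seen in practice).
`simulate_calibration()` additionally perturbs the slope once per series to
emulate day-wise calibration lines. Defaults mirror the motivating
three-series, seven-level captopril design: nominal 55.56 µg/mL, slope 3.5,
between-series slope RSD 0.1 % (the day-wise slopes of such assays differ in
the third decimal), per-level true biases between −2.3 and +3.5 %, and
$\sigma_W = \sigma_B = 1\%$, which lands repeatability and
intermediate-precision RSDs in the 0.6–2.3 % window typical of a validated
spectrophotometric assay.

What the generator does **not** emulate: heteroscedastic count-like noise,
drift within a series, carry-over between zones, non-Gaussian outliers, or
any chemistry (dispersion, kinetics). Passing tests therefore demonstrate
the statistical machinery under its stated model, not robustness of a real
instrument to model violations.

`simulate_dissolution_pair()` generates per-unit first-order release
$F(t)=f_\infty(1-e^{-kt})$ scaled by a per-unit effect, observed twice with
independent measurement noise — a pair of analytical methods measuring the
same tablets, exchangeable under the null of no method difference. Defaults
($f_\infty = 100\%$, $k = 0.15\,\text{min}^{-1}$, unit RSD 2.5 %,
measurement RSD 1 %) give ≈95 % release at 20 min and plateau SDs of 2–3 %,
the regime of a rapidly dissolving immediate-release tablet.

## Numerical choices and degenerate inputs

* **Truncation.** $\hat\sigma^2_B < 0$ is truncated to zero, so $R = 0$,
  $B^2 = 1$ and $s_R = s_r$ — the standard practice for negative
  variance-component estimates.
* **Zero variance.** A level with zero within-series variance has no
  estimable interval; by default this raises a classed degenerate-data
  error rather than silently producing a zero-width interval. Idealised
  noise-free data are still useful for exactness tests, so
  `allow_degenerate = TRUE` opts into collapsed intervals
  ($s_r = s_R = 0$, $\nu = \infty$).
* **Balance.** Unbalanced series are an error, never silently reweighted:
  the closed-form ANOVA and $\nu$ expressions assume balance.
* **Back-calculation.** Validation standards are inverted through their own
  series' calibration fit (day-wise calibration, as run in practice); the
  pooled fit across series is used only for the regression LOD
  ($3.3\,SD_b/s$), where pooling maximises the information in the intercept
  standard error.
* **Model selection.** `compare_response_models()` ranks candidates by
  widest valid range, then smallest mean interval half-width, then fewest
  parameters — so a one-point calibration is preferred only when it is not
  measurably worse.
* **Rounding.** Reports round percent statistics to 1 decimal and
  concentrations to 2 (`percent_to_concentration()` rounds half up);
  everything is carried at full precision internally.

## Properties checked by simulation, and a known limitation

The test suite verifies, with fixed seeds, that the estimators recover the
generator's truths (per-level bias to within ±0.1 % over 1000 replicated
designs; mean estimated $s_R$ within ±0.1 % of
$\sqrt{\sigma_W^2+\sigma_B^2}$, sitting slightly *under* it because the
square root of an unbiased variance estimate is itself downward-biased at
$p = 3$), and that the Monte-Carlo expected content of the $\beta$-ETI is
close to $\beta$ (2000 replicated designs per variance ratio, a size chosen
to keep the whole suite fast while holding the Monte-Carlo standard error
near 0.002).

The content check also documents the method's known weak spot: with only
$p = 3$ series the interval's expected content degrades as the
between-series component dominates — about 0.968/0.960/0.947/0.931 at
$\sigma_B/\sigma_W = 0, 0.5, 1, 2$ under the generating model. The last
figure sits at the edge of the $0.95 \pm 0.02$ band: a Satterthwaite-based
$\beta$-expectation interval is only approximate, and users whose assays
show dominant day-to-day variance should add series rather than trust the
nominal $\beta$ at $p = 3$.

The paired dissolution comparison holds its size (empirical type-I error
≈ 0.05 under the null generator, 2000 replicates).

## Scope decisions

* The USP Q-criterion is implemented as stage S1 only (every unit
  $\ge Q+5\%$ at the checkpoint): that is the decision rule quoted for
  rapidly dissolving products; S2/S3 staging and $f_1/f_2$ profile-similarity
  metrics are out of scope.
* No correction for withdrawn-sample volume is applied between time points
  by default — whether an autosampler replaces medium is instrument-specific
  and the cumulative correction is easy to apply upstream when needed.
* Weighted calibration models ($1/x$, $1/x^2$) are available as candidates
  but off by default; $\beta$-content (γ-confidence) tolerance intervals
  are not implemented.
* The zone-fluidics module covers the sequence *arithmetic* (cycle time,
  throughput, per-port consumption, volume audit); it does not model
  dispersion or control hardware.

## A complete run

```{r, fig.width = 6, fig.height = 4}
report <- run_pipeline(run_config(seed = 7))
glance(report$profile)
tidy(report$profile) |>
  select(level_pct, bias_pct, s_r_pct, s_R_pct, eti_low_pct, eti_high_pct)
autoplot(report$profile)
```
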