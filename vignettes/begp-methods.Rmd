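---
title: "Modelling diurnal heart-rate baselines with a basis-expansion Gaussian process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diurnal heart-rate baselines with a basis-expansion Gaussian process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(begp)
```

## The problem

Wrist-worn photoplethysmography (PPG) sensors make continuous heart-rate (HR)
monitoring cheap and unobtrusive, which matters most for older adults whose
cardiovascular state needs day-to-day attention. The data they produce are
poor, in two specific ways: measurements carry substantial noise and sporadic
motion-artifact shocks, and whole stretches of the day are missing at once —
the device is charging, was taken off, or lost its connection — so gaps arrive
as contiguous blocks of an hour or more, not as scattered holes. Summary
statistics (a daily mean, a cut-off) throw away the diurnal pattern; generic
Gaussian-process imputation with stationary kernels is expensive at
one-sample-per-minute scale and struggles with the strongly non-stationary
day shape.

`begp` implements a functional-data-analysis answer: represent each day's
latent HR curve in a low-dimensional B-spline basis, learn a personalized
*baseline* — the subject's typical diurnal curve plus its day-to-day
variability — from a couple of weeks of history, and then *calibrate* that
baseline against each new day's measurements by a closed-form Bayesian
update. The result is a denoised, gap-free curve with honest pointwise
uncertainty.

## The model

Time $t$ lives on one diurnal period $[0, 24]$ hours. The latent curve is a
basis expansion

$$x(t) = \Phi(t)^\top C, \qquad
  \Phi(t) = (\phi_1(t), \dots, \phi_P(t))^\top,$$

with $P$ clamped B-spline functions and coefficient vector $C$. Observations
on day $i$ at timestamps $T_i$ (length $N_i$) are

$$y_{ij} = x_i(t_{ij}) + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \overset{iid}{\sim} N(0, \sigma^2),$$

and the day-to-day variation of the coefficients is modelled as
$C_i \sim N(C, \Sigma_C)$. Together these induce a Gaussian process with
basis-structured mean and covariance functions

$$\mu(t) = \Phi(t)^\top C, \qquad
  k(t, \tau) = \Phi(t)^\top \Sigma_C\, \Phi(\tau),$$

which is the *baseline*: `baseline_mean()`, `baseline_cov()` and
`baseline_band()` evaluate $\mu$, $k$ and the $\mu \pm 3\sqrt{k(t,t)}$ band.

### Estimation (method of moments, closed form)

Each day is fit by least squares on the basis kernel matrix
$\Phi(T_i)$ ($P \times N_i$):

$$\hat C_i = \left[\Phi(T_i)\Phi(T_i)^\top\right]^{-1}\Phi(T_i) Y_i,$$

with residuals $\epsilon_i = (I_{N_i} - H_i) Y_i$ and hat matrix
$H_i = \Phi(T_i)^\top[\Phi(T_i)\Phi(T_i)^\top]^{-1}\Phi(T_i)$. Pooling $M$
retained days:

* $\bar C = M^{-1}\sum_i \hat C_i$ — the coefficient mean, used as the prior
  mean;
* $\hat\sigma^2 = M^{-1}\sum_i \epsilon_i^\top\epsilon_i /
  \mathrm{trace}(I_{N_i} - H_i)$ — unbiased for the noise variance;
* $\hat\Sigma_C = S_C - (\hat\sigma^2/M)\sum_i
  [\Phi(T_i)\Phi(T_i)^\top]^{-1}$, where $S_C$ is the outer-product sample
  covariance of the $\hat C_i$ with divisor $M - 1$. The subtraction removes
  the estimation noise that $S_C$ carries on top of the true between-day
  covariance, making $\hat\Sigma_C$ unbiased for $\Sigma_C$.

$S_C$ is written in some treatments with an inner rather than outer product,
which would be a scalar; the only form conformable with the debiasing
subtraction (and with $k(t,\tau)$) is the standard $P \times P$ sample
covariance, which is what `estimate_baseline()` computes.

### Calibration

Given a new day's measurements $Y^*$ at timestamps $T$, conjugacy gives the
posterior over that day's coefficients in closed form:

$$C^* = \bar C + \hat\Sigma_C \Phi \left[\Phi^\top \hat\Sigma_C \Phi
        + \hat\sigma^2 I\right]^{-1} (Y^* - \Phi^\top \bar C),$$
$$\Sigma^* = \hat\Sigma_C - \hat\Sigma_C \Phi \left[\Phi^\top \hat\Sigma_C
        \Phi + \hat\sigma^2 I\right]^{-1} \Phi^\top \hat\Sigma_C,$$

implemented in `calibrate_day()`. The posterior curve
$x^*(t) \sim GP(\Phi^\top C^*,\ \Phi^\top \Sigma^* \Phi)$ is the calibrated
estimate; `impute_gaps()` evaluates it across data gaps and flags grid
points more than a configurable distance (default 1 h) from any observation,
where the curve is prior-driven. With no observations the posterior *is* the
prior; conditioning can only shrink the pointwise variance, which the test
suite verifies as a Loewner-ordering property.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_basis` | 13 | — | one inflection per ~2.4 h resolves a diurnal swing without chasing noise |
| `order` | 4 (cubic) | — | the standard FDA smoothness default; HR dynamics are differentiable |
| knots | uniform, clamped | h | nothing in the method favours non-uniform placement; clamped ends keep the partition of unity |
| `ridge` | 0 | — | the closed-form estimators assume plain least squares; ridge is an opt-in stabilizer |
| `min_obs` | `n_basis + 2` | obs | a full-rank fit plus spare residual degrees of freedom |
| `vif_max` | 10 | — | identifiability cap, see below |
| `k_sigma` | 3 | sd | the conventional "possible range" band |
| `include_noise` | `FALSE` | — | the band describes the latent curve; set `TRUE` for a predictive band on raw observations |
| `max_gap_hours` (imputation flag) | 1 | h | beyond one hour from data the curve is mostly prior |
| `max_gap_hours` (benchmark alignment) | 5/60 | h | nearest-neighbour match tolerance between the two sensors |

The basis dimension and order are genuinely open choices: the method is
agnostic to the basis family, and nothing in the estimators pins $P$. The
defaults are exposed in every entry point and in the `model` block of the
run configuration.

## Numerical choices

* **Gram solves.** Per-day coefficients come from a Cholesky solve of the
  $P \times P$ Gram matrix. A day whose Gram matrix has relative condition
  above $10^{10}$ is flagged `rank_ok = FALSE` and solved by the
  minimum-norm pseudo-inverse instead of erroring — such days surface in
  `excluded_days` when a baseline is pooled.
* **Identifiability filter (`vif_max`).** Block missingness can leave a
  basis function with almost no data under its support. Such a day passes
  the rank test — condition number $10^5$–$10^9$ — yet its least-squares
  coefficient can land thousands of bpm away from truth, and a single such
  day wrecks the pooled mean and covariance. The diagonal of the inverse
  Gram matrix is exactly the factor by which $\sigma^2$ is inflated in each
  coefficient estimate, so `estimate_baseline()` excludes days where any
  entry exceeds `vif_max = 10` (every coefficient estimable to within about
  $3\sigma$). On a healthy 1-minute day this diagnostic is below 2.5; on a
  gap-crippled day it is in the thousands, so the filter separates cleanly.
  Exclusion depends only on timestamps, never on values, so it introduces
  no bias.
* **Indefinite covariance.** $\hat\Sigma_C$ is unbiased but can be
  indefinite in finite samples. The raw estimate is kept for diagnostics
  (`coef_cov_raw`); everywhere a variance is formed, the eigenvalue-clipped
  PSD repair (`psd_repair()`) is used. Clipping never raises an eigenvalue.
* **The $N \times N$ calibration system** is solved by Cholesky
  factorization, retried once with a jitter of $10^{-10}$ times the mean
  diagonal, never by explicit inversion; $\Sigma^*$ is symmetrized and
  PSD-repaired afterwards. A prior with exactly zero covariance returns the
  prior unchanged rather than attempting a degenerate solve.
* **Exact symmetry.** $k(t, \tau)$ averages the two evaluation orders of
  the quadratic form, so `baseline_cov(b, t, tau)` and
  `baseline_cov(b, tau, t)` are bit-identical, not merely close.
* **Serialization** (baseline JSON, dataset CSVs) renders doubles with 17
  significant digits, the width guaranteed to round-trip IEEE doubles
  through decimal exactly; ingestion uses the C-library `strtod` path,
  which parses correctly rounded.

## The synthetic-data generator

Real cohort recordings of this kind are not redistributable, so the package
ships a seeded generator (`sim_config()`, `simulate_hr_dataset()`) that
emulates the data-collection setting the method targets, and every
statistical claim in the test suite is made against it:

* a smooth diurnal truth curve per subject (low nocturnal HR, a daytime
  elevation of at least 12 bpm, bounded in [45, 110] bpm), projected onto
  the basis; day-to-day coefficient variation with an AR(1)-correlated
  covariance giving a curve-scale sd of roughly 2–4 bpm;
* additive i.i.d. Gaussian sensor noise (default sd 3 bpm);
* motion-artifact shocks: a Bernoulli 5% of samples receive an additional
  shock with sd 25 bpm (optionally one-sided positive, as PPG artifacts
  typically inflate HR). The artifact rate and magnitude are placeholders —
  consumer devices do not publish artifact characteristics — and both are
  configuration fields;
* contiguous-block missingness: exponential block lengths (mean 1 h)
  deleted until a target fraction (default 0.25, within the 0.12–0.42 range
  reported for comparable cohorts) is reached, the last block trimmed so
  the realized rate is exact to one sample;
* a paired dense "ECG-like" reference sensor (noise sd 1 bpm, no
  artifacts, lighter independent missingness) playing the role of a
  chest-strap ground truth;
* two weeks of collection: 15 days at 1-minute resolution. One-second
  device rates exist, but minute resolution keeps a full cohort benchmark
  in seconds of compute and changes nothing structural; the resolution is a
  configuration field.

Each mechanism draws from its own seeded RNG stream, so switching artifacts
off does not perturb the noise or the missingness under the same seed — the
test suite relies on this to isolate mechanisms.

What the generator does **not** emulate: circadian phase shifts across days,
activity-driven heteroscedasticity, device quantization, and
heart-rate-variability structure within the minute. Passing tests therefore
demonstrate correctness of the estimators and the update under the model's
own assumptions plus artifact/missingness contamination — not performance on
any particular real device.

## The benchmark

`run_benchmark()` scores five estimators against the reference sensor under
leave-one-day-out: for each test day the baseline is fit on the remaining
days and calibrated with the test day's *noisy* data only.

* **A** — the raw noisy sensor, nearest-timestamp matched;
* **B** — the population mean of all subjects' historical values;
* **C** — the subject's own historical mean;
* **D** — the subject's baseline functional mean;
* **E** — the calibrated functional mean (the method under study).

Alignment between the two sensors' irregular timestamps is
nearest-neighbour with a 5-minute cap, and unmatched test points are dropped
from *all* methods, so every method is scored on the identical test set.
The error SD uses divisor $n - 1$; method B weights observations, not
subjects (a per-subject-weighted variant would differ only when collection
lengths differ). On synthetic cohorts the expected ordering
$E \le D \le C \le B$ and $E \le A$ holds, and removing the artifact
mechanism narrows the E-vs-A gap, confirming that robustness to artifacts
is where the calibrated estimate earns most of its advantage.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations to make
each statistical property sharp but cheap: 100 random instances for
posterior-oracle equivalence, 500 replicates at $M = 20$ days and
$N = 100$ samples/day for estimator unbiasedness, 100 replicates per
setting for the consistency sweeps ($M \in \{10, 50, 200\}$,
$N \in \{5, 20, 100\}$), and cohorts of 5–50 synthetic subjects at the
default generator settings for the benchmark ordering. These sizes are the
package's own choice of what makes the Monte-Carlo standard errors small
relative to the effects being tested.

## Known limitations

* The noise model is homoscedastic and Gaussian; motion artifacts violate
  it by construction. The method's robustness comes entirely from the
  smoothing and the prior, not from a robust likelihood — a heavy-tailed
  observation model would be the natural extension.
* Calibration is day-by-day; no information flows between calibrated days
  (no Kalman-style recursion), and baselines are strictly per subject.
* The basis interface ships B-splines only; the containers are
  basis-agnostic, but wavelet or Fourier systems would need a new
  constructor.
* With fewer than two usable history days no baseline exists; the
  identifiability filter can push short, gappy collections under that
  limit, which is reported as an error listing the excluded days and
  reasons.
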