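---
title: "Information-transfer constants for EEG: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-transfer constants for EEG: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iekappa)
```

## The model

`iekappa` treats a single-channel EEG recording as an information-transfer
process from the time domain to the scalp-recorded voltage. Under the
assumption of ideal transfer (information equilibrium), the relative change
of the destination variable is tied to the relative change of the source by
a constant ratio. For a voltage series $V(t)$ sampled at rate $f_s$, that
ratio is estimated at every instant as

$$\kappa(t; \Delta t) \;=\; \frac{\ln\lvert V(t+\Delta t) - V(t)\rvert}{\ln \Delta t},$$

with $\Delta t$ in seconds and natural logarithms throughout. If the
increments follow a power law $\lvert \Delta V\rvert \sim \Delta t^{\kappa_{\mathrm{avg}}}$,
then $\kappa_{\mathrm{avg}}$ — the arithmetic mean of the per-instant values
over a segment — is exactly that exponent. Three segment-level statistics
feed the group analysis:

* `kappa_avg`, the mean retained $\kappa$ at each $\Delta t$;
* `low_it_fraction`, the fraction of $\kappa$ values below 0.2 at the
  sampling-rate lag, a heuristic marker of low information transfer that is
  elevated in deep sleep;
* `significant_power`, the summed normalized Lomb-Scargle power of the
  kernel-density estimate of the $\kappa$ sample over frequencies whose
  peak significance clears $p \le 0.01$ — a measure of the comb-like
  periodicity of preferred $\kappa$ magnitudes.

States of consciousness are then compared segment-wise by a
repeated-measures ANOVA with Bonferroni correction.

## Estimator conventions

Several conventions are under-determined by the model and fixed here
explicitly:

**$\Delta t$ in seconds, lag in samples.** The log argument is the interval
in seconds; the sample lag is `round(delta_t_s * fs)`. This makes
$\ln\Delta t$ change sign at 1 s, which is why `kappa_avg` is positive at
sub-second intervals and negative at $\Delta t = 4$ s for signals whose
increments stay below one voltage unit. $\Delta t = 1$ s is rejected
outright (zero denominator), and an interval that is not a whole number of
samples (relative rounding error above $10^{-6}$) is an error unless
`allow_lag_rounding = TRUE`.

**Exclusion rule and the mean's denominator.** Instants with
$V(t) = V(t+\Delta t)$ — common in integer-quantized recordings at short
lags — are excluded, since $\ln 0$ is undefined. Only exact ties are
excluded; no epsilon tolerance. The mean divides by the count of *retained*
values, not by the number of candidate instants: an excluded datum carries
no evidence that $\kappa = 0$, so letting it shrink the mean toward zero
would bias segments with heavy quantization. The exclusion count is
reported separately (`n_excluded`), and a segment whose instants are all
excluded raises a typed "degenerate segment" error rather than returning
`NaN`.

**Units.** $\kappa$ involves the log of a dimensional quantity, so it is
unit-dependent: rescaling the voltage by $a$ shifts every value by
$\ln a / \ln\Delta t$ (an identity the test suite asserts to floating-point
precision). Readers therefore preserve the recording's native unit label,
never rescale, and every summary row carries the unit. Comparisons across
datasets are meaningful only with matched units.

## Periodicity of the $\kappa$ distribution

The density of a segment's $\kappa$ sample is estimated with
`stats::density`: Gaussian kernel, rule-of-thumb bandwidth
$0.9\,\min(\mathrm{SD}, \mathrm{IQR}/1.34)\,n^{-1/5}$, 512 grid points on
$[\min - 3bw, \max + 3bw]$. The density curve is then treated as a signal
over the $\kappa$ axis and analyzed with the classical variance-normalized
Lomb-Scargle periodogram (mean subtraction, time-shift parameter $\tau$,
power in units of the density's sample variance), on the standard
oversampled frequency grid: spacing $1/(\mathrm{span}\cdot 4)$ up to
$n_\mathrm{grid}/(2\cdot\mathrm{span})$.

Significance uses the peak false-alarm relation
$p = 1 - (1 - e^{-z})^M$ with the number of independent frequencies taken
heuristically as $M = 2\,n_\mathrm{grid}$; at the defaults
($n_\mathrm{grid} = 512$, $p \le 0.01$) the cutoff is $z \approx 11.53$.
The statistic is the *sum* of normalized power over frequencies at or above
the cutoff (boundary inclusive); a switch (`area = "trapezoid"`) integrates
over frequency instead, for users who prefer a spectral-area reading.

Two properties of this construction deserve emphasis:

* A genuine comb in the $\kappa$ distribution (equally spaced modes at
  spacing $d$) produces a significant peak within one grid step of $1/d$,
  provided the KDE bandwidth does not smooth the comb away — which
  requires, roughly, $n \gtrsim (0.8\,k)^5$ samples for $k$ modes. The
  detection test uses 8 modes at $n = 15{,}000$, comfortably inside that
  regime.
* The exponential null calibration applies to flat-spectrum noise *on the
  grid*. A KDE density is never that: even a structureless Gaussian
  $\kappa$ sample yields a smooth unimodal curve whose low-frequency power
  exceeds the cutoff essentially always (measured rate 100%). The
  `significant_power` of a real segment is therefore dominated by the
  distribution's overall shape, with the comb adding to it; it should be
  read as a *relative* statistic compared across states — which is how the
  group analysis uses it — not as evidence that any one segment is
  "significantly periodic". The acceptance suite records this measured
  false-positive behaviour rather than hiding it.

## Group comparisons

Segment-level metrics are stacked into a long table keyed by (subject,
state, segment, $\Delta t$, metric). `rm_anova` compares two states by a
sequential fixed-effects decomposition: state first (1 df), subject next
($n_\mathrm{subj} - 1$ df), residual error with
$N - 1 - 1 - (n_\mathrm{subj} - 1)$ df; $F$ is the state mean square over
the error mean square. Segments enter as replicates (they are not averaged
per subject first — the between-segment spread is part of the error term).
Unbalanced designs — subjects missing a state, unequal segment counts —
enter the sequential decomposition as observed, and lone-state subjects are
flagged. The implementation is deliberately simple and is verified, across
randomized small designs, against a brute-force sums-of-squares oracle
coded independently of the fitting route.

Bonferroni correction defaults to the family of time scales within one
(state pair, metric) — $m = 4$ under the default grid — and is overridable.
Mixed-model alternatives (e.g. unstructured within-subject covariance) are
intentionally out of scope; the cohort table exports cleanly for users who
want them.

## What the synthetic cohort emulates

The generator reproduces the study conditions the statistics were designed
for: 250 Hz single-channel voltage segments of one minute, grouped by
subject and state, with amplitudes of order $10^{-2}$–$10^{0}$ mV-like
units so that multi-second $\kappa$ values go negative as they do on real
recordings. Ground truth comes from signal families with closed-form
expectations:

* ramps and alternating signals pin the estimator identities exactly;
* `powerlaw_increment` signals have $\lvert\Delta V\rvert = c\,\Delta t^{\kappa_0}$
  exactly at one declared lag, so `kappa_series` must return
  $\kappa_0 + \ln c / \ln \Delta t$ to machine precision;
* fractional Brownian motion is synthesized by circulant embedding
  (Davies-Harte), which reproduces the increment covariance
  $\mathrm{Var}[\Delta V] = \sigma^2 \Delta t^{2H}$ *exactly*, so
  $E[\kappa] = H + (\ln\sigma + E\ln\lvert Z\rvert)/\ln\Delta t$ with
  $E\ln\lvert Z\rvert = -(\gamma + \ln 2)/2$ is a sharp test, and the
  regression of mean $\ln\lvert\Delta V\rvert$ on $\ln\Delta t$ recovers
  $H$. The embedding is padded to a power-of-two FFT length; this changes
  nothing in the covariance.

Cohorts place the waking-like and deep-sleep-like states at $H = 0.30$ and
$H = 0.50$ ($\sigma = 0.1$), with a per-subject Gaussian offset
(SD 0.03, shared across the subject's states and clipped to
$(0.05, 0.95)$) standing in for stable individual differences; 10 subjects
with 8 one-minute segments per state mirror the design the pipeline
targets. At the 0.004 s lag this yields a mean-$\kappa$ contrast of
0.20 — detected at $p < 0.01$ in every seeded replicate — while
identical-state null cohorts reject at roughly the nominal rate after
correction.

What the generator does *not* emulate: oscillatory EEG rhythms, movement
and breathing artifacts, integer ADC quantization (except in the EDF writer,
which quantizes to 16 bits), non-Gaussian heavy tails, and nonstationarity
within a segment. Passing tests on these surrogates therefore validate the
*estimators and statistics*, not any claim about real sleep recordings.

## Numerical choices and degenerate inputs

* CSV time bases must be uniform to 1 part in $10^4$; the rate snaps to an
  integer when the time column was printed at finite precision.
* EDF reading uses the per-signal digital-to-physical scaling; the fixture
  writer spans the sample range over the 16-bit digital range, so
  round-trips agree to one quantization step.
* KDE requires at least 10 finite values and nonzero spread; the
  periodogram requires a non-constant density. Both failure modes raise
  typed degenerate-data errors (CLI exit code 4), and the periodicity
  command skips such segments with a warning instead of aborting a run.
* Problem sizes in the test and acceptance runs — 10 fBm seeds for Hurst
  recovery, 100 randomized ANOVA tables, 200 calibration draws, 100 cohort
  replicates — were chosen as the smallest sizes at which the Monte-Carlo
  standard errors are comfortably below the asserted margins.
* TSV outputs print floats at 6 significant digits in a fixed row order,
  so identical configs and seeds produce byte-identical files.

## Known limitations

Absolute `kappa_avg` values depend on the recording unit, so they are not
comparable across datasets with unknown units — only within-dataset
contrasts are. The `significant_power` statistic inherits the
shape-dominance caveat above. The ANOVA treats segments as exchangeable
replicates within subject and state; temporally adjacent segments of a
recording are correlated for $H \ne 1/2$ signals and in real EEG, which the
fixed-effects error term does not model. No artifact detection is
attempted: segment selection is the user's responsibility.
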