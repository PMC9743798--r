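---
title: "Measuring maternal-fetal RR-interval coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring maternal-fetal RR-interval coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcoupling)
```

## The measurement problem

Heart-rate variability is driven by the autonomic nervous system, and the
maternal and fetal circulations are autonomically independent. If fetal
RR-interval (RRI) fluctuations nevertheless track maternal ones, some
mediator couples the two systems, and the strength of that coupling is a
candidate marker of fetal development. The package quantifies this
coupling from one primitive observable per subject: the sequence of beat
times (equivalently RR intervals) recorded simultaneously for a mother and
one of her fetuses on a shared clock.

Two obstacles shape the design. First, the two tachograms are irregularly
sampled at very different rates (mouse-scale defaults: maternal RRI
~130 ms, fetal RRI anywhere from ~300 to ~1000 ms), so they must be
brought onto a common grid before any bivariate statistic is meaningful.
Second, in-vivo recordings contain noise and arrhythmic stretches, so the
analysis is restricted to screened, artifact-free epochs.

## The pipeline

### Epoch selection

The first 60 s of every recording are discarded (settling artifacts), then
3-minute windows are slid in 1-s steps and kept when **both** subjects
pass screening. Absent a published numeric criterion for "no noise or
consistent arrhythmia", screening is a deterministic stand-in for manual
inspection: a window fails if any RRI deviates from the window median by
more than 30 %, or leaves a physiological band (maternal 50–300 ms, fetal
200–1100 ms; the fetal band brackets the 306–981 ms range of mean fetal
RRI seen in anesthetized pregnant mice). After an accepted epoch the
search resumes at its end, so clean recordings yield consecutive epochs.
Dyads with fewer than two clean epochs are flagged and, by default,
excluded — the conventional inclusion rule. All thresholds sit in
`quality_config()`.

### Resampling and normalization

Each tachogram is averaged into 2-s bins (`resample_uniform()`): bin *k*
holds the mean of the intervals whose terminating beat falls in
[start + 2k, start + 2(k+1)) s. Two seconds is the shortest bin that
always contains at least one fetal beat (mean fetal RRI reaches ~1 s), and
a 3-minute epoch gives exactly 180/2 = 90 samples at 0.5 Hz. An empty bin
is an error by default; `gap_policy = "interpolate"` fills it linearly
instead. Each series is then normalized
(`x' = (x - mean(x)) / max|x - mean(x)|`), which fixes mean 0 and peak
amplitude exactly 1. The epoch mean of the *resampled* series is used —
the natural reading once resampling precedes normalization in the chain.
A constant series cannot be normalized and raises a degenerate-signal
error rather than producing NaNs.

### Windowed cross-correlation (CC1, CC2)

The 90 normalized samples are cut into nine consecutive, non-overlapping
10-sample windows; per window the statistic is the **zero-lag** normalized
cross-correlation `r_w = sum(m f) / sqrt(sum(m^2) sum(f^2))`. Zero lag is
the only per-window summary that keeps sign information — required because
the signed mean CC2 must distinguish positive from mirrored similarity —
and matches a generator whose coupling is instantaneous. A
`lag_policy = "max_abs"` option keeps the largest-magnitude lagged
coefficient instead, for sensitivity analyses. Windows are *not*
re-centred (the epoch mean was already removed once; `center_windows`
flips this), a window that is identically zero has an undefined
coefficient and is excluded from both means rather than imputed, and a
trailing remainder shorter than one window is dropped with a warning.
CC1 = mean |r_w| and CC2 = mean r_w, so |CC2| <= CC1 <= 1 identically.

### Welch coherence (CLF, CHF)

Frequency-domain similarity uses Welch magnitude-squared coherence
(`msc_spectrum()`): 10-sample segments, Hamming taper, 50 % overlap,
zero-padded 256-point FFT — the conventional defaults of the reference
implementation once segment length 10 and fs = 0.5 Hz are fixed. Ninety
samples give 17 averaged segments; a single segment is refused, since
one-segment coherence is identically 1. Frequencies run 0–0.25 Hz with
spacing fs/256. The band summaries are the **mean** coherence over
LF = [0.04, 0.15) Hz and HF = [0.15, 0.25] Hz (human-defined bands,
applicable because fetal mean RRI lies in the 306–981 ms range); a mean
keeps CLF/CHF in [0, 1]. The shared 0.15 Hz edge is counted once, in HF.
The implementation was validated bin-for-bin (to ~1e-13) against an
independent reference implementation of Welch coherence with matching
parameters; those frozen values live in the test suite.

### Cohort statistics

Every test is gated by Shapiro–Wilk at alpha = 0.05 (the alpha implied by
conventional significance reporting): trends against embryonic day use
Pearson when both variables pass, Spearman otherwise; group comparisons
use one-way ANOVA / Welch t when every group passes, Kruskal–Wallis /
Wilcoxon rank-sum otherwise. "Wilcoxon" here is the two-sample rank-sum
test — all contrasts are between independent groups, so the signed-rank
variant never applies; the nonparametric omnibus across four stages is
Kruskal–Wallis, the standard rank analogue of one-way ANOVA. Embryonic
day is treated as a numeric covariate; because it takes only four values,
it always fails the gate and auto-gated trends are effectively Spearman
(`method = "pearson"` forces the alternative). Pairwise stage contrasts
are reported unadjusted by default, with an optional Holm flag.

Two design caveats are deliberate mirrors of common practice rather than
best practice: each (fetus, epoch) row counts as one observation (an
`aggregate = "epoch_mean"` option averages epochs within fetus first), and
fetuses sharing a mother are not modeled as clustered. Both inflate the
effective sample size; p-values from `compare_groups()` should be read
accordingly. Mixed-effects modeling of mother-level clustering is out of
scope.

## The synthetic dyad generator

`simulate_dyad()` produces the data the pipeline needs with known ground
truth:

* **Maternal instantaneous RRI**: mean 130 ms plus an LF sinusoid
  (0.08 Hz, amplitude 8 ms), an HF sinusoid (0.2 Hz, half amplitude,
  random phase) and AR(1) noise (phi = 0.9 on a 100-ms grid, sd 2 ms).
  130 ms is a literature-typical anesthetized-mouse placeholder, exposed
  as a parameter rather than asserted as fact.
* **Fetal instantaneous RRI**: mean drawn uniformly from 306–981 ms (the
  observed range of mean fetal RRI), plus `sign * rho * g * (maternal
  fluctuation)` and an independent AR(1) component (phi = 0.98,
  correlation time ~5 s). The gain g rescales maternal fluctuation to the
  fetal fluctuation scale (`fetal_noise_sd`, 25 ms), and the coupled and
  independent parts carry variance shares rho^2 and 1 − rho^2, so the
  expected maternal–fetal correlation is approximately rho. The
  independent component must be *slow*: per-bin averaging attenuates
  fast noise, and white fetal noise would vanish at 0.5 Hz, making every
  weakly coupled dyad look perfect.
* **Beat times** integrate the instantaneous RRI (next beat after one
  interval), evaluating the fluctuation at the interval midpoint — with
  start-point evaluation the slow fetal sampling lags the dense maternal
  sampling by half a fetal interval, which visibly depresses recovered
  coupling at rho = 1. Times are quantized to 1 ms, mirroring 1 kHz
  acquisition, and an instantaneous RRI below 10 % of the mean is clipped
  with a warning counter.

The test suite verifies the calibration property directly: across
rho in {0, 0.25, 0.5, 0.75, 1} (50 dyads each, fixed seeds) the median CC1
increases strictly and median CC2 tracks rho and its sign almost exactly.

### Cohort scenarios

`cohort_scenario("development")` draws the typical-development design:
stages ED13.5/15.5/17.5/18.5 with 6/6/10/7 mothers carrying 10/10/17/11
analyzed fetuses (two fetuses per mother where counts allow, sharing their
mother's simulated series, as in a real simultaneous recording) and a
coupling schedule 0.2/0.4/0.6/0.8 — a smooth increase emulating the
maturation of whatever mediates the coupling.
`cohort_scenario("asd")` draws a saline and a VPA arm (ED15.5: 8 + 8
mothers, 13 + 13 fetuses; ED18.5: 5 + 5 mothers, 7 + 7 fetuses); the VPA
arm's coupling is the schedule times 0.3 at ED15.5 and 0.95 at ED18.5 —
strongly reduced early, essentially caught up late, emulating delayed
development.

Two heterogeneity features make the cohorts realistic rather than
idealized, and their defaults (both sd 0.15) were set from the qualitative
spread real data show — within one stage, dyads range from weakly to
almost perfectly coupled, and two fetuses of the same mother can
simultaneously show strong positive and strong negative similarity:

* **per-dyad jitter**: each dyad's coupling is its scheduled value plus
  Gaussian jitter, truncated to [0, 1];
* **within-recording drift**: the effective coupling gain wanders slowly
  (correlation time ~150 s), so the two epochs of one dyad are correlated
  but not duplicate observations.

Without these, every dyad at a stage scores nearly identically, and any
arbitrarily small group difference becomes statistically detectable — the
opposite of how real cohorts behave. Even with them, the two-epochs-per-
fetus convention leaves residual pseudo-replication, so with one master
seed out of several a small ED18.5 saline-vs-VPA difference can reach
nominal significance; this is a property of the mirrored statistical
design, not of the scoring.

What the generator does **not** emulate: anesthetic heart-rate drift,
fetal behavioral states, sex effects, real fetal-ECG extraction noise, or
any physiological waveform morphology (`synth_ecg()` draws schematic
Gaussian R bumps purely to exercise the peak detector). Passing tests
therefore demonstrate that the pipeline recovers known coupling under
controlled conditions, not that the scores are unbiased on real
recordings.

## Numerical choices and degenerate inputs

* All internal times are milliseconds; seconds are converted at I/O.
* Per-window and per-segment energies of exactly zero yield a missing
  coefficient (never 0/0); constant series are refused by normalization.
* The peak detector thresholds at mean + 0.4 (max − mean) with a 50-ms
  refractory period, keeping the taller of two peaks closer than the
  refractory window; it pads the trace ends so a peak in the first or
  last sample is still found. It is a toy-trace utility, not a QRS
  detector.
* Ties in Spearman and rank-sum branches use the standard asymptotic
  approximations (`exact = FALSE`).
* Problem sizes in the test suite — 50 dyads per coupling level,
  full-size development (48 dyads) and treatment (40 dyads) cohorts,
  2000-replicate calibration nulls, 500-pair oracle sweeps — were chosen
  as the smallest sizes at which the checked properties are stable, and
  run in well under a minute each.

## Known limitations

* CC2's sign summarizes net direction only; with mixed positive and
  negative windows it attenuates toward 0, which is why CC1 is the
  primary strength measure.
* Resampling at 2 s discards fetal spectral content above 0.25 Hz, so HF
  coherence reflects band-limited similarity, not full fetal HF activity.
* The statistical battery mirrors a conventional design that treats
  correlated rows as independent (see caveats above).
* Epoch screening is a fixed rule; pathological rhythms that stay within
  the deviation and band limits pass it.
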