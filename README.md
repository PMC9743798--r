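# mfcoupling

Quantifying the similarity between maternal and fetal heart rhythms from
simultaneous RR-interval (RRI) recordings.

## The problem

In a pregnant animal the maternal and fetal circulations are separate, yet
beat-to-beat fluctuations of the fetal heart rate can track — or mirror —
those of the mother, and the strength of that coupling changes with
gestational age. `mfcoupling` implements the standard epoch-based analysis
of this phenomenon for dyads of simultaneously recorded beat sequences
(mouse-scale defaults: maternal RRI ~130 ms, fetal RRI ~300–1000 ms,
15-minute recordings at 1 kHz timing resolution). It is written for
physiologists and biomedical-signal analysts who have paired beat or RRI
series and want reproducible similarity scores plus the cohort-level
statistics built on them.

## The method

For each artifact-free 3-minute epoch shared by a dyad:

1. **Resample** both RRI tachograms onto a common 2-s grid (0.5 Hz) by
   per-bin averaging — 90 samples per epoch. A 2-s bin is the shortest that
   is guaranteed to contain a fetal beat.
2. **Normalize** each series: `x' = (x − mean(x)) / max|x − mean(x)|`,
   giving mean 0 and peak amplitude exactly 1, so the very different
   maternal and fetal RRI scales become comparable.
3. **Windowed cross-correlation**: cut the 90 samples into nine 10-sample
   windows and compute, per window, the zero-lag normalized
   cross-correlation `r_w = Σ m f / √(Σ m² Σ f²)`. The epoch scores are
   **CC1** = mean |r_w| (strength of similarity, in [0, 1]) and
   **CC2** = mean r_w (its net sign, in [−1, 1]); always |CC2| ≤ CC1.
4. **Coherence**: Welch magnitude-squared coherence
   `C(f) = |Pxy|² / (Pxx Pyy)` (10-sample Hamming segments, 50 % overlap,
   256-point FFT; frequencies 0–0.25 Hz), averaged over the LF band
   0.04–0.15 Hz (**CLF**) and the HF band 0.15–0.25 Hz (**CHF**).

Cohort tables of scores are then analyzed with a Shapiro–Wilk-gated
battery: Pearson/Spearman trends against embryonic day, and one-way
ANOVA / Kruskal–Wallis / Wilcoxon rank-sum group comparisons (e.g. a
saline vs VPA treatment contrast per stage).

Because paired in-vivo recordings are rarely shareable, the package also
ships a synthetic dyad generator with known coupling strength ρ, sign,
spectral content and cohort structure, used by the test suite to validate
the whole pipeline end to end.

## Worked example

```r
library(mfcoupling)

dyad     <- simulate_dyad(dyad_params(coupling_rho = 0.8, seed = 2024))
maternal <- beats_to_rri(dyad$maternal)
fetal    <- beats_to_rri(dyad$fetal)

epochs <- select_epochs(maternal, fetal)   # two clean 3-min epochs after t = 60 s
fit    <- score_epoch(epochs[[1]])
fit
#> Maternal-fetal RRI similarity
#>   epoch: [60000, 240000] ms (180 s), 9 valid CC windows
#>   cc1   cc2   clf   chf
#> 0.813 0.813 0.763 0.793
```

The dyad was simulated with coupling ρ = 0.8 and positive sign; the fitted
scores recover that: CC1 = CC2 = 0.81 (strong, uniformly positive
similarity — all nine window coefficients are positive), and both band
coherences sit near 0.8. `summary(fit)` additionally lists the nine
per-window coefficients; `plot(fit)` draws the normalized series, the
window coefficients and the coherence spectrum.

A full cohort, scored and tested:

```r
co     <- simulate_cohort(cohort_scenario("development"), seed = 2024)
scores <- analyze_cohort(co)             # one row per (dyad, epoch)
st     <- cohort_stats(scores, design = "development")
st$trends
#>  coefficient   method     r        p  n
#>          cc1 spearman 0.875 2.50e-31 96
#>          cc2 spearman 0.873 4.35e-31 96
#>          clf spearman 0.858 5.92e-29 96
#>          chf spearman 0.794 4.71e-22 96
```

The development scenario schedules coupling to rise with embryonic day
(ρ = 0.2 → 0.8 across ED13.5 → ED18.5), and all four coefficients show the
corresponding positive, significant trend.

A small command-line front end wraps the same functions:

```sh
Rscript inst/cli/mfcoupling.R simulate --scenario development --seed 7 --outdir raw/
Rscript inst/cli/mfcoupling.R analyze  --manifest raw/manifest.csv --outdir scored/
Rscript inst/cli/mfcoupling.R stats    --scores scored/scores.csv --design development --outdir stats/
```

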