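# lakescape

Ecoacoustic analysis of lake soundscapes across urbanization gradients.

Freshwater lakes are everyday soundscapes for people and wildlife, and
urban development reshapes them: low-frequency anthropogenic noise
(*anthrophony*) rises with surrounding impervious surface, while
biological sound (*biophony*, chiefly the dawn chorus) declines with
urbanization and shoreline park use. `lakescape` implements the full
measurement-and-inference chain a soundscape ecologist needs to quantify
these patterns from 24-hour shoreline recordings — and, because field
audio is expensive and rarely shareable, a deterministic synthetic
soundscape generator with known injected structure so that every stage
of the pipeline can be validated end to end.

The package is aimed at ecologists and urban planners analyzing passive
acoustic monitoring data from lakes or similar sites, and at
methodologists who need a fully testable reference implementation of the
band-power / acoustic-index / permutation-inference workflow.

## What it computes

Starting from mono PCM WAV clips (one per lake × hour × channel, air
microphone and optional hydrophone):

1. **Short-time PSD and band power.** Hann window (512 samples, 50%
   overlap), one-sided per-bin power over 0–8 kHz. *Average power* of a
   band follows the convention
   $10\log_{10}(\sum \text{PSD} / N_{\text{bins}})$ — the sum of the
   grid over a selection divided by its number of time–frequency bins —
   computed for each half-open 1-kHz interval $[k, k+1)$, $k = 0..7$.
   Selections are screened for wind feedback (0–1 kHz dominance ×
   gustiness).
2. **Acoustic indices.** Each row of eight band powers is standardized
   to proportions summing to 1. Anthrophony = the relative power of the
   central $[1,2)$ kHz interval (conservative: human noise concentrates
   below 3 kHz but 0–1 kHz is wind-contaminated). Biophony = the maximum
   relative power over $[3,8)$ kHz after excluding everything below
   3 kHz.
3. **Diel aggregation.** Hours map to Night (22–03), Morning (04–09),
   Day (10–15), Evening (16–21); indices are averaged per lake × period
   (40 rows for a ten-lake study), and hourly 1–2 kHz profiles per urban
   category are tabulated against a threshold reference (e.g. the 55 dB
   outdoor-disturbance level, given a calibration).
4. **Inference.** OLS regressions of both indices on urbanization, park
   presence, parcel density and period (Night reference); Pearson
   correlations; per-band air↔hydrophone regressions; covariance PCA of
   the 8-band composition with permutation significance; and one-way
   **PERMANOVA** and **PERMDISP** (Euclidean, 9,999 permutations by
   default) written from first principles — the univariate pseudo-F
   reduces exactly to the classical ANOVA F, and both are cross-checked
   against `vegan` in the tests.

The synthetic generator injects: diel anthrophony (logistic rise curves
per urban category, amplitude monotone in urbanization), a dawn-chorus
biophony bed plus Poisson FM-chirp events (3–8 kHz, reduced by parks and
urbanization), optional wind gusts, and a hydrophone channel receiving
only the low-passed (< 1 kHz) component plus independent noise — with
per-clip ground truth recorded alongside the audio.

## Worked example

Generate a ten-lake synthetic study (hydrophone at 7 lakes), run the
whole pipeline, and look at the results. A calibration offset of 90 dB
maps full scale to a plausible recorder level so the 55 dB threshold is
meaningful:

```r
library(lakescape)

cfg <- pipeline_config(
  synth     = synth_config(n_lakes = 10, duration = 2, seed = 11),
  spectral  = list(calibration_offset_db = 90),
  inference = list(n_perm = 999)
)
report <- run_pipeline(cfg)
report
#> <soundscape_report>
#>   10 lakes, 408 band-power rows (air+hydro)
#>   period summary: 40 rows; PCA PC1/PC2 = 97%/2%
#>   permutation tests:
#>     urban_category PERMANOVA p = 0.001
#>     urban_category PERMDISP  p = 0.883
#>     park           PERMANOVA p = 0.001
#>     park           PERMDISP  p = 0.136
#>     period         PERMANOVA p = 0.042
#>     period         PERMDISP  p = 0.226
```

408 rows are 240 air (10 lakes × 24 h) plus 168 hydro (7 × 24) hourly
records. PERMANOVA finds the multivariate acoustic composition shifted
by urban category, park presence and period; dispersions are
homogeneous. Exceedance of the 55 dB threshold separates the urban
categories:

```r
report$exceedance
#> # A tibble: 3 × 4
#>   category     n n_above percent
#>   <fct>    <int>   <int>   <dbl>
#> 1 Low         96       0       0
#> 2 Medium      72       0       0
#> 3 High        72      54      75
```

The period-mean regressions (n = 40 lake-periods) recover the injected
structure — anthrophony rises with urbanization, biophony falls with
park presence and peaks in the Morning (dawn chorus):

```r
tidy(report$regressions) |>
  dplyr::filter(term %in% c("urban", "park", "periodMorning"))
#>      response          term estimate std.error statistic  p.value
#> 1 anthrophony         urban  0.05886  0.004015     14.66 5.25e-16
#> 2 anthrophony          park  0.00850  0.001553      5.47 4.56e-06
#> 3 anthrophony periodMorning -0.00770  0.001817     -4.24 1.71e-04
#> 4    biophony         urban -0.03762  0.002527    -14.88 3.37e-16
#> 5    biophony          park -0.00586  0.000977     -6.00 9.73e-07
#> 6    biophony periodMorning  0.00708  0.001144      6.19 5.53e-07
```

`autoplot(report$pca)`, `plot_diel_profile(report$diel_profile, 55)` and
`plot_cross_medium(report$cross_medium)` draw the ordination, the diel
category profiles with the threshold line, and the per-band air/water
R² bars. `write_report(report, "out/")` saves every stage as CSV with a
provenance stamp; `analyze_study()` re-runs the inference from a saved
band-power CSV with identical results.

A command-line front end over the same functions lives at
`inst/cli/lakescape.R` (subcommands `synth`, `index`, `analyze`, `all`).

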