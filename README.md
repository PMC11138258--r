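# eegretest

Test–retest reliability of resting-state EEG spectral features, as a
reproducible R pipeline.

## What this package is for

Quantitative EEG measures can only serve as clinical-trial outcomes if they
are stable under repetition — within a day and across the weeks of a trial.
`eegretest` implements the full analysis chain for establishing that
stability from repeated-session resting EEG:

1. **Synthetic study generation** — multichannel recordings
   (1/f^χ aperiodic background, five band-limited components, a
   subject-specific alpha oscillation, optional artifacts) whose
   feature-level variance is decomposed into between-subject,
   between-session and residual parts, so the **true ICC of every feature
   is known** and the whole pipeline can be validated by parameter
   recovery.
2. **Deterministic preprocessing** — zero-phase windowed-sinc FIR filtering
   (2 Hz highpass, 80 Hz lowpass, 55–65 Hz mains bandstop with harmonics up
   to Nyquist), 2 s epoching, threshold-based artifact-epoch rejection,
   bad-channel detection and spherical-spline interpolation (≤ 5% of
   channels).
3. **Feature extraction** — Welch PSD (2 s Hanning, 50% overlap, 0.5 Hz
   grid), relative band power in delta/theta/alpha/beta/gamma, and the
   individual alpha peak frequency (argmax of the log relative spectrum in
   5–14 Hz), averaged over the 108-channel analysis montage.
4. **Reliability estimation** — ICC(A,1), the two-way random-effects,
   absolute-agreement, single-measure intraclass correlation:

   ```
   ICC(A,1) = (BMS − EMS) / (BMS + (k − 1) EMS + (k / n)(RMS − EMS))
   ```

   with McGraw–Wong 95% confidence intervals and conventional class bands
   (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent).
5. **Power planning** — exact central-F power, detectable ICC and required
   sample size for the one-way reliability F-test of H0: ICC = ρ0.

It is written tidyverse-style: tabular stages are tibbles, fitted ICC
objects have `tidy()`/`glance()` methods, and result tables have
`autoplot()` methods.

## Worked example

Design question first: with 30 subjects and 2 visits, which ICC can be
detected with 80% power against a null of 0.50?

```r
library(eegretest)
rho1 <- detectable_icc(n = 30, k = 2, rho0 = 0.50, target_power = 0.80, alpha = 0.05)
round(rho1, 4)
#> [1] 0.7671
```

So the design resolves reliabilities of about 0.77 and better. Now a small
synthetic study through the whole pipeline (6 subjects, 2 same-day
sessions, 8 channels, 60 s at 250 Hz — a fast fixture):

```r
cfg <- pipeline_config(
  out_dir = file.path(tempdir(), "demo"),
  simulation = list(n_subjects = 6, sessions_per_subject = 2,
                    fs = 250, duration = 60, n_channels = 8),
  seed = 8)
report <- run_pipeline(cfg)
report
#> <run_report>
#>   config hash : 0c1a3b0a (v0.1.0)
#>   recordings  : 12 (epochs kept 359/360)
#>   reliability : .../demo/reliability.csv
#>   elapsed     : 2.5 s

tibble::as_tibble(report$reliability)[, 1:7]
#> # A tibble: 6 x 7
#>   feature_name interval_label estimate  ci_low ci_high     n reliability_class
#>   <fct>        <fct>             <dbl>   <dbl>   <dbl> <int> <chr>
#> 1 rbp_delta    same_day          0.763  0.0854   0.962     6 good
#> 2 rbp_theta    same_day          0.782 -0.0137   0.967     6 good
#> 3 rbp_alpha    same_day          0.945  0.685    0.992     6 excellent
#> 4 rbp_beta     same_day          0.197 -0.897    0.843     6 poor
#> 5 rbp_gamma    same_day          0.891  0.492    0.984     6 good
#> 6 ipf          same_day          0.718  0.0456   0.953     6 moderate
```

Each row is one feature's ICC(A,1) for the same-day interval with its 95%
CI, the number of complete subject pairs, and the reliability class. At
n = 6 the intervals are wide and single estimates scatter far around their
generating values (here the six features were simulated with true ICCs
between 0.81 and 0.959) — exactly the sampling behaviour the power
calculation above quantifies; estimator calibration at realistic sizes is
covered by the parameter-recovery tests. `autoplot(report$reliability)`
draws the classification heatmap, and `write_reliability_table()` exports
the features-by-intervals CSV. A thin command-line front end is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","eegretest.R",package="eegretest"))')" \
  power --solve detectable --n 30 --k 2 --rho0 0.5 --power 0.8 --alpha 0.05
#> n,k,rho0,rho1,alpha,power
#> 30,2,0.5,0.77,0.05,0.8
```

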