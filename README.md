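# audioprog

Audiometric progression modelling for hereditary sensorineural hearing
loss, built for genotype–phenotype studies of autosomal dominant
non-syndromic hearing loss (ADNSHL) — in particular cohorts stratified by
the two conserved domains of TBC1D24 (TBC vs TLDc). The package takes
cross-sectional audiogram tables (one pure-tone audiogram per subject at
one age), models how hearing thresholds worsen with age, and compares
deterioration rates between mutation-domain groups.

## The model

Air-conduction thresholds `y` (dB HL) are regressed on age `x` (years)
under four candidate families:

| family      | equation               | parameters |
|-------------|------------------------|------------|
| power       | y = a·x^b, a > 0       | 2          |
| linear      | y = c0 + c1·x          | 2          |
| logarithmic | y = c0 + c1·ln(x)      | 2          |
| quadratic   | y = c0 + c1·x + c2·x²  | 3          |

R² is always computed as 1 − SS_res/SS_tot on the original dB scale, so
the nonlinear power fit (Levenberg–Marquardt, initialized from log–log
OLS) is comparable with the linear-model families. Candidates are ranked
by a Schwarz-penalized score, `n·log(1 − R²) + p·log(n)`, which orders
like R² for equal parameter counts but stops the 3-parameter quadratic
from displacing a true 2-parameter law by absorbing noise.

Three summary statistics are derived by inverting fitted curves:

- **Onset age** — the age at which the fitted PTA-versus-age curve
  (PTA = mean threshold at 500/1000/2000/4000 Hz) crosses 25 dB HL; for
  the power family the closed form `x = (25/a)^(1/b)`.
- **Hearing progression time (HPT)** — years for a frequency band's
  fitted threshold to rise from 25 to 60 dB HL, per band: low (250/500
  Hz), mid (1000/2000 Hz), high (4000/8000 Hz).
- **Annual threshold deterioration (ATD)** — the cross-sectional OLS
  slope of threshold on age (dB/year) at one frequency within one group;
  TBC-vs-TLDc differences are tested with a seeded, two-sided,
  studentized label-permutation test over subjects, p = (b + 1)/(B + 1).

A synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`,
`tbc1d24_profile_spec()`) draws cross-sectional cohorts whose thresholds
follow group-specific power laws plus Gaussian noise, so the whole
pipeline is testable without patient data.

## Worked example

The published TBC1D24 audioprofile reaches 25 dB at 26.07 y and 60 dB at
65.30 y in the low band. The power law through those two points gives the
low-band HPT by curve inversion:

```r
library(audioprog)
m <- two_point_power_model(c(26.07, 25), c(65.30, 60))
hearing_progression_time(m)
#> [1] 39.23
```

End to end on a simulated cohort (60 subjects, 3 dB noise, band curves
anchored at the published crossing ages):

```r
spec <- tbc1d24_profile_spec(n_subjects = 60, noise_sd = 3, seed = 101)
write_audiogram_table(generate_cohort(spec), "cohort.csv")
report <- run_pipeline(pipeline_config("cohort.csv", seed = 202))
report$progression
#> <progression_summary> n = 60 | power model | onset (25 dB): 22.24 y
#>   low   25 dB at 26.19 y, 60 dB at 64.26 y, HPT 38.07 y (extrapolated)
#>   mid   25 dB at 22.90 y, 60 dB at 41.36 y, HPT 18.45 y
#>   high  25 dB at 18.52 y, 60 dB at 37.87 y, HPT 19.35 y
```

The fitted band HPTs (38.07/18.45/19.35 y) recover the generating
profile's 39.23/18.47/19.37 y despite the noise; "extrapolated" flags a
crossing age beyond the observed age range. The numbered scripts under
`analysis/` run this workflow (simulate → fit/invert → ATD comparison)
and write their tables under `results/`.

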