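# dvheval

Dosimetric and radiobiological evaluation of external-beam radiotherapy
plans from cumulative dose–volume histograms (DVHs), built around the
plan-comparison workflow used in prophylactic irradiation for heterotopic
ossification (HO) of the hip: a single 7 Gy fraction evaluated once with
the dose engine's inhomogeneity correction off (IC-off, water-equivalent
density) and once with it on (IC-on). It is aimed at medical physicists and
methodologists who want the full evaluation chain — indices, paired
statistics, resampling — as tested, scriptable functions rather than
spreadsheet arithmetic.

## What it computes

For each plan, from the target cumulative DVH `V(D)` (fraction of the
structure receiving at least dose `D`):

- **Coverage indices** `D_q%` — the dose received by the hottest `q%` of
  the volume, linearly interpolated on the cumulative curve
  (`q ∈ {2, 50, 90, 95, 98}`).
- **Homogeneity index** (ICRU 83): `HI = (D2% − D98%) / D50%`.
- **Gradient index** (ICRU 91): `GI = V50% / V100%`, the ratio of the 50%
  to 100% prescription isodose volumes.
- **Generalized equivalent uniform dose** (power-mean form):
  `gEUD = (Σ_i v_i D_i^a)^(1/a)` over the differential DVH `(D_i, v_i)`;
  `a = 1` gives the mean dose.
- **Linear–quadratic EUD** — the uniform dose producing the same LQ
  clonogen survival `S = Σ_i v_i exp(−α D_i − β D_i²/n)`, i.e. the
  non-negative root of `α·EUD + (β/n)·EUD² = −ln S`, evaluated in closed
  form with log-domain survival accumulation.
- **EQD2** — the standard isoeffect conversion
  `EQD2 = D·(d + α/β)/(2 + α/β)`, at `α/β = 3` and `10` Gy.

At cohort level it reproduces the paired-study statistical battery: mean ±
SD with z-based 95% CIs, Shapiro–Wilk normality (with the classic
small-sample critical-value table, e.g. W = 0.908 at n = 21), skewness,
and the exact tie-aware Wilcoxon signed-rank test with effect size
`r = |z|/√m`. A Monte Carlo module resamples 10,000 values per index from
cohort `(mean, SD)` summaries to map index distributions and
below-threshold fractions, and a calibrated synthetic paired-cohort
generator (two-sided logistic DVH model) lets the whole pipeline run with
no patient data.

## Worked example

Generate a calibrated 21-patient paired cohort, evaluate every plan, and
build the comparison table:

```r
library(dvheval)

cal    <- calibrate_cohort(cohort_config(n_patients = 21, seed = 1))
plans  <- generate_cohort(cal$config)
panels <- cohort_index_panels(plans)
comp   <- build_comparison_tables(panels)
writeLines(format_comparison_table(comp))
```

```
Index            IC-off                       IC-on                               p
-----------------------------------------------------------------------------------
D2               7.26 +/- 0.20 (7.17-7.35)    7.31 +/- 0.19 (7.23-7.39)      0.1281
D50              7.07 +/- 0.11 (7.02-7.11)    6.89 +/- 0.18 (6.82-6.97)      0.0000
D90              6.77 +/- 0.17 (6.70-6.84)    6.39 +/- 0.28 (6.28-6.51)      0.0000
D95              6.67 +/- 0.20 (6.59-6.75)    6.22 +/- 0.33 (6.08-6.36)      0.0000
D98              6.54 +/- 0.23 (6.44-6.64)    6.01 +/- 0.40 (5.84-6.18)      0.0000
HI               0.10 +/- 0.04 (0.09-0.12)    0.19 +/- 0.06 (0.17-0.21)      0.0000
GI               1.52 +/- 0.52 (1.29-1.74)    3.05 +/- 1.22 (2.53-3.57)      0.0000
gEUD             7.01 +/- 0.13 (6.95-7.06)    6.81 +/- 0.19 (6.73-6.89)      0.0000
EUD_LQ_ab3       6.98 +/- 0.13 (6.92-7.03)    6.71 +/- 0.22 (6.62-6.81)      0.0000
EQD2_ab3_gEUD    14.03 +/- 0.43 (13.84-14.21) 13.37 +/- 0.64 (13.10-13.65)   0.0000
EQD2_ab3_LQ      13.92 +/- 0.45 (13.73-14.12) 13.05 +/- 0.73 (12.74-13.36)   0.0000
EUD_LQ_ab10      7.00 +/- 0.13 (6.94-7.05)    6.78 +/- 0.20 (6.69-6.86)      0.0000
EQD2_ab10_gEUD   9.93 +/- 0.26 (9.82-10.04)   9.55 +/- 0.38 (9.38-9.71)      0.0000
EQD2_ab10_LQ     9.91 +/- 0.26 (9.80-10.02)   9.48 +/- 0.40 (9.31-9.65)      0.0000
```

Each row compares the 21 matched IC-off/IC-on plans for one index:
`mean ± SD (95% CI)` per arm and the exact paired signed-rank p-value.
Turning the inhomogeneity correction on leaves the hot end (D2) unchanged
but drops median and low-dose coverage (D50 7.07 → 6.89 Gy, D98 6.54 →
6.01 Gy), roughly doubles HI and GI, and reduces the mean gEUD by about
0.2 Gy — every contrast except D2 significant. The same run is available
end-to-end (including the Monte Carlo stage and all file exports) as

```r
res <- run_full_study(run_config(mode = "synthetic", seed = 1,
                                 out_dir = "dvheval_out"))
```

or from a shell via the thin wrapper `inst/cli/run_study.R`
(`Rscript inst/cli/run_study.R --seed 1 --out dvheval_out`).

Single quantities work standalone, e.g. the EQD2 of a 7.02 Gy mean dose
delivered in one fraction:

```r
eqd2(7.02, 7.02, alpha_beta = 3)   # 14.07 Gy
eqd2(7.02, 7.02, alpha_beta = 10)  # 9.96 Gy
```

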