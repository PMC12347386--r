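---
title: "Methods: DVH-based dosimetric and radiobiological plan evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH-based dosimetric and radiobiological plan evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvheval)
```

## Scope and model

`dvheval` evaluates paired external-beam plans for prophylactic hip
irradiation against heterotopic ossification (HO): a single 7 Gy fraction
computed twice per patient, with the dose engine's inhomogeneity
correction off (IC-off, water-equivalent density everywhere) and on
(IC-on, accounting for bone and prosthetic density). The package takes
cumulative target DVHs as its input — it does not model CT geometry,
beams, or dose computation — and carries them through four layers:
per-plan indices, paired-cohort statistics, Monte Carlo resampling of
index distributions, and (when no patient data are available) a synthetic
paired-cohort generator calibrated to published cohort summaries.

### Dosimetric indices

`dose_at_volume()` reads `D_q%` off the cumulative curve as the dose at
which the cumulative volume falls to `q/100`, linearly interpolated in
dose between grid points. The phrase "maximum dose covering at most q% of
the volume" is ambiguous on a discrete grid; we adopt the conventional
interpolated reading, resolving flat segments to the lowest dose that
achieves the volume. When a curve ends with residual volume above `q`%
(all of the hottest `q`% sits at or beyond the last recorded dose), the
last grid dose is returned — the conservative in-support answer.

`HI = (D2 − D98)/D50` (ICRU 83) and `GI = V50/V100` (ICRU 91) follow
directly. The isodose volumes `V100` and `V50` refer to the whole
irradiated region, not the target alone, so they cannot be derived from
the target DVH; they travel with each plan record and GI is reported `NA`
when absent. Conformity indices (CI, Paddick CN) are deliberately out of
scope.

### Radiobiological indices

The differential DVH `(D_i, v_i)` (partial volumes summing to 1) feeds
three models:

* `geud()` — the power mean `(Σ v_i D_i^a)^{1/a}`. With the volume-effect
  exponent `a = 1` (the package default and the choice used for the HO
  target region) this is exactly the mean dose; the implementation
  special-cases `a = 1` so no floating-point power round trip occurs.
* `eud_lq()` — the uniform dose giving the same linear–quadratic survival
  `S = Σ v_i e^{−αD_i − βD_i²/n}` as the heterogeneous distribution. The
  defining equation `αE + (β/n)E² = −ln S` has the closed-form
  non-negative root `E = 2L / (√(α² + 4βL/n) + α)`, `L = −ln S`, written
  in the subtraction-free form so it stays accurate as `β → 0`. A uniform
  DVH returns its dose exactly, for every admissible `(α, β, n)` — this
  identity pins down the formula and is enforced in the tests together
  with agreement (to 1e−9) with an independent scalar root-finder on
  random DVHs.
* `eqd2()` — `D (d + α/β)/(2 + α/β)`, with `d = EUD/n` as the dose per
  fraction of the converted quantity (a single 7 Gy fraction gives
  `d = EUD`).

Two parameter decisions were genuinely open. First, the LQ EUD needs `α`
and `β` separately while plan-comparison studies typically state only
`α/β`; we default to `α = 0.3 Gy⁻¹`, a conventional soft-tissue value,
and expose it in `radiobio_params()`. For the near-uniform DVHs of this
application the result is insensitive to `α` (and exactly independent of
it in the uniform limit), so the choice does not drive any cohort-level
conclusion. Second, cohort EQD2 is computed per patient and then
averaged, not converted from the cohort-mean EUD; with a convex
conversion the two orders differ at the 0.01–0.03 Gy level and the
per-patient order is the one consistent with published cohort tables.

### Cohort statistics

`summarize_values()` reports mean, sample SD (denominator n − 1) and the
z-based 95% CI `mean ± 1.96·SD/√n`. The z interval (not t) is a fidelity
choice: it is the convention that reproduces the published intervals this
battery mirrors (e.g. 7.08 ± 0.10 at n = 21 → 7.04–7.12, where t would
give 7.03–7.13).

`shapiro_wilk()` wraps the Royston approximation (`stats::shapiro.test`)
and adds the classic small-sample critical-value table (n = 3–50,
α = 0.05; 0.908 at n = 21) so results can be read either through the
p-value or the tabulated reference W. The accompanying `effect_size`
column has no standardized definition in this battery; we report
`|qnorm(p)|/√n` and treat it as descriptive only.

`wilcoxon_signed_rank()` drops zero differences (classic treatment),
midranks ties, and reports the smaller rank sum. For m ≤ 25 remaining
pairs the two-sided p is exact, computed from the full tie-aware null
distribution of the rank sum — algebraically identical to enumerating all
2^m sign assignments, which the test suite does independently for m ≤ 12.
Beyond 25 a normal approximation with the exact tie-corrected variance
`Σr_i²/4` and continuity correction takes over. The effect size is
`r = |z|/√m`. Exact p-values are reported in full, with no display floor,
and no multiple-testing adjustment is applied (none is standard in this
table format).

## Monte Carlo resampling

`run_mc_study()` implements the cohort-level uncertainty study: for every
(index, arm) it draws `n_samples` (default 10,000) independent values
from `N(mean, SD²)` with the mean and SD taken from cohort summaries —
by default the bundled reference table `ho_cohort_baseline()`. The normal
family is what the "baseline mean/SD defines the distribution" design
implies; distributions are not truncated at zero because at these
baselines negative draws are vanishingly rare. Indices are sampled
independently: no covariance structure is published, so joint behavior
across indices is *not* reproduced — the study is marginal by
construction. Each stream is seeded as `stream_seed(seed, "mc", index,
arm)`, so results are reproducible and adding an index never perturbs
existing streams. `fraction_below()` turns a distribution into the
simulated probability of missing a threshold (e.g. the 7 Gy prophylactic
goal); histogram bin width is a config knob since no canonical width
exists.

## The synthetic cohort generator

Real per-patient DVHs for this application are not publicly deposited, so
`generate_cohort()` stands in with a parametric family. Each target DVH
is a two-sided logistic fall-off

\[ V(D) = \frac{1}{1 + e^{(D-\mu)/s(D)}}, \qquad
   s(D) = \begin{cases} s_{lo} & D < \mu \\ s_{hi} & D \ge \mu \end{cases} \]

rescaled to `V(0) = 1` on a 0.01 Gy grid up to a 9 Gy hot-spot cap. The
asymmetry matters: published cohorts show a broad cold-side shoulder
(D50 − D98 ≈ 0.5 Gy IC-off) against a tight hot tail (D2 − D50 ≈ 0.2 Gy),
which a symmetric logistic cannot represent. Under this family the
quantiles are analytic (`D_q = μ ± s·ln((1−q)/q)`), which makes
calibration well-conditioned.

Per patient, `(μ, s_lo, s_hi)` are drawn from arm-specific normals
(steepness draws truncated positive with a retry limit), and the isodose
volumes as `V100 ~ lognormal` with `GI = 1 + lognormal` per arm — the
`1 +` form guarantees `GI ≥ 1` and its two lognormal parameters are set
from the target GI mean and SD in closed form. Pairing between arms is
induced by two shared per-patient latents — one entering both arms'
midpoints, one both shoulder steepnesses, each scaled by an arm-specific
`*_sd_shared` — with the shared components carrying most of each arm's
dispersion. This mirrors the defining feature of the published paired
tests: p-values near the exact minimum on essentially every index at
n = 21, which requires paired differences of near-uniform sign, i.e.
strong within-patient correlation across arms. Arm totals
(`√(sd_shared² + sd²)`) are set to the published per-arm SDs.

`calibrate_cohort()` polishes the hyperparameters by coordinate descent
against cohort means of D2–D98, HI, GI and gEUD over a 500-patient-per-arm
calibration cohort: the midpoint follows the D50/gEUD residuals, `s_hi`
the D2 residual (slope `ln 49` per Gy), `s_lo` a least-squares blend of
the D90/D95/D98 residuals, and the GI lognormal location the log ratio of
target to achieved mean excess over 1. Default tolerances are ±0.05 Gy on
dose indices, ±0.02 on HI, ±0.15 on GI; HI is checked but not separately
driven since it follows from the steepness parameters. The defaults ship
at the analytic start values, so calibration typically converges in one
or two passes (a few seconds); non-convergence within the iteration
budget raises an error carrying the best-achieved residuals. Calibration
matches means; SDs are matched structurally through the hyperparameter
scales rather than enforced, because the published SDs entangle unknown
per-patient DVH shapes.

What passing tests on this generator do **not** show: anatomical realism
(no prosthesis or interface physics), cross-index correlations beyond
those induced by the shared DVH parameters, per-patient fidelity to any
real cohort, or dose-engine behavior. The generator defines a plausible
study condition whose *cohort summaries* match the reference table;
conclusions about real plans still require real DVHs, which the
file-based pipeline (`load_cohort()` on a manifest) accepts
interchangeably.

## Numerical conventions and degenerate inputs

* **Cumulative↔differential conversion.** Differentiation takes
  `v_i = cum[i] − cum[i+1]` at the midpoint of the bracketing doses, with
  residual volume at the last grid point kept as a terminal point mass so
  `Σv_i = 1` exactly. The inverse reconstructs bin edges by the
  midpoint-inverse recursion `e_{i+1} = 2D_i − e_i` from `e_1 = 0`
  (terminal point masses detected as bins sitting on the current edge),
  which makes the round trip exact to machine precision on any curve
  whose grid starts at 0 Gy. A consequence of committing to exact
  invertibility: a standalone single bin at dose D reconstructs to a step
  at 2D (volume and mean dose conserved) rather than a step at D — edge
  information simply does not exist in a one-bin DVH, and we prefer the
  convention that makes the conversions mutual inverses.
* **Validation tolerances.** Cumulative volume increases up to 1e−6 are
  clamped (scanner/export jitter); larger increases are errors naming the
  offending row. Partial volumes must sum to 1 within 1e−9.
* **Survival sums** are accumulated in the log domain (max-factored), so
  `eud_lq()` is finite whenever any partial volume is positive, at any
  dose scale; an all-zero-dose DVH returns EUD 0.
* **Degenerate statistics.** Constant samples: SD 0 and a zero-width CI
  from `summarize_values()`, an error from `shapiro_wilk()` and
  `sample_skewness()` (W undefined). All-zero paired differences: a
  degenerate-input error from `wilcoxon_signed_rank()`, reported as a
  non-significant degenerate row by `build_comparison_tables()`.
* **Seeds.** Every stochastic stage requires an explicit seed; named
  streams are derived via a stable string hash (`stream_seed()`), kept
  within 32-bit integer range. There is no wall-clock fallback.

## Problem sizes

Defaults reflect the study design this package mirrors: 21 patients per
cohort, 10,000 Monte Carlo draws per index, 500 patients per arm per
calibration pass, DVHs on a 0.01 Gy grid to 9 Gy. The test suite runs the
same operations at these or smaller sizes (e.g. 1,000 random DVHs for the
root-finder agreement check, 40-patient cohorts for dispersion
properties) and completes in well under a minute.

## Known limitations

* The generator reproduces cohort summaries, not patients; its DVH family
  is smooth and unimodal, so multi-modal or scalloped real DVHs are out
  of reach.
* LQ EUD ignores repopulation, dose-rate and time factors, and no
  NTCP/TCP layer is included (gEUD's Lyman ancestry is used only as a
  dose-summary statistic).
* The Monte Carlo study treats indices as independent normals; tails and
  joint exceedance probabilities inherit that assumption.
* The Shapiro–Wilk critical table is embedded for α = 0.05 only; other
  levels go through the p-value.
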