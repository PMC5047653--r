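---
title: "Methods: respirometry analysis and the synthetic trial generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry analysis and the synthetic trial generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalmet)
```

## The measurement model

Intermittent-flow respirometry measures aerobic metabolism as oxygen uptake
in a sealed chamber. The chamber alternates a 9-min sealed *measurement*
phase, during which dissolved oxygen declines, with a 3-min *flush* that
restores air saturation; a fibre-optic optode samples oxygen every 2 s.
Within each measurement period the package fits an ordinary least-squares
line to concentration versus time, after discarding the first and last
minute of the period so the recirculation loop is well mixed, and converts
the slope to whole-animal uptake through the effective water volume:

$$\dot{M}\mathrm{O}_2 = -s \cdot V_{\mathrm{eff}}, \qquad
V_{\mathrm{eff}} = V_{\mathrm{chamber}} - m/\rho,$$

with $s$ in mg O~2~ L^-1^ h^-1^, $m$ the fish's wet mass and tissue density
$\rho$ taken as 1 g mL^-1^. Subtracting body volume is standard practice but
can be disabled (`subtract_body_volume = FALSE`) for compatibility with
analyses that used the nominal chamber volume; at 1.84 g in a 100 mL chamber
the difference is 1.8%.

Bacterial (background) respiration is estimated from empty-chamber runs
before and after each trial — each reduced to the mean uptake over its
measurement windows with the full chamber volume — and subtracted from every
fish estimate assuming a linear increase in time. The pre-trial rate is
anchored at trial start, the post-trial rate at trial end, and each
per-period estimate is corrected at its window midpoint, which is unbiased
for a linear drift. Corrected values are floored at zero (with a counter)
since a fish cannot produce oxygen.

Fits are quality-controlled on the coefficient of determination:
windows with $r^2 \le 0.97$ are flagged and excluded from the metrics by
default, but retained in the output so nothing is silently dropped. A window
with zero oxygen variance carries no rate information; its $r^2$ is defined
as 0 and it fails QC rather than producing an undefined statistic.

## Metabolic summary metrics

* **MR_min** (minimum metabolic rate) is computed over the whole trial as
  the mean of the values at or below the empirical 10th percentile of the
  per-period estimates, the usual standard-metabolic-rate proxy for
  quiescent overnight data. The percentile point estimate itself is exposed
  via `method = "quantile"`; the lowest-decile mean is the default because a
  single noisy period then cannot dominate the statistic. MR_min deliberately
  includes the pre-settling phase — the decile filter removes it in practice —
  while RMR applies an explicit exclusion; the asymmetry is intentional.
* **RMR** (routine metabolic rate) is the arithmetic mean of estimates whose
  window midpoint falls more than `settle_cutoff` (default 5) hours after
  transfer, excluding the handling-stress transient.
* **ISR** (initial stress response) is the first post-transfer estimate
  minus MR_min. If the first period fails QC, ISR is reported missing, never
  imputed from a later period. ISR uses the background-corrected first slope
  by default; the raw slope is one switch away (`isr_use_corrected = FALSE`)
  since either convention appears in practice.
* **Stabilization time** has no canonical estimator; the package defines it
  as the earliest window midpoint from which every rolling mean of
  `k = 3` consecutive periods stays within `delta = 10%` of the trial's
  final level (the mean over the last 3 h). The detector is monotone in
  `delta`, returns the trace end flagged "unstabilized" when the criterion
  is never met, and is validated against the generator's analytic decay.

## Treatment comparisons

Each fish is measured once per testing condition (solitary, shoal), so the
primary inference is paired. The package's own test is an exact sign-flip
permutation test: under the null the sign of each within-fish difference is
exchangeable, and all $2^n$ assignments are enumerated for $n \le 12$
(Monte-Carlo with a fixed seed beyond that, with the identity assignment
counted so $p > 0$). Effect size is reported as the per-fish percent
reduction $100(x_{\mathrm{sol}} - x_{\mathrm{shoal}})/x_{\mathrm{sol}}$,
averaged across fish — per fish first, because the individual spread (not
just the ratio of group means) is biologically meaningful.

The conventional path, `mixed_model_compare()`, fits a linear mixed model
with holding treatment and testing condition as fixed effects, body mass as
a covariate and a per-individual random intercept, delegating numerics to
`lmerTest::lmer` (Satterthwaite F tests). It complements the bespoke test:
the permutation test stands alone and is exactly verifiable; the mixed model
matches the field's reporting conventions. No autocorrelation structure is
modelled beyond the random intercept; with ~2 observations per fish there is
nothing to estimate it from. A singular random-effect fit falls back to
fixed-effects-only OLS, flagged in the result. For body-condition
trajectories the response is Fulton's K on its natural scale (log K is a
documented alternative via the response column).

Allometric mass correction regresses $\log(\text{value})$ on
$\log(\text{mass})$ pooled across the cohort — one relationship, since the
paired design measures the same fish in both conditions — and rebuilds each
fish at the reference mass (default 1.84 g, the calibrated cohort mean):
$\exp(\hat{y}(\log m_{\mathrm{ref}}) + e_i)$. When all masses equal the
reference the correction is exactly the identity; with zero mass variance
but a different reference it degrades to a warned no-op.

## What the generator simulates

`simulate_trial()` integrates the chamber mass balance
$d[\mathrm{O}_2]/dt = -(\dot{M}\mathrm{O}_2(t) + B(t))/V_{\mathrm{eff}}$
per 2-s sample (trapezoidal rule — exact for the piecewise-linear rates the
tests rely on), with

$$\dot{M}\mathrm{O}_2(t) = \max\!\big(0,\; F + A e^{-t/\tau} + \epsilon_j\big),$$

a floor $F$, a handling-stress amplitude $A$ decaying with time constant
$\tau$, and one activity draw $\epsilon_j$ per measurement period.
Flushing is modelled as exponential relaxation towards full saturation with
a 25-s time constant, restoring >99.9% saturation within the 3-min flush —
the simplest physically plausible model of a pump exchanging chamber water.
Instrument noise is a per-sample Gaussian on concentration. Separating
biological noise (per period) from optode noise (per sample) keeps the
oracle tests clean: the former moves whole-period estimates, the latter
controls $r^2$.

Calibrated defaults (all overridable in `sim_config()`):

| parameter | default | rationale |
|---|---|---|
| chamber volume / cycle | 0.100 L, 540 s + 180 s, 2 s sampling | the dual-chamber design the package targets |
| O~2~ solubility | 6.3 mg L^-1^ | air-saturated seawater at 29 °C, 35 ppt |
| cohort | 8 fish per holding treatment; mass 1.84 ± 0.11 g; length 3.69 ± 0.085 cm | study-scale cohort; SDs chosen so the s.e.m. at n = 8 is ~0.04 g / 0.03 cm |
| floor `baseline_mo2_ref` | 0.42 mg O~2~ h^-1^ at 1.84 g | ~230 mg O~2~ kg^-1^ h^-1^, low-end resting rate for a warm-water damselfish; keeps the worst-case drawdown above 80% saturation |
| allometric exponent | 0.89 | typical intraspecific metabolic scaling in teleosts |
| shoal effect | Beta on [0.05, 0.60], mean 0.259, concentration 10 | matches the calibrated mean and individual range; the Beta shape is an explicit config choice, not an estimate |
| stress `A`, `tau` | 0.20 mg O~2~ h^-1^, 2.95 h | yields ~4.6 h stabilization for a solitary-tested fish under the detector's defaults |
| background | 0.005 → 0.020 mg O~2~ h^-1^ | a few percent of the fish signal, rising overnight as biofilm grows |
| activity noise | 0.01 mg O~2~ h^-1^ per period | ~2% of the floor: a quiescent fish at night |
| optode noise | 0.005 mg L^-1^ per sample | ~0.08% of saturation, typical for fibre-optic optodes; set jointly with the signal so every window clears $r^2 > 0.97$, a coupling that is documented rather than derived |
| trial length | 11.5 h | overnight run; must exceed 6 h so the 5-h RMR exclusion leaves data |

Solitary-held fish additionally lose 5 ± 1.5% of body mass between holding
weeks 0 and 1 (shoal-held fish drift neutrally, SD 1%), giving the
body-condition signal; lengths are held fixed over the two weeks.

`simulate_cohort()` gives every fish one trial per testing condition plus
pre/post empty-chamber runs, and returns a ground-truth table (floors,
per-fish effects, background endpoints, analytic stabilization times) for
parameter-recovery testing. `simulate_metric_cohort()` is a summary-level
shortcut — floors times log-normal measurement error, no oxygen dynamics —
used to study the inference machinery (type-I error, power) over many
replicate cohorts cheaply; it shares the truth parameters but none of the
trace pipeline, so it validates the statistics, not the slope extraction.

What the generator does **not** emulate: behavioural activity bouts
(spontaneous swimming produces heavier-tailed, autocorrelated period noise
than the white draw used here), temperature drift, optode drift/hysteresis,
incomplete mixing, digestion, and any behaviour of the shoal-mates — the
outer chamber enters only through the effect multiplier. Passing
parameter-recovery tests therefore demonstrates the pipeline's correctness
under idealised noise, not robustness to every artefact of real traces.

## Numerical and interface choices

- Phase segmentation uses half-open intervals in seconds; a sample exactly
  on a transition belongs to the later phase. `annotate_phases()` never
  overwrites existing labels.
- Windows shorter than 120 s after trimming are dropped (too few samples
  for a stable slope at 2-s sampling); fits require ≥ 3 samples and refuse
  identical timestamps.
- Background rates are clamped at zero with a warning: a negative fitted
  rate is sensor noise, and subtracting it would inflate fish estimates.
- Trace CSVs are written at full round-trip precision, so write-then-read
  is the identity on samples.
- All simulation randomness flows from `config$seed` through one RNG
  stream (restored afterwards), so identical configs give bit-identical
  cohorts; per-trial seeds are drawn once at cohort level.
- Problem sizes in the test suite: unit tests run 6-h trials and small
  cohorts; the end-to-end recovery checks use five full 11.5-h cohorts
  (8 fish per treatment, ~57 periods per trial) and the inference
  calibration uses 50 summary-level replicates — sizes at which the
  recovery targets are comfortably identifiable.
- The package's interface is function-first (tibbles in, tibbles out); the
  bundled CLI script is a thin wrapper for shell users and adds no logic.

## Known limitations

- The stabilization detector is a package definition, not a community
  standard; comparisons across studies should report (`k`, `delta`,
  reference window) alongside the estimate.
- The permutation test addresses only the paired testing contrast; crossed
  holding-by-testing questions go through the delegated mixed model.
- With n = 8 pairs the smallest attainable two-sided permutation p is
  2/256 ≈ 0.0078; smaller p-values are not meaningful at this design size.
- Mass correction assumes a common allometric exponent across treatments;
  a per-treatment fit is available (`mass_correct` applied per group) but
  halves the data behind each regression.
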