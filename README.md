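# shoalmet

Quantifying the metabolic "calming effect" of shoaling in gregarious fishes
from intermittent-flow respirometry data.

Group living is thought to lower individual energy demand: with shoal-mates
nearby, a fish needs less vigilance and mounts a weaker stress response. The
measurable signature is a drop in minimum oxygen uptake when the same
individual is tested with conspecific visual and olfactory cues versus
alone. `shoalmet` implements the full analysis chain for paired
solitary/shoal respirometry designs — and ships a seeded simulator of
dual-chamber respirometry trials with known ground truth, so the whole
pipeline runs, and can be validated by parameter recovery, without any
external data. It is aimed at comparative ecophysiologists analysing
intermittent-flow respirometry of small social fishes (or anyone who wants a
reproducible, testable alternative to chart-software slope reading).

## What it computes

Intermittent-flow respirometry alternates sealed 9-min measurement periods
with 3-min flushes. Within each measurement window (trimmed by one minute on
each side) the oxygen decline is fit by ordinary least squares and converted
to whole-animal oxygen uptake

&nbsp;&nbsp;&nbsp;&nbsp;*Ṁ*O₂ = −s · V_eff&nbsp;&nbsp;[mg O₂ h⁻¹],

with slope *s* in mg O₂ L⁻¹ h⁻¹ and V_eff the chamber volume minus fish
body volume. Bacterial background respiration, measured in the empty chamber
before and after each trial, is subtracted assuming a linear increase over
the night. From the corrected per-period series the package derives:

- **MR_min** — minimum metabolic rate: the mean of the lowest 10th
  percentile of *Ṁ*O₂ values (the standard-metabolic-rate proxy);
- **RMR** — routine metabolic rate: mean *Ṁ*O₂ excluding the first 5 h;
- **ISR** — initial stress response: first post-transfer *Ṁ*O₂ minus MR_min;
- **stabilization time** — when the post-handling decay settles to within
  10% of the trial's final level;
- **Fulton's K** = 100·M/L³ body condition, with allometric mass correction
  of metabolic metrics via residuals of the log–log mass regression added
  back at a reference mass.

Paired solitary-vs-shoal testing conditions are compared two ways: a
self-contained exact sign-flip permutation test on the paired differences
(with per-fish percent reductions), and the conventional linear mixed model
(holding and testing treatments as fixed effects, body mass covariate,
per-individual random intercept) delegated to `lmer`.

## Worked example

Simulate a small paired cohort, process every trace, and test the shoaling
effect on MR_min:

```r
library(shoalmet)

cfg <- sim_config(n_fish_per_treatment = 4, seed = 42)
sim <- simulate_cohort(cfg)             # 8 fish x 2 testing conditions
summaries <- process_cohort(sim)        # slopes -> background correction -> metrics
dplyr::select(summaries, fish_id, testing, mr_min, rmr, isr)
#> # A tibble: 16 x 5
#>   fish_id testing  mr_min   rmr   isr
#> 1 F01     solitary  0.447 0.467 0.183
#> 2 F01     shoal     0.345 0.360 0.197
#> 3 F02     solitary  0.404 0.420 0.184
#> ...

compare_conditions(summaries, metric = "mr_min")
#> Paired sign-flip permutation test (exact, 256 flips)
#>   mean difference 0.1106, mean reduction 25.8%, p = 0.007812 (n = 8 pairs)

tidy(mixed_model_compare(summaries, "mr_min"), "ftests")
#> # A tibble: 3 x 5
#>   term    f_value num_df den_df  p_value
#> 1 holding  0.0899      1   5.00 0.776
#> 2 testing 52.4         1   7.00 0.000171
#> 3 mass_g   1.63        1   5.00 0.258
```

Each fish's MR_min drops under shoal testing (here a 25.8% mean per-fish
reduction, the generator's calibrated effect); the permutation p of 2/256 is
the smallest attainable two-sided value for 8 uniformly signed pairs, and
the mixed model attributes the effect to the testing condition, not to
holding history or body mass.

Plot helpers: `plot_trace()` / `autoplot()` for raw traces,
`plot_mo2_series()` for corrected *Ṁ*O₂ series, `plot_comparison()` for
paired condition contrasts, `plot_condition_trajectory()` for Fulton's K
over the holding weeks. A thin command-line front end
(`inst/scripts/shoalmet-cli.R`) exposes `simulate`, `process`, `metrics`
and `report` subcommands over the same functions.

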