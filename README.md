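# facecontact

Tools for asking **when** social contact shapes other-race face recognition.
Adults recognise own-race faces better than other-race faces (the other-race
effect, ORE; its within-race analogue across ethnicities is the OEE). If face
recognition is more plastic in childhood than adulthood, an adult's ORE should
track the interracial contact they had as a *child*, not the contact they have
now. Testing that requires samples in which childhood and adult contact are
dissociated, a battery of self-reported contact measures that are skewed and
intercorrelated, and a way to attach a single error rate to a whole pattern of
correlations. This package implements that inferential machinery for
researchers in face perception and individual differences, together with a
synthetic-cohort generator so every stage is testable without participant
data.

## What it computes

- **Scoring.** Percent correct on 72-trial three-alternative forced-choice
  face-memory tests (chance = 33.3%), and the difference score
  `ORE_i = own%_i − other%_i` (positive = worse other-group recognition).
  Cronbach's α, SEM = SD·√(1−α), and a ±1 combined-SEM (≈68%) interval for a
  difference score, √(SEM²_own + SEM²_other). A reproducible bivariate-outlier
  rule (robust Mahalanobis distance > χ²₂(0.999); flagged scores replaced by
  the next-highest value on each variable).
- **Skew-gated correlation battery.** For each (sample, life stage, measure,
  own/other group) cell: Kendall's τ_b (tie-corrected, tie-adjusted normal
  p; exact enumeration for n ≤ 9) when the contact distribution is
  significantly skewed (D'Agostino z-test), Pearson r otherwise. Cells are
  annotated with the predicted sign (other-group contact → negative with the
  ORE, own-group → positive), two-tailed p, and flags for
  significant (p < .05, uncorrected) and approaching (p < .09). A
  (sample, stage) block is excluded when the other-group classmates median is
  below 10% (insufficient range).
- **Evidence-pattern Monte-Carlo test.** A battery is summarised as counts
  (m, d, s, a): cells, cells in the predicted direction, significant,
  approaching. The condition-wise p-value is the probability, under
  within-sample permutation of the outcome with the contact columns held
  fixed (preserving their skew and intercorrelation; method tags, masks and
  exclusions frozen), of a pattern at least as strong as observed. The
  default strength ordering is lexicographic on (d, s), a total order, so the
  p-value is a valid permutation p. The naive benchmark that ignores
  intercorrelation, C(n,k)/2ⁿ for k of n directions, is
  `binomial_direction_p()`.
- **Trend.** Pooled OLS of the difference score on total primary other-group
  contact (mean of classmates/friends/neighbours), 95% confidence band on the
  trendline, and the contact level at which the fitted effect reaches zero.
- **Synthetic cohorts.** A Gaussian-copula generator: four samples
  (120/72/103/78, total 373), zero-inflated scaled-Beta contact marginals
  (school-age other-group contact of the Eastern-raised sample is nearly all
  zeros and is range-gated out, as designed), stage-specific contact effects
  on the ORE (primary-only by default), 72-trial binomial test noise, and a
  contact–prejudice link for validation batteries. `null_cohort()` zeroes
  every effect for calibration.

## Worked example

```r
library(facecontact)

study <- generate_cohort(seed = 1)          # synthetic, 373 participants
mc <- monte_carlo_p(study, "primary", n_runs = 2e4, seed = 2)
mc
#> evidence pattern: 19/20 in predicted direction, 10 significant, 3 approaching
#> condition-wise p = 0.00195 (39/20000 runs, MC SE 0.00031, seed 2, ordering lex)

monte_carlo_p(study, "adult", n_runs = 2e4, seed = 4)
#> evidence pattern: 6/29 in predicted direction, 0 significant, 0 approaching
#> condition-wise p = 0.97155 (19431/20000 runs, MC SE 0.0012, seed 4, ordering lex)

study_trend(study)
#> trend: effect = 13.033 -0.3147 * contact%  (n = 310, residual SD 9.85)
#> fitted effect reaches zero at 41.4% contact (band inversion: 37.9 to 45.1)
```

Read: at primary school age, 19 of 20 contact–ORE correlations point the
predicted way and 10 are individually significant; under the permutation
null that pattern arises in 39 of 20,000 runs (p ≈ 0.002). Adult contact
shows no such pattern (p ≈ 0.97). The pooled trend says each additional 10%
childhood other-group contact shaves ~3 points off the adult ORE, which
reaches zero near 41% contact. The same pipeline runs end to end with
`run_pipeline(run_config(...))`, from a CSV of real participant data
(`read_study_table()`, with a schema file for arbitrary column layouts) or a
simulated cohort, writing per-stage battery CSVs and JSON reports; a thin
command-line front end ships in `inst/cli/facecontact.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full default pipeline from scratch — simulates the default
cohort from the given seed, runs the three per-stage batteries and their
Monte-Carlo evidence tests (2×10⁴ runs each), fits the pooled trend, prints
the results, and writes the JSON summary to `--out`.
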