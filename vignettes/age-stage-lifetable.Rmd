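---
title: "Methods: the age-stage, two-sex life table in agestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the age-stage, two-sex life table in agestage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The data model

The unit of analysis is a reared cohort followed by daily census: one row
per individual per day, with an `id`, a 0-based `age` (day of cohort start
is age 0; "day N" in entomological prose is age N−1), a `stage` code, and
the number of `eggs` laid that day. Three conventions matter and are
enforced by `validate_cohort()`:

- **Death is truncation.** An individual's last row is its last day
  alive; there is no death row. This matches how a daily census is
  actually collected. Censoring (individuals lost rather than dead) is
  not modelled — any truncation counts as a death.
- **Stages advance by at most one per day**, except at the final molt,
  where the last instar branches into exactly one of the two adult
  stages. A skip of two stages within one day would mean two molts
  between censuses, which the data model treats as an error rather than
  an observation.
- **Eggs only on adult-female days.** The cohort starts at the first
  instar; the egg stage of the next generation is not tracked, so
  projected newborns recruit directly to age 0 of the first instar (see
  "Projection" for the consequence).

The stage scheme is configurable (`stage_scheme()`), which lets the test
suite exercise every estimator on three-stage toy schemes whose answers
can be enumerated by hand.

## Schedules and scalar parameters

With `N(x, j)` the number of individuals observed in stage *j* at age *x*
and `E(x, j)` their summed eggs, the schedules are frequency estimates:
`s_xj = N(x, j)/n0`, `f_xj = E(x, j)/N(x, j)` (0 in empty cells),
`l_x = Σ_j s_xj`, `m_x = Σ_j s_xj f_xj / l_x` (defined as 0 where
`l_x = 0`, so it contributes nothing to `R0`), and `l_x m_x`. The scalar
parameters follow: `R0 = Σ_x l_x m_x`, which equals total eggs divided by
`n0` exactly — an integer-exact conservation identity the tests assert.

The intrinsic rate solves the Euler–Lotka equation with the end-of-day
credit convention,

`Σ_x exp(−r (x + 1)) l_x m_x = 1,`

whose left side is strictly decreasing in `r`, so the root is unique.
`intrinsic_rate()` brackets it on `[−1, 5]` per day (far beyond any
biologically attainable insect rate in either direction), solves with
Brent's method, and polishes with up to three Newton steps until the
residual is below `1e-12`. This convention preserves `T = ln(R0)/r`, the
identity the published parameter triplets satisfy to printed rounding,
and gives `λ = e^r` as the finite daily rate.

## The transition model, life expectancy, reproductive value, SASD

The engine behind the remaining schedules is an empirical daily Markov
model over age-stage cells. The probability of moving from cell `(x, j)`
to `(x+1, j′)` is estimated by the observed cell-frequency ratio — the
maximum-likelihood estimator under the Markov assumption — and the
per-cell death probability is the remainder. Cells no one occupied carry
zero transitions, and no transitions leave the oldest observed age.

- **Life expectancy** `e_xj` is the expected number of further days lived
  by an occupant of `(x, j)`, *including the current day* (so `e ≥ 1` in
  any occupied cell), by backward recursion
  `e(x, j) = 1 + Σ_j′ g(x, j → j′) e(x+1, j′)`. With unpooled empirical
  transitions, `e(0, first stage)` reproduces the raw mean lifespan
  exactly; the suite also checks `e_xj` against a 10^5-walker Monte-Carlo
  simulation of the same chain.
- **Reproductive value** `v_xj` is the discounted expected future
  reproduction of a current occupant of `(x, j)`:
  `v(x, j) = f(x, j) + e^{−r} Σ_j′ g(x, j → j′) v(x+1, j′)`. This is the
  conditional (per-occupant) normalization of the age-stage framework and
  satisfies the identity `v(0, first stage) = λ`, which the tests assert
  to `1e-6` on every cohort with `R0 > 0`. The published figures quote
  "initial reproductive values" of 29–55 for these cohorts, which cannot
  be `v(0, 1)` under this identity (λ is ~1.2/day); the normalization
  behind those printed numbers is not stated in the source and is not
  reproduced here.
- **SASD.** The stable age-stage distribution is obtained by power
  iteration of the daily projection map (survive/advance each cell,
  recruit `Σ` female-cell count × fecundity to age 0 of stage 1) rather
  than by building and decomposing the large sparse projection matrix:
  the iteration *is* the projection machinery, so consistency between the
  two is structural. Iteration stops when the L1 change of the
  cell-proportion vector falls below `1e-10` (cap 10^5 iterations); the
  converged day-to-day total ratio equals `e^r` to well under `1e-6`,
  which is asserted rather than assumed.

Degenerate cohorts (`R0 = 0`, e.g. no female reproduced) leave `r`, `λ`,
`T`, `v_xj` and the SASD as `NA` rather than raising: bootstrap
resamples routinely produce such replicates and must not abort the run.

## Bootstrap uncertainty

The resampling unit is the whole individual — its complete life history —
drawn `n0` at a time with replacement, preserving the within-individual
correlation between development and fecundity. The scalar parameters
depend on a resample only through the per-age egg totals, so replicates
are computed from a precomputed individual × age egg matrix; each
replicate re-solves the Euler–Lotka equation. `B` defaults to 100,000
(the study's setting); the tests use 10^3–10^4, which is ample for SEs
and percentile CIs of these smooth functionals. SE is the sample SD over
non-degenerate replicates, the CI the 2.5/97.5 percentiles, and the
degenerate count is reported. One seeded generator drives the replicate
stream sequentially, so identical `(cohort, B, seed)` reproduce results
bit for bit.

The paired comparison draws `B` independent replicate pairs, one from
each cohort, and reports the two-sided percentile p-value
`2·min(#{d* ≤ 0}, #{d* > 0})/B′` on the differences (capped at 1,
degenerate pairs excluded from `B′`). The published duration/longevity
tables mark significance with both a bootstrap and an ANOVA/Duncan
procedure cited side by side; this package implements the bootstrap
comparison only, and makes no multiple-testing correction across
parameters.

## Projection

`project_population()` is a deterministic expected-value projection with
real-valued cell counts — reproducibility is the point; the smooth
published prediction curves are expectations, not stochastic runs. The
default initial composition is 10 individuals at age 0 of the first
stage over a 60-day horizon (both configurable); the source does not
state the initial composition behind its prediction figure, so the
default here is this package's own. Beyond the cohort's oldest observed
age all rates are zero. Because newborns recruit to the first instar
with no egg-stage delay, horizons are effectively shifted by the
(untracked) egg duration relative to a program that models an egg stage.
Daily totals oscillate with the generation cycle (period ≈ `T`) while
the age structure converges, so short-horizon growth is best read as a
geometric-mean daily ratio over one cycle; the single-day ratio matches
`e^r` to `1e-6` only after several hundred days, when the subdominant
transient (decaying at roughly 0.97/day for these cohorts) has died out.

## Summary tables

Stage durations count **completers only** — individuals that advanced
out of the stage — because a per-stage census with decreasing `n` is only
consistent with that convention; adult "duration" is longevity to death.
`APOP` is first-egg age minus female-emergence age (0 if she lays on
emergence day); `TPOP` counts calendar days from cohort start with day
1 = age 0, hence first-egg age + 1. The total pre-oviposition origin is
taken at the first instar (the cohort's own start), a convention-
sensitive choice documented here because sources differ on whether the
egg cohort's oviposition is the origin. Lifetime fecundity is reported
both over reproducing females (the table statistic) and over all females
(the quantity entering the `R0` identity). The mortality distribution
assigns each individual's death to the stage of its last observed day
and aggregates to immature/female/male/adult; the fractions sum to 1 by
construction.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design so that every stage of the
pipeline is testable without raw data: cohorts of 90 individuals, five
nymphal instars of ~2–5 days, a sex branch at the final molt, adult
longevities of ~18–25 days and lifetime fecundities of ~250–410 eggs per
reproducing female. Structurally:

- **Instar durations** are discretized gamma, `D = max(1, round(Γ))`,
  with shape 25 by default (matching the small printed SEs of the
  duration means); a shifted-geometric option exists for analytic
  tractability in tests.
- **Mortality acts per day within stages**, competing with development;
  death mid-stage truncates the record — exactly the structure the
  estimators assume. Per-stage daily survival in the presets is derived
  from the printed per-stage mortality fractions and mean durations.
- **Adult survival is geometric** per sex, with daily survival
  `1 − 1/longevity` so the mean matches the printed adult longevities
  (geometric lifespans also reproduce the printed longevity SEs'
  magnitude, whose SD ≈ mean).
- **Reproduction**: a discretized-gamma adult pre-oviposition period
  (shape 4, matching the printed APOP SEs), then daily Poisson egg
  counts around a triangular curve — rise to a peak at laying day 6,
  linear decline over a 25-day window, the single-peak shape of the
  published daily-fecundity curves. The peak height is calibrated so the
  expected lifetime fecundity of a female surviving into the laying
  window matches the printed treatment mean given her survival curve.

The four `treatment_preset()` configs encode the printed table values as
calibration targets, not ground truth: passing recovery tests shows the
estimators invert the generator, not that the generator is the insect.
Real cohorts differ in ways the generator deliberately omits — duration
and survival correlations within individuals, non-geometric adult
senescence, overdispersed (non-Poisson) daily eggs, censoring — so
generator-based coverage results should be read as properties of the
method, not of any particular rearing.

`theoretical_schedule()` is the oracle: it propagates the exact
stage/day-in-stage occupancy distribution implied by a config (duration
hazards competing with daily survival, the sex branch, the
APOP-convolved egg curve) and solves the same Euler–Lotka equation,
entirely independently of any simulated cohort. Estimated `r` from an
n = 5000 simulated cohort recovers the theoretical `r` within ±0.01 for
every preset, and the bootstrap percentile CI for `r` at the study size
(n = 90, B = 1000) covers the theoretical value at close to the nominal
95% over 200 replicate cohorts.

## Problem sizes and numerical choices at a glance

- Euler–Lotka: Brent on `[−1, 5]`, Newton-polished, residual < `1e-12`;
  the acceptance checks require < `1e-9`.
- SASD power iteration: L1 tolerance `1e-10`, cap 10^5 iterations.
- Generator tail truncation: duration pmfs cut at upper-tail mass
  `1e-12`; theoretical schedules stop once survivorship < `1e-10`; adult
  lifespans capped at 400 days (reaching the cap has probability
  ~`1e-11` at the presets' survival rates), mirrored exactly in the
  oracle.
- Test-suite sizes: property sweeps use 100 random 30-individual
  cohorts on 3–5-stage schemes; Monte-Carlo cross-checks use 10^5
  walkers (life expectancy) and 3 × 10^4 individuals (survivorship);
  recovery uses n = 5000 per preset; coverage uses 200 cohorts at
  n = 90 with B = 1000.

## Known limitations

Daily census only — no continuous-time or variable-interval variant; no
censoring; no jackknife or BCa intervals; no density dependence,
immigration or intervention timing in the projection; the generator's
independence assumptions listed above. The published per-stage sample
sizes (80, 82, … of a nominal 90) suggest some pre-analysis exclusions
the source does not describe; the data model makes no assumption about
them, and presets simply start at n = 90.
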