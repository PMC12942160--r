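# agestage

Age-stage, two-sex life table analysis for insect cohorts in R.

## What this is for

Classical female-only, age-only life tables ignore males, ignore the
developmental stage an individual occupies at a given age, and force every
individual through an identical development schedule. The age-stage,
two-sex framework removes those simplifications: a reared cohort is
followed **daily**, one record per individual per day (`id, age, stage,
eggs`), through its nymphal instars and into either adult sex, and every
demographic quantity is indexed by both age *x* and stage *j*. The
framework is the standard tool for quantifying how a treatment — a host
plant, a symbiont, an insecticide — changes the population fitness of an
insect such as the brown planthopper (*Nilaparvata lugens*), where the
treatments of interest are rice varieties with and without a bacterial
symbiont.

From the daily records the package computes:

- **Schedules** — age-stage survival
  `s_xj = N(x,j)/n0`, age-stage fecundity `f_xj = E(x,j)/N(x,j)`,
  age-specific survival `l_x = Σ_j s_xj`, age-specific fecundity
  `m_x = Σ_j s_xj f_xj / l_x`, net maternity `l_x m_x`, age-stage life
  expectancy `e_xj`, reproductive value `v_xj`, and the stable age-stage
  distribution (SASD).
- **Scalar parameters** — net reproductive rate `R0 = Σ_x l_x m_x`; the
  intrinsic rate of increase `r` solving the Euler–Lotka equation
  `Σ_x e^{-r(x+1)} l_x m_x = 1` (age counted from 0, reproduction credited
  at the end of day *x*); finite rate `λ = e^r`; mean generation time
  `T = ln(R0)/r`.
- **Uncertainty** — bootstrap standard errors and percentile confidence
  intervals by resampling whole individuals with replacement, and a
  paired-bootstrap two-sided test for comparing a parameter between two
  treatments.
- **Projection** — a deterministic 60-day (or any horizon) population
  projection from the cohort-derived daily transition rates, with
  newborns recruiting to the first instar.
- **Summaries** — stage durations, adult longevities, APOP/TPOP,
  oviposition days, lifetime fecundity and the per-stage mortality
  distribution, plus the `2^-ΔΔCt` qPCR fold-change helper.
- **Synthetic cohorts** — a stochastic generator
  (`simulate_cohort()`) with four treatment presets calibrated to the
  published summary tables, and `theoretical_schedule()`, the exact
  schedule implied by a generator config, so the whole pipeline can be
  validated by parameter recovery without any raw-data download.

## Worked example

```r
library(agestage)

cfg    <- treatment_preset("KF30-14_Ars+", n = 90)   # symbiont-infected, Bt rice
cohort <- simulate_cohort(cfg, seed = 7)
cohort
#> Cohort of 90 individuals, 2189 individual-days, ages 0- 95
#>   scheme: N1 N2 N3 N4 N5 F M
#>   total eggs: 6889

lt <- life_table(cohort)
lt
#> Age-stage, two-sex life table (n0 = 90 , ages 0- 95 )
#>   R0 = 76.5444 offspring/individual
#>   r  = 0.16219 /day   lambda = 1.17608 /day   T = 26.746 days
```

The cohort multiplies 76.5-fold per generation (`R0`), grows 17.6% per day
once its age-stage structure stabilizes (`λ`), and a generation spans
about 26.7 days (`T`). Uncertainty comes from resampling individuals:

```r
bootstrap_lifetable(cohort, params = c("r", "R0"), B = 5000, seed = 1)
#>   param   point        se  ci_low  ci_high    B seed n_degenerate
#> 1     r  0.1622  0.008267  0.1439   0.1763 5000    1            0
#> 2    R0 76.5444 14.894017 48.6886 106.9119 5000    1            0

ref <- simulate_cohort(treatment_preset("KF30-14_Ars-", n = 90), seed = 8)
paired_bootstrap_test(ref, cohort, param = "r", B = 5000, seed = 1)
#> Paired bootstrap comparison of r
#>   A - B = 0.03961, p = 0.0004 (B = 5000 pairs, 0 degenerate)
```

On the Bt rice host the symbiont-free cohort grows significantly faster
(`Δr ≈ 0.04/day`, p < 0.001), the same direction the rearing study
reports. Finally, project ten first-instar nymphs forward:

```r
project_population(lt, days = 60)
#> Population projection over 60 days
#>   total: day 0 = 10.0, day 60 = 3.236e+04
#>   final daily growth ratio = 1.07250
```

Real cohort files are read with `read_cohort("cohort.csv", scheme)`
(header `id,age,stage,eggs`, one row per individual-day, death encoded by
truncation); `write_lifetable(lt, dir)` exports every schedule as CSV
plus a `params.json`.

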