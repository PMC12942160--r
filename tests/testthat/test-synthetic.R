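test_that("simulated cohorts always satisfy the data-model invariants", {
  set.seed(55)
  for (i in 1:8) {
    co <- simulate_cohort(random_config(n = 25L), seed = 300 + i)
    expect_identical(nrow(validate_cohort(co)), 0L)
    expect_identical(co$n0, 25L)
  }
})

test_that("a fixed seed reproduces the simulated cohort exactly", {
  cfg <- treatment_preset("MH86_Ars-", n = 40)
  c1 <- simulate_cohort(cfg, seed = 99)
  c2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(c1$data, c2$data)
  c3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(c1$data, c3$data))
})

test_that("degenerate configs produce degenerate but valid cohorts", {
  # no mortality, near-deterministic durations, no females: identical males
  cfg <- simulation_config(
    n = 6, scheme = toy_scheme(), dur_mean = 3, dur_shape = 1e6,
    stage_survival = 1, p_female = 0, female_survival = 1,
    male_survival = 1, egg_peak = 10, max_adult_days = 4)
  co <- simulate_cohort(cfg, seed = 1)
  per <- split(co$data$stage, co$data$id)
  expect_true(all(vapply(per, identical, TRUE, per[[1]])))
  sd <- stage_duration_summary(co)
  expect_equal(sd[sd$stage == "N1", ]$se, 0)
  expect_equal(life_table(co)$params$R0, 0)  # no females, no eggs
})

test_that("completed stage durations obey the config-implied conditional mean", {
  # completers are biased toward shorter durations because each extra day
  # risks death; the oracle weights the duration pmf by p^D
  cfg <- treatment_preset("MH86_Ars-", n = 5000)
  co <- simulate_cohort(cfg, seed = 61)
  sd <- stage_duration_summary(co)
  n1 <- sd[sd$stage == "N1", ]
  pmf <- agestage:::dur_pmf(cfg$dur_mean[1], cfg$dur_shape[1], cfg$dur_dist)
  w <- pmf * cfg$stage_survival[1]^seq_along(pmf)
  oracle <- sum(seq_along(pmf) * w) / sum(w)
  expect_lt(abs(n1$mean - oracle), 3 * n1$se)
})

test_that("theoretical schedule reproduces trivial closed forms", {
  # one 1-day stage, no mortality, all female, one egg on the second day
  cfg <- simulation_config(
    n = 10, scheme = stage_scheme(c("S1", "F", "M")), dur_mean = 1,
    dur_shape = 1e6, stage_survival = 1, p_female = 1,
    female_survival = 0, male_survival = 0, apop_mean = 0,
    egg_peak = 1, egg_peak_day = 1, egg_days = 1)
  th <- theoretical_schedule(cfg)
  expect_equal(th$lxmx, c(0, 1), tolerance = 1e-9)
  expect_equal(th$R0, 1, tolerance = 1e-9)
  expect_equal(th$r, 0, tolerance = 1e-9)

  # doubling the fecundity curve doubles R0 exactly
  cfg2 <- treatment_preset("KF30-14_Ars-")
  th1 <- theoretical_schedule(cfg2)
  cfg2$egg_peak <- 2 * cfg2$egg_peak
  th2 <- theoretical_schedule(cfg2)
  expect_equal(th2$R0, 2 * th1$R0, tolerance = 1e-10)
})

test_that("simulated survivorship matches the exact theoretical lx", {
  cfg <- treatment_preset("MH86_Ars+", n = 30000)
  th <- theoretical_schedule(cfg)
  co <- simulate_cohort(cfg, seed = 77)
  counts <- age_stage_counts(co)
  lx_hat <- rowSums(counts$N) / cfg$n
  ages <- seq_len(min(length(lx_hat), length(th$lx)))
  se <- sqrt(pmax(th$lx[ages] * (1 - th$lx[ages]), 1e-12) / cfg$n)
  keep <- th$lx[ages] > 1e-4
  z <- (lx_hat[ages][keep] - th$lx[ages][keep]) / se[keep]
  expect_lt(max(abs(z)), 4)  # simultaneous bound over ~60 ages
})

test_that("estimated R0 converges to the theoretical value at large n", {
  # R0_hat is a mean of iid lifetime egg counts, so the right convergence
  # band is the Monte-Carlo one: |R0_hat - R0| within a few analytic SEs
  # (the per-individual egg SD is large -- immature deaths and males
  # contribute zeros -- so a fixed small percentage would just be a coin
  # flip on the sampling noise)
  cfg <- treatment_preset("MH86_Ars-", n = 10000)
  th <- theoretical_schedule(cfg)
  co <- simulate_cohort(cfg, seed = 1)
  R0_hat <- sum(co$data$eggs) / co$n0
  eggs <- tapply(co$data$eggs, co$data$id, sum)
  se <- stats::sd(eggs) / sqrt(co$n0)
  expect_lt(abs(R0_hat - th$R0), 3 * se)
})

test_that("treatment presets encode the printed study magnitudes", {
  sv <- study_printed_values()
  for (tr in sv$treatments) {
    cfg <- treatment_preset(tr)
    expect_identical(cfg$n, 90L)
    expect_equal(cfg$dur_mean, unname(sv$stage_duration[, tr]))
    lon <- sv$longevity[tr, ]
    expect_equal(1 / (1 - cfg$female_survival), lon$female_longevity)
    expect_equal(cfg$p_female, lon$n_female / (lon$n_female + lon$n_male))
  }
})
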