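test_that("age-stage survival and fecundity match the toy enumeration", {
  counts <- age_stage_counts(toy_cohort())
  s <- survival_rates(counts)
  expect_equal(s["1", "N1"], 0.5)
  expect_equal(s["1", "M"], 0.25)
  expect_equal(s["2", "F"], 0.5)
  expect_equal(s["3", "F"], 0.25)
  expect_equal(sum(s["0", ]), 1)  # the cohort starts complete
  expect_error(survival_rates(counts, n0 = 0), "positive")

  f <- fecundity_matrix(counts)
  expect_equal(f["2", "F"], 2.0)
  expect_equal(f["3", "F"], 1.0)
  expect_true(all(f[, c("N1", "M")] == 0))
})

test_that("fecundity is zero without females and per-cell with one female", {
  males <- as_cohort(data.frame(id = c("A", "A"), age = c(0, 1),
                                stage = c("N1", "M"), eggs = c(0, 0)),
                     toy_scheme())
  expect_true(all(fecundity_matrix(age_stage_counts(males)) == 0))

  one <- as_cohort(data.frame(id = c("A", "A"), age = c(0, 1),
                              stage = c("N1", "F"), eggs = c(0, 5)),
                   toy_scheme())
  expect_equal(fecundity_matrix(age_stage_counts(one))["1", "F"], 5)
})

test_that("age-specific schedules collapse the matrices correctly", {
  counts <- age_stage_counts(toy_cohort())
  sched <- age_schedules(survival_rates(counts), fecundity_matrix(counts))
  expect_equal(unname(sched$lx), c(1, 0.75, 0.75, 0.25))
  expect_equal(unname(sched$mx[3]), 4 / 3)
  expect_equal(unname(sched$lxmx), c(0, 0, 1, 0.25))
  expect_equal(net_reproductive_rate(sched$lxmx), 1.25)  # 5 eggs / 4
  expect_equal(net_reproductive_rate(numeric(5)), 0)
})

test_that("the Euler-Lotka solver agrees with closed forms and the bisection oracle", {
  # single term at age 0: exp(-r) * 2 = 1
  expect_equal(intrinsic_rate(2), log(2), tolerance = 1e-12)
  # toy schedule vs an independent bisection
  lxmx <- c(0, 0, 1, 0.25)
  r <- intrinsic_rate(lxmx)
  expect_equal(r, bisect_r(lxmx), tolerance = 1e-10)
  expect_lt(abs(sum(exp(-r * seq_along(lxmx)) * lxmx) - 1), 1e-9)
  # unit total reproduction concentrated anywhere gives r = 0
  expect_equal(intrinsic_rate(c(0, 0, 0, 1)), 0, tolerance = 1e-10)
  expect_error(intrinsic_rate(numeric(3)), "R0")
})

test_that("finite rate and generation time follow their identities", {
  expect_equal(finite_rate(0), 1)
  expect_equal(finite_rate(log(2)), 2)
  expect_equal(mean_generation_time(exp(1), 1), 1)
  lxmx <- c(0, 0, 1, 0.25)
  r <- intrinsic_rate(lxmx)
  expect_equal(mean_generation_time(1.25, r), log(1.25) / r)
  expect_error(mean_generation_time(1.25, 0), "undefined")
  expect_error(mean_generation_time(0, 0.1), "undefined")
})

test_that("transition probabilities are the observed cell-frequency ratios", {
  m <- transition_model(toy_cohort())
  expect_equal(m$G["0", "N1", "N1"], 0.5)
  expect_equal(m$G["0", "N1", "M"], 0.25)
  expect_equal(sum(m$G["0", "N1", ]), 0.75)  # death fills the rest
  expect_equal(m$G["1", "N1", "F"], 1)
  expect_equal(m$G["2", "M", "M"], 0)        # terminal cell, all die
  # every individual dies exactly once under the fitted model
  deaths <- m$N * (1 - apply(m$G, c(1, 2), sum))
  expect_equal(sum(deaths), 4)
})

test_that("life expectancy follows the backward occupancy recursion", {
  m <- transition_model(toy_cohort())
  e <- life_expectancy(m)
  expect_equal(e["0", "N1"], 2.75)  # 1 + 0.75 + 0.75 + 0.25
  expect_equal(e["2", "M"], 1)      # occupant dies before the next day
  expect_equal(e["3", "F"], 1)
  expect_true(is.na(e["0", "F"]))   # unoccupied cell
  # e(0, first stage) is the raw mean lifespan, counting the first day
  expect_equal(e["0", "N1"], mean(c(4, 3, 3, 1)))

  # deterministic survival for exactly k further days gives e = k + 1
  det <- as_cohort(data.frame(id = rep("A", 4), age = 0:3,
                              stage = c("N1", "M", "M", "M"),
                              eggs = 0L), toy_scheme())
  expect_equal(life_expectancy(transition_model(det))["0", "N1"], 4)
})

test_that("reproductive value satisfies the Euler-Lotka identity and vanishes post-reproduction", {
  tc <- toy_cohort()
  lt <- life_table(tc)
  expect_equal(lt$vxj["0", "N1"], lt$params$lambda, tolerance = 1e-9)
  expect_equal(lt$vxj["1", "M"], 0)  # no future eggs from a male cell
  expect_equal(lt$vxj["3", "F"], 1)  # lays today, then dies
})

test_that("stable distribution proportions sum to one and grow at lambda", {
  lt <- life_table(toy_cohort())
  expect_equal(sum(lt$sasd), 1, tolerance = 1e-12)
  expect_equal(lt$growth_ratio, exp(lt$params$r), tolerance = 1e-6)
})

test_that("full life table handles a cohort with no reproduction", {
  barren <- as_cohort(data.frame(id = c("A", "A", "B"), age = c(0, 1, 0),
                                 stage = c("N1", "M", "N1"), eggs = 0L),
                      toy_scheme())
  lt <- life_table(barren)
  expect_equal(lt$params$R0, 0)
  expect_true(is.na(lt$params$r))
  expect_true(is.na(lt$params$T))
  expect_false(anyNA(lt$exj[lt$model$N > 0]))  # still computed
})

test_that("scalar identities hold on the toy life table", {
  lt <- life_table(toy_cohort())
  p <- lt$params
  expect_equal(p$T * p$r, log(p$R0), tolerance = 1e-12)
  expect_equal(p$R0, sum(toy_cohort()$data$eggs) / 4)
  expect_equal(p$lambda, exp(p$r))
})

test_that("life table CSV/JSON export writes the full schedule set", {
  dir <- withr::local_tempdir()
  write_lifetable(life_table(toy_cohort()), dir)
  files <- c("sxj.csv", "lx_mx.csv", "exj.csv", "vxj.csv", "sasd.csv",
             "params.json")
  expect_true(all(file.exists(file.path(dir, files))))
  pars <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(pars$R0, 1.25)
  sxj <- utils::read.csv(file.path(dir, "sxj.csv"), check.names = FALSE)
  expect_identical(names(sxj), c("age", "N1", "F", "M"))
  expect_equal(sxj$N1[1], 1)
})
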