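test_that("cohort CSV round-trips exactly", {
  tc <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tc, path)
  back <- read_cohort(path, toy_scheme())
  expect_identical(back$data, tc$data)
  expect_identical(back$n0, tc$n0)
})

test_that("read_cohort rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,age,stage,eggs", path)
  expect_error(read_cohort(path, toy_scheme()), "empty cohort")

  writeLines(c("id,age,stage", "A,0,N1"), path)
  expect_error(read_cohort(path, toy_scheme()), "missing column")

  writeLines(c("id,age,stage,eggs", "A,0,XX,0"), path)
  expect_error(read_cohort(path, toy_scheme()), "unknown_stage")

  writeLines(c("id,age,stage,eggs", "A,0,N1,0", "A,2,N1,0"), path)
  expect_error(read_cohort(path, toy_scheme()), "age_sequence")
})

test_that("a one-individual, one-day cohort is valid with omega = 0", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,stage,eggs", "A,0,N1,0"), path)
  co <- read_cohort(path, toy_scheme())
  expect_identical(co$n0, 1L)
  expect_identical(max(co$data$age), 0L)
  counts <- age_stage_counts(co)
  expect_identical(dim(counts$N), c(1L, 3L))
  expect_identical(counts$N[1, "N1"], 1L)
  expect_identical(sum(counts$N), 1L)
})

test_that("validate_cohort reports rule violations as data", {
  expect_identical(nrow(validate_cohort(toy_cohort())), 0L)

  eggs_on_male <- as_cohort(data.frame(
    id = c("A", "A"), age = c(0, 1), stage = c("N1", "M"), eggs = c(0, 2)),
    toy_scheme(), validate = FALSE)
  v <- validate_cohort(eggs_on_male)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "eggs_outside_female")

  regression <- as_cohort(data.frame(
    id = c("A", "A", "A"), age = c(0, 1, 2),
    stage = c("N1", "F", "N1"), eggs = c(0, 0, 0)),
    toy_scheme(), validate = FALSE)
  v <- validate_cohort(regression)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "stage_regression")

  skip2 <- as_cohort(data.frame(
    id = c("A", "A"), age = c(0, 1), stage = c("N1", "N3"), eggs = c(0, 0)),
    stage_scheme(c("N1", "N2", "N3", "F", "M")), validate = FALSE)
  v <- validate_cohort(skip2)
  expect_identical(v$rule, "stage_skip")
})

test_that("age-stage counts and egg totals match the hand enumeration", {
  counts <- age_stage_counts(toy_cohort())
  N <- counts$N
  expect_identical(N["0", "N1"], 4L)
  expect_identical(N["1", "N1"], 2L)
  expect_identical(N["1", "M"], 1L)
  expect_identical(N["2", "F"], 2L)
  expect_identical(N["2", "M"], 1L)
  expect_identical(N["3", "F"], 1L)
  expect_identical(sum(N), 11L)  # one cell per individual-day
  E <- counts$E
  expect_identical(E["2", "F"], 4L)
  expect_identical(E["3", "F"], 1L)
  expect_identical(sum(E), 5L)
})

test_that("round-trip, cohort-start and egg-conservation invariants hold on random cohorts", {
  set.seed(71)
  for (i in 1:10) {
    cfg <- random_config(n = 20L)
    co <- simulate_cohort(cfg, seed = 1000 + i)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    back <- read_cohort(path, cfg$scheme)
    expect_identical(back$data, co$data)

    counts <- age_stage_counts(co)
    expect_identical(sum(counts$N[1, ]), co$n0)
    expect_identical(sum(counts$E), sum(co$data$eggs))
  }
})

test_that("stage scheme config files read back correctly", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# scheme", "stages = N1, N2, F, M", "female = F",
               "male = M"), path)
  sch <- read_stage_scheme(path)
  expect_identical(sch$stages, c("N1", "N2", "F", "M"))
  expect_identical(sch$branch, "N2")
  expect_identical(sch$n_immature, 2L)
})
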