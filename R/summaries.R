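# Per-individual digest used by the summary tables: stage day-counts, the
# death stage, female reproduction quantities.
individual_digest <- function(cohort) {
  sch <- cohort$scheme
  stages <- sch$stages
  lapply(split(cohort$data, factor(cohort$data$id,
                                   levels = unique(cohort$data$id))),
         function(ind) {
    days_in <- table(factor(ind$stage, levels = stages))
    last_stage <- ind$stage[nrow(ind)]
    is_female <- any(ind$stage == sch$female)
    is_male <- any(ind$stage == sch$male)
    fem <- NULL
    if (is_female) {
      fdays <- ind[ind$stage == sch$female, , drop = FALSE]
      first_egg <- if (any(fdays$eggs > 0)) min(fdays$age[fdays$eggs > 0])
                   else NA_integer_
      fem <- list(emergence_age = min(fdays$age),
                  first_egg_age = first_egg,
                  od = sum(fdays$eggs > 0),
                  eggs = sum(fdays$eggs))
    }
    list(id = ind$id[1], days_in = days_in, last_stage = last_stage,
         lifespan = nrow(ind), is_female = is_female, is_male = is_male,
         female = fem)
  })
}

mean_se <- function(x) {
  n <- length(x)
  list(n = n,
       mean = if (n > 0) mean(x) else NA_real_,
       se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
}

#' Stage durations and longevities
#'
#' Duration of an immature stage is the number of days an individual spent
#' in it, counted only for individuals that advanced out of the stage
#' (deaths within the stage are excluded, which is why the sample size
#' decreases with stage). For the adult stages the duration is the adult
#' longevity: days from emergence to death. Two aggregate rows are added:
#' `adult` (both sexes pooled) and `total` (whole lifespan of every
#' individual, counting the first day).
#'
#' @param cohort A valid `cohort`.
#' @return A data frame with columns `stage`, `n`, `mean`, `se` (days).
#' @export
stage_duration_summary <- function(cohort) {
  sch <- cohort$scheme
  dig <- individual_digest(cohort)
  stages <- sch$stages
  rows <- lapply(stages, function(st) {
    adult <- st %in% c(sch$female, sch$male)
    durs <- unlist(lapply(dig, function(z) {
      d <- z$days_in[[st]]
      if (d == 0L) return(NULL)
      if (!adult && z$last_stage == st) return(NULL)  # died in stage
      d
    }))
    c(list(stage = st), mean_se(as.numeric(durs)))
  })
  adult_long <- unlist(lapply(dig, function(z) {
    d <- z$days_in[[sch$female]] + z$days_in[[sch$male]]
    if (d > 0L) d else NULL
  }))
  total_long <- vapply(dig, function(z) as.numeric(z$lifespan), 0)
  rows <- c(rows,
            list(c(list(stage = "adult"), mean_se(as.numeric(adult_long))),
                 c(list(stage = "total"), mean_se(as.numeric(total_long)))))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Reproductive parameter summary
#'
#' Over females that laid at least one egg: the adult pre-oviposition
#' period `APOP` (first-egg age minus emergence age, days), the total
#' pre-oviposition period `TPOP` (calendar days from cohort start with day
#' 1 = age 0, hence first-egg age + 1), oviposition days `Od` (days with
#' at least one egg), and lifetime fecundity `F`. Fecundity is also
#' reported over all females (`fecundity_all`), the quantity entering the
#' cohort-level identity `R0 = mean(F_all) * n_females / n0`.
#'
#' @param cohort A valid `cohort`.
#' @return A list with `per_female` (one row per female), `summary` (rows
#'   APOP/TPOP/Od/fecundity over reproducing females, plus
#'   `fecundity_all`), `n_females` and `n_reproducing`.
#' @export
reproduction_summary <- function(cohort) {
  dig <- individual_digest(cohort)
  fem <- Filter(function(z) z$is_female, dig)
  per <- do.call(rbind, lapply(fem, function(z) {
    f <- z$female
    data.frame(id = z$id,
               emergence_age = f$emergence_age,
               apop = if (is.na(f$first_egg_age)) NA_integer_
                      else f$first_egg_age - f$emergence_age,
               tpop = if (is.na(f$first_egg_age)) NA_integer_
                      else f$first_egg_age + 1L,
               od = f$od, fecundity = f$eggs,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(id = character(), emergence_age = integer(),
                      apop = integer(), tpop = integer(), od = integer(),
                      fecundity = integer(), stringsAsFactors = FALSE)
  rownames(per) <- NULL
  rep_f <- per[!is.na(per$apop), , drop = FALSE]
  srow <- function(name, x) c(list(parameter = name), mean_se(as.numeric(x)))
  summ <- do.call(rbind, lapply(list(
    srow("APOP", rep_f$apop),
    srow("TPOP", rep_f$tpop),
    srow("Od", rep_f$od),
    srow("fecundity", rep_f$fecundity),
    srow("fecundity_all", per$fecundity)
  ), as.data.frame))
  list(per_female = per, summary = summ,
       n_females = nrow(per), n_reproducing = nrow(rep_f))
}

#' Mortality distribution over stages
#'
#' The fraction of the initial cohort dying while in each stage (the stage
#' of an individual's last observed day), which sums to 1 on any complete
#' cohort, plus the aggregates printed in study tables: `immature` (all
#' nymphal stages), `female`, `male`, and `adult` (female + male).
#'
#' @param cohort A valid `cohort`.
#' @return A list with `by_stage` (named fractions over all stages) and
#'   scalars `immature`, `female`, `male`, `adult`.
#' @export
mortality_distribution <- function(cohort) {
  sch <- cohort$scheme
  dig <- individual_digest(cohort)
  last <- vapply(dig, function(z) z$last_stage, "")
  frac <- table(factor(last, levels = sch$stages)) / cohort$n0
  by_stage <- stats::setNames(as.numeric(frac), sch$stages)
  imm <- sum(by_stage[seq_len(sch$n_immature)])
  fem <- by_stage[[sch$female]]
  mal <- by_stage[[sch$male]]
  list(by_stage = by_stage, immature = imm, female = fem, male = mal,
       adult = fem + mal)
}

#' qPCR relative expression (2^-ddCt)
#'
#' Fold change of a target gene in a treatment sample relative to a
#' control, each normalized to a reference gene:
#' `RQ = 2^-[(Ct_target_t - Ct_ref_t) - (Ct_target_c - Ct_ref_c)]`.
#'
#' @param ct_target_t,ct_ref_t Target and reference-gene Ct in treatment.
#' @param ct_target_c,ct_ref_c Target and reference-gene Ct in control.
#' @return The relative quantity (vectorized).
#' @export
qpcr_relative_expression <- function(ct_target_t, ct_ref_t,
                                     ct_target_c, ct_ref_c) {
  stopifnot(all(is.finite(c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c))))
  2^-((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c))
}
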