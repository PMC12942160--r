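# --- duration distributions -------------------------------------------------
#
# Immature stage durations are integer days >= 1, drawn either from a
# discretized gamma, D = max(1, round(Gamma(shape, scale = mean/shape))),
# with realistic overdispersion control, or from a shifted geometric,
# D = 1 + Geom(1/mean), which is analytically convenient in tests. The
# adult pre-oviposition period uses the same discretization but allows 0.

dur_sample <- function(n, mean, shape, dist) {
  switch(dist,
    gamma = pmax(1, round(stats::rgamma(n, shape, scale = mean / shape))),
    geometric = 1L + stats::rgeom(n, 1 / mean),
    stop("unknown duration distribution: ", dist))
}

# pmf over k = 1, 2, ... truncated where the upper tail < eps
dur_pmf <- function(mean, shape, dist, eps = 1e-12) {
  if (dist == "gamma") {
    kmax <- max(2, ceiling(stats::qgamma(1 - eps, shape,
                                         scale = mean / shape)) + 1)
    k <- seq_len(kmax)
    p <- stats::pgamma(k + 0.5, shape, scale = mean / shape) -
         stats::pgamma(k - 0.5, shape, scale = mean / shape)
    p[1] <- stats::pgamma(1.5, shape, scale = mean / shape)
  } else if (dist == "geometric") {
    q <- 1 / mean
    kmax <- max(2, ceiling(log(eps) / log(1 - q)) + 1)
    k <- seq_len(kmax)
    p <- q * (1 - q)^(k - 1)
  } else stop("unknown duration distribution: ", dist)
  p / sum(p)
}

apop_sample <- function(n, mean, shape) {
  if (mean == 0) return(rep(0L, n))
  pmax(0, round(stats::rgamma(n, shape, scale = mean / shape)))
}

apop_pmf <- function(mean, shape, eps = 1e-12) {
  if (mean == 0) return(1)
  kmax <- max(1, ceiling(stats::qgamma(1 - eps, shape,
                                       scale = mean / shape)) + 1)
  k <- 0:kmax
  p <- stats::pgamma(k + 0.5, shape, scale = mean / shape) -
       stats::pgamma(pmax(k - 0.5, 0), shape, scale = mean / shape)
  p[1] <- stats::pgamma(0.5, shape, scale = mean / shape)
  p / sum(p)
}

# Triangular daily egg-mean curve over laying days 1..egg_days: linear
# rise to `peak` at `peak_day`, linear decline to zero after the last day.
egg_curve <- function(config) {
  d <- seq_len(config$egg_days)
  pd <- config$egg_peak_day
  L <- config$egg_days
  ifelse(d <= pd,
         config$egg_peak * d / pd,
         config$egg_peak * (L + 1 - d) / (L + 1 - pd))
}

#' Configuration for the stochastic cohort generator
#'
#' Encodes the statistical structure the life-table estimators assume:
#' per-instar duration distributions competing with daily within-stage
#' mortality, a Bernoulli sex assignment at the final molt, geometric
#' adult survival per sex, a discretized-gamma adult pre-oviposition
#' period, and daily Poisson egg counts around a triangular age curve.
#'
#' @param n Cohort size (default 90, the study design).
#' @param scheme A [stage_scheme()]; immature stage count must match the
#'   length of `dur_mean`.
#' @param dur_mean Mean duration (days) per immature stage.
#' @param dur_shape Gamma shape per immature stage (recycled); larger =
#'   less dispersed. Ignored for `dur_dist = "geometric"`.
#' @param dur_dist `"gamma"` (discretized, default) or `"geometric"`.
#' @param stage_survival Daily survival probability per immature stage.
#' @param p_female Probability an individual surviving the final molt
#'   becomes female.
#' @param female_survival,male_survival Daily adult survival probability.
#' @param apop_mean,apop_shape Mean (days, may be 0) and gamma shape of
#'   the adult pre-oviposition period.
#' @param egg_peak Peak of the daily egg-mean curve (eggs/day).
#' @param egg_peak_day Laying day at which the curve peaks.
#' @param egg_days Length of the laying window (days).
#' @param max_adult_days Hard cap on adult lifespan (days); the survival
#'   probabilities make reaching it vanishingly rare.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 90L,
                              scheme = default_scheme(),
                              dur_mean,
                              dur_shape = 25,
                              dur_dist = c("gamma", "geometric"),
                              stage_survival,
                              p_female = 0.6,
                              female_survival = 0.94,
                              male_survival = 0.95,
                              apop_mean = 3,
                              apop_shape = 4,
                              egg_peak = 40,
                              egg_peak_day = 6L,
                              egg_days = 25L,
                              max_adult_days = 400L,
                              seed = 1L) {
  dur_dist <- match.arg(dur_dist)
  k <- scheme$n_immature
  dur_shape <- rep_len(dur_shape, k)
  stopifnot(n >= 1, length(dur_mean) == k, all(dur_mean >= 1),
            length(stage_survival) == k,
            all(stage_survival >= 0 & stage_survival <= 1),
            p_female >= 0, p_female <= 1,
            female_survival >= 0, female_survival <= 1,
            male_survival >= 0, male_survival <= 1,
            apop_mean >= 0, apop_shape > 0,
            egg_peak >= 0, egg_peak_day >= 1, egg_days >= egg_peak_day,
            max_adult_days >= 1)
  structure(list(n = as.integer(n), scheme = scheme,
                 dur_mean = dur_mean, dur_shape = dur_shape,
                 dur_dist = dur_dist, stage_survival = stage_survival,
                 p_female = p_female,
                 female_survival = female_survival,
                 male_survival = male_survival,
                 apop_mean = apop_mean, apop_shape = apop_shape,
                 egg_peak = egg_peak, egg_peak_day = as.integer(egg_peak_day),
                 egg_days = as.integer(egg_days),
                 max_adult_days = as.integer(max_adult_days),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Cohort simulation config: n =", x$n, ", ",
      x$scheme$n_immature, "immature stages (", x$dur_dist, "durations )\n")
  cat("  mean durations:", paste(round(x$dur_mean, 2), collapse = ", "),
      " daily survival:", paste(round(x$stage_survival, 3), collapse = ", "),
      "\n")
  cat(sprintf("  p_female = %.3f; adult daily survival F %.3f / M %.3f\n",
              x$p_female, x$female_survival, x$male_survival))
  cat(sprintf("  APOP mean %.2f d; eggs peak %.1f/day at laying day %d of %d\n",
              x$apop_mean, x$egg_peak, x$egg_peak_day, x$egg_days))
  invisible(x)
}

#' Treatment presets calibrated to the printed study tables
#'
#' Builds a [simulation_config()] for one of the four study treatments,
#' with magnitudes read from [study_printed_values()]: mean instar
#' durations; per-stage daily survival derived from the printed stage
#' mortality fractions and durations; adult daily survival matching the
#' printed adult longevities under geometric survival (`q = 1 - 1/mean`);
#' the sex ratio from the printed adult counts; the printed APOP mean; and
#' an egg-curve peak calibrated so the expected lifetime fecundity of a
#' reproducing female matches the printed value given her survival curve.
#'
#' @param treatment One of `"MH86_Ars-"`, `"MH86_Ars+"`, `"KF30-14_Ars-"`,
#'   `"KF30-14_Ars+"`.
#' @param n Cohort size (default 90, the study design).
#' @param seed Default seed stored in the config.
#' @return A `simulation_config`.
#' @export
treatment_preset <- function(treatment = c("MH86_Ars-", "MH86_Ars+",
                                           "KF30-14_Ars-", "KF30-14_Ars+"),
                             n = 90L, seed = 1L) {
  treatment <- match.arg(treatment)
  sv <- study_printed_values()
  dur <- sv$stage_duration[, treatment]
  mort <- sv$mortality[, treatment]
  # conditional within-stage survival from cohort-fraction mortalities
  entrants <- 1 - cumsum(c(0, mort[-length(mort)]))
  stage_surv_frac <- pmin(1, pmax(0, 1 - mort / entrants))
  daily_surv <- stage_surv_frac^(1 / dur)
  lon <- sv$longevity[treatment, ]
  q_f <- 1 - 1 / lon$female_longevity
  q_m <- 1 - 1 / lon$male_longevity
  p_female <- lon$n_female / (lon$n_female + lon$n_male)
  rep_tab <- sv$reproduction[treatment, ]
  egg_peak_day <- 6L
  egg_days <- 25L
  # unit-peak triangle weighted by survival from the first laying day
  d <- seq_len(egg_days)
  tri <- ifelse(d <= egg_peak_day, d / egg_peak_day,
                (egg_days + 1 - d) / (egg_days + 1 - egg_peak_day))
  egg_peak <- rep_tab$fecundity / sum(tri * q_f^(d - 1))
  simulation_config(
    n = n, scheme = default_scheme(),
    dur_mean = unname(dur), dur_shape = 25, dur_dist = "gamma",
    stage_survival = unname(daily_surv),
    p_female = p_female,
    female_survival = q_f, male_survival = q_m,
    apop_mean = rep_tab$APOP, apop_shape = 4,
    egg_peak = egg_peak, egg_peak_day = egg_peak_day, egg_days = egg_days,
    seed = seed)
}

#' Simulate a cohort of daily life-history records
#'
#' Draws one individual at a time: a duration for each immature stage and
#' a geometric within-stage survival race (death mid-stage truncates the
#' record, exactly the structure the estimators assume); a Bernoulli sex
#' at the final molt; geometric adult survival; and, for females, daily
#' Poisson egg counts around the triangular age curve after the sampled
#' pre-oviposition period. A fixed seed reproduces the cohort exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to the config's.
#' @return A valid `cohort`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  sch <- config$scheme
  k <- sch$n_immature
  curve <- egg_curve(config)
  recs <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    stages <- character(0)
    eggs <- integer(0)
    dead <- FALSE
    for (s in seq_len(k)) {
      D <- dur_sample(1L, config$dur_mean[s], config$dur_shape[s],
                      config$dur_dist)
      p <- config$stage_survival[s]
      # days survived before the first failed daily check
      Z <- if (p >= 1) Inf else stats::rgeom(1L, 1 - p)
      ndays <- min(D, Z + 1)
      stages <- c(stages, rep(sch$stages[s], ndays))
      eggs <- c(eggs, integer(ndays))
      if (Z < D) { dead <- TRUE; break }
    }
    if (!dead) {
      female <- stats::runif(1L) < config$p_female
      q <- if (female) config$female_survival else config$male_survival
      Z <- if (q >= 1) Inf else stats::rgeom(1L, 1 - q)
      adays <- min(Z + 1, config$max_adult_days)
      if (female) {
        A <- apop_sample(1L, config$apop_mean, config$apop_shape)
        lay <- seq_len(adays) - A          # laying day of each adult day
        mu <- ifelse(lay >= 1 & lay <= config$egg_days,
                     curve[pmax(lay, 1)], 0)
        e <- stats::rpois(adays, mu)
        stages <- c(stages, rep(sch$female, adays))
        eggs <- c(eggs, e)
      } else {
        stages <- c(stages, rep(sch$male, adays))
        eggs <- c(eggs, integer(adays))
      }
    }
    recs[[i]] <- data.frame(id = sprintf("ind%04d", i),
                            age = seq_along(stages) - 1L,
                            stage = stages, eggs = as.integer(eggs),
                            stringsAsFactors = FALSE)
  }
  as_cohort(do.call(rbind, recs), sch, validate = FALSE)
}

#' Exact theoretical schedules implied by a generator config
#'
#' Computes, independently of any simulated cohort, the expected
#' age-specific survival `lx` and net maternity `lxmx` implied by a
#' [simulation_config()]: the stage/day-in-stage occupancy distribution is
#' propagated exactly (duration hazards competing with daily survival, the
#' sex branch, adult survival and the pre-oviposition-convolved egg
#' curve), and the scalar parameters follow from the same Euler-Lotka
#' solver the estimators use. This is the oracle for parameter-recovery
#' checks.
#'
#' @param config A [simulation_config()].
#' @param tail_eps Stop once survivorship falls below this (default
#'   `1e-10`).
#' @return An object of class `theoretical_schedule`: vectors `lx`, `mx`,
#'   `lxmx` (ages from 0), and scalars `R0`, `r`, `lambda`, `T` (`NA`
#'   rates when `R0 = 0`).
#' @export
theoretical_schedule <- function(config, tail_eps = 1e-10) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$scheme$n_immature
  pmfs <- lapply(seq_len(k), function(s)
    dur_pmf(config$dur_mean[s], config$dur_shape[s], config$dur_dist))
  # hazard of molting after day d in stage s, given still in the stage
  hazards <- lapply(pmfs, function(p) {
    surv <- rev(cumsum(rev(p)))
    h <- ifelse(surv > 0, p / surv, 1)
    h[length(h)] <- 1
    h
  })
  ap <- apop_pmf(config$apop_mean, config$apop_shape)
  curve <- egg_curve(config)
  cap <- config$max_adult_days
  # expected eggs on adult day a, marginalized over the APOP
  eggmean <- vapply(seq_len(cap), function(a) {
    lay <- a - (seq_along(ap) - 1L)
    sum(ap[lay >= 1 & lay <= config$egg_days] *
          curve[lay[lay >= 1 & lay <= config$egg_days]])
  }, 0)

  occ <- lapply(pmfs, function(p) numeric(length(p)))
  occ[[1]][1] <- 1
  fem <- numeric(cap)
  mal <- numeric(cap)
  lx <- numeric(0)
  ex <- numeric(0)   # expected eggs per original individual at each age
  max_age <- 5000L
  for (x in seq_len(max_age)) {
    alive <- sum(unlist(occ)) + sum(fem) + sum(mal)
    if (alive < tail_eps) break
    lx <- c(lx, alive)
    ex <- c(ex, sum(fem * eggmean))
    nocc <- lapply(pmfs, function(p) numeric(length(p)))
    nfem <- numeric(cap)
    nmal <- numeric(cap)
    for (s in seq_len(k)) {
      o <- occ[[s]]
      live <- which(o > 0)
      if (!length(live)) next
      m <- o[live] * config$stage_survival[s]
      molt <- m * hazards[[s]][live]
      stay <- m - molt
      dd <- live[live + 1L <= length(o)]
      if (length(dd))
        nocc[[s]][dd + 1L] <- nocc[[s]][dd + 1L] + stay[live %in% dd]
      total_molt <- sum(molt)
      if (s < k) {
        nocc[[s + 1L]][1L] <- nocc[[s + 1L]][1L] + total_molt
      } else {
        nfem[1L] <- nfem[1L] + total_molt * config$p_female
        nmal[1L] <- nmal[1L] + total_molt * (1 - config$p_female)
      }
    }
    if (cap > 1L) {
      nfem[2:cap] <- nfem[2:cap] + fem[1:(cap - 1L)] * config$female_survival
      nmal[2:cap] <- nmal[2:cap] + mal[1:(cap - 1L)] * config$male_survival
    }
    occ <- nocc
    fem <- nfem
    mal <- nmal
  }
  R0 <- sum(ex)
  mx <- ifelse(lx > 0, ex / lx, 0)
  if (R0 > 0) {
    r <- intrinsic_rate(ex)
    lam <- exp(r)
    Tg <- if (r != 0) log(R0) / r else NA_real_
  } else {
    r <- lam <- Tg <- NA_real_
  }
  structure(list(ages = seq_along(lx) - 1L, lx = lx, mx = mx, lxmx = ex,
                 R0 = R0, r = r, lambda = lam, T = Tg),
            class = "theoretical_schedule")
}

#' @export
print.theoretical_schedule <- function(x, ...) {
  cat("Theoretical schedule over ages 0-", max(x$ages), "\n", sep = "")
  if (is.finite(x$r))
    cat(sprintf("  R0 = %.4f, r = %.5f /day, lambda = %.5f, T = %.3f days\n",
                x$R0, x$r, x$lambda, x$T))
  else
    cat(sprintf("  R0 = %.4f, rates undefined\n", x$R0))
  invisible(x)
}
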