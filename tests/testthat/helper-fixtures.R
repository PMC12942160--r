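# Shared fixtures and independent oracles for the test suite.

toy_scheme <- function() stage_scheme(c("N1", "F", "M"))

# Four-individual hand-checkable cohort:
#   A: N1 on days 0-1, female on days 2-3 laying 3 then 1 egg
#   B: N1 on days 0-1, female on day 2 laying 1 egg
#   C: N1 on day 0, male on days 1-2
#   D: N1 on day 0 only (dies as N1)
toy_cohort <- function() {
  as_cohort(data.frame(
    id    = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "C", "D"),
    age   = c(0, 1, 2, 3, 0, 1, 2, 0, 1, 2, 0),
    stage = c("N1", "N1", "F", "F", "N1", "N1", "F", "N1", "M", "M", "N1"),
    eggs  = c(0, 0, 3, 1, 0, 0, 1, 0, 0, 0, 0)),
    toy_scheme())
}

# Independent Euler-Lotka oracle: plain bisection on the residual.
bisect_r <- function(lxmx, lo = -1, hi = 5, iters = 200) {
  f <- function(r) sum(exp(-r * seq_along(lxmx)) * lxmx) - 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small random generator config for property-style tests; relies on the
# caller having seeded the RNG.
random_config <- function(n = 30L) {
  k <- sample(1:3, 1)
  stages <- c(paste0("S", seq_len(k)), "F", "M")
  simulation_config(
    n = n,
    scheme = stage_scheme(stages),
    dur_mean = stats::runif(k, 1.5, 4),
    dur_shape = sample(c(4, 10, 25), 1),
    dur_dist = sample(c("gamma", "geometric"), 1),
    stage_survival = stats::runif(k, 0.85, 1),
    p_female = stats::runif(1, 0.3, 0.7),
    female_survival = stats::runif(1, 0.75, 0.92),
    male_survival = stats::runif(1, 0.75, 0.92),
    apop_mean = stats::runif(1, 0, 3),
    apop_shape = 4,
    egg_peak = stats::runif(1, 5, 30),
    egg_peak_day = sample(2:5, 1),
    egg_days = sample(8:15, 1),
    max_adult_days = 200L)
}

# Monte-Carlo oracle for life expectancy: walkers started in cell
# (x0, j0) follow the empirical transition model day by day; returns the
# mean and standard error of their lifespans (current day included).
mc_life_expectancy <- function(model, x0, j0, walkers = 1e5) {
  G <- model$G
  X <- dim(G)[1L]; S <- dim(G)[2L]
  counts <- integer(S)
  counts[j0] <- walkers
  span_val <- integer(0)
  span_n <- integer(0)
  day <- 1L
  x <- x0 + 1L
  while (sum(counts) > 0) {
    newc <- integer(S)
    died <- 0L
    if (x > X) {
      died <- sum(counts)
    } else {
      for (j in which(counts > 0)) {
        pr <- G[x, j, ]
        draw <- as.vector(stats::rmultinom(1, counts[j],
                                           c(pr, max(0, 1 - sum(pr)))))
        newc <- newc + draw[seq_len(S)]
        died <- died + draw[S + 1L]
      }
    }
    if (died > 0) {
      span_val <- c(span_val, day)
      span_n <- c(span_n, died)
    }
    counts <- newc
    x <- x + 1L
    day <- day + 1L
  }
  v <- rep(span_val, span_n)
  list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
}
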