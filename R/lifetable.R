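#' Age-stage survival rates
#'
#' `sxj(x, j) = N(x, j) / n0`: the probability that a newborn cohort member
#' is alive and in stage `j` at age `x`.
#'
#' @param counts An [age_stage_counts()] object.
#' @param n0 Initial cohort size; defaults to the cohort's own.
#' @return A numeric matrix (ages x stages).
#' @export
survival_rates <- function(counts, n0 = counts$n0) {
  if (is.null(n0) || n0 <= 0) stop("n0 must be positive")
  counts$N / n0
}

#' Age-stage fecundity
#'
#' `fxj(x, j) = E(x, j) / N(x, j)`: mean daily eggs of an individual in
#' cell `(x, j)`; zero where the cell is empty. Nonzero only for the adult
#' female stage.
#'
#' @param counts An [age_stage_counts()] object.
#' @return A numeric matrix (ages x stages), eggs per female per day.
#' @export
fecundity_matrix <- function(counts) {
  f <- counts$E / counts$N
  f[counts$N == 0L] <- 0
  f
}

#' Age-specific schedules
#'
#' Collapses the age-stage matrices over stages: `lx = sum_j sxj` (survival),
#' `mx = sum_j sxj * fxj / lx` (mean daily eggs among survivors, 0 where
#' `lx = 0`), and the net maternity `lxmx = lx * mx`.
#'
#' @param sxj,fxj Conforming matrices from [survival_rates()] and
#'   [fecundity_matrix()].
#' @return A list with numeric vectors `lx`, `mx`, `lxmx`.
#' @export
age_schedules <- function(sxj, fxj) {
  stopifnot(identical(dim(sxj), dim(fxj)))
  lx <- rowSums(sxj)
  num <- rowSums(sxj * fxj)
  mx <- ifelse(lx > 0, num / lx, 0)
  list(lx = lx, mx = mx, lxmx = lx * mx)
}

#' Net reproductive rate
#'
#' `R0 = sum_x lxmx`: expected lifetime offspring per newborn cohort
#' member. Equals (total eggs)/n0 exactly for the source cohort.
#'
#' @param lxmx Net maternity vector.
#' @return A single number.
#' @export
net_reproductive_rate <- function(lxmx) sum(lxmx)

#' Intrinsic rate of increase
#'
#' Solves the Euler-Lotka equation `sum_x exp(-r (x + 1)) lxmx = 1` for
#' `r`, with age `x` counted from 0 and reproduction credited at the end of
#' day `x`. The left-hand side is strictly decreasing in `r`, so the root
#' is unique; it is bracketed on `[lower, upper]` and found with Brent's
#' method, then polished by Newton steps until the residual is below `tol`.
#'
#' @param lxmx Net maternity vector (ages 0, 1, ... in order).
#' @param tol Residual tolerance (default `1e-12`).
#' @param lower,upper Bracketing interval for `r`.
#' @return The intrinsic rate of increase, per day.
#' @export
intrinsic_rate <- function(lxmx, tol = 1e-12, lower = -1, upper = 5) {
  R0 <- sum(lxmx)
  if (R0 <= 0) stop("no growth: R0 <= 0, intrinsic rate undefined")
  x1 <- seq_along(lxmx)  # exponent x + 1 for age x = 0, 1, ...
  f  <- function(r) sum(exp(-r * x1) * lxmx) - 1
  fp <- function(r) -sum(x1 * exp(-r * x1) * lxmx)
  fl <- f(lower); fu <- f(upper)
  if (fl < 0 || fu > 0)
    stop("Euler-Lotka root not bracketed in [", lower, ", ", upper, "]")
  r <- stats::uniroot(f, lower = lower, upper = upper,
                      f.lower = fl, f.upper = fu, tol = 1e-14)$root
  for (i in 1:3) {            # Newton polish to the residual tolerance
    fr <- f(r)
    if (abs(fr) < tol) break
    step <- fr / fp(r)
    if (!is.finite(step)) break
    r <- r - step
  }
  r
}

#' Finite rate of increase
#'
#' @param r Intrinsic rate of increase (per day).
#' @return `lambda = exp(r)`, the daily multiplication factor.
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' `T = ln(R0) / r`: the time, in days, for the population to grow
#' `R0`-fold when increasing at rate `r`.
#'
#' @param R0 Net reproductive rate (> 0).
#' @param r Intrinsic rate of increase (non-zero).
#' @return Mean generation time in days.
#' @export
mean_generation_time <- function(R0, r) {
  if (any(R0 <= 0)) stop("mean generation time undefined for R0 <= 0")
  if (any(r == 0)) stop("mean generation time undefined for r = 0")
  log(R0) / r
}

#' Empirical age-stage transition model
#'
#' Estimates the daily transition probabilities between age-stage cells by
#' the observed cell-frequency ratios:
#' `g(x, j -> x+1, j') = #{individuals in (x, j) seen in (x+1, j')} / N(x, j)`.
#' The per-cell death probability is the remainder `1 - sum_j' g`. Cells
#' with no occupants carry zero transitions; no transitions leave the last
#' observed age.
#'
#' @param cohort A valid `cohort`.
#' @return An object of class `transition_model` with the transition array
#'   `G` (age x stage x next-stage), the count matrix `N`, the underlying
#'   [age_stage_counts()] and the scheme.
#' @export
transition_model <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  counts <- age_stage_counts(cohort)
  d <- cohort$data
  stages <- counts$stages
  S <- length(stages)
  X <- length(counts$ages)
  n <- nrow(d)
  G <- array(0, dim = c(X, S, S),
             dimnames = list(age = as.character(counts$ages),
                             from = stages, to = stages))
  if (n > 1L) {
    same <- d$id[-1L] == d$id[-n]
    from <- which(c(same, FALSE))
    if (length(from)) {
      xi <- d$age[from]                       # 0-based age of origin cell
      ji <- match(d$stage[from], stages)
      jn <- match(d$stage[from + 1L], stages)
      key <- (xi * S + (ji - 1L)) * S + jn    # jn fastest, then ji, then x
      cnt <- tabulate(key, nbins = X * S * S)
      Tarr <- aperm(array(cnt, dim = c(S, S, X)), c(3L, 2L, 1L))
      G <- Tarr / c(counts$N)                 # divide by N(x, j), recycled
      G[!is.finite(G)] <- 0
      dimnames(G) <- list(age = as.character(counts$ages),
                          from = stages, to = stages)
    }
  }
  structure(list(G = G, N = counts$N, counts = counts,
                 scheme = cohort$scheme),
            class = "transition_model")
}

#' Age-stage life expectancy
#'
#' Expected number of further days, including the current one, that an
#' individual now in cell `(x, j)` will live, under the empirical
#' transition model. Computed by the backward recursion
#' `e(x, j) = 1 + sum_j' g(x, j -> j') e(x+1, j')`, so `e >= 1` in any
#' occupied cell. Unoccupied cells are `NA`.
#'
#' @param model A [transition_model()].
#' @return A numeric matrix (ages x stages), in days.
#' @export
life_expectancy <- function(model) {
  G <- model$G
  X <- dim(G)[1L]; S <- dim(G)[2L]
  e <- matrix(0, X, S)
  for (x in X:1) {
    enext <- if (x < X) e[x + 1L, ] else numeric(S)
    e[x, ] <- 1 + as.vector(G[x, , , drop = TRUE] %*% enext)
  }
  e[model$N == 0L] <- NA_real_
  dimnames(e) <- dimnames(model$N)
  e
}

#' Age-stage reproductive value
#'
#' Expected contribution of an individual currently in cell `(x, j)` to
#' future population growth, with future reproduction discounted at the
#' intrinsic rate: `v(x, j) = sum_{i >= x} exp(-r (i - x)) * (occupancy-
#' weighted fecundity)`, where occupancy starts at 1 in `(x, j)` and
#' evolves under the transition model. Equivalent backward recursion:
#' `v(x, j) = f(x, j) + exp(-r) sum_j' g(x, j -> j') v(x+1, j')`.
#' Satisfies the identity `v(0, first stage) = exp(r)` whenever the rates
#' come from the same cohort that `r` was solved for. Unoccupied cells are
#' `NA`.
#'
#' @param model A [transition_model()].
#' @param fxj Age-stage fecundity matrix for the same cohort.
#' @param r Intrinsic rate of increase solved for the same cohort.
#' @return A numeric matrix (ages x stages).
#' @export
reproductive_value <- function(model, fxj, r) {
  G <- model$G
  X <- dim(G)[1L]; S <- dim(G)[2L]
  stopifnot(identical(dim(fxj), c(X, S)))
  er <- exp(-r)
  v <- matrix(0, X, S)
  for (x in X:1) {
    vnext <- if (x < X) v[x + 1L, ] else numeric(S)
    v[x, ] <- fxj[x, ] + er * as.vector(G[x, , , drop = TRUE] %*% vnext)
  }
  v[model$N == 0L] <- NA_real_
  dimnames(v) <- dimnames(model$N)
  v
}

# One day of the deterministic age-stage projection: survive/advance every
# cell by the model, recruit newborns (count x fecundity) to age 0 of the
# first stage. Shared by stable_distribution() and project_population().
project_step <- function(state, G, fxj, recruit_stage = 1L) {
  X <- nrow(state); S <- ncol(state)
  out <- matrix(0, X, S)
  for (x in seq_len(X - 1L)) {
    sx <- state[x, ]
    if (any(sx != 0))
      out[x + 1L, ] <- sx %*% G[x, , , drop = TRUE]
  }
  out[1L, recruit_stage] <- out[1L, recruit_stage] + sum(state * fxj)
  out
}

#' Stable age-stage distribution
#'
#' Power-iterates the daily projection map (survival/advance by the
#' transition model, newborn recruitment to age 0 of the first stage) from
#' a unit mass at the first cell until the cell-proportion vector changes
#' by less than `tol` in L1 norm. The converged day-to-day ratio of totals
#' is the finite rate of increase implied by the projection machinery and
#' agrees with `exp(r)` from [intrinsic_rate()].
#'
#' @param model A [transition_model()].
#' @param fxj Age-stage fecundity matrix.
#' @param tol L1 convergence tolerance on proportions (default `1e-10`).
#' @param max_iter Iteration cap (default `1e5`).
#' @return A list with `sasd` (matrix of proportions summing to 1) and
#'   `growth_ratio`.
#' @export
stable_distribution <- function(model, fxj, tol = 1e-10, max_iter = 1e5L) {
  G <- model$G
  X <- dim(G)[1L]; S <- dim(G)[2L]
  p <- matrix(0, X, S)
  p[1L, 1L] <- 1
  growth <- NA_real_
  for (it in seq_len(max_iter)) {
    nxt <- project_step(p, G, fxj)
    growth <- sum(nxt)
    if (growth <= 0)
      stop("projection vanished; stable distribution undefined")
    nxt <- nxt / growth
    if (sum(abs(nxt - p)) < tol) {
      dimnames(nxt) <- dimnames(model$N)
      return(list(sasd = nxt, growth_ratio = growth, iterations = it))
    }
    p <- nxt
  }
  stop("stable distribution did not converge in ", max_iter, " iterations")
}

#' Full age-stage, two-sex life table
#'
#' Orchestrates the whole analysis for one cohort: age-stage survival and
#' fecundity, age-specific schedules, the empirical transition model, life
#' expectancy, reproductive value, the stable age-stage distribution, and
#' the scalar parameters `R0`, `r`, `lambda = exp(r)` and `T = ln(R0)/r`.
#' When the cohort produced no offspring (`R0 = 0`), the rate parameters
#' and the rate-dependent schedules are `NA` rather than errors, so that
#' degenerate bootstrap resamples are handled gracefully.
#'
#' @param cohort A valid `cohort`.
#' @return An object of class `life_table` with matrices `sxj`, `fxj`,
#'   `exj`, `vxj`, `sasd`; vectors `lx`, `mx`, `lxmx`; the scalar `params`
#'   (list `R0`, `r`, `lambda`, `T`); `growth_ratio`; and the underlying
#'   `model` and `counts`.
#' @examples
#' cfg <- treatment_preset("MH86_Ars-", n = 30)
#' lt <- life_table(simulate_cohort(cfg, seed = 1))
#' lt$params
#' @export
life_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  counts <- age_stage_counts(cohort)
  sxj <- survival_rates(counts)
  fxj <- fecundity_matrix(counts)
  sched <- age_schedules(sxj, fxj)
  R0 <- net_reproductive_rate(sched$lxmx)
  model <- transition_model(cohort)
  exj <- life_expectancy(model)
  if (R0 > 0) {
    r <- intrinsic_rate(sched$lxmx)
    lam <- finite_rate(r)
    Tg <- if (r != 0) log(R0) / r else NA_real_
    vxj <- reproductive_value(model, fxj, r)
    sd <- stable_distribution(model, fxj)
    sasd <- sd$sasd
    growth <- sd$growth_ratio
  } else {
    r <- lam <- Tg <- growth <- NA_real_
    vxj <- sasd <- NULL
  }
  structure(list(
    sxj = sxj, fxj = fxj,
    lx = sched$lx, mx = sched$mx, lxmx = sched$lxmx,
    exj = exj, vxj = vxj, sasd = sasd,
    growth_ratio = growth,
    params = list(R0 = R0, r = r, lambda = lam, T = Tg),
    model = model, counts = counts,
    scheme = cohort$scheme, n0 = cohort$n0
  ), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("Age-stage, two-sex life table (n0 =", x$n0, ", ages 0-",
      length(x$lx) - 1L, ")\n")
  p <- x$params
  cat(sprintf("  R0 = %.4f offspring/individual\n", p$R0))
  if (is.finite(p$r)) {
    cat(sprintf("  r  = %.5f /day   lambda = %.5f /day   T = %.3f days\n",
                p$r, p$lambda, p$T))
  } else {
    cat("  r, lambda, T undefined (no reproduction)\n")
  }
  invisible(x)
}

#' Export a life table to CSV schedules and a JSON parameter file
#'
#' Writes `sxj.csv`, `lx_mx.csv`, `exj.csv`, `vxj.csv`, `sasd.csv` (age
#' rows, stage columns) and `params.json` (keys `R0`, `r`, `lambda`, `T`)
#' into `dir`.
#'
#' @param lt A [life_table()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lifetable <- function(lt, dir) {
  stopifnot(inherits(lt, "life_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, file) {
    if (is.null(m)) return(invisible(NULL))
    df <- data.frame(age = as.integer(rownames(m)), m, check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wm(lt$sxj, "sxj.csv")
  wm(lt$exj, "exj.csv")
  wm(lt$vxj, "vxj.csv")
  wm(lt$sasd, "sasd.csv")
  utils::write.csv(data.frame(age = seq_along(lt$lx) - 1L, lx = lt$lx,
                              mx = lt$mx, lxmx = lt$lxmx),
                   file.path(dir, "lx_mx.csv"), row.names = FALSE)
  jsonlite::write_json(lt$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
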