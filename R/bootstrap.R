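# n0 x (omega + 1) matrix: eggs laid by each individual at each age. The
# scalar demographic parameters depend on the resample only through the
# column sums of this matrix (lxmx = eggs at age x / n0), which makes
# bootstrap replicates cheap.
lifetime_egg_matrix <- function(cohort) {
  d <- cohort$data
  ids <- unique(d$id)
  omega <- max(d$age)
  M <- matrix(0, length(ids), omega + 1L,
              dimnames = list(ids, as.character(0:omega)))
  M[cbind(match(d$id, ids), d$age + 1L)] <- d$eggs
  M
}

# (r, lambda, R0, T) from a net-maternity vector; NA rates for degenerate
# (R0 = 0) schedules.
scalar_params_from_lxmx <- function(lxmx) {
  R0 <- sum(lxmx)
  if (R0 > 0) {
    r <- intrinsic_rate(lxmx)
    c(r = r, lambda = exp(r), R0 = R0,
      T = if (r != 0) log(R0) / r else NA_real_)
  } else {
    c(r = NA_real_, lambda = NA_real_, R0 = R0, T = NA_real_)
  }
}

boot_replicates <- function(EG, n0, B) {
  reps <- matrix(NA_real_, B, 4L,
                 dimnames = list(NULL, c("r", "lambda", "R0", "T")))
  for (b in seq_len(B)) {
    idx <- sample.int(n0, n0, replace = TRUE)
    reps[b, ] <- scalar_params_from_lxmx(
      colSums(EG[idx, , drop = FALSE]) / n0)
  }
  reps
}

#' Bootstrap standard errors for demographic parameters
#'
#' Resamples whole individuals (entire life histories) with replacement,
#' `n0` at a time, and recomputes the requested scalar parameters for each
#' replicate. Resampling the individual preserves the within-individual
#' correlation of development and fecundity. The standard error is the
#' sample standard deviation over non-degenerate replicates and the
#' confidence interval the 2.5/97.5 percentiles. Replicates in which no
#' eggs were drawn (`R0 = 0`) leave `r`, `lambda` and `T` undefined; they
#' are dropped from the SE/CI computation and counted in `n_degenerate`.
#' Identical `(cohort, B, seed)` give identical output.
#'
#' @param cohort A valid `cohort`.
#' @param params Which parameters to report, a subset of
#'   `c("r", "lambda", "R0", "T")`.
#' @param B Number of bootstrap replicates (>= 2). The study convention is
#'   100,000; smaller values are appropriate for interactive use.
#' @param seed Integer seed for the replicate stream.
#' @return A data frame of class `bootstrap_result`, one row per parameter:
#'   `param`, `point` (full-cohort estimate), `se`, `ci_low`, `ci_high`,
#'   `B`, `seed`, `n_degenerate`.
#' @export
bootstrap_lifetable <- function(cohort, params = c("r", "lambda", "R0", "T"),
                                B = 100000L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), B >= 2)
  params <- match.arg(params, c("r", "lambda", "R0", "T"),
                      several.ok = TRUE)
  EG <- lifetime_egg_matrix(cohort)
  n0 <- nrow(EG)
  point <- scalar_params_from_lxmx(colSums(EG) / n0)
  set.seed(seed)
  reps <- boot_replicates(EG, n0, B)
  out <- do.call(rbind, lapply(params, function(p) {
    x <- reps[, p]
    ok <- x[!is.na(x)]
    data.frame(param = p,
               point = unname(point[p]),
               se = if (length(ok) > 1) stats::sd(ok) else NA_real_,
               ci_low = if (length(ok)) unname(stats::quantile(ok, 0.025))
                        else NA_real_,
               ci_high = if (length(ok)) unname(stats::quantile(ok, 0.975))
                         else NA_real_,
               B = B, seed = seed, n_degenerate = sum(is.na(x)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

#' Paired bootstrap comparison of two cohorts
#'
#' Draws `B` independent bootstrap replicate pairs (one resample of each
#' cohort per replicate), forms the differences
#' `d* = theta*_A - theta*_B`, and reports the two-sided percentile
#' p-value `p = 2 min(#{d* <= 0}, #{d* > 0}) / B'`, capped at 1, where
#' `B'` is the number of pairs in which the parameter was defined on both
#' sides (degenerate replicates are excluded and counted).
#'
#' @param cohort_a,cohort_b Valid cohorts, e.g. two treatments.
#' @param param The parameter to compare: one of `"r"`, `"lambda"`,
#'   `"R0"`, `"T"`.
#' @param B Number of replicate pairs (>= 2).
#' @param seed Integer seed; both resampling streams derive from it.
#' @return An object of class `paired_bootstrap`: `param`, `diff` (A - B
#'   point difference), `p_value`, `B`, `seed`, `n_degenerate`, `n_used`.
#' @export
paired_bootstrap_test <- function(cohort_a, cohort_b, param = "r",
                                  B = 10000L, seed = 1L) {
  stopifnot(inherits(cohort_a, "cohort"), inherits(cohort_b, "cohort"),
            B >= 2)
  param <- match.arg(param, c("r", "lambda", "R0", "T"))
  EA <- lifetime_egg_matrix(cohort_a)
  EB <- lifetime_egg_matrix(cohort_b)
  na <- nrow(EA); nb <- nrow(EB)
  pa <- scalar_params_from_lxmx(colSums(EA) / na)[param]
  pb <- scalar_params_from_lxmx(colSums(EB) / nb)[param]
  set.seed(seed)
  d <- numeric(B)
  for (b in seq_len(B)) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- sample.int(nb, nb, replace = TRUE)
    ta <- scalar_params_from_lxmx(colSums(EA[ia, , drop = FALSE]) / na)[param]
    tb <- scalar_params_from_lxmx(colSums(EB[ib, , drop = FALSE]) / nb)[param]
    d[b] <- ta - tb
  }
  ok <- d[!is.na(d)]
  p <- if (length(ok)) min(1, 2 * min(sum(ok <= 0), sum(ok > 0)) / length(ok))
       else NA_real_
  structure(list(param = param, diff = unname(pa - pb), p_value = p,
                 B = B, seed = seed, n_degenerate = B - length(ok),
                 n_used = length(ok)),
            class = "paired_bootstrap")
}

#' @export
print.paired_bootstrap <- function(x, ...) {
  cat("Paired bootstrap comparison of", x$param, "\n")
  cat(sprintf("  A - B = %.5f, p = %.4f (B = %d pairs, %d degenerate)\n",
              x$diff, x$p_value, x$B, x$n_degenerate))
  invisible(x)
}
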