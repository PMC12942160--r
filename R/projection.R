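#' Deterministic age-stage population projection
#'
#' Projects an initial age-stage composition forward day by day with the
#' cohort-derived rates: each cell survives and advances according to the
#' transition model (real-valued expected counts, not stochastic
#' simulation), and newborns -- the summed product of female-cell counts
#' and their daily fecundity -- recruit to age 0 of the first stage.
#' Beyond the cohort's last observed age the rates are zero, i.e. all
#' remaining individuals die. The map is linear in the initial
#' composition.
#'
#' @param model A [transition_model()], or a [life_table()] (in which case
#'   `fxj` is taken from it).
#' @param fxj Age-stage fecundity matrix conforming to the model.
#' @param initial Initial composition: either a named numeric vector of
#'   stage counts placed at age 0, or a full ages x stages matrix.
#'   Defaults to 10 individuals at age 0 of the first stage. Referring to
#'   stages or cells outside the model is an error.
#' @param days Projection horizon in days (>= 0); default 60.
#' @return An object of class `population_projection` with `horizon`,
#'   `per_day` (data frame: day, per-stage counts summed over ages, and
#'   `total`) and `totals`.
#' @export
project_population <- function(model, fxj = NULL, initial = NULL,
                               days = 60L) {
  if (inherits(model, "life_table")) {
    if (is.null(fxj)) fxj <- model$fxj
    model <- model$model
  }
  stopifnot(inherits(model, "transition_model"), days >= 0)
  if (is.null(fxj)) stop("fxj is required when passing a transition model")
  G <- model$G
  X <- dim(G)[1L]; S <- dim(G)[2L]
  stages <- model$scheme$stages
  stopifnot(identical(dim(fxj), c(X, S)))
  state <- matrix(0, X, S, dimnames = dimnames(model$N))
  if (is.null(initial)) initial <- stats::setNames(10, stages[1L])
  if (is.matrix(initial)) {
    if (!identical(dim(initial), dim(state)))
      stop("initial composition refers to cells outside the model")
    if (any(initial < 0)) stop("initial counts must be non-negative")
    state[] <- initial
  } else {
    if (is.null(names(initial)) || !all(names(initial) %in% stages))
      stop("initial composition refers to stages outside the model")
    if (any(initial < 0)) stop("initial counts must be non-negative")
    state[1L, match(names(initial), stages)] <- initial
  }
  per_day <- matrix(0, days + 1L, S, dimnames = list(NULL, stages))
  per_day[1L, ] <- colSums(state)
  if (days > 0) {
    for (t in seq_len(days)) {
      state <- project_step(state, G, fxj)
      per_day[t + 1L, ] <- colSums(state)
    }
  }
  totals <- rowSums(per_day)
  structure(list(
    horizon = as.integer(days),
    per_day = data.frame(day = 0:days, per_day, total = totals,
                         check.names = FALSE),
    totals = unname(totals)
  ), class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat("Population projection over", x$horizon, "days\n")
  n <- length(x$totals)
  cat(sprintf("  total: day 0 = %.1f, day %d = %.4g\n",
              x$totals[1], x$horizon, x$totals[n]))
  if (n >= 2 && x$totals[n - 1] > 0)
    cat(sprintf("  final daily growth ratio = %.5f\n",
                x$totals[n] / x$totals[n - 1]))
  invisible(x)
}
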