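#' Build a cohort from daily life-history records
#'
#' A cohort is the unit of all estimation and resampling: one row per
#' individual-day with columns `id`, `age` (integer days since cohort start,
#' 0-based), `stage` (a code from the scheme) and `eggs` (eggs laid that
#' day). Death is encoded by truncation: an individual's last row is its
#' last day alive. Rows are grouped by individual and sorted by age.
#'
#' @param data A data frame with columns `id`, `age`, `stage`, `eggs`.
#' @param scheme A [stage_scheme()].
#' @param validate If `TRUE` (default), stop on any invariant violation;
#'   set to `FALSE` to build a deliberately invalid cohort for inspection
#'   with [validate_cohort()].
#' @return An object of class `cohort` with elements `data`, `scheme`, `n0`.
#' @seealso [read_cohort()], [validate_cohort()], [age_stage_counts()]
#' @export
as_cohort <- function(data, scheme, validate = TRUE) {
  need <- c("id", "age", "stage", "eggs")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("empty cohort")
  d <- data.frame(id    = as.character(data$id),
                  age   = as.integer(data$age),
                  stage = as.character(data$stage),
                  eggs  = as.integer(data$eggs),
                  stringsAsFactors = FALSE)
  d <- d[order(match(d$id, unique(d$id)), d$age), , drop = FALSE]
  rownames(d) <- NULL
  obj <- structure(list(data = d, scheme = scheme,
                        n0 = length(unique(d$id))),
                   class = "cohort")
  if (validate) {
    v <- validate_cohort(obj)
    if (nrow(v) > 0L)
      stop("invalid cohort (", nrow(v), " violation(s)); first: id=",
           v$id[1], " age=", v$age[1], " [", v$rule[1], "] ", v$detail[1])
  }
  obj
}

#' Read a cohort from a life-history CSV file
#'
#' The file must have the header `id,age,stage,eggs`, one row per
#' individual-day. The cohort is validated on read; any invariant
#' violation is an error.
#'
#' @param path Path to the CSV file.
#' @param scheme A [stage_scheme()]; defaults to the seven-stage scheme.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, scheme = default_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(d, scheme, validate = TRUE)
}

#' Write a cohort to a life-history CSV file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), scheme)`
#' reproduces `x` exactly.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a cohort against the data-model invariants
#'
#' Violations are returned as data, not raised: each row names the
#' individual, the age at which the rule failed, the rule, and a detail
#' message. An empty result means the cohort is valid. Rules checked:
#' ages consecutive from 0; stage codes known to the scheme; stage
#' occupancy non-decreasing, advancing at most one stage per day (with the
#' branch stage allowed to enter either adult stage); eggs non-negative
#' and positive only on adult-female days.
#'
#' @param cohort A `cohort` (possibly built with `validate = FALSE`).
#' @return A data frame with columns `id`, `age`, `rule`, `detail`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  sch <- cohort$scheme
  out <- list()
  add <- function(id, age, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(id = id, age = age, rule = rule,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }

  unknown <- !(d$stage %in% sch$stages)
  if (any(unknown)) {
    u <- d[unknown, ]
    for (i in seq_len(nrow(u)))
      add(u$id[i], u$age[i], "unknown_stage",
          paste0("stage code '", u$stage[i], "' not in scheme"))
  }

  for (ind in split(d, factor(d$id, levels = unique(d$id)))) {
    id <- ind$id[1]
    if (anyDuplicated(ind$age)) {
      dup <- ind$age[duplicated(ind$age)][1]
      add(id, dup, "duplicate_age", "more than one row for this age")
    }
    if (!identical(ind$age, seq(0L, length.out = nrow(ind)))) {
      add(id, ind$age[1], "age_sequence",
          "ages must be consecutive integers starting at 0")
    }
    if (any(ind$eggs < 0, na.rm = TRUE))
      add(id, ind$age[which(ind$eggs < 0)[1]], "negative_eggs",
          "egg counts must be >= 0")
    bad_eggs <- which(ind$eggs > 0 & ind$stage != sch$female)
    if (length(bad_eggs))
      add(id, ind$age[bad_eggs[1]], "eggs_outside_female",
          paste0("eggs laid in stage '", ind$stage[bad_eggs[1]], "'"))
    j <- match(ind$stage, sch$stages)
    if (!anyNA(j) && nrow(ind) > 1L) {
      for (i in seq_len(nrow(ind) - 1L)) {
        if (!(j[i + 1L] %in% allowed_next_stages(sch, j[i]))) {
          rule <- if (j[i + 1L] < j[i]) "stage_regression" else "stage_skip"
          add(id, ind$age[i + 1L], rule,
              paste0("transition ", ind$stage[i], " -> ", ind$stage[i + 1L]))
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id = character(), age = integer(), rule = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Tabulate age-stage counts and egg totals
#'
#' Counts `N(x, j)`: the number of individuals whose day-`x` record is in
#' stage `j`; and `E(x, j)`: the total eggs those individuals laid on day
#' `x`. Ages run from 0 to the last observed day of the longest-lived
#' individual.
#'
#' @param cohort A valid `cohort`.
#' @return An object of class `age_stage_counts` with integer matrices `N`
#'   and `E` (ages x stages), plus `n0`, `ages`, `stages`.
#' @export
age_stage_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  stages <- cohort$scheme$stages
  omega <- max(d$age)
  fa <- factor(d$age, levels = 0:omega)
  fs <- factor(d$stage, levels = stages)
  N <- matrix(unclass(table(fa, fs)), omega + 1L, length(stages))
  E <- tapply(d$eggs, list(fa, fs), sum)
  E <- matrix(ifelse(is.na(E), 0L, E), omega + 1L, length(stages))
  storage.mode(N) <- "integer"
  storage.mode(E) <- "integer"
  dimnames(N) <- dimnames(E) <- list(age = as.character(0:omega),
                                     stage = stages)
  structure(list(N = N, E = E, n0 = cohort$n0, ages = 0:omega,
                 stages = stages, scheme = cohort$scheme),
            class = "age_stage_counts")
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  cat("Cohort of", x$n0, "individuals,",
      nrow(d), "individual-days, ages 0-", max(d$age), "\n", sep = " ")
  cat("  scheme:", paste(x$scheme$stages, collapse = " "), "\n")
  cat("  total eggs:", sum(d$eggs), "\n")
  invisible(x)
}
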