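#' Define a developmental stage scheme
#'
#' A stage scheme fixes the ordered list of stage codes used in a cohort's
#' daily records: the immature (nymphal) stages in developmental order,
#' followed by the two terminal adult stages. The last immature stage is the
#' branch stage: its successors are the two adult stages, one of which each
#' individual enters at the final molt. Adults never leave their stage.
#'
#' @param stages Character vector of unique stage codes in developmental
#'   order; the final two entries must be the adult female and male codes.
#' @param female,male Codes of the adult female and male stages.
#' @return An object of class `stage_scheme`.
#' @examples
#' stage_scheme(c("N1", "N2", "N3", "N4", "N5", "F", "M"))
#' stage_scheme(c("N1", "F", "M"))  # minimal scheme for toy examples
#' @export
stage_scheme <- function(stages, female = "F", male = "M") {
  stages <- as.character(stages)
  if (anyDuplicated(stages)) stop("stage codes must be unique")
  k <- length(stages) - 2L
  if (k < 1L)
    stop("a scheme needs at least one immature stage plus the two adult stages")
  if (!setequal(stages[(k + 1L):(k + 2L)], c(female, male)))
    stop("the final two stages must be the adult female ('", female,
         "') and male ('", male, "') codes")
  structure(list(
    stages       = stages,
    female       = female,
    male         = male,
    branch       = stages[k],
    n_immature   = k,
    female_index = match(female, stages),
    male_index   = match(male, stages)
  ), class = "stage_scheme")
}

#' Default seven-stage scheme
#'
#' Five nymphal instars (`N1`--`N5`) followed by adult females (`F`) and
#' males (`M`), the design used for brown planthopper cohorts.
#'
#' @return A `stage_scheme`.
#' @export
default_scheme <- function() {
  stage_scheme(c("N1", "N2", "N3", "N4", "N5", "F", "M"))
}

# Stage indices an individual in stage j may occupy on the next day
# (staying included); adults are absorbing.
allowed_next_stages <- function(scheme, j) {
  k <- scheme$n_immature
  if (j < k) c(j, j + 1L)
  else if (j == k) c(j, scheme$female_index, scheme$male_index)
  else j
}

#' @export
print.stage_scheme <- function(x, ...) {
  cat("Stage scheme:", paste(x$stages, collapse = " -> "), "\n")
  cat("  immature:", x$n_immature, "stage(s); branch stage:", x$branch,
      "; adults:", x$female, "(female),", x$male, "(male)\n")
  invisible(x)
}

#' Read a stage scheme from a plain-text config file
#'
#' The file holds `key = value` lines; recognised keys are `stages`
#' (comma-separated codes in developmental order), `female` and `male`.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A `stage_scheme`.
#' @export
read_stage_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed scheme line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  get <- function(key, default = NULL) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  stages <- get("stages")
  if (is.null(stages)) stop("scheme file must define 'stages'")
  stage_scheme(trimws(strsplit(stages, ",")[[1]]),
               female = get("female", "F"), male = get("male", "M"))
}
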