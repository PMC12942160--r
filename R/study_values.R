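#' Printed study values used for preset calibration
#'
#' The published cohort summaries for the four brown planthopper
#' treatments -- two rice hosts (non-transgenic MH86 and transgenic
#' cry30Fa1 line KF30-14), each with and without the Arsenophonus symbiont
#' -- as printed: per-instar developmental durations and adult
#' longevities, stage mortality fractions with their printed immature and
#' adult aggregates, reproductive parameters, and the population
#' parameters (r, T, R0). These are the calibration targets for
#' [treatment_preset()], not raw data; the underlying per-individual
#' records were not deposited.
#'
#' @return A list of matrices/data frames keyed by treatment
#'   (`"MH86_Ars-"`, `"MH86_Ars+"`, `"KF30-14_Ars-"`, `"KF30-14_Ars+"`).
#' @export
study_printed_values <- function() {
  tr <- c("MH86_Ars-", "MH86_Ars+", "KF30-14_Ars-", "KF30-14_Ars+")
  instars <- c("N1", "N2", "N3", "N4", "N5")
  m <- function(x, rn) matrix(x, nrow = length(rn), ncol = 4L,
                              dimnames = list(rn, tr))
  list(
    treatments = tr,
    # mean instar durations (days)
    stage_duration = m(c(2.96, 2.46, 2.54, 2.87, 4.25,
                         3.41, 2.45, 2.41, 2.71, 4.16,
                         2.98, 2.29, 2.49, 2.61, 4.34,
                         3.13, 2.50, 2.74, 2.88, 4.89), instars),
    # adult longevity means (days) and adult counts by sex
    longevity = data.frame(
      treatment = tr,
      female_longevity = c(17.89, 18.07, 23.78, 22.30),
      male_longevity   = c(22.10, 25.36, 21.61, 23.35),
      n_female = c(35L, 41L, 37L, 27L),
      n_male   = c(21L, 28L, 28L, 17L),
      row.names = tr, stringsAsFactors = FALSE),
    # mortality fractions of the initial cohort, per instar, with the
    # printed aggregates (immature; female/male/adult)
    mortality = m(c(0.10, 0.07, 0.06, 0.08, 0.07,
                    0.05, 0.05, 0.00, 0.01, 0.07,
                    0.02, 0.06, 0.05, 0.05, 0.05,
                    0.08, 0.17, 0.10, 0.05, 0.07), instars),
    mortality_printed_aggregates = data.frame(
      treatment = tr,
      immature = c(0.37, 0.18, 0.23, 0.47),
      female   = c(0.39, 0.49, 0.44, 0.33),
      male     = c(0.24, 0.33, 0.33, 0.20),
      adult    = c(0.63, 0.82, 0.77, 0.53),
      row.names = tr, stringsAsFactors = FALSE),
    # reproductive parameters over reproducing females
    reproduction = data.frame(
      treatment = tr,
      APOP = c(2.97, 2.67, 3.51, 4.33),
      TPOP = c(18.36, 18.03, 18.41, 20.41),
      Od   = c(13.33, 14.18, 17.16, 14.22),
      fecundity = c(349.12, 407.72, 373.62, 255.93),
      n = c(33L, 39L, 37L, 27L),
      row.names = tr, stringsAsFactors = FALSE),
    # population parameters (point +/- bootstrap SE as printed)
    population = data.frame(
      treatment = tr,
      r    = c(0.204, 0.218, 0.202, 0.167),
      r_se = c(0.009, 0.008, 0.007, 0.010),
      T    = c(23.805, 24.041, 25.272, 26.340),
      T_se = c(0.432, 0.311, 0.410, 0.720),
      R0    = c(129.449, 189.298, 164.571, 83.253),
      R0_se = c(24.021, 30.262, 26.67, 18.237),
      row.names = tr, stringsAsFactors = FALSE)
  )
}
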