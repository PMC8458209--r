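#' @name deformity-classification
#' @title Malalignment test, varus severity and correction potential
#' @description
#' The malalignment test locates the bony origin of a coronal deformity by
#' comparing the knee-base angles to their normal range of 85-90 degrees:
#' a tibial deformity has mMPTA < 85 with a normal (or low) mLDFA, a
#' femoral deformity has mLDFA > 90 with a normal (or high) mMPTA, both
#' pathologic angles give a combined deformity, and two normal angles give
#' no bony deformity. Normality is treated as the closed interval
#' \eqn{[85, 90]}; deformity requires the strict inequalities.
#'
#' Varus severity bins the varus-positive mFTA into mild (3 to <6),
#' moderate (6 to <9) and severe (>= 9) degrees; half-open intervals keep
#' the printed integer cut points without double counting.
NULL

LOCATION_LEVELS <- c("TIBIAL", "FEMORAL", "TIBIAL_AND_FEMORAL",
                     "NO_BONY_DEFORMITY")
SEVERITY_LEVELS <- c("MILD", "MODERATE", "SEVERE")
PLAN_LEVELS <- c("TIBIAL", "FEMORAL", "DOUBLE_LEVEL", "UNCORRECTABLE")
POTENTIAL_LEVELS <- c("TIBIAL", "FEMORAL", "TIBIAL_AND_FEMORAL", "NONE")

# vectorised core of the malalignment test
classify_location_vec <- function(mMPTA, mLDFA) {
  tib <- mMPTA < 85
  fem <- mLDFA > 90
  out <- rep("NO_BONY_DEFORMITY", length(mMPTA))
  out[tib & !fem] <- "TIBIAL"
  out[fem & !tib] <- "FEMORAL"
  out[tib & fem] <- "TIBIAL_AND_FEMORAL"
  factor(out, levels = LOCATION_LEVELS)
}

#' Locate the bony deformity (malalignment test)
#'
#' @param alignment a [knee_alignment()] (or list with `mMPTA`, `mLDFA`).
#' @return One of `"TIBIAL"`, `"FEMORAL"`, `"TIBIAL_AND_FEMORAL"`,
#'   `"NO_BONY_DEFORMITY"` (character scalar).
#' @examples
#' classify_location(knee_alignment(5, 84, 89))  # "TIBIAL"
#' classify_location(knee_alignment(5, 86, 89))  # "NO_BONY_DEFORMITY"
#' @export
classify_location <- function(alignment) {
  a <- as_alignment(alignment)
  as.character(classify_location_vec(a$mMPTA, a$mLDFA))
}

classify_severity_vec <- function(mFTA_varus) {
  if (any(mFTA_varus < 3))
    stop("varus severity is defined only for mFTA >= 3 degrees varus",
         call. = FALSE)
  cut(mFTA_varus, breaks = c(3, 6, 9, Inf), labels = SEVERITY_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

#' Grade varus severity
#'
#' @param mFTA_varus varus-positive mFTA in degrees; must be >= 3 (the
#'   inclusion threshold below which severity is undefined).
#' @return `"MILD"` (3 to <6), `"MODERATE"` (6 to <9) or `"SEVERE"` (>= 9).
#' @examples
#' classify_severity(3)    # MILD
#' classify_severity(5.5)  # MILD
#' classify_severity(9)    # SEVERE
#' @export
classify_severity <- function(mFTA_varus) {
  stopifnot(length(mFTA_varus) == 1L, is.finite(mFTA_varus))
  as.character(classify_severity_vec(mFTA_varus))
}

#' Bony correction potential at the tibia and femur
#'
#' The tibial potential is the valgization (degrees) available by raising
#' mMPTA to the scenario's upper limit; the femoral potential is the
#' valgization available by lowering mLDFA to the 85-degree floor. Both
#' are floored at zero. The categorical grouping follows from which
#' potentials are positive.
#'
#' @param alignment a [knee_alignment()].
#' @param limits a [scenario_limits()] (the anatomic scenario by default).
#' @return A list with `tibial`, `femoral` (degrees >= 0) and `category`
#'   (one of `"TIBIAL"`, `"FEMORAL"`, `"TIBIAL_AND_FEMORAL"`, `"NONE"`).
#' @examples
#' correction_potential(knee_alignment(5, 86, 89))
#' @export
correction_potential <- function(alignment, limits = scenario_limits()) {
  a <- as_alignment(alignment)
  stopifnot(inherits(limits, "scenario_limits"))
  tib <- max(0, limits$mMPTA_upper - a$mMPTA)
  fem <- max(0, a$mLDFA - limits$mLDFA_lower)
  category <- if (tib > 0 && fem > 0) "TIBIAL_AND_FEMORAL"
              else if (tib > 0) "TIBIAL"
              else if (fem > 0) "FEMORAL"
              else "NONE"
  list(tibial = tib, femoral = fem, category = category)
}

#' Classify a whole cohort
#'
#' Appends `location`, `severity` and the two anatomic-bound correction
#' potentials to a cohort table.
#'
#' @param cohort data frame with columns `mFTA`, `mMPTA`, `mLDFA` (and
#'   typically `id`, `JLCA`, `WBL_ratio`), e.g. from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param limits a [scenario_limits()] used for the potential columns.
#' @return The cohort with columns `location`, `severity`,
#'   `potential_tibial`, `potential_femoral` appended.
#' @export
classify_cohort <- function(cohort, limits = scenario_limits()) {
  stopifnot(is.data.frame(cohort),
            all(c("mFTA", "mMPTA", "mLDFA") %in% names(cohort)))
  cohort$location <- as.character(classify_location_vec(cohort$mMPTA,
                                                        cohort$mLDFA))
  cohort$severity <- as.character(classify_severity_vec(cohort$mFTA))
  cohort$potential_tibial <- pmax(0, limits$mMPTA_upper - cohort$mMPTA)
  cohort$potential_femoral <- pmax(0, cohort$mLDFA - limits$mLDFA_lower)
  cohort
}
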