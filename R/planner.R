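#' @name osteotomy-model
#' @title First-order wedge model
#' @description
#' Osteotomies are simulated purely in angle space: a medial open-wedge
#' high tibial osteotomy (HTO) of `w` degrees raises mMPTA by `w` and
#' reduces the varus mFTA by `w`; a lateral closed-wedge distal femoral
#' osteotomy (DFO) of `w` degrees lowers mLDFA by `w` and reduces the varus
#' mFTA by `w`. JLCA and the opposite knee-base angle are unchanged (the
#' simulation considers static alignment only), and the weight-bearing-line
#' ratio is dropped (`NA`) because it is not re-derivable without the full
#' landmark geometry.
NULL

apply_wedge <- function(alignment, wedge, site) {
  a <- as_alignment(alignment)
  stopifnot(length(wedge) == 1L, is.finite(wedge))
  if (wedge < 0)
    stop("osteotomy wedge must be non-negative", call. = FALSE)
  if (site == "TIBIA") {
    a$mMPTA <- a$mMPTA + wedge
  } else {
    a$mLDFA <- a$mLDFA - wedge
  }
  a$mFTA <- a$mFTA - wedge
  a$WBL_ratio <- NA_real_
  knee_alignment(a$mFTA, a$mMPTA, a$mLDFA, a$JLCA, a$WBL_ratio)
}

#' Apply a medial open-wedge HTO of a given angle
#'
#' @param alignment a [knee_alignment()].
#' @param wedge wedge angle in degrees, >= 0.
#' @return The post-osteotomy [knee_alignment()]. The operator itself is
#'   unconstrained; scenario limits are enforced by [plan_correction()].
#' @examples
#' apply_tibial_osteotomy(knee_alignment(6, 85.3, 89.3), 4.7)
#' @export
apply_tibial_osteotomy <- function(alignment, wedge) {
  apply_wedge(alignment, wedge, "TIBIA")
}

#' Apply a lateral closed-wedge DFO of a given angle
#'
#' @inheritParams apply_tibial_osteotomy
#' @return The post-osteotomy [knee_alignment()] (unconstrained; see
#'   [plan_correction()] for limit handling).
#' @export
apply_femoral_osteotomy <- function(alignment, wedge) {
  apply_wedge(alignment, wedge, "FEMUR")
}

# vectorised primary-site rule; mMPTA/mLDFA numeric vectors
choose_primary_site_vec <- function(mMPTA, mLDFA) {
  loc <- classify_location_vec(mMPTA, mLDFA)
  site <- character(length(mMPTA))
  site[loc == "TIBIAL"] <- "TIBIA"
  site[loc == "FEMORAL"] <- "FEMUR"
  both <- loc == "TIBIAL_AND_FEMORAL"
  # greatest deviation beyond the normal range decides; ties go to the tibia
  site[both] <- ifelse((85 - mMPTA[both]) >= (mLDFA[both] - 90),
                       "TIBIA", "FEMUR")
  none <- loc == "NO_BONY_DEFORMITY"
  # no true deformity: greatest anatomic-bound correction potential decides
  # (anatomic bounds 90/85 in every scenario, so site choice is
  # scenario-stable and only wedge capacity varies with the limits)
  site[none] <- ifelse((90 - mMPTA[none]) >= (mLDFA[none] - 85),
                       "TIBIA", "FEMUR")
  site
}

#' Choose the primary osteotomy site
#'
#' Simulation starts at the site of the greatest deformity found by the
#' malalignment test: tibia for a tibial deformity, femur for a femoral
#' one. For a combined deformity the site with the larger deviation beyond
#' the 85-90 normal range wins; without a true bony deformity the site
#' with the larger anatomic-bound correction potential (90 - mMPTA vs
#' mLDFA - 85) wins. Ties prefer the tibia, HTO being the historical
#' default procedure.
#'
#' @param alignment a [knee_alignment()] with mFTA >= 3 degrees varus.
#' @param limits a [scenario_limits()]; site choice itself always uses the
#'   anatomic bounds, the argument is accepted for interface symmetry.
#' @return `"TIBIA"` or `"FEMUR"`.
#' @examples
#' choose_primary_site(knee_alignment(10, 84.4, 90))  # "TIBIA"
#' @export
choose_primary_site <- function(alignment, limits = scenario_limits()) {
  a <- as_alignment(alignment)
  if (a$mFTA < 3)
    stop("osteotomy planning requires mFTA >= 3 degrees varus",
         call. = FALSE)
  choose_primary_site_vec(a$mMPTA, a$mLDFA)
}

#' Simulate a single capped osteotomy at one site
#'
#' Applies as much wedge as the scenario limit at `site` allows, up to the
#' wedge needed to reach the target alignment. Useful to inspect the
#' residual varus after an isolated HTO or DFO before deciding on a
#' double-level correction.
#'
#' @param alignment a [knee_alignment()].
#' @param site `"TIBIA"` or `"FEMUR"`.
#' @param limits a [scenario_limits()].
#' @return The post-osteotomy [knee_alignment()]; its `mFTA` equals the
#'   target when the site's capacity suffices, otherwise the residual
#'   varus with the knee-base angle driven to its limit.
#' @examples
#' # isolated HTO capped at mMPTA = 90 leaves residual varus:
#' simulate_single_osteotomy(knee_alignment(6, 85.3, 89.3), "TIBIA",
#'                           scenario_limits("anatomic"))
#' @export
simulate_single_osteotomy <- function(alignment, site = c("TIBIA", "FEMUR"),
                                      limits = scenario_limits()) {
  a <- as_alignment(alignment)
  site <- match.arg(site)
  stopifnot(inherits(limits, "scenario_limits"))
  delta <- a$mFTA - limits$target_mFTA
  if (delta <= 0)
    stop("target alignment is not a valgization of the presenting mFTA",
         call. = FALSE)
  cap <- if (site == "TIBIA") max(0, limits$mMPTA_upper - a$mMPTA)
         else max(0, a$mLDFA - limits$mLDFA_lower)
  apply_wedge(a, min(delta, cap), site)
}

#' Plan the correction of one varus knee
#'
#' Deterministic implementation of the simulation rule set. The required
#' valgization is `delta = mFTA - target_mFTA` (> 0). The primary site is
#' chosen by [choose_primary_site()]; `P1` is the wedge capacity there
#' under the scenario limits and `P2` the capacity at the opposite site.
#'
#' * `delta <= P1`: a single osteotomy at the primary site reaches the
#'   target (`category` `"TIBIAL"` or `"FEMORAL"`).
#' * `P1 < delta <= P1 + P2`: double-level osteotomy; the first wedge
#'   drives the primary knee-base angle to its scenario limit (`P1`), the
#'   second wedge (`delta - P1`) finishes the correction at the opposite
#'   site.
#' * `delta > P1 + P2`: `"UNCORRECTABLE"`; the plan records the best
#'   achievable alignment with both knee-base angles at their limits.
#'
#' @param alignment a [knee_alignment()] with mFTA >= 3 degrees varus.
#' @param limits a [scenario_limits()].
#' @return An object of class `osteotomy_plan`: list with `primary_site`,
#'   `tibial_wedge`, `femoral_wedge`, `post_alignment`
#'   (a [knee_alignment()]) and `category`.
#' @examples
#' plan_correction(knee_alignment(6, 85.3, 89.3, 2),
#'                 scenario_limits("overcorrection"))
#' @export
plan_correction <- function(alignment, limits = scenario_limits()) {
  a <- as_alignment(alignment)
  stopifnot(inherits(limits, "scenario_limits"))
  if (a$mFTA < 3)
    stop("osteotomy planning requires mFTA >= 3 degrees varus",
         call. = FALSE)
  if (limits$target_mFTA >= a$mFTA)
    stop("target mFTA must be smaller (more valgus) than the presenting mFTA",
         call. = FALSE)
  df <- data.frame(id = 1L, mFTA = a$mFTA, mMPTA = a$mMPTA,
                   mLDFA = a$mLDFA,
                   JLCA = a$JLCA, WBL_ratio = a$WBL_ratio)
  p <- plan_cohort(df, limits)
  post <- knee_alignment(p$post_mFTA, p$post_mMPTA, p$post_mLDFA, a$JLCA)
  structure(list(primary_site = p$primary_site,
                 tibial_wedge = p$tibial_wedge,
                 femoral_wedge = p$femoral_wedge,
                 post_alignment = post,
                 category = p$category,
                 limits = limits),
            class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat(sprintf("<osteotomy_plan> %s (%s scenario)\n", x$category,
              x$limits$name))
  cat(sprintf("  primary site %s | HTO wedge %.1f deg | DFO wedge %.1f deg\n",
              x$primary_site, x$tibial_wedge, x$femoral_wedge))
  cat(sprintf("  post: mFTA %.1f | mMPTA %.1f | mLDFA %.1f\n",
              x$post_alignment$mFTA, x$post_alignment$mMPTA,
              x$post_alignment$mLDFA))
  invisible(x)
}

#' Plan corrections for a whole cohort (vectorised)
#'
#' @param cohort data frame with columns `mFTA`, `mMPTA`, `mLDFA` (all in
#'   degrees, mFTA varus-positive) and optionally `id`.
#' @param limits a [scenario_limits()].
#' @return The cohort with appended columns `primary_site`, `tibial_wedge`,
#'   `femoral_wedge`, `post_mFTA`, `post_mMPTA`, `post_mLDFA`, `category`.
#' @export
plan_cohort <- function(cohort, limits = scenario_limits()) {
  stopifnot(is.data.frame(cohort),
            all(c("mFTA", "mMPTA", "mLDFA") %in% names(cohort)),
            inherits(limits, "scenario_limits"))
  n <- nrow(cohort)
  if (n == 0L) {
    out <- cohort
    out$primary_site <- character(0)
    out$tibial_wedge <- out$femoral_wedge <- numeric(0)
    out$post_mFTA <- out$post_mMPTA <- out$post_mLDFA <- numeric(0)
    out$category <- character(0)
    return(out)
  }
  if (any(cohort$mFTA < 3))
    stop("osteotomy planning requires mFTA >= 3 degrees varus for every knee",
         call. = FALSE)
  if (any(limits$target_mFTA >= cohort$mFTA))
    stop("target mFTA must be smaller than every presenting mFTA",
         call. = FALSE)

  eps <- 1e-9  # absorb floating-point slack in the capacity comparisons
  delta <- cohort$mFTA - limits$target_mFTA
  pot_t <- pmax(0, limits$mMPTA_upper - cohort$mMPTA)
  pot_f <- pmax(0, cohort$mLDFA - limits$mLDFA_lower)
  site <- choose_primary_site_vec(cohort$mMPTA, cohort$mLDFA)
  p1 <- ifelse(site == "TIBIA", pot_t, pot_f)
  p2 <- ifelse(site == "TIBIA", pot_f, pot_t)

  single <- delta <= p1 + eps
  dbl <- !single & delta <= p1 + p2 + eps
  uncor <- !single & !dbl

  w1 <- ifelse(single, pmin(delta, p1), p1)
  w2 <- ifelse(single, 0, ifelse(dbl, delta - p1, p2))
  tw <- ifelse(site == "TIBIA", w1, w2)
  fw <- ifelse(site == "TIBIA", w2, w1)

  category <- ifelse(uncor, "UNCORRECTABLE",
              ifelse(dbl, "DOUBLE_LEVEL",
              ifelse(site == "TIBIA", "TIBIAL", "FEMORAL")))

  out <- cohort
  out$primary_site <- site
  out$tibial_wedge <- tw
  out$femoral_wedge <- fw
  out$post_mFTA <- cohort$mFTA - tw - fw
  out$post_mMPTA <- cohort$mMPTA + tw
  out$post_mLDFA <- cohort$mLDFA - fw
  out$category <- category
  out
}

#' Ideal osteotomy level by varus severity
#'
#' Cross-tabulates plan category against varus severity for a planned
#' cohort: the shape of the study-style summary tables.
#'
#' @param cohort data frame; if it lacks `category` or `severity` columns
#'   these are computed with `limits`.
#' @param limits a [scenario_limits()].
#' @return A `table` with severity rows (`MILD`, `MODERATE`, `SEVERE`) and
#'   plan-category columns (`TIBIAL`, `FEMORAL`, `DOUBLE_LEVEL`,
#'   `UNCORRECTABLE`).
#' @export
ideal_level_table <- function(cohort, limits = scenario_limits()) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L)
    return(table(factor(character(0), levels = SEVERITY_LEVELS),
                 factor(character(0), levels = PLAN_LEVELS),
                 dnn = c("severity", "category")))
  if (!("category" %in% names(cohort)))
    cohort <- plan_cohort(cohort, limits)
  if (!("severity" %in% names(cohort)))
    cohort$severity <- as.character(classify_severity_vec(cohort$mFTA))
  table(severity = factor(cohort$severity, levels = SEVERITY_LEVELS),
        category = factor(cohort$category, levels = PLAN_LEVELS))
}
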