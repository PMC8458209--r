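#' Coronal alignment of one lower limb
#'
#' Bundles the five coronal parameters measured on a calibrated full-leg
#' standing radiograph. The sign conventions are the ones used throughout
#' the package: `mFTA` is varus-positive (a 6 means 6 degrees of mechanical
#' varus, -2 means 2 degrees of valgus) and `JLCA` is positive when the
#' femoral and tibial joint lines converge medially, i.e. the joint space
#' opens laterally, as is typical for varus knees.
#'
#' @param mFTA mechanical femorotibial (hip-knee-ankle) angle in decimal
#'   degrees, varus-positive.
#' @param mMPTA mechanical medial proximal tibial angle in degrees
#'   (normal range 85-90).
#' @param mLDFA mechanical lateral distal femoral angle in degrees
#'   (normal range 85-90).
#' @param JLCA joint line convergence angle in degrees,
#'   lateral-opening-positive.
#' @param WBL_ratio position of the weight-bearing line on the tibial
#'   plateau, in percent of the medial-to-lateral plateau width (0 = medial
#'   edge, 100 = lateral edge). May fall outside `[0, 100]` when the line
#'   misses the plateau. Optional (`NA` if not measured).
#'
#' @return An object of class `knee_alignment`: a named list with the five
#'   parameters as length-one numerics.
#' @examples
#' knee_alignment(mFTA = 6, mMPTA = 85.3, mLDFA = 89.3, JLCA = 2)
#' @export
knee_alignment <- function(mFTA, mMPTA, mLDFA, JLCA = NA_real_,
                           WBL_ratio = NA_real_) {
  x <- list(mFTA = as.numeric(mFTA), mMPTA = as.numeric(mMPTA),
            mLDFA = as.numeric(mLDFA), JLCA = as.numeric(JLCA),
            WBL_ratio = as.numeric(WBL_ratio))
  for (nm in names(x)) {
    if (length(x[[nm]]) != 1L)
      stop("`", nm, "` must be a single number", call. = FALSE)
  }
  if (!is.finite(x$mFTA)) stop("`mFTA` must be finite", call. = FALSE)
  if (!is.finite(x$mMPTA) || x$mMPTA <= 60 || x$mMPTA >= 120)
    stop("`mMPTA` must lie in (60, 120) degrees", call. = FALSE)
  if (!is.finite(x$mLDFA) || x$mLDFA <= 60 || x$mLDFA >= 120)
    stop("`mLDFA` must lie in (60, 120) degrees", call. = FALSE)
  # physiologic JLCA is (-10, 15); the hard check only rejects values that
  # cannot arise from coronal knee geometry at all, so that measured JLCA
  # of deliberately extreme constructed legs remains representable
  if (is.finite(x$JLCA) && (x$JLCA <= -30 || x$JLCA >= 30))
    stop("`JLCA` must lie in (-30, 30) degrees", call. = FALSE)
  if (is.finite(x$WBL_ratio) && (x$WBL_ratio < -100 || x$WBL_ratio > 200))
    stop("`WBL_ratio` must lie in [-100, 200] percent", call. = FALSE)
  structure(x, class = "knee_alignment")
}

#' @export
print.knee_alignment <- function(x, ...) {
  side <- if (x$mFTA >= 0) "varus" else "valgus"
  cat(sprintf("<knee_alignment> mFTA %.1f deg %s | mMPTA %.1f | mLDFA %.1f | JLCA %s | WBL %s\n",
              abs(x$mFTA), side, x$mMPTA, x$mLDFA,
              if (is.na(x$JLCA)) "NA" else sprintf("%.1f", x$JLCA),
              if (is.na(x$WBL_ratio)) "NA" else sprintf("%.1f%%", x$WBL_ratio)))
  invisible(x)
}

#' @export
as.data.frame.knee_alignment <- function(x, ...) {
  data.frame(mFTA = x$mFTA, mMPTA = x$mMPTA, mLDFA = x$mLDFA,
             JLCA = x$JLCA, WBL_ratio = x$WBL_ratio)
}

#' Mechanical femorotibial angle under the first-order coronal model
#'
#' The additive (first-order) coronal model decomposes the overall limb
#' axis deviation into a tibial contribution (`90 - mMPTA`), a femoral
#' contribution (`mLDFA - 90`) and the intra-articular contribution
#' (`JLCA`):
#' \deqn{mFTA = (90 - mMPTA) + (mLDFA - 90) + JLCA}
#' All terms are varus-positive. The model is exact to first order in the
#' small angles involved; full 2D landmark geometry agrees with it to well
#' under 0.2 degrees across the physiologic range.
#'
#' @param mMPTA,mLDFA,JLCA numeric vectors of angles in degrees.
#' @return Numeric vector of varus-positive mFTA values in degrees.
#' @examples
#' coronal_mfta(86, 89, 2) # 5 degrees varus
#' @export
coronal_mfta <- function(mMPTA, mLDFA, JLCA) {
  (90 - mMPTA) + (mLDFA - 90) + JLCA
}

#' Correction limits and target for an osteotomy simulation scenario
#'
#' A scenario fixes the joint-line-obliquity bounds that a simulated
#' correction must respect and the intended postoperative alignment.
#' The two scenarios studied here are *anatomic* correction
#' (`mMPTA_upper = 90`) and *overcorrection* (`mMPTA_upper = 95`), both
#' with an mLDFA floor of 85 degrees and a target of 2 degrees mechanical
#' valgus (`target_mFTA = -2` in the varus-positive convention).
#'
#' @param mMPTA_upper postoperative upper limit for mMPTA, degrees.
#' @param mLDFA_lower postoperative lower limit for mLDFA, degrees.
#' @param target_mFTA intended postoperative mFTA, varus-positive degrees
#'   (-2 = 2 degrees valgus).
#' @param name optional scenario label carried into reports.
#' @return An object of class `scenario_limits`.
#' @examples
#' scenario_limits("anatomic")
#' scenario_limits(mMPTA_upper = 95) # overcorrection bounds
#' @export
scenario_limits <- function(mMPTA_upper = 90, mLDFA_lower = 85,
                            target_mFTA = -2, name = NULL) {
  if (is.character(mMPTA_upper)) {
    preset <- match.arg(mMPTA_upper, c("anatomic", "overcorrection"))
    return(switch(preset,
      anatomic = scenario_limits(90, 85, -2, name = "anatomic"),
      overcorrection = scenario_limits(95, 85, -2, name = "overcorrection")))
  }
  mMPTA_upper <- as.numeric(mMPTA_upper)
  mLDFA_lower <- as.numeric(mLDFA_lower)
  target_mFTA <- as.numeric(target_mFTA)
  stopifnot(length(mMPTA_upper) == 1L, length(mLDFA_lower) == 1L,
            length(target_mFTA) == 1L)
  if (!is.finite(mMPTA_upper) || !is.finite(mLDFA_lower) ||
      !is.finite(target_mFTA))
    stop("scenario limits must be finite", call. = FALSE)
  if (!(mLDFA_lower <= 90 && 90 <= mMPTA_upper))
    stop("require mLDFA_lower <= 90 <= mMPTA_upper", call. = FALSE)
  if (is.null(name)) {
    name <- if (mMPTA_upper == 90) "anatomic"
            else if (mMPTA_upper == 95) "overcorrection"
            else "custom"
  }
  structure(list(mMPTA_upper = mMPTA_upper, mLDFA_lower = mLDFA_lower,
                 target_mFTA = target_mFTA, name = name),
            class = "scenario_limits")
}

#' @export
print.scenario_limits <- function(x, ...) {
  cat(sprintf("<scenario_limits> %s: mMPTA <= %g, mLDFA >= %g, target mFTA %g\n",
              x$name, x$mMPTA_upper, x$mLDFA_lower, x$target_mFTA))
  invisible(x)
}

# internal: accept either a knee_alignment or a one-row-equivalent list
as_alignment <- function(x) {
  if (inherits(x, "knee_alignment")) return(x)
  if (is.list(x) && all(c("mFTA", "mMPTA", "mLDFA") %in% names(x)))
    return(knee_alignment(x$mFTA, x$mMPTA, x$mLDFA,
                          if (!is.null(x$JLCA)) x$JLCA else NA_real_,
                          if (!is.null(x$WBL_ratio)) x$WBL_ratio else NA_real_))
  stop("expected a `knee_alignment` or a list with mFTA/mMPTA/mLDFA",
       call. = FALSE)
}
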