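#' Configuration for the synthetic varus cohort generator
#'
#' The generator emulates a varus cohort by drawing the two knee-base
#' angles and the joint line convergence angle from independent truncated
#' normal distributions, deriving mFTA from the first-order coronal model
#' ([coronal_mfta()]), and rejection-sampling until the inclusion criterion
#' (mFTA at least `inclusion_min_varus` degrees varus) holds. Defaults are
#' the published marginal summaries of a 303-leg varus cohort: mMPTA
#' 86 +/- 2 (range 78-93), mLDFA 89 +/- 2 (range 83-95), JLCA 2 +/- 2
#' (range 0-8), inclusion at 3 degrees varus. Truncation bounds default to
#' the observed ranges so no non-physiologic angles are drawn.
#'
#' @param n number of accepted knees to generate.
#' @param mMPTA_mean,mMPTA_sd,mMPTA_bounds tibial knee-base angle marginal.
#' @param mLDFA_mean,mLDFA_sd,mLDFA_bounds femoral knee-base angle marginal.
#' @param JLCA_mean,JLCA_sd,JLCA_bounds joint-line convergence marginal.
#' @param inclusion_min_varus inclusion threshold for mFTA (degrees varus).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 303,
                          mMPTA_mean = 86, mMPTA_sd = 2,
                          mMPTA_bounds = c(78, 93),
                          mLDFA_mean = 89, mLDFA_sd = 2,
                          mLDFA_bounds = c(83, 95),
                          JLCA_mean = 2, JLCA_sd = 2,
                          JLCA_bounds = c(0, 8),
                          inclusion_min_varus = 3,
                          seed = 1L) {
  cfg <- list(n = as.integer(n),
              mMPTA_mean = mMPTA_mean, mMPTA_sd = mMPTA_sd,
              mMPTA_bounds = as.numeric(mMPTA_bounds),
              mLDFA_mean = mLDFA_mean, mLDFA_sd = mLDFA_sd,
              mLDFA_bounds = as.numeric(mLDFA_bounds),
              JLCA_mean = JLCA_mean, JLCA_sd = JLCA_sd,
              JLCA_bounds = as.numeric(JLCA_bounds),
              inclusion_min_varus = inclusion_min_varus,
              seed = as.integer(seed))
  if (cfg$n < 0) stop("`n` must be >= 0", call. = FALSE)
  for (p in c("mMPTA", "mLDFA", "JLCA")) {
    if (cfg[[paste0(p, "_sd")]] <= 0)
      stop("`", p, "_sd` must be positive", call. = FALSE)
    b <- cfg[[paste0(p, "_bounds")]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("`", p, "_bounds` must be an ordered finite pair", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n=%d seed=%d | mMPTA %g+/-%g [%g,%g] | mLDFA %g+/-%g [%g,%g] | JLCA %g+/-%g [%g,%g] | mFTA >= %g varus\n",
              x$n, x$seed, x$mMPTA_mean, x$mMPTA_sd, x$mMPTA_bounds[1],
              x$mMPTA_bounds[2], x$mLDFA_mean, x$mLDFA_sd,
              x$mLDFA_bounds[1], x$mLDFA_bounds[2], x$JLCA_mean, x$JLCA_sd,
              x$JLCA_bounds[1], x$JLCA_bounds[2], x$inclusion_min_varus))
  invisible(x)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic varus cohort
#'
#' Draws knees per the configured truncated-normal marginals, computes
#' mFTA from the coronal model and keeps knees meeting the inclusion
#' criterion until `n` are accepted. The weight-bearing-line ratio of each
#' accepted knee is measured geometrically on a landmark set built with
#' [inverse_construct_landmarks()] at default segment lengths (so WBL is a
#' deterministic function of the angles, not an extra random draw).
#'
#' Dependence between the angles of accepted knees is an emergent effect
#' of the selection, not a calibrated joint distribution: cohort-level
#' percentages from this generator are illustrative, not reproductions of
#' any real cohort.
#'
#' @param config a [cohort_config()].
#' @param compute_wbl set `FALSE` to skip the geometric WBL measurement
#'   (column becomes `NA`), e.g. for large property-test cohorts.
#' @return Data frame with columns `id`, `mFTA`, `mMPTA`, `mLDFA`, `JLCA`,
#'   `WBL_ratio`.
#' @examples
#' head(generate_cohort(cohort_config(n = 5, seed = 42)))
#' @export
generate_cohort <- function(config = cohort_config(), compute_wbl = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  empty <- data.frame(id = integer(0), mFTA = numeric(0),
                      mMPTA = numeric(0), mLDFA = numeric(0),
                      JLCA = numeric(0), WBL_ratio = numeric(0))
  if (config$n == 0L) return(empty)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)

  acc <- empty[, -1]
  attempts <- 0L
  max_attempts <- 60L
  while (nrow(acc) < config$n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("inclusion criterion mFTA >= ", config$inclusion_min_varus,
           " accepts (almost) no draws under this configuration",
           call. = FALSE)
    m <- max(2L * (config$n - nrow(acc)), 100L)
    mmpta <- rtruncnorm(m, config$mMPTA_mean, config$mMPTA_sd,
                        config$mMPTA_bounds[1], config$mMPTA_bounds[2])
    mldfa <- rtruncnorm(m, config$mLDFA_mean, config$mLDFA_sd,
                        config$mLDFA_bounds[1], config$mLDFA_bounds[2])
    jlca <- rtruncnorm(m, config$JLCA_mean, config$JLCA_sd,
                       config$JLCA_bounds[1], config$JLCA_bounds[2])
    mfta <- coronal_mfta(mmpta, mldfa, jlca)
    keep <- mfta >= config$inclusion_min_varus
    if (any(keep))
      acc <- rbind(acc, data.frame(mFTA = mfta[keep], mMPTA = mmpta[keep],
                                   mLDFA = mldfa[keep], JLCA = jlca[keep],
                                   WBL_ratio = NA_real_))
  }
  acc <- acc[seq_len(config$n), , drop = FALSE]
  acc <- cbind(id = seq_len(config$n), acc)
  rownames(acc) <- NULL
  if (compute_wbl) {
    acc$WBL_ratio <- vapply(seq_len(config$n), function(i) {
      lm <- inverse_construct_landmarks(
        knee_alignment(acc$mFTA[i], acc$mMPTA[i], acc$mLDFA[i], acc$JLCA[i]))
      weight_bearing_line_ratio(lm)
    }, numeric(1))
  }
  acc
}

#' Construct a landmark set realizing specified coronal angles
#'
#' Builds an idealized 2D landmark geometry whose measured mFTA, mMPTA and
#' mLDFA reproduce the requested values exactly (to numerical precision);
#' the JLCA of the construction is emergent (it equals the coronal-model
#' value \eqn{mFTA - (90 - mMPTA) - (mLDFA - 90)} up to second-order terms,
#' a fraction of 0.1 degree in the physiologic range). The tibial
#' mechanical axis is placed vertically with the tibial knee base at the
#' origin; medial direction is resolved by `side`.
#'
#' @param alignment a [knee_alignment()]; only `mFTA`, `mMPTA`, `mLDFA`
#'   are used.
#' @param segment_lengths `c(femur, tibia)` mechanical-axis lengths in mm.
#' @param plateau_width tibial plateau width in mm (condylar and talar
#'   widths are scaled from it).
#' @param side `"right"` or `"left"`.
#' @return A [landmark_set()].
#' @examples
#' lm <- inverse_construct_landmarks(knee_alignment(5, 86, 89))
#' measure_alignment(lm)
#' @export
inverse_construct_landmarks <- function(alignment,
                                        segment_lengths = c(450, 380),
                                        plateau_width = 80,
                                        side = c("right", "left")) {
  a <- as_alignment(alignment)
  side <- match.arg(side)
  stopifnot(length(segment_lengths) == 2L, all(segment_lengths > 0),
            plateau_width > 0)
  if (a$mMPTA < 70 || a$mMPTA > 110 || a$mLDFA < 70 || a$mLDFA > 110 ||
      abs(a$mFTA) > 30)
    stop("requested angles are outside the physiologic construction range",
         call. = FALSE)
  s <- medial_sign(side)
  lf <- segment_lengths[1]
  lt <- segment_lengths[2]
  wp <- plateau_width
  wc <- plateau_width * 1.05   # condyles slightly wider than the plateau
  wt <- plateau_width * 0.65   # talus narrower
  gap <- plateau_width * 0.1   # radiographic joint space (8 mm at default)

  phi <- rad(a$mFTA)           # varus tilt of the femoral axis
  theta <- rad(a$mMPTA - 90)   # plateau medial-end elevation
  delta <- rad(a$mLDFA - 90)   # condylar medial-end elevation (femur frame)

  kt <- c(0, 0)
  ankle <- c(0, lt)
  kf <- kt - c(0, gap)
  v_f <- c(-s * sin(phi), cos(phi))        # distal femoral axis direction
  fh <- kf - lf * v_f
  m_f <- c(s * cos(phi), sin(phi))         # medial, perpendicular to v_f
  c_med <- cos(delta) * m_f - sin(delta) * v_f
  p_med <- c(s * cos(theta), -sin(theta))

  landmark_set(
    femoral_head_center = fh,
    greater_trochanter_apex = fh + c(-s * 55, 5),
    femoral_condyle_medial = kf + (wc / 2) * c_med,
    femoral_condyle_lateral = kf - (wc / 2) * c_med,
    knee_center_femoral = kf,
    knee_center_tibial = kt,
    tibial_plateau_medial = kt + (wp / 2) * p_med,
    tibial_plateau_lateral = kt - (wp / 2) * p_med,
    talus_medial = ankle + c(s * wt / 2, 0),
    talus_lateral = ankle - c(s * wt / 2, 0),
    talus_joint_line = list(ankle + c(s * wt * 0.4, 0),
                            ankle - c(s * wt * 0.4, 0)),
    side = side)
}
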