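#' Named 2D landmarks of one lower limb on a full-leg radiograph
#'
#' Coordinates follow the digital-radiograph convention: x increases to the
#' patient's left, y increases downward, units are millimetres. The `side`
#' flag ("left"/"right") resolves which image direction is medial, so the
#' same measurement code yields side-aware signs (varus is positive on both
#' sides).
#'
#' @param femoral_head_center,greater_trochanter_apex,femoral_condyle_medial,femoral_condyle_lateral,knee_center_femoral,knee_center_tibial,tibial_plateau_medial,tibial_plateau_lateral,talus_medial,talus_lateral
#'   numeric length-2 vectors `c(x, y)` in millimetres.
#' @param talus_joint_line list of two `c(x, y)` points spanning the talar
#'   joint line.
#' @param side `"left"` or `"right"`.
#' @return An object of class `landmark_set`.
#' @seealso [measure_alignment()], [weight_bearing_line_ratio()],
#'   [inverse_construct_landmarks()]
#' @export
landmark_set <- function(femoral_head_center, greater_trochanter_apex,
                         femoral_condyle_medial, femoral_condyle_lateral,
                         knee_center_femoral, knee_center_tibial,
                         tibial_plateau_medial, tibial_plateau_lateral,
                         talus_medial, talus_lateral, talus_joint_line,
                         side = c("right", "left")) {
  side <- match.arg(side)
  pts <- list(femoral_head_center = femoral_head_center,
              greater_trochanter_apex = greater_trochanter_apex,
              femoral_condyle_medial = femoral_condyle_medial,
              femoral_condyle_lateral = femoral_condyle_lateral,
              knee_center_femoral = knee_center_femoral,
              knee_center_tibial = knee_center_tibial,
              tibial_plateau_medial = tibial_plateau_medial,
              tibial_plateau_lateral = tibial_plateau_lateral,
              talus_medial = talus_medial,
              talus_lateral = talus_lateral)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop("landmark `", nm, "` must be a finite c(x, y) pair", call. = FALSE)
    pts[[nm]] <- p
  }
  if (!is.list(talus_joint_line) || length(talus_joint_line) != 2L)
    stop("`talus_joint_line` must be a list of two points", call. = FALSE)
  talus_joint_line <- lapply(talus_joint_line, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p)))
      stop("`talus_joint_line` points must be finite c(x, y) pairs",
           call. = FALSE)
    p
  })
  for (pair in list(c("femoral_condyle_medial", "femoral_condyle_lateral"),
                    c("tibial_plateau_medial", "tibial_plateau_lateral"),
                    c("talus_medial", "talus_lateral"))) {
    if (sqrt(sum((pts[[pair[1]]] - pts[[pair[2]]])^2)) <= .Machine$double.eps)
      stop("landmarks `", pair[1], "` and `", pair[2],
           "` must be distinct points", call. = FALSE)
  }
  structure(c(pts, list(talus_joint_line = talus_joint_line, side = side)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s leg, 11 landmarks (mm, image coordinates)\n",
              x$side))
  invisible(x)
}

medial_sign <- function(side) if (identical(side, "right")) 1 else -1

unit_or_stop <- function(v, axis) {
  n <- sqrt(sum(v^2))
  if (n <= 1e-12)
    stop("degenerate (zero-length) ", axis, " axis", call. = FALSE)
  v / n
}

rad <- function(deg) deg * pi / 180
deg <- function(rad) rad * 180 / pi

#' Measure the five coronal alignment parameters from landmarks
#'
#' Computes, from raw 2D landmarks, the mechanical axes and joint lines and
#' from them the varus-positive mFTA, the medial proximal tibial angle
#' (mMPTA), the lateral distal femoral angle (mLDFA), the joint line
#' convergence angle (JLCA, lateral-opening-positive) and the
#' weight-bearing-line ratio.
#'
#' Axis definitions: the femoral mechanical axis runs from the femoral head
#' centre to the femoral knee-base point; the tibial mechanical axis runs
#' from the tibial knee-base point to the ankle centre, taken as the
#' midpoint between the medial and lateral talar borders. mMPTA is the
#' medial angle between the tibial axis and the plateau line, mLDFA the
#' lateral angle between the femoral axis and the condylar line.
#'
#' All outputs are invariant to rigid motions of the landmark set and to
#' uniform scaling; mirroring the set left/right together with flipping the
#' `side` flag leaves every value unchanged.
#'
#' @param landmarks a [landmark_set()].
#' @return A [knee_alignment()].
#' @examples
#' lm <- inverse_construct_landmarks(knee_alignment(6, 85.3, 89.3))
#' measure_alignment(lm)
#' @export
measure_alignment <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  s <- medial_sign(landmarks$side)

  ankle <- (landmarks$talus_medial + landmarks$talus_lateral) / 2
  f_hat <- unit_or_stop(landmarks$knee_center_femoral -
                          landmarks$femoral_head_center, "femoral mechanical")
  t_hat <- unit_or_stop(ankle - landmarks$knee_center_tibial,
                        "tibial mechanical")
  # lateral unit vector perpendicular to the tibial axis
  lat_hat <- s * c(-t_hat[2], t_hat[1])

  mFTA <- deg(atan2(sum(f_hat * lat_hat), sum(f_hat * t_hat)))

  p_med <- unit_or_stop(landmarks$tibial_plateau_medial -
                          landmarks$tibial_plateau_lateral, "tibial plateau")
  mMPTA <- deg(acos(max(-1, min(1, sum(p_med * t_hat)))))

  c_lat <- unit_or_stop(landmarks$femoral_condyle_lateral -
                          landmarks$femoral_condyle_medial, "femoral condylar")
  mLDFA <- deg(acos(max(-1, min(1, sum(c_lat * (-f_hat))))))

  # JLCA: signed angle from the plateau's medial direction to the condylar
  # medial direction; positive when the joint space opens laterally
  c_med <- -c_lat
  cross_z <- p_med[1] * c_med[2] - p_med[2] * c_med[1]
  JLCA <- s * deg(atan2(cross_z, sum(p_med * c_med)))

  wbl <- weight_bearing_line_ratio(landmarks)
  knee_alignment(mFTA = mFTA, mMPTA = mMPTA, mLDFA = mLDFA, JLCA = JLCA,
                 WBL_ratio = wbl)
}

#' Weight-bearing line ratio on the tibial plateau
#'
#' Intersects the weight-bearing line (femoral head centre to ankle centre)
#' with the infinite line through the tibial plateau landmarks and reports
#' the intersection position in percent of the medial-to-lateral plateau
#' width: 0 at the medial edge, 100 at the lateral edge; values outside
#' `[0, 100]` indicate that the line misses the plateau.
#'
#' @param landmarks a [landmark_set()].
#' @return Ratio in percent (numeric scalar).
#' @export
weight_bearing_line_ratio <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ankle <- (landmarks$talus_medial + landmarks$talus_lateral) / 2
  a <- landmarks$tibial_plateau_medial
  b <- landmarks$tibial_plateau_lateral
  p <- landmarks$femoral_head_center
  d_wbl <- ankle - p
  if (sqrt(sum(d_wbl^2)) <= 1e-12)
    stop("degenerate (zero-length) weight-bearing line", call. = FALSE)
  d_pl <- b - a
  # solve a + t*d_pl = p + u*d_wbl
  det <- d_pl[1] * (-d_wbl[2]) - (-d_wbl[1]) * d_pl[2]
  if (abs(det) <= 1e-12 * sqrt(sum(d_pl^2)) * sqrt(sum(d_wbl^2)))
    stop("weight-bearing line is parallel to the tibial plateau",
         call. = FALSE)
  rhs <- p - a
  t <- (rhs[1] * (-d_wbl[2]) - (-d_wbl[1]) * rhs[2]) / det
  100 * t
}

#' Read a landmark file (JSON or CSV)
#'
#' JSON files hold an object mapping landmark name to `[x, y]` (with
#' `talus_joint_line` a list of two points) plus a `"side"` entry. CSV
#' files have columns `name,x,y` (talus joint line points named
#' `talus_joint_line_1` / `talus_joint_line_2`) and the side given in a
#' `side` row or via the `side` argument. The reader validates the full
#' landmark list.
#'
#' @param path file path; format chosen by extension (`.json` vs `.csv`).
#' @param side fallback side for CSV files lacking a `side` row.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, side = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$side)) stop("landmark JSON lacks \"side\"", call. = FALSE)
    tjl <- obj$talus_joint_line
    if (is.matrix(tjl)) tjl <- list(tjl[1, ], tjl[2, ])
    args <- obj[setdiff(names(obj), c("side", "talus_joint_line"))]
    do.call(landmark_set,
            c(args, list(talus_joint_line = tjl, side = obj$side)))
  } else {
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    need <- c("name", "x", "y")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns name,x,y", call. = FALSE)
    if ("side" %in% df$name) {
      side <- as.character(df$x[df$name == "side"][1])
      df <- df[df$name != "side", , drop = FALSE]
    }
    if (is.null(side))
      stop("CSV has no `side` row and no `side` argument given",
           call. = FALSE)
    pts <- lapply(seq_len(nrow(df)),
                  function(i) c(as.numeric(df$x[i]), as.numeric(df$y[i])))
    names(pts) <- df$name
    tjl_names <- c("talus_joint_line_1", "talus_joint_line_2")
    if (!all(tjl_names %in% names(pts)))
      stop("landmark CSV must contain rows ",
           paste(tjl_names, collapse = " and "), call. = FALSE)
    args <- pts[setdiff(names(pts), tjl_names)]
    do.call(landmark_set,
            c(args, list(talus_joint_line = list(pts[[tjl_names[1]]],
                                                 pts[[tjl_names[2]]]),
                         side = side)))
  }
}

#' Write a landmark set to JSON
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- unclass(landmarks)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
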