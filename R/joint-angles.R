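# Joint angles from skeleton frames: included angle at a vertex joint between
# proximal and distal segment vectors.

.movements <- c("shoulder_abduction", "shoulder_adduction",
                "elbow_flexion", "elbow_extension")

#' Segment definition for a movement
#'
#' Each movement is measured as the included angle at a vertex joint between
#' the vector to a proximal joint (Vp) and the vector to a distal joint (Vd).
#' Defaults follow the hip/shoulder/elbow/hand joint triples used for AROM
#' calculation in the seated protocol:
#' abduction (Hip, Shoulder, Elbow) with the shoulder as vertex;
#' adduction (Hand, Shoulder, Hip); flexion (Shoulder, Elbow, Hand) with the
#' elbow as vertex; extension (Hand, Elbow, Shoulder). `"Hand"` maps to the
#' HandLeft/HandRight joints (not wrist, not hand tip); override via the
#' `proximal`/`vertex`/`distal` arguments if a different landmark is wanted.
#'
#' @param movement One of `"shoulder_abduction"`, `"shoulder_adduction"`,
#'   `"elbow_flexion"`, `"elbow_extension"`.
#' @param side `"left"` or `"right"`.
#' @param proximal,vertex,distal Optional joint-name overrides (side suffix
#'   included, e.g. `"WristRight"`).
#' @return A list with elements `movement`, `side`, `proximal`, `vertex`,
#'   `distal` (full joint names).
#' @export
#' @examples
#' segment_definition("shoulder_abduction", "right")
segment_definition <- function(movement, side = c("right", "left"),
                               proximal = NULL, vertex = NULL, distal = NULL) {
  movement <- match.arg(movement, .movements)
  side <- match.arg(side)
  sfx <- if (side == "right") "Right" else "Left"
  base <- switch(movement,
    shoulder_abduction = c(p = "Hip", v = "Shoulder", d = "Elbow"),
    shoulder_adduction = c(p = "Hand", v = "Shoulder", d = "Hip"),
    elbow_flexion      = c(p = "Shoulder", v = "Elbow", d = "Hand"),
    elbow_extension    = c(p = "Hand", v = "Elbow", d = "Shoulder"))
  joints <- paste0(base, sfx)
  if (!is.null(proximal)) joints[1] <- proximal
  if (!is.null(vertex))   joints[2] <- vertex
  if (!is.null(distal))   joints[3] <- distal
  if (anyDuplicated(joints))
    stop("segment definition needs three distinct joints", call. = FALSE)
  bad <- setdiff(joints, joint_names())
  if (length(bad)) stop("unknown joint name: ", bad[1], call. = FALSE)
  list(movement = movement, side = side,
       proximal = joints[1], vertex = joints[2], distal = joints[3])
}

#' Angle between two 3D vectors
#'
#' theta = arccos( clamp(Vd.Vp / (|Vd||Vp|), -1, 1) ) in degrees, in
#' [0, 180]. Symmetric in its arguments and invariant to positive rescaling
#' of either vector. The cosine is clamped into [-1, 1] before arccos for
#' floating-point safety.
#'
#' @param vd,vp Numeric length-3 vectors.
#' @return Angle in degrees.
#' @export
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # 90
#' angle_between(c(1, 1, 0), c(1, 0, 0))  # 45
angle_between <- function(vd, vp) {
  stopifnot(length(vd) == 3L, length(vp) == 3L)
  nd <- sqrt(sum(vd^2)); np <- sqrt(sum(vp^2))
  if (nd <= 1e-9 || np <= 1e-9)
    stop("degenerate geometry: near-zero segment vector", call. = FALSE)
  ct <- sum(vd * vp) / (nd * np)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Joint angle of one movement in one frame
#'
#' Forms Vp = proximal - vertex and Vd = distal - vertex from the frame's
#' joint positions and returns the full 3D included angle via
#' [angle_between()]. The frontal/sagittal-plane description of the movements
#' refers to how the movement is performed, not to a projection: by default no
#' plane projection is applied. Set `project` to project both segment vectors
#' onto an anatomical plane first, for sensitivity analysis.
#'
#' @param frame A [skeleton_frame()].
#' @param movement,side Movement and side, passed to [segment_definition()]
#'   when `segments` is `NULL`.
#' @param segments Optional [segment_definition()] result.
#' @param project `"none"` (default), `"frontal"` (drop z) or `"sagittal"`
#'   (drop x) before the angle is taken.
#' @return A list of class `angle_measurement` with `theta` (degrees),
#'   `movement`, `side`, `frame_index`; or `NULL` with attribute handling via
#'   [angle_series()] when a required joint is not tracked.
#' @export
joint_angle <- function(frame, movement, side, segments = NULL,
                        project = c("none", "frontal", "sagittal")) {
  project <- match.arg(project)
  if (is.null(segments)) segments <- segment_definition(movement, side)
  need <- c(segments$proximal, segments$vertex, segments$distal)
  trk <- frame$tracking[need]
  if (any(is.na(trk)) || any(trk == "not_tracked")) {
    bad <- need[is.na(trk) | trk == "not_tracked"]
    cond <- structure(class = c("kinarom_frame_excluded", "condition"),
                      list(message = paste0("joint not tracked: ",
                                            paste(bad, collapse = ", ")),
                           call = NULL))
    stop(cond)
  }
  pos <- frame$positions
  vp <- pos[segments$proximal, ] - pos[segments$vertex, ]
  vd <- pos[segments$distal, ] - pos[segments$vertex, ]
  if (project == "frontal") { vp["z"] <- 0; vd["z"] <- 0 }
  if (project == "sagittal") { vp["x"] <- 0; vd["x"] <- 0 }
  structure(list(theta = angle_between(vd, vp),
                 movement = segments$movement, side = segments$side,
                 frame_index = frame$frame_index),
            class = "angle_measurement")
}

#' Per-frame angle series for one movement over a stream
#'
#' Computes [joint_angle()] on every frame. Frames whose required joints are
#' in state `not_tracked` (or degenerate) are excluded and listed with the
#' reason rather than contaminating the series.
#'
#' @param stream A [skeleton_stream()].
#' @inheritParams joint_angle
#' @return An object of class `angle_series`: list with `measurements`
#'   (data.frame `frame_index`, `theta_deg`), `excluded` (data.frame
#'   `frame_index`, `reason`), `movement`, `side`.
#' @export
angle_series <- function(stream, movement, side, segments = NULL,
                         project = c("none", "frontal", "sagittal")) {
  project <- match.arg(project)
  stopifnot(inherits(stream, "skeleton_stream"))
  if (is.null(segments)) segments <- segment_definition(movement, side)
  idx <- numeric(0); theta <- numeric(0)
  ex_idx <- integer(0); ex_reason <- character(0)
  for (f in stream$frames) {
    m <- tryCatch(joint_angle(f, segments = segments, project = project),
                  kinarom_frame_excluded = function(c) c,
                  error = function(e) e)
    if (inherits(m, "angle_measurement")) {
      idx <- c(idx, f$frame_index); theta <- c(theta, m$theta)
    } else {
      ex_idx <- c(ex_idx, f$frame_index)
      ex_reason <- c(ex_reason, conditionMessage(m))
    }
  }
  if (length(idx) == 0L)
    stop("empty series: no usable frames in stream", call. = FALSE)
  structure(list(
    measurements = data.frame(frame_index = idx, theta_deg = theta),
    excluded = data.frame(frame_index = ex_idx, reason = ex_reason),
    movement = segments$movement, side = segments$side),
    class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series: %s/%s, %d measurements, %d excluded>\n",
              x$movement, x$side, nrow(x$measurements), nrow(x$excluded)))
  invisible(x)
}
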