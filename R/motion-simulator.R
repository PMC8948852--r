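# Forward-kinematics simulator of seated upper-limb skeleton streams.
#
# The simulator replaces the depth sensor: it places a seated body template in
# camera space, articulates one arm to a prescribed shoulder-abduction /
# elbow-flexion pose, and injects calibrated angular noise plus positional
# jitter. Zero-noise poses are exact: re-measuring with joint_angle() recovers
# the prescribed angles to floating-point precision.

#' Arm pose specification
#'
#' @param side `"left"` or `"right"`.
#' @param shoulder_abduction Abduction angle in degrees, [0, 180] (0 = arm
#'   hanging along the trunk, 90 = horizontal).
#' @param elbow_flexion_included Elbow angle in the included-angle convention,
#'   degrees in [0, 180]; 180 = straight arm, smaller = more flexed.
#' @return List of class `arm_pose`.
#' @export
#' @examples
#' arm_pose("right", 90, 180)
arm_pose <- function(side = c("right", "left"), shoulder_abduction,
                     elbow_flexion_included = 180) {
  side <- match.arg(side)
  if (!is.finite(shoulder_abduction) || shoulder_abduction < 0 ||
      shoulder_abduction > 180)
    stop("shoulder_abduction must be in [0, 180] degrees", call. = FALSE)
  if (!is.finite(elbow_flexion_included) || elbow_flexion_included < 0 ||
      elbow_flexion_included > 180)
    stop("elbow_flexion_included must be in [0, 180] degrees", call. = FALSE)
  structure(list(side = side,
                 shoulder_abduction = shoulder_abduction,
                 elbow_flexion_included = elbow_flexion_included),
            class = "arm_pose")
}

#' Segment lengths of the simulated body
#'
#' Child-scale defaults; all lengths in meters and configurable.
#'
#' @param upper_arm_length Shoulder-to-elbow length.
#' @param forearm_plus_hand_length Elbow-to-hand-joint length.
#' @param shoulder_to_hip_drop Vertical shoulder-to-hip distance.
#' @param shoulder_half_width Half the biacromial width.
#' @return List of class `anthropometry`.
#' @export
default_anthropometry <- function(upper_arm_length = 0.28,
                                  forearm_plus_hand_length = 0.30,
                                  shoulder_to_hip_drop = 0.40,
                                  shoulder_half_width = 0.18) {
  a <- list(upper_arm_length = upper_arm_length,
            forearm_plus_hand_length = forearm_plus_hand_length,
            shoulder_to_hip_drop = shoulder_to_hip_drop,
            shoulder_half_width = shoulder_half_width)
  if (any(unlist(a) <= 0)) stop("all segment lengths must be > 0", call. = FALSE)
  structure(a, class = "anthropometry")
}

# Seated template in camera space: x = camera's left (participant's right),
# y up, z from camera toward participant. Torso centered on x = 0 at depth z0.
.seated_template <- function(anthro, z0) {
  w <- anthro$shoulder_half_width
  drop <- anthro$shoulder_to_hip_drop
  sh_y <- 0.30
  hip_y <- sh_y - drop
  hip_x <- 0.45 * w
  tmpl <- rbind(
    SpineBase     = c(0,        hip_y + 0.03, z0),
    SpineMid      = c(0,        sh_y - 0.14,  z0),
    SpineShoulder = c(0,        sh_y + 0.02,  z0),
    Neck          = c(0,        sh_y + 0.06,  z0),
    Head          = c(0,        sh_y + 0.16,  z0),
    ShoulderRight = c(w,        sh_y,         z0),
    ShoulderLeft  = c(-w,       sh_y,         z0),
    HipRight      = c(hip_x,    hip_y,        z0),
    HipLeft       = c(-hip_x,   hip_y,        z0),
    KneeRight     = c(hip_x,    hip_y - 0.02, z0 - 0.32),
    KneeLeft      = c(-hip_x,   hip_y - 0.02, z0 - 0.32),
    AnkleRight    = c(hip_x,    hip_y - 0.32, z0 - 0.34),
    AnkleLeft     = c(-hip_x,   hip_y - 0.32, z0 - 0.34),
    FootRight     = c(hip_x,    hip_y - 0.36, z0 - 0.44),
    FootLeft      = c(-hip_x,   hip_y - 0.36, z0 - 0.44))
  colnames(tmpl) <- c("x", "y", "z")
  tmpl
}

# Articulate one arm. Abduction rotates the shoulder->hip direction laterally
# within the frontal (x-y) plane of the template, so the hip-shoulder-elbow
# included angle equals the prescribed abduction exactly. Elbow flexion bends
# the forearm forward (toward the camera, the seated sagittal direction) in
# the plane spanned by the upper arm and the camera axis, so the
# shoulder-elbow-hand included angle equals the prescribed elbow angle.
.arm_joints <- function(side, abduction, elbow_included, anthro, tmpl) {
  sfx <- if (side == "right") "Right" else "Left"
  sh <- tmpl[paste0("Shoulder", sfx), ]
  hip <- tmpl[paste0("Hip", sfx), ]
  u <- hip - sh
  u <- u / sqrt(sum(u^2))              # in the x-y plane by construction
  s <- if (side == "right") 1 else -1  # lateral direction
  a <- abduction * pi / 180
  v <- c(cos(s * a) * u[1] - sin(s * a) * u[2],
         sin(s * a) * u[1] + cos(s * a) * u[2],
         0)
  elbow <- sh + anthro$upper_arm_length * v
  phi <- (180 - elbow_included) * pi / 180
  fwd <- c(0, 0, -1)                   # toward the camera
  wdir <- cos(phi) * v + sin(phi) * fwd
  hand <- elbow + anthro$forearm_plus_hand_length * wdir
  wrist <- elbow + 0.78 * anthro$forearm_plus_hand_length * wdir
  tip <- elbow + 1.10 * anthro$forearm_plus_hand_length * wdir
  thumb <- hand + c(0, 0.03, 0)
  out <- rbind(elbow, wrist, hand, tip, thumb)
  rownames(out) <- paste0(c("Elbow", "Wrist", "Hand", "HandTip", "Thumb"), sfx)
  out
}

#' Build a full skeleton frame from an arm pose
#'
#' Places the seated body template at `distance` meters from the camera and
#' articulates the arm on `pose$side` by forward kinematics; the opposite arm
#' rests at 10 degrees abduction with a straight elbow. With zero noise the
#' hip-shoulder-elbow and shoulder-elbow-hand included angles re-measured by
#' [joint_angle()] reproduce the prescribed pose to well below 1e-6 degrees.
#'
#' @param pose An [arm_pose()].
#' @param anthropometry An anthropometry list, see [default_anthropometry()].
#' @param distance Camera-to-participant depth in meters (default 2, the
#'   recommended placement).
#' @param frame_index Frame counter for the returned frame.
#' @return A [skeleton_frame()].
#' @export
#' @examples
#' f <- pose_to_skeleton(arm_pose("right", 90, 135))
#' joint_angle(f, "shoulder_abduction", "right")$theta  # 90
#' joint_angle(f, "elbow_flexion", "right")$theta       # 135
pose_to_skeleton <- function(pose, anthropometry = default_anthropometry(),
                             distance = 2, frame_index = 0L) {
  stopifnot(inherits(pose, "arm_pose"))
  tmpl <- .seated_template(anthropometry, z0 = distance)
  test <- .arm_joints(pose$side, pose$shoulder_abduction,
                      pose$elbow_flexion_included, anthropometry, tmpl)
  other <- setdiff(c("right", "left"), pose$side)
  rest <- .arm_joints(other, 10, 180, anthropometry, tmpl)
  pos <- rbind(tmpl, test, rest)[joint_names(), ]
  skeleton_frame(frame_index, pos)
}

#' Angular noise model of an acquisition condition
#'
#' @param angle_bias Systematic angular offset in degrees added to every
#'   prescribed movement angle.
#' @param angle_sd SD of the zero-mean Gaussian angular perturbation, degrees.
#' @param positional_jitter_sd SD of isotropic positional jitter added to
#'   every joint coordinate, meters.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(angle_bias = 0, angle_sd = 0,
                        positional_jitter_sd = 0.003) {
  if (angle_sd < 0 || positional_jitter_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(angle_bias = angle_bias, angle_sd = angle_sd,
                 positional_jitter_sd = positional_jitter_sd),
            class = "noise_model")
}

# Calibrated presets: 90-degree bench measurements at {1,2,3} m x {7,73} lx.
# bias = measured mean - 90; sd = measured SD at that condition.
.noise_presets <- data.frame(
  distance = c(1, 2, 3, 1, 2, 3),
  illuminance = c(7, 7, 7, 73, 73, 73),
  mean_deg = c(94.19, 89.74, 89.33, 111.32, 91.65, 95.96),
  sd_deg = c(5.64, 2.94, 4.77, 4.01, 2.06, 1.96))

#' Noise parameters of a calibrated acquisition condition
#'
#' Looks up the empirical angular bias and SD measured at a fixed 90-degree
#' arm pose under six calibrated conditions: distances of 1, 2 and 3 m crossed
#' with illuminances of 7 and 73 lx. The bias is the measured mean minus the
#' true 90 degrees. The presets are an empirical lookup; no mechanistic model
#' of the illumination dependence is attempted.
#'
#' @param distance Camera distance in meters: 1, 2 or 3.
#' @param illuminance Illuminance in lx: 7 or 73.
#' @param positional_jitter_sd Passed through to [noise_model()].
#' @return A [noise_model()] with the preset's bias and SD.
#' @export
#' @examples
#' condition_noise_params(2, 73)  # bias +1.65, sd 2.06
condition_noise_params <- function(distance, illuminance,
                                   positional_jitter_sd = 0.003) {
  hit <- which(.noise_presets$distance == distance &
               .noise_presets$illuminance == illuminance)
  if (length(hit) != 1L)
    stop("no calibrated preset for (", distance, " m, ", illuminance,
         " lx); presets are distances {1, 2, 3} m x illuminances {7, 73} lx",
         call. = FALSE)
  noise_model(angle_bias = .noise_presets$mean_deg[hit] - 90,
              angle_sd = .noise_presets$sd_deg[hit],
              positional_jitter_sd = positional_jitter_sd)
}

#' Simulate one measurement session as a noisy skeleton stream
#'
#' Resamples `trajectory` (a single [arm_pose()] or a list of poses, linearly
#' interpolated in both angles) to `n_frames` frames. Per frame, the angular
#' noise `bias + N(0, sd)` is applied to each movement angle in its movement
#' plane (the pose is re-articulated at the perturbed angles, clamped to
#' [0, 180]), then isotropic Gaussian positional jitter is added to every
#' joint. Identical seeds give identical streams.
#'
#' @param trajectory An [arm_pose()] or list of poses (all on one side).
#' @param anthropometry See [default_anthropometry()].
#' @param noise A [noise_model()].
#' @param n_frames Number of frames (default 30, one measurement session).
#' @param rate Sampling rate in Hz (default 30).
#' @param seed Integer seed; required for reproducibility.
#' @param distance Camera depth in meters used for the template.
#' @param metadata Extra metadata stored on the stream.
#' @return A [skeleton_stream()] with `n_frames` frames.
#' @export
simulate_measurement_session <- function(trajectory,
                                         anthropometry = default_anthropometry(),
                                         noise = noise_model(),
                                         n_frames = 30, rate = 30, seed = 1,
                                         distance = 2, metadata = list()) {
  if (inherits(trajectory, "arm_pose")) trajectory <- list(trajectory)
  if (length(trajectory) == 0L)
    stop("empty trajectory", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  sides <- unique(vapply(trajectory, `[[`, character(1), "side"))
  if (length(sides) != 1L)
    stop("all poses in a trajectory must be on the same side", call. = FALSE)
  ab <- vapply(trajectory, `[[`, numeric(1), "shoulder_abduction")
  el <- vapply(trajectory, `[[`, numeric(1), "elbow_flexion_included")
  if (length(ab) == 1L) {
    ab_t <- rep(ab, n_frames); el_t <- rep(el, n_frames)
  } else {
    s <- seq(0, 1, length.out = length(ab))
    t <- seq(0, 1, length.out = n_frames)
    ab_t <- stats::approx(s, ab, xout = t)$y
    el_t <- stats::approx(s, el, xout = t)$y
  }
  set.seed(seed)
  clamp <- function(x) pmin(180, pmax(0, x))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    ab_i <- clamp(ab_t[i] + noise$angle_bias + stats::rnorm(1, 0, noise$angle_sd))
    el_i <- clamp(el_t[i] + noise$angle_bias + stats::rnorm(1, 0, noise$angle_sd))
    f <- pose_to_skeleton(arm_pose(sides, ab_i, el_i), anthropometry,
                          distance = distance, frame_index = i - 1L)
    if (noise$positional_jitter_sd > 0)
      f$positions <- f$positions +
        matrix(stats::rnorm(75, 0, noise$positional_jitter_sd), 25, 3)
    frames[[i]] <- f
  }
  skeleton_stream(frames, rate = rate,
                  metadata = c(list(side = sides, distance = distance), metadata))
}

#' Simulate a cohort of participants with streams and manual item sheets
#'
#' Generates `n_participants` records for one group. Per participant and side,
#' a true abduction AROM and a true elbow-flexion limit (included angle) are
#' drawn from the group's generative distribution, and a 30-frame
#' constant-pose measurement stream per movement is simulated under the
#' acquisition preset (the held-limit protocol: the participant holds the
#' reached limit while samples accumulate). Manual Fugl-Meyer items are drawn
#' to match a target total profile. Ground-truth angles and targets are
#' retained in each record for recovery tests.
#'
#' Group defaults (means and SDs): abduction 108.51 +/- 19.67 (control) vs
#' 81.60 +/- 26.94 degrees (study); elbow flexion limit 100.85 +/- 37.88 vs
#' 116.15 +/- 44.09 degrees included; Fugl-Meyer total 65 +/- 1 vs 56 +/- 10.
#'
#' @param n_participants Number of records (>= 1).
#' @param group `"control"` or `"study"`.
#' @param fma_profile Optional list with `mean` and `sd` of the target
#'   Fugl-Meyer total; defaults per group as above.
#' @param seed Integer seed.
#' @param distance,illuminance Acquisition preset (default 2 m, 73 lx).
#' @param n_frames Frames per measurement stream (default 30).
#' @param abduction_mean,abduction_sd,flexion_mean,flexion_sd Optional
#'   overrides of the group angle distributions (degrees).
#' @return List of `participant_record` objects.
#' @export
simulate_cohort <- function(n_participants, group = c("control", "study"),
                            fma_profile = NULL, seed = 1,
                            distance = 2, illuminance = 73, n_frames = 30,
                            abduction_mean = NULL, abduction_sd = NULL,
                            flexion_mean = NULL, flexion_sd = NULL) {
  group <- match.arg(group)
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  defaults <- list(
    control = list(ab = c(108.51, 19.67), fl = c(100.85, 37.88),
                   fma = list(mean = 65, sd = 1)),
    study   = list(ab = c(81.60, 26.94), fl = c(116.15, 44.09),
                   fma = list(mean = 56, sd = 10)))[[group]]
  if (is.null(abduction_mean)) abduction_mean <- defaults$ab[1]
  if (is.null(abduction_sd)) abduction_sd <- defaults$ab[2]
  if (is.null(flexion_mean)) flexion_mean <- defaults$fl[1]
  if (is.null(flexion_sd)) flexion_sd <- defaults$fl[2]
  if (is.null(fma_profile)) fma_profile <- defaults$fma
  noise <- condition_noise_params(distance, illuminance)
  set.seed(seed)
  clamp <- function(x, lo = 5, hi = 180) pmin(hi, pmax(lo, x))
  records <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    id <- sprintf("%s-%02d", toupper(substr(group, 1, 1)), i)
    ca <- sample(4:12, 1)
    truth <- list(); streams <- list()
    for (side in c("left", "right")) {
      ab_true <- clamp(stats::rnorm(1, abduction_mean, abduction_sd))
      fl_true <- clamp(stats::rnorm(1, flexion_mean, flexion_sd))
      truth[[side]] <- list(abduction = ab_true, flexion = fl_true)
      seed_ab <- (seed * 1000L + i * 10L +
                    if (side == "left") 1L else 2L) %% .Machine$integer.max
      streams[[side]] <- list(
        abduction = simulate_measurement_session(
          arm_pose(side, ab_true, 180), noise = noise, n_frames = n_frames,
          seed = seed_ab, distance = distance,
          metadata = list(participant = id, movement = "shoulder_abduction")),
        flexion = simulate_measurement_session(
          arm_pose(side, 10, fl_true), noise = noise, n_frames = n_frames,
          seed = seed_ab + 5L, distance = distance,
          metadata = list(participant = id, movement = "elbow_flexion")))
    }
    target <- round(stats::rnorm(1, fma_profile$mean, fma_profile$sd))
    target <- min(66, max(0, target))
    manual <- .draw_manual_items(target)
    records[[i]] <- structure(
      list(id = id, group = group, chronological_age = ca,
           mental_age = if (group == "study") max(3, ca - sample(0:4, 1)) else ca,
           macs = if (group == "study") sample(c("I", "II"), 1) else NA,
           gmfcs = if (group == "study") sample(c("I", "II"), 1) else NA,
           streams = streams, manual_sheet = manual,
           truth = c(truth, list(fma_target_total = target))),
      class = "participant_record")
  }
  records
}

# Draw the 30 manual item scores so their subtotal tracks target * 30/33.
.draw_manual_items <- function(target_total) {
  sheet <- fma_sheet_template()
  manual <- sheet[sheet$mode == "manual", ]
  subtotal <- round(target_total * nrow(manual) / 33)
  subtotal <- min(2L * nrow(manual), max(0L, subtotal))
  scores <- rep(2L, nrow(manual))
  deficit <- 2L * nrow(manual) - subtotal
  while (deficit > 0L) {
    idx <- which(scores > 0L)
    k <- idx[sample.int(length(idx), 1)]
    scores[k] <- scores[k] - 1L
    deficit <- deficit - 1L
  }
  manual$score <- scores
  manual
}
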