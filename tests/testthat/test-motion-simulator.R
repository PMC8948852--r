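test_that("identity and orthogonal poses re-measure exactly", {
  hang <- pose_to_skeleton(arm_pose("right", 0, 180))
  expect_equal(joint_angle(hang, "shoulder_abduction", "right")$theta, 0,
               tolerance = 1e-9)
  expect_equal(joint_angle(hang, "elbow_flexion", "right")$theta, 180,
               tolerance = 1e-9)
  ninety <- pose_to_skeleton(arm_pose("right", 90, 180))
  expect_equal(joint_angle(ninety, "shoulder_abduction", "right")$theta, 90,
               tolerance = 1e-9)
})

test_that("pose validation rejects out-of-range angles", {
  expect_error(arm_pose("right", -1), "\\[0, 180\\]")
  expect_error(arm_pose("right", 90, 181), "\\[0, 180\\]")
  expect_error(default_anthropometry(upper_arm_length = 0), "> 0")
})

test_that("calibrated presets map condition to bias and SD", {
  p <- condition_noise_params(2, 73)
  expect_equal(p$angle_bias, 1.65)
  expect_equal(p$angle_sd, 2.06)
  p2 <- condition_noise_params(1, 73)
  expect_equal(p2$angle_bias, 21.32)
  expect_equal(p2$angle_sd, 4.01)
  p3 <- condition_noise_params(2, 7)
  expect_equal(p3$angle_bias, -0.26)
  expect_equal(p3$angle_sd, 2.94)
  # remaining presets
  expect_equal(condition_noise_params(1, 7)$angle_bias, 4.19)
  expect_equal(condition_noise_params(3, 7)$angle_sd, 4.77)
  expect_equal(condition_noise_params(3, 73)$angle_bias, 5.96)
  expect_error(condition_noise_params(2.5, 73), "presets")
})

test_that("zero-noise sessions are exact and seeded sessions deterministic", {
  st <- simulate_measurement_session(arm_pose("right", 90),
                                     noise = noise_model(0, 0, 0),
                                     n_frames = 30, seed = 5)
  th <- angle_series(st, "shoulder_abduction", "right")$measurements$theta_deg
  expect_equal(th, rep(90, 30), tolerance = 1e-9)

  a <- simulate_measurement_session(arm_pose("left", 70, 120),
                                    noise = condition_noise_params(2, 73),
                                    seed = 42)
  b <- simulate_measurement_session(arm_pose("left", 70, 120),
                                    noise = condition_noise_params(2, 73),
                                    seed = 42)
  expect_identical(lapply(a$frames, `[[`, "positions"),
                   lapply(b$frames, `[[`, "positions"))
  expect_error(simulate_measurement_session(list(), seed = 1),
               "empty trajectory")
})

test_that("trajectories interpolate between poses", {
  traj <- list(arm_pose("right", 0, 180), arm_pose("right", 120, 180))
  st <- simulate_measurement_session(traj, noise = noise_model(0, 0, 0),
                                     n_frames = 31, seed = 1)
  th <- angle_series(st, "shoulder_abduction", "right")$measurements$theta_deg
  expect_equal(th, seq(0, 120, length.out = 31), tolerance = 1e-6)
  expect_error(simulate_measurement_session(
    list(arm_pose("right", 0), arm_pose("left", 10)), seed = 1), "same side")
})

test_that("simulated cohorts have the right shape, ordering and determinism", {
  ctrl <- simulate_cohort(6, "control", seed = 7, n_frames = 30)
  expect_length(ctrl, 6)
  for (rec in ctrl) {
    expect_s3_class(rec, "participant_record")
    for (side in c("left", "right")) {
      expect_length(rec$streams[[side]]$abduction, 30)
      expect_length(rec$streams[[side]]$flexion, 30)
    }
    expect_equal(nrow(rec$manual_sheet), 30)
  }

  # construction implies ordering: a lowered study abduction ceiling
  study <- simulate_cohort(6, "study", seed = 7, n_frames = 30)
  ab_truth <- function(recs)
    mean(unlist(lapply(recs, function(r)
      c(r$truth$left$abduction, r$truth$right$abduction))))
  expect_lt(ab_truth(study), ab_truth(ctrl))

  again <- simulate_cohort(6, "control", seed = 7, n_frames = 30)
  expect_identical(lapply(again, `[[`, "truth"), lapply(ctrl, `[[`, "truth"))
  expect_identical(again[[3]]$streams$left$abduction$frames[[1]]$positions,
                   ctrl[[3]]$streams$left$abduction$frames[[1]]$positions)
})

test_that("noise injection is self-consistent with its preset (Monte Carlo)", {
  # angular path only (no positional jitter): replicate 90-degree sessions
  # under the 2 m / 73 lx preset and recover its bias and SD
  nm <- condition_noise_params(2, 73, positional_jitter_sd = 0)
  th <- unlist(lapply(1:120, function(i) {
    st <- simulate_measurement_session(arm_pose("right", 90), noise = nm,
                                       n_frames = 30, seed = 9000 + i)
    angle_series(st, "shoulder_abduction", "right")$measurements$theta_deg
  }))
  n <- length(th)
  expect_equal(mean(th), 91.65, tolerance = 3 * 2.06 / sqrt(n) / 91.65 + 1e-4)
  expect_equal(sd(th), 2.06, tolerance = 0.05)
})
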