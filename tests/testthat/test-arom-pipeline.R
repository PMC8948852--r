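# Build an angle_series directly from a numeric vector, bypassing streams.
series_of <- function(theta, movement = "shoulder_abduction", side = "right") {
  structure(list(
    measurements = data.frame(frame_index = seq_along(theta) - 1L,
                              theta_deg = theta),
    excluded = data.frame(frame_index = integer(0), reason = character(0)),
    movement = movement, side = side), class = "angle_series")
}

test_that("median smoothing: identity at window 1, spike removal, range preserved", {
  s <- series_of(c(88, 91, 90, 89.5, 92, 90.2))
  expect_equal(smooth_series(s, 1)$measurements, s$measurements)
  expect_equal(smooth_series(series_of(rep(90, 10)), 5)$measurements$theta_deg,
               rep(90, 10))
  # single-frame spike is removed by the centered window-5 median
  sp <- smooth_series(series_of(c(90, 90, 140, 90, 90)), 5)
  expect_equal(sp$measurements$theta_deg[3], 90)
  expect_error(smooth_series(s, 4), "odd")
  expect_error(smooth_series(s, 0), "odd")

  set.seed(15)
  for (k in 1:20) {
    y <- runif(sample(5:40, 1), 0, 180)
    sm <- smooth_series(series_of(y), sample(c(3, 5, 7), 1))$measurements$theta_deg
    expect_gte(min(sm), min(y) - 1e-12)
    expect_lte(max(sm), max(y) + 1e-12)
  }
})

test_that("AROM extraction: constants, ramps, monotonicity under appended frames", {
  cst <- extract_arom(series_of(rep(90, 30)))
  expect_equal(cst$arom, 90)
  expect_equal(cst$mean, 90)
  expect_equal(cst$sd, 0)
  expect_equal(cst$n_used, 30)

  ramp <- extract_arom(series_of(seq(0, 120, length.out = 30)), window = 1)
  expect_equal(ramp$arom, 120)

  set.seed(16)
  y <- runif(25, 20, 150)
  base <- extract_arom(series_of(y))$arom
  for (extra in list(10, c(40, 170), runif(5, 0, 180))) {
    grown <- extract_arom(series_of(c(y, extra)))$arom
    expect_gte(grown, base - 1e-12)
  }

  one <- extract_arom(series_of(42))
  expect_equal(one$arom, 42)
  expect_true(is.na(one$sd))
})

test_that("simulated constant-pose replicate sessions recover the preset mean", {
  nm <- condition_noise_params(2, 73, positional_jitter_sd = 0)
  means <- vapply(1:100, function(i) {
    st <- simulate_measurement_session(arm_pose("right", 90), noise = nm,
                                       n_frames = 30, seed = 4000 + i)
    extract_arom(angle_series(st, "shoulder_abduction", "right"))$mean
  }, numeric(1))
  # replicate session means average near true + bias = 91.65
  expect_equal(mean(means), 91.65, tolerance = 3 * 2.06 / sqrt(3000) / 91.65)
})

test_that("accuracy rows: absolute/relative error definitions and rounding", {
  r <- accuracy_row(30.549, 30)
  expect_equal(r$absolute_error, 0.549)
  expect_equal(r$relative_error, 1.83)
  r2 <- accuracy_row(45.540, 45)
  expect_equal(r2$absolute_error, 0.540)
  expect_equal(r2$relative_error, 1.20)
  r3 <- accuracy_row(90, 90)
  expect_equal(r3$absolute_error, 0)
  expect_equal(r3$relative_error, 0)
  expect_error(accuracy_row(10, 0), "reference")

  # truncation mode: 0.546/120 -> 0.455% prints as 0.45
  expect_equal(accuracy_row(120.546, 120, "truncate")$relative_error, 0.45)
  expect_equal(accuracy_row(120.546, 120, "half_up")$relative_error, 0.46)
})

test_that("bundled bench table: error columns recompute and stay under 1 degree", {
  bench <- fixed_angle_bench()
  expect_equal(nrow(bench), 16)
  acc <- accuracy_table(bench$measured_mean_deg, bench$reference_deg,
                        round_mode = "truncate")
  expect_true(all(acc$absolute_error < 1))       # the sub-degree headline
  expect_equal(max(acc$absolute_error), 0.876)
  # the 60-degree right-shoulder row of the bundled table carries a
  # typographic 0.001 inconsistency between its mean and error columns;
  # every other row recomputes exactly under truncation of the relative error
  printed_abs <- c(0.549, 0.005, 0.425, 0.546, 0.664, 0.624, 0.449, 0.548,
                   0.257, 0.590, 0.514, 0.876, 0.540, 0.504, 0.511, 0.603)
  printed_rel <- c(1.83, 0.00, 0.47, 0.45, 1.47, 0.69, 0.33, 0.30,
                   0.85, 0.98, 0.57, 0.73, 1.20, 0.56, 0.37, 0.33)
  consistent <- seq_len(16)[-2]
  expect_equal(acc$absolute_error[consistent], printed_abs[consistent])
  expect_equal(acc$relative_error[consistent], printed_rel[consistent])
  expect_equal(acc$absolute_error[2], 0.006)
})

test_that("half-up rounding helper rounds .5 away from zero", {
  expect_equal(kinarom:::round_half_up(2.5), 3)
  expect_equal(kinarom:::round_half_up(77.775, 2), 77.78)
  expect_equal(kinarom:::round_half_up(-2.5), -3)
  expect_equal(kinarom:::trunc_digits(1.4756, 2), 1.47)
})
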