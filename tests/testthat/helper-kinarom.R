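# Shared fixtures and independent oracles for the test suite.

# Clean zero-noise constant-pose stream.
clean_stream <- function(n = 30, side = "right", abduction = 90,
                         elbow = 180, seed = 1) {
  simulate_measurement_session(arm_pose(side, abduction, elbow),
                               noise = noise_model(0, 0, 0),
                               n_frames = n, seed = seed)
}

# Independent angle oracle: atan2 of |cross| and dot, never arccos.
angle_atan2 <- function(a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

# Independent rank-sum oracle: brute-force over all 2^N subsets (bitmask),
# keeping those of size nx; two-sided p by symmetric deviation of the rank
# sum about its mean. Written without combn so it shares no code with the
# implementation's enumeration.
ranksum_bruteforce_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(nx)])
  muW <- nx * (N + 1) / 2
  Ws <- c()
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[1:N]
    if (sum(bits) == nx) Ws <- c(Ws, sum(r[bits == 1]))
  }
  mean(abs(Ws - muW) >= abs(W_obs - muW) - 1e-9)
}

# Reflect a frame across the body midline (x = 0), swapping left/right
# joint labels so the result is again an anatomically labelled frame.
mirror_frame <- function(frame) {
  pos <- frame$positions
  pos[, "x"] <- -pos[, "x"]
  nm <- rownames(pos)
  swapped <- nm
  swapped[grepl("Left$", nm)] <- sub("Left$", "Right", nm[grepl("Left$", nm)])
  swapped[grepl("Right$", nm)] <- sub("Right$", "Left", nm[grepl("Right$", nm)])
  rownames(pos) <- swapped
  trk <- frame$tracking
  names(trk) <- swapped[match(names(trk), nm)]
  skeleton_frame(frame$frame_index, pos, timestamp = frame$timestamp,
                 tracking = trk)
}

# Complete manual item set, all at a given score.
manual_items_all <- function(score = 2L) {
  tmpl <- fma_sheet_template()
  m <- tmpl[tmpl$mode == "manual", c("item_id", "score")]
  m$score <- score
  m
}

# Bundled 18 + 18 cohort split by group.
fixture_cohort <- function() {
  co <- read_cohort()
  split(co, co$group)
}
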