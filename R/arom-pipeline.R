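# Session reduction: angle series -> AROM summary; accuracy vs goniometer
# reference angles.

# Rounding helpers. Clinical tables round half-up (2.5 -> 3), which differs
# from R's round() (banker's); a truncation mode is provided because bundled
# bench-table relative errors follow truncation to 2 decimals.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

trunc_digits <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

#' Running-median smoothing of an angle series
#'
#' Centered running median of width `window`; at the edges the window shrinks
#' symmetrically to fit, so the first and last points use what remains of the
#' centered window. `window = 1` is the identity. Median smoothing suppresses
#' single-frame spikes (depth-sensor "flying pixels") without widening the
#' series range.
#'
#' @param series An [angle_series()].
#' @param window Odd positive integer window width (default 5).
#' @return A smoothed `angle_series` (exclusions carried through unchanged).
#' @export
smooth_series <- function(series, window = 5) {
  stopifnot(inherits(series, "angle_series"))
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer", call. = FALSE)
  y <- series$measurements$theta_deg
  n <- length(y)
  h <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    stats::median(y[lo:hi])
  }, numeric(1))
  series$measurements$theta_deg <- out
  series
}

#' Reduce a measurement session to an AROM summary
#'
#' The active range of motion (AROM) of a session is taken as the maximum of
#' the median-smoothed angle series: robust to single-frame spikes while
#' capturing the active limit actually reached. The mean and sample SD
#' (denominator n - 1) of the smoothed series are reported alongside, so a
#' mean-based session value can be compared as well.
#'
#' @param series An [angle_series()].
#' @param window Smoothing window passed to [smooth_series()]; 1 disables
#'   smoothing.
#' @return Object of class `arom_result`: list with `movement`, `side`,
#'   `arom`, `mean`, `sd` (NA when only one frame), `n_used`, `n_excluded`.
#' @export
#' @examples
#' st <- simulate_measurement_session(arm_pose("right", 90), seed = 1,
#'                                    noise = noise_model(0, 0, 0))
#' extract_arom(angle_series(st, "shoulder_abduction", "right"))
extract_arom <- function(series, window = 5) {
  stopifnot(inherits(series, "angle_series"))
  n <- nrow(series$measurements)
  if (n == 0L) stop("empty series", call. = FALSE)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  sm <- smooth_series(series, window = window)
  y <- sm$measurements$theta_deg
  structure(list(movement = series$movement, side = series$side,
                 arom = max(y),
                 mean = mean(y),
                 sd = if (n >= 2) stats::sd(y) else NA_real_,
                 n_used = n,
                 n_excluded = nrow(series$excluded)),
            class = "arom_result")
}

#' @export
print.arom_result <- function(x, ...) {
  cat(sprintf("<arom_result: %s/%s arom=%.2f mean=%.2f sd=%s n=%d (+%d excluded)>\n",
              x$movement, x$side, x$arom, x$mean,
              ifelse(is.na(x$sd), "NA", sprintf("%.2f", x$sd)),
              x$n_used, x$n_excluded))
  invisible(x)
}

#' Accuracy of a measured mean against a goniometer reference angle
#'
#' Absolute error |measured - reference| rounded to 3 decimals and relative
#' error (absolute / reference * 100) rounded to 2 decimals. `round_mode`
#' selects half-up rounding (default) or truncation of the relative error;
#' the bundled bench table's printed relative errors follow truncation.
#'
#' @param measured_mean Mean measured angle, degrees.
#' @param reference Goniometer-set reference angle, degrees; must be > 0.
#' @param round_mode `"half_up"` or `"truncate"` (applies to the relative
#'   error; the absolute error always rounds half-up to 3 decimals).
#' @return data.frame row: `reference`, `measured_mean`, `absolute_error`,
#'   `relative_error`.
#' @export
#' @examples
#' accuracy_row(30.549, 30)  # absolute 0.549, relative 1.83
accuracy_row <- function(measured_mean, reference,
                         round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  if (!is.finite(reference) || reference <= 0)
    stop("relative error undefined: reference must be > 0", call. = FALSE)
  abs_err <- round_half_up(abs(measured_mean - reference), 3)
  rel <- abs_err / reference * 100
  rel_err <- if (round_mode == "half_up") round_half_up(rel, 2) else
    trunc_digits(rel, 2)
  data.frame(reference = reference, measured_mean = measured_mean,
             absolute_error = abs_err, relative_error = rel_err)
}

#' Accuracy table for a set of reference/measured pairs
#'
#' @param measured_means,references Equal-length numeric vectors.
#' @param round_mode See [accuracy_row()].
#' @return data.frame with one [accuracy_row()] per pair.
#' @export
accuracy_table <- function(measured_means, references,
                           round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  stopifnot(length(measured_means) == length(references))
  do.call(rbind, Map(function(m, r) accuracy_row(m, r, round_mode),
                     measured_means, references))
}

#' Bundled fixed-angle bench validation dataset
#'
#' Goniometer-referenced bench test of the measurement system: 30-sample mean
#' measured angles at fixed goniometer-marked reference angles (shoulder
#' abduction at 30/60/90/120 degrees, elbow at 45/90/135/180 degrees, both
#' sides), as shipped with the package.
#'
#' @return data.frame with columns `side`, `movement`, `reference_deg`,
#'   `measured_mean_deg`.
#' @export
fixed_angle_bench <- function() {
  utils::read.csv(system.file("extdata", "fixed_angle_bench.csv",
                              package = "kinarom"),
                  stringsAsFactors = FALSE)
}
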