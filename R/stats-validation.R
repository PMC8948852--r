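# Group summaries, Wilcoxon rank-sum comparison (Mann-Whitney U), and
# cohort capacity-classification shares.
#
# The rank-sum test is authored here rather than delegated because the exact
# method must enumerate all C(nx+ny, nx) group assignments on the mid-rank
# scale (stats::wilcox.test abandons exactness under ties); the tie-corrected,
# continuity-corrected normal approximation matches wilcox.test and is
# cross-checked against it in the test suite.

#' Mean and sample SD of a group, rounded half-up
#'
#' @param values Numeric vector, length >= 1.
#' @param decimals Decimal places for reporting (half-up rounding).
#' @return List of class `summary_stats`: `n`, `mean`, `sd` (sample,
#'   denominator n - 1; `NA` for a single value), `decimals`.
#' @export
#' @examples
#' group_summary(c(4, 5, 5, 6, 6, 8, 8, 8, 9, 9, 9, 9, 9, 9, 10, 11, 12, 12))
group_summary <- function(values, decimals = 2) {
  if (length(values) == 0L) stop("empty group", call. = FALSE)
  structure(list(n = length(values),
                 mean = round_half_up(mean(values), decimals),
                 sd = if (length(values) >= 2)
                   round_half_up(stats::sd(values), decimals) else NA_real_,
                 decimals = decimals),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n=%d  %s +/- %s\n", x$n, format(x$mean),
              ifelse(is.na(x$sd), "NA", format(x$sd))))
  invisible(x)
}

# Rank-sum statistic pieces shared by both methods.
.ranksum_setup <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))              # mid-ranks under ties
  W <- sum(r[seq_len(nx)])        # rank sum of x
  U <- W - nx * (nx + 1) / 2      # Mann-Whitney U of x
  list(nx = nx, ny = ny, N = N, r = r, W = W, U = U,
       muW = nx * (N + 1) / 2)
}

#' Wilcoxon rank-sum test (Mann-Whitney U)
#'
#' Two-sided two-sample location test on ranks, with mid-ranks for ties.
#' The exact method enumerates all `choose(nx+ny, nx)` assignments of the
#' pooled mid-ranks to group x and computes
#' `p = P(|W - mu_W| >= |w_obs - mu_W|)` under that permutation distribution
#' (symmetric about `mu_W`, so this equals the usual two-sided tail sum).
#' The normal approximation uses the tie-corrected variance
#' `nx*ny/12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))` and a 0.5 continuity
#' correction. `method = "auto"` picks exact for `nx + ny <= 16`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @param alpha Significance level for the `h0_rejected` flag (default 0.05).
#' @return List of class `rank_sum_result`: `u_statistic`, `rank_sum`,
#'   `p_two_sided`, `method`, `h0_rejected`, `alpha`, `nx`, `ny`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), method = "exact")$p_two_sided  # 1/3
rank_sum_test <- function(x, y, method = c("auto", "exact", "normal_approx"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  s <- .ranksum_setup(x, y)
  if (method == "auto")
    method <- if (s$N <= 16) "exact" else "normal_approx"
  if (all(c(x, y) == c(x, y)[1])) {
    p <- 1
  } else if (method == "exact") {
    # enumerate every assignment of nx of the N mid-ranks to group x
    combs <- utils::combn(s$N, s$nx)
    Ws <- colSums(matrix(s$r[combs], nrow = s$nx))
    dev <- abs(s$W - s$muW)
    p <- mean(abs(Ws - s$muW) >= dev - 1e-9)
  } else {
    ties <- table(s$r)
    sigma2 <- s$nx * s$ny / 12 *
      ((s$N + 1) - sum(ties^3 - ties) / (s$N * (s$N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      muU <- s$nx * s$ny / 2
      z <- s$U - muU
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(u_statistic = s$U, rank_sum = s$W, p_two_sided = p,
                 method = method, h0_rejected = (p < alpha), alpha = alpha,
                 nx = s$nx, ny = s$ny),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("rank-sum (%s): U=%g W=%g p=%.4g  H0 %s at alpha=%g\n",
              x$method, x$u_statistic, x$rank_sum, x$p_two_sided,
              ifelse(x$h0_rejected, "rejected", "not rejected"), x$alpha))
  invisible(x)
}

#' Compare two groups: summaries plus rank-sum test
#'
#' @param a,b Numeric vectors.
#' @param label Report-row label.
#' @param alpha Significance level.
#' @param decimals Rounding of the reported means/SDs.
#' @param method Passed to [rank_sum_test()].
#' @return One-row data.frame: `label`, `n_a`, `mean_a`, `sd_a`, `n_b`,
#'   `mean_b`, `sd_b`, `u_statistic`, `p_value`, `h0` (1 = rejected).
#' @export
compare_groups <- function(a, b, label = "", alpha = 0.05, decimals = 2,
                           method = "auto") {
  sa <- group_summary(a, decimals); sb <- group_summary(b, decimals)
  rs <- rank_sum_test(a, b, method = method, alpha = alpha)
  data.frame(label = label,
             n_a = sa$n, mean_a = sa$mean, sd_a = sa$sd,
             n_b = sb$n, mean_b = sb$mean, sd_b = sb$sd,
             u_statistic = rs$u_statistic, p_value = rs$p_two_sided,
             h0 = as.integer(rs$h0_rejected),
             stringsAsFactors = FALSE)
}

#' Capacity-category shares of a cohort of total scores
#'
#' @param scores Integer totals in 0..66.
#' @param bands Band table from [capacity_bands()].
#' @return data.frame `category`, `count`, `percent` (half-up integer
#'   percents) covering every band category (zero counts included).
#' @export
#' @examples
#' cohort_classification_shares(c(66, 66, 40))
cohort_classification_shares <- function(scores,
                                         bands = capacity_bands("hybrid")) {
  if (any(scores < 0 | scores > 66))
    stop("scores must lie in 0..66", call. = FALSE)
  cats <- vapply(scores, classify_capacity, character(1), bands = bands)
  lev <- unique(bands$category)
  counts <- vapply(lev, function(cc) sum(cats == cc), integer(1))
  data.frame(category = lev, count = unname(counts),
             percent = round_half_up(unname(counts) / length(scores) * 100, 0),
             stringsAsFactors = FALSE)
}
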