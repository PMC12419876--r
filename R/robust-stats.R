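#' Median and interquartile range of a force sample
#'
#' Abscission forces are strongly right-skewed, so populations are summarised
#' by medians and interquartile ranges rather than means. The median is the
#' middle order statistic (mean of the middle two for even n); quartiles use
#' linear interpolation between order statistics (the default sample-quantile
#' convention, `type = 7`).
#'
#' @param x Numeric vector of forces, mN (n >= 1).
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))
#' @export
median_iqr <- function(x) {
  if (length(x) < 1 || any(!is.finite(x))) {
    abort("`x` must be a nonempty vector of finite values.")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the data `B` times with replacement, computes the statistic on
#' each resample, sorts the `B` values and returns the 25th and 975th order
#' statistics (for the default `B = 1000`), i.e. an approximate 95% percentile
#' interval. The interval bounds are literally those order statistics, so `B`
#' must be at least 40 for them to exist at the 2.5%/97.5% depths. The input
#' is sorted before resampling, making the interval invariant under
#' permutation of the sample for a given seed.
#'
#' @param x Numeric vector (n >= 2).
#' @param statistic Function of a numeric vector returning one number;
#'   defaults to the median.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed; the interval is reproducible for a fixed seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' bootstrap_ci(rlnorm(50), seed = 1)
#' @export
bootstrap_ci <- function(x, statistic = median, B = 1000, seed = 0) {
  if (length(x) < 2) abort("Need at least two observations to bootstrap.")
  if (B < 40) {
    abort("`B` must be >= 40 for the 2.5%/97.5% order statistics to exist.")
  }
  x <- sort(x)
  n <- length(x)
  lo_idx <- floor(0.025 * B)
  hi_idx <- ceiling(0.975 * B)
  stats <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    apply(idx, 2, function(j) statistic(x[j]))
  })
  stats <- sort(stats)
  c(lo = stats[lo_idx], hi = stats[hi_idx])
}

#' Wilcoxon rank-sum test between two force populations
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. When both groups are small
#' (`min(n_x, n_y) <= 10`) and the pooled data are tie-free the p-value is
#' exact, from the full null distribution of rank assignments; otherwise the
#' normal approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @return A one-row tibble: `statistic` (the Mann-Whitney statistic for `x`),
#'   `p_value`, `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("Both samples must be nonempty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 10 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(ht$p.value, 1),
    method = if (exact) "exact" else "normal",
    n_x = length(x), n_y = length(y)
  )
}

#' Summarise force measurements per experiment and angle bin
#'
#' Groups a force-measurement table by `experiment` and `angle_bin` and
#' reports, per bin, the robust summary (median, quartiles) and a percentile-
#' bootstrap confidence interval for the median, mirroring the study's summary
#' table. Bootstrap seeds are derived deterministically from `seed` and the
#' bin index so reordering input rows does not change the result.
#'
#' @param samples Data frame with columns `experiment`, `angle_bin`,
#'   `force_mN`.
#' @param B Bootstrap resamples per bin.
#' @param seed Base integer seed.
#' @return A tibble with columns `experiment`, `angle_bin`, `n`, `median_mN`,
#'   `ci_lo`, `ci_hi`, `q1_mN`, `q3_mN`.
#' @examples
#' summarize_forces(sample_forces(seed = 1))
#' @export
summarize_forces <- function(samples, B = 1000, seed = 0) {
  check_force_table(samples)
  grouped <- samples |>
    dplyr::arrange(.data$experiment, .data$angle_bin) |>
    dplyr::group_by(.data$experiment, .data$angle_bin) |>
    dplyr::summarise(forces = list(.data$force_mN), .groups = "drop")
  stats <- purrr::map_dfr(grouped$forces, median_iqr)
  cis <- purrr::imap(grouped$forces, function(f, i) {
    if (length(f) >= 2) {
      bootstrap_ci(f, median, B = B, seed = seed + i)
    } else {
      c(lo = NA_real_, hi = NA_real_)
    }
  })
  tibble(
    experiment = grouped$experiment, angle_bin = grouped$angle_bin,
    n = stats$n, median_mN = stats$median,
    ci_lo = purrr::map_dbl(cis, "lo"),
    ci_hi = purrr::map_dbl(cis, "hi"),
    q1_mN = stats$q1, q3_mN = stats$q3
  )
}

#' All pairwise direction/angle comparisons within each experiment
#'
#' For each experiment in the table, runs [wilcoxon_ranksum()] on every pair
#' of angle bins (three bins per experiment gives three comparisons, nine in
#' total for the full design). P-values are reported unadjusted. A bin named
#' in `expected_bins` but absent from the data yields an explicit row with
#' `NA` results rather than being skipped silently.
#'
#' @param samples Data frame with columns `experiment`, `angle_bin`,
#'   `force_mN`.
#' @param expected_bins Optional data frame with columns `experiment`,
#'   `angle_bin` naming the bins that must be present; defaults to the bins in
#'   the data.
#' @return A tibble with columns `experiment`, `bin_a`, `bin_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `method`.
#' @examples
#' pairwise_direction_tests(sample_forces(seed = 1))
#' @export
pairwise_direction_tests <- function(samples, expected_bins = NULL) {
  check_force_table(samples)
  if (is.null(expected_bins)) {
    expected_bins <- dplyr::distinct(samples, .data$experiment, .data$angle_bin)
  }
  purrr::map_dfr(unique(expected_bins$experiment), function(exp_label) {
    bins <- expected_bins$angle_bin[expected_bins$experiment == exp_label]
    if (length(bins) < 2) return(tibble())
    pairs <- utils::combn(bins, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      xa <- samples$force_mN[samples$experiment == exp_label &
                               samples$angle_bin == pr[1]]
      xb <- samples$force_mN[samples$experiment == exp_label &
                               samples$angle_bin == pr[2]]
      if (length(xa) == 0 || length(xb) == 0) {
        return(tibble(experiment = exp_label, bin_a = pr[1], bin_b = pr[2],
                      n_a = length(xa), n_b = length(xb),
                      statistic = NA_real_, p_value = NA_real_,
                      method = "missing bin"))
      }
      res <- wilcoxon_ranksum(xa, xb)
      tibble(experiment = exp_label, bin_a = pr[1], bin_b = pr[2],
             n_a = res$n_x, n_b = res$n_y,
             statistic = res$statistic, p_value = res$p_value,
             method = res$method)
    })
  })
}

check_force_table <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("experiment", "angle_bin", "force_mN") %in% names(samples))) {
    abort("Expected a force table with columns experiment, angle_bin, force_mN.")
  }
  if (nrow(samples) > 0 &&
      (any(!is.finite(samples$force_mN)) || any(samples$force_mN <= 0))) {
    abort("Forces must be finite and strictly positive (mN).")
  }
  invisible(samples)
}
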