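#' Reference angle-bin specifications for the force experiments
#'
#' The nine experiment/angle bins of the abscission-force study with their
#' published medians and interquartile ranges (mN), plus per-bin sample sizes.
#' Per-bin counts were not published; each experiment's printed total (128
#' sideways, 75 azimuth, 90 elevation) is split evenly over its three bins.
#' These rows calibrate the synthetic log-normal force generator.
#'
#' @return A tibble with columns `experiment`, `angle_bin`, `median_mN`,
#'   `q1_mN`, `q3_mN`, `n`.
#' @examples
#' force_bin_specs()
#' @export
force_bin_specs <- function() {
  tibble(
    experiment = rep(c("sideways", "azimuth", "elevation"), each = 3),
    angle_bin = c("0", "-90", "+90",
                  "0", "~45", "~90",
                  "0", "acute", "obtuse"),
    median_mN = c(45, 1.3, 0.26,
                  54, 2.3, 0.71,
                  47, 2.0, 0.30),
    q1_mN = c(23, 0.7, 0.20,
              28, 1.0, 0.47,
              28, 0.8, 0.25),
    q3_mN = c(68, 3.2, 0.37,
              83, 5.1, 1.08,
              75, 7.1, 0.44),
    n = c(43L, 43L, 42L,
          25L, 25L, 25L,
          30L, 30L, 30L)
  )
}

#' Calibrate a log-normal distribution to a median and quartiles
#'
#' The force populations are right-skewed over orders of magnitude, which a
#' log-normal (multiplicative noise) model captures. Matching its median and
#' its log-scale interquartile spread to target values gives the closed form
#' `mu = log(median)` and `sigma = log(q3/q1) / (2 * qnorm(0.75))`. The
#' calibrated distribution reproduces the target median and the quartile
#' ratio `q3/q1` exactly; the two individual quartiles are reproduced exactly
#' too whenever the targets are log-symmetric (`median^2 = q1 * q3`), and to
#' within the targets' asymmetry otherwise -- a two-parameter family cannot
#' pin the median and both quartiles independently.
#'
#' @param median,q1,q3 Target median and quartiles (same units); vectors are
#'   recycled element-wise. Requires `0 < q1 < q3`.
#' @return A tibble with columns `mu` and `sigma` (log-scale mean and sd).
#' @examples
#' calibrate_lognormal(45, 23, 68)
#' @export
calibrate_lognormal <- function(median, q1, q3) {
  if (any(q1 <= 0) || any(median <= 0)) {
    abort("`median` and `q1` must be positive.")
  }
  if (any(q1 >= q3)) abort("Requires q1 < q3.")
  if (any(median < q1) || any(median > q3)) {
    abort("Requires q1 <= median <= q3.")
  }
  tibble(mu = log(median), sigma = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Generate synthetic abscission-force measurements
#'
#' Draws, for every bin of `bins`, `n` independent log-normal forces with the
#' parameters returned by [calibrate_lognormal()] for that bin's median and
#' quartiles. The result emulates the direction-binned, right-skewed load-cell
#' measurements of the pulling experiments and is deterministic for a fixed
#' seed.
#'
#' @param bins Bin specification table as from [force_bin_specs()] (columns
#'   `experiment`, `angle_bin`, `median_mN`, `q1_mN`, `q3_mN`, `n`).
#' @param seed Integer seed.
#' @return A tibble with columns `experiment`, `angle_bin`, `force_mN`; one
#'   row per simulated measurement, strictly positive forces.
#' @examples
#' head(sample_forces(seed = 1))
#' @export
sample_forces <- function(bins = force_bin_specs(), seed = 0) {
  stopifnot(is.data.frame(bins),
            all(c("experiment", "angle_bin", "median_mN",
                  "q1_mN", "q3_mN", "n") %in% names(bins)))
  cal <- calibrate_lognormal(bins$median_mN, bins$q1_mN, bins$q3_mN)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(bins)), function(i) {
      tibble(
        experiment = bins$experiment[i],
        angle_bin = bins$angle_bin[i],
        force_mN = rlnorm(bins$n[i], meanlog = cal$mu[i], sdlog = cal$sigma[i])
      )
    })
  })
}

#' Draw morphology parameter sets around the reference means
#'
#' Independent truncated-normal draws per morphological parameter, centred on
#' the reference means of [dandelion_morphology()]. `spread = "sd"` uses the
#' population standard deviations (emulating between-seed variation);
#' `spread = "se"` uses the bootstrapped standard errors of the means (the
#' spread relevant for propagating parameter uncertainty into model
#' predictions). Lengths are truncated to positive values and `k` to (0, 1];
#' the pedicle length `ell` is held constant.
#'
#' @param n Number of draws (>= 1).
#' @param morph Reference table in the format of [dandelion_morphology()].
#' @param spread `"sd"` or `"se"`.
#' @param ell Constant pedicle length, um.
#' @param seed Integer seed.
#' @return A tibble with `n` rows and columns `L`, `w`, `r`, `c`, `k`, `ell`.
#' @examples
#' sample_morphology(5, seed = 1)
#' @export
sample_morphology <- function(n, morph = dandelion_morphology(),
                              spread = c("sd", "se"), ell = 200, seed = 0) {
  if (n < 1) abort("`n` must be >= 1.")
  spread <- match.arg(spread)
  means <- setNames(morph$mean, morph$parameter)
  sds <- setNames(morph[[spread]], morph$parameter)
  draw_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
    if (sd == 0) return(rep(mean, n))
    out <- rnorm(n, mean, sd)
    bad <- which(out <= lower | out > upper)
    while (length(bad) > 0) {
      out[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[out[bad] <= lower | out[bad] > upper]
    }
    out
  }
  withr::with_seed(seed, {
    tibble(
      L = draw_trunc(n, means[["L"]], sds[["L"]]),
      w = draw_trunc(n, means[["w"]], sds[["w"]]),
      r = draw_trunc(n, means[["r"]], sds[["r"]]),
      c = draw_trunc(n, means[["c"]], sds[["c"]]),
      k = draw_trunc(n, means[["k"]], sds[["k"]], upper = 1),
      ell = rep(ell, n)
    )
  })
}

#' Read and write force-measurement CSV files
#'
#' The on-disk format is a UTF-8 comma-separated file with header
#' `experiment,angle_bin,force_mN` and `.` as the decimal mark. Reading
#' validates every row and names the offending line (header = line 1) on
#' malformed or non-positive forces; writing a zero-row table produces a
#' header-only file. A write followed by a read reproduces the table up to
#' numeric text round-trip.
#'
#' @param samples Force table with columns `experiment`, `angle_bin`,
#'   `force_mN`.
#' @param path File path.
#' @return `read_forces_csv()`: the force tibble. `write_forces_csv()`: the
#'   input, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_forces_csv(sample_forces(seed = 1), f)
#' head(read_forces_csv(f))
#' @export
write_forces_csv <- function(samples, path) {
  check_force_table(samples)
  readr::write_csv(samples[, c("experiment", "angle_bin", "force_mN")], path)
  invisible(samples)
}

#' @rdname write_forces_csv
#' @export
read_forces_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      experiment = readr::col_character(),
      angle_bin = readr::col_character(),
      force_mN = readr::col_double()
    )
  ))
  if (!identical(names(raw), c("experiment", "angle_bin", "force_mN"))) {
    abort("Expected header: experiment,angle_bin,force_mN.")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed force CSV at line %d: expected %s.",
                  probs$row[1], probs$expected[1]))
  }
  bad <- which(!is.finite(raw$force_mN) | raw$force_mN <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Non-positive or missing force at line %d.", bad[1] + 1L))
  }
  as_tibble(raw)
}
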