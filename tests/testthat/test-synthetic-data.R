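test_that("log-normal calibration inverts the median and quartiles exactly", {
  cal <- calibrate_lognormal(45, 23, 68)
  expect_equal(cal$mu, log(45))
  expect_equal(cal$mu, 3.807, tolerance = 1e-3)
  expect_equal(cal$sigma, 0.803, tolerance = 1e-3)

  cal2 <- calibrate_lognormal(0.26, 0.20, 0.37)
  expect_equal(cal2$sigma, log(1.85) / 1.349, tolerance = 1e-3)

  # the calibrated distribution reproduces the target median and quartile
  # ratio to machine precision, for every published bin
  bins <- force_bin_specs()
  cal_all <- calibrate_lognormal(bins$median_mN, bins$q1_mN, bins$q3_mN)
  expect_equal(qlnorm(0.5, cal_all$mu, cal_all$sigma), bins$median_mN)
  expect_equal(qlnorm(0.75, cal_all$mu, cal_all$sigma) /
                 qlnorm(0.25, cal_all$mu, cal_all$sigma),
               bins$q3_mN / bins$q1_mN)
  # a log-symmetric target is reproduced quartile by quartile
  sym <- calibrate_lognormal(20, 10, 40)
  expect_equal(qlnorm(c(0.25, 0.75), sym$mu, sym$sigma), c(10, 40))

  # vanishing spread collapses to a spike at the median
  expect_lt(calibrate_lognormal(1, 1 - 1e-9, 1 + 1e-9)$sigma, 1e-8)
  expect_error(calibrate_lognormal(1, 2, 2))
  expect_error(calibrate_lognormal(1, -1, 2))
})

test_that("calibration is confirmed by large-sample Monte Carlo recovery", {
  cal <- calibrate_lognormal(45, 23, 68)
  x <- withr::with_seed(6, rlnorm(2e5, cal$mu, cal$sigma))
  s <- median_iqr(x)
  expect_equal(s$median, 45, tolerance = 0.02)
  expect_equal(s$q3 / s$q1, 68 / 23, tolerance = 0.02)
})

test_that("force generator is seeded, binned and calibrated", {
  a <- sample_forces(seed = 3)
  b <- sample_forces(seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sample_forces(seed = 4)))

  specs <- force_bin_specs()
  expect_equal(nrow(a), sum(specs$n))
  expect_true(all(a$force_mN > 0))
  counts <- dplyr::count(a, experiment, angle_bin)
  expect_equal(nrow(counts), 9)

  # within every experiment the bin medians keep the printed ordering
  med <- summarize_forces(a, B = 50, seed = 1)
  med <- med[match(paste(specs$experiment, specs$angle_bin),
                   paste(med$experiment, med$angle_bin)), ]
  for (e in unique(specs$experiment)) {
    i <- specs$experiment == e
    expect_equal(order(med$median_mN[i]), order(specs$median_mN[i]))
  }

  # a large single bin recovers its target median closely
  big <- sample_forces(tibble::tibble(experiment = "sideways", angle_bin = "0",
                                      median_mN = 45, q1_mN = 23, q3_mN = 68,
                                      n = 10000L), seed = 5)
  expect_equal(median(big$force_mN), 45, tolerance = 0.02)
})

test_that("morphology draws are truncated and calibrated to the reference table", {
  fixed <- dandelion_morphology()
  fixed$sd <- 0
  det <- sample_morphology(5, morph = fixed, spread = "sd", seed = 1)
  expect_equal(det$c, rep(18.6, 5))
  expect_equal(det$L, rep(12400, 5))
  expect_equal(det$ell, rep(200, 5))

  draws <- sample_morphology(10000, seed = 2)
  expect_equal(mean(draws$c), 18.6, tolerance = 0.01)
  expect_true(all(draws$c > 0 & draws$k > 0 & draws$k <= 1))
  expect_identical(sample_morphology(50, seed = 7),
                   sample_morphology(50, seed = 7))
})

test_that("force CSV files round-trip and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- sample_forces(seed = 1)
  write_forces_csv(x, path)
  y <- read_forces_csv(path)
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-12)

  # zero rows produce a header-only file that reads back empty
  write_forces_csv(x[0, ], path)
  expect_equal(readLines(path), "experiment,angle_bin,force_mN")
  expect_equal(nrow(read_forces_csv(path)), 0)

  writeLines(c("experiment,angle_bin,force_mN",
               "sideways,0,12.5",
               "sideways,0,-3"), path)
  expect_error(read_forces_csv(path), "line 3")

  writeLines(c("experiment,angle_bin,force_mN",
               "sideways,0,not_a_number"), path)
  expect_error(read_forces_csv(path), "line 2")

  writeLines("a,b,c", path)
  expect_error(read_forces_csv(path), "header")
})

test_that("analysing a large synthetic dataset recovers the calibration", {
  specs <- force_bin_specs()
  specs$n <- rep(20000L, 9)
  samples <- sample_forces(specs, seed = 10)
  summ <- summarize_forces(samples, B = 50, seed = 1)
  summ <- summ[match(paste(specs$experiment, specs$angle_bin),
                     paste(summ$experiment, summ$angle_bin)), ]
  expect_true(all(abs(summ$median_mN - specs$median_mN) /
                    specs$median_mN < 0.05))
  tests <- pairwise_direction_tests(samples)
  expect_true(all(tests$p_value < 0.01))
})
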