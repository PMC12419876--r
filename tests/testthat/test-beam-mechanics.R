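p_ref <- morph_params()
beta_ref <- 25.9

test_that("neutral axis is the modulus-weighted centroid", {
  expect_equal(neutral_axis_offset(engaged_section(p_ref, "straight")), 0)

  # base weight vanishes in the stiff-pedicle limit
  stiff <- engaged_section(p_ref, "negative", beta = 1e9)
  expect_equal(neutral_axis_offset(stiff), 0, tolerance = 1e-6)

  neg <- engaged_section(p_ref, "negative", beta = beta_ref)
  delta <- neutral_axis_offset(neg)
  expect_lt(delta, 0)          # shifts toward the engaged scape-side tissue
  expect_lt(abs(delta), p_ref$c)
  expect_equal(delta, oracle_section_props(neg)$delta, tolerance = 5e-3)
})

test_that("composite second moment follows the parallel-axis theorem", {
  straight <- engaged_section(p_ref, "straight")
  expect_equal(section_moment(straight, about_x = 0),
               p_ref$k * pi * p_ref$c^4 / 4)

  neg <- engaged_section(p_ref, "negative", beta = beta_ref)
  delta <- neutral_axis_offset(neg)
  # minimal about the neutral axis
  for (shift in c(-10, -1, 1, 10)) {
    expect_gt(section_moment(neg, about_x = delta + shift),
              section_moment(neg))
  }
  expect_equal(section_moment(neg), oracle_section_props(neg)$I,
               tolerance = 5e-3)
})

test_that("composite sections agree with the quadrature oracle across random draws", {
  withr::local_seed(7)
  for (i in 1:15) {
    p <- random_morph()
    beta <- runif(1, 1, 200)
    dir <- sample(c("positive", "negative"), 1)
    sec <- engaged_section(p, dir, beta = beta)
    o <- oracle_section_props(sec)
    expect_equal(neutral_axis_offset(sec), o$delta, tolerance = 5e-3)
    expect_equal(section_moment(sec), o$I, tolerance = 5e-3)
    expect_equal(y_max_of(sec, p), p$c + abs(o$delta), tolerance = 5e-3)
  }
})

test_that("y_max is measured to the pedicle edge opposite the pull", {
  expect_equal(y_max_of(engaged_section(p_ref, "straight"), p_ref), p_ref$c)
  expect_equal(y_max_of(engaged_section(p_ref, "positive", beta = 1e9), p_ref),
               p_ref$c, tolerance = 1e-6)
  y_neg <- y_max_of(engaged_section(p_ref, "negative", beta = beta_ref), p_ref)
  expect_gt(y_neg, p_ref$c)
  expect_lt(y_neg, 2 * p_ref$c)
})

test_that("moment arm is the transverse projection of the whole lever", {
  expect_equal(moment_arm(p_ref, pull_scenario("positive", 40, 40)), 0)
  expect_equal(moment_arm(p_ref, pull_scenario("negative", 90, 0)),
               p_ref$L + p_ref$ell)
  expect_equal(moment_arm(p_ref, pull_scenario("positive", 90, 15)),
               12600 * sin(75 * pi / 180))
  expect_error(pull_scenario("positive", theta1 = 10, theta2 = 20),
               class = "abscissr_invalid_scenario")
})

test_that("stress components split the load into tension and bending", {
  A <- p_ref$k * pi * p_ref$c^2
  s0 <- stress_components(2, p_ref, engaged_section(p_ref, "straight"),
                          pull_scenario("straight", 0, 0))
  expect_equal(s0$sigma_b, 0)
  expect_equal(s0$sigma_t, 2 / A)

  scen <- pull_scenario("negative", 90, 35)
  sec <- engaged_section(p_ref, "negative", beta = beta_ref)
  s1 <- stress_components(1, p_ref, sec, scen)
  s2 <- stress_components(2, p_ref, sec, scen)
  expect_equal(2 * s1$sigma_t, s2$sigma_t)
  expect_equal(2 * s1$sigma_b, s2$sigma_b)
  # hand-composed bending stress M * y / I
  M <- 1 * moment_arm(p_ref, scen)
  expect_equal(s1$sigma_b, M * y_max_of(sec, p_ref) / section_moment(sec))
})

test_that("full force ratio reduces to 1 without bending and composes prior parts", {
  expect_equal(force_ratio_full(p_ref, pull_scenario("straight", 0, 0),
                                beta = beta_ref)$ratio, 1)
  # theta2 -> theta1: no angle change, no moment arm
  near <- force_ratio_full(p_ref, pull_scenario("positive", 30, 30),
                           beta = beta_ref)
  expect_equal(near$ratio, 1)

  scen <- pull_scenario("positive", 90, 15)
  sec <- engaged_section(p_ref, "positive", beta = beta_ref)
  A <- p_ref$k * pi * p_ref$c^2
  expected <- 1 / (cos(75 * pi / 180) +
                     A * y_max_of(sec, p_ref) *
                       moment_arm(p_ref, scen) / section_moment(sec))
  expect_equal(force_ratio_full(p_ref, scen, beta = beta_ref)$ratio, expected)

  # half-angle variant uses cos(delta/2) and so gives a smaller ratio
  half <- force_ratio_full(p_ref, scen, beta = beta_ref, halfangle = TRUE)
  expect_lt(half$ratio, force_ratio_full(p_ref, scen, beta = beta_ref)$ratio)
})

test_that("pure-bending ratio has its closed-form limits", {
  # pedicle alone, right-angle pull: I/(A*c*L) = c/(4L)
  scen <- pull_scenario("straight", 90, 0)
  expect_equal(force_ratio_approx(p_ref, scen)$ratio, p_ref$c / (4 * p_ref$L))

  # dimensionless in length: uniform x10 rescale leaves it unchanged
  p10 <- morph_params(L = 10 * p_ref$L, w = 10 * p_ref$w, r = 10 * p_ref$r,
                      c = 10 * p_ref$c, k = p_ref$k, ell = 10 * p_ref$ell)
  for (d in c("positive", "negative")) {
    expect_equal(force_ratio_approx(p10, pull_scenario(d), beta = beta_ref)$ratio,
                 force_ratio_approx(p_ref, pull_scenario(d), beta = beta_ref)$ratio)
  }

  expect_error(force_ratio_approx(p_ref, pull_scenario("positive", 20, 20),
                                  beta = beta_ref),
               class = "abscissr_undefined_ratio")
})

test_that("approximation tracks the full ratio inside the validity regime", {
  withr::local_seed(11)
  checked <- 0
  for (i in 1:40) {
    p <- random_morph()
    beta <- runif(1, 1, 300)
    dir <- sample(c("positive", "negative"), 1)
    th2 <- runif(1, 0, 40)
    scen <- pull_scenario(dir, 90, th2)
    full <- force_ratio_full(p, scen, beta = beta)
    if (!full$valid) next
    appr <- force_ratio_approx(p, scen, beta = beta)
    expect_lte(abs(appr$ratio - full$ratio) / full$ratio, 0.1)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("directional ordering holds over the whole stiffness range", {
  for (beta in c(1, 2, 5, 10, 25.9, 100, 500, 1000)) {
    rp <- force_ratio_approx(p_ref, pull_scenario("positive"), beta = beta)$ratio
    rn <- force_ratio_approx(p_ref, pull_scenario("negative"), beta = beta)$ratio
    expect_lt(rp, rn)
    expect_lt(rn, 1)
  }
})

test_that("more bending means easier abscission (monotone in the bending angle)", {
  ratios <- vapply(seq(5, 90, by = 5), function(th1) {
    force_ratio_full(p_ref, pull_scenario("negative", th1, 0),
                     beta = beta_ref)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("validity flags encode the stated regime", {
  flags <- validity_check(p_ref, pull_scenario("negative", 90, 35), y_max = 25)
  expect_true(flags[["long_lever"]])    # L/ell = 62 >= 20
  expect_true(flags[["angle_ratio"]])   # 90/35 ~ 2.57 >= 1.5
  expect_true(flags[["bending_angle"]]) # 55 deg >= 45 deg
  expect_true(flags[["y_max_in_pedicle"]])

  bad <- validity_check(p_ref, pull_scenario("negative", 90, 35),
                        y_max = 2.5 * p_ref$c)
  expect_false(bad[["y_max_in_pedicle"]])

  short <- morph_params(ell = 1000)
  expect_false(validity_check(short, pull_scenario("negative", 90, 35),
                              y_max = 25)[["long_lever"]])
  expect_false(validity_check(p_ref, pull_scenario("negative", 50, 40),
                              y_max = 25)[["angle_ratio"]])
})
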