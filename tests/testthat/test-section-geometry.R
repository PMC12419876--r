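test_that("primitive areas match closed forms and the quadrature oracle", {
  ped <- section_region("porous-disc", a = 18.6, solid_fraction = 0.33)
  expect_equal(region_area(ped), 0.33 * pi * 18.6^2)
  expect_equal(region_area(ped), 358.7, tolerance = 1e-3)

  unit_sq <- section_region("rectangle", a = 1, b = 1)
  expect_equal(region_area(unit_sq), 1)

  lobe <- section_region("semi-ellipse", a = 39, b = 82.6)
  expect_equal(region_area(lobe), 5059, tolerance = 1e-3)

  for (reg in list(ped, unit_sq, lobe)) {
    o <- oracle_region_props(reg$shape, reg$a, reg$b, reg$solid_fraction,
                             reg$centroid_x)
    expect_equal(region_area(reg), o$area, tolerance = 5e-3)
  }
})

test_that("own second moments match closed forms and the quadrature oracle", {
  ped <- section_region("porous-disc", a = 18.6, solid_fraction = 0.33)
  expect_equal(region_self_moment(ped), 0.33 * pi * 18.6^4 / 4)
  expect_equal(region_self_moment(ped), 31021, tolerance = 1e-4)

  rect <- section_region("rectangle", a = 2, b = 3)
  expect_equal(region_self_moment(rect), 2)

  lobe <- section_region("semi-ellipse", a = 39, b = 82.6)
  expect_equal(region_self_moment(lobe), 5.38e5, tolerance = 1e-2)

  for (reg in list(ped, rect, lobe)) {
    o <- oracle_region_props(reg$shape, reg$a, reg$b, reg$solid_fraction,
                             reg$centroid_x, about_x = reg$centroid_x)
    expect_equal(region_self_moment(reg), o$second, tolerance = 5e-3)
  }
})

test_that("area and self moment agree with the oracle on randomised shapes", {
  withr::local_seed(42)
  for (i in 1:20) {
    a <- runif(1, 1, 60)
    b <- runif(1, 1, 120)
    k <- runif(1, 0.05, 1)
    x0 <- runif(1, -50, 50)
    for (shape in c("porous-disc", "rectangle", "semi-ellipse")) {
      reg <- section_region(shape, a = a, b = b,
                            solid_fraction = if (shape == "porous-disc") k else NA,
                            centroid_x = x0)
      o <- oracle_region_props(shape, a, b, k, x0, about_x = x0)
      expect_equal(region_area(reg), o$area, tolerance = 5e-3)
      expect_equal(region_self_moment(reg), o$second, tolerance = 5e-3)
    }
  }
})

test_that("invalid geometry is rejected", {
  expect_error(section_region("rectangle", a = -1, b = 2),
               class = "abscissr_invalid_geometry")
  expect_error(section_region("porous-disc", a = 10, solid_fraction = 1.4),
               class = "abscissr_invalid_geometry")
  expect_error(section_region("rectangle", a = 1, b = 1, weight = 0),
               class = "abscissr_invalid_geometry")
  expect_error(morph_params(c = 0), class = "abscissr_invalid_geometry")
  expect_error(morph_params(k = 0), class = "abscissr_invalid_geometry")
  expect_error(morph_params(beta = 0.5), class = "abscissr_invalid_geometry")
})

test_that("engaged sections have the direction-dependent composition", {
  p <- morph_params()
  beta <- 25.9

  straight <- engaged_section(p, "straight")
  expect_equal(nrow(straight), 1)
  expect_equal(straight$shape, "porous-disc")
  expect_equal(straight$centroid_x, 0)

  pos <- engaged_section(p, "positive", beta = beta)
  neg <- engaged_section(p, "negative", beta = beta)
  expect_equal(nrow(pos), 3)
  expect_equal(nrow(neg), 4)
  expect_true("semi-ellipse" %in% neg$shape)
  expect_false("semi-ellipse" %in% pos$shape)

  # total weighted area of the negative section, from region areas
  expect_equal(sum(neg$weight * region_area(neg)),
               358.7 + (2 * 1190.4 + 5059) / beta, tolerance = 1e-3)

  # rectangles identical across directions, mirrored along the bending axis
  pos_rect <- pos[pos$shape == "rectangle", ]
  neg_rect <- neg[neg$shape == "rectangle", ]
  expect_equal(region_area(pos_rect), region_area(neg_rect))
  expect_equal(pos_rect$centroid_x, -neg_rect$centroid_x)
  expect_equal(pos_rect$centroid_x, rep(p$c / 2, 2))

  # base weight vanishes as the pedicle becomes infinitely stiffer
  pos_stiff <- engaged_section(p, "positive", beta = 1e9)
  base_area <- sum(pos_stiff$weight[-1] * region_area(pos_stiff[-1, ]))
  expect_lt(base_area, 1e-5 * region_area(pos_stiff[1, ]))

  # beta required for angled pulls
  expect_error(engaged_section(p, "positive"),
               class = "abscissr_invalid_geometry")
})

test_that("morphology parameters round-trip through the flat config mapping", {
  p <- morph_params(L = 9000, c = 21, k = 0.4, beta = 12)
  cfg <- morph_config(p)
  expect_named(cfg, c("L_um", "w_um", "r_um", "c_um", "k", "ell_um", "beta"))
  p2 <- as_morph_params(cfg)
  expect_equal(p2$L, 9000)
  expect_equal(p2$c, 21)
  expect_equal(p2$beta, 12)
  # missing keys fall back to defaults
  expect_equal(as_morph_params(list(c_um = 25))$w, morph_params()$w)
})
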