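# Independent numerical oracles used across the suite.
#
# Section properties are re-derived by 1-D slice quadrature: each primitive
# region has a known load-bearing width profile along the bending axis, and
# area / first moment / second moment are midpoint-rule integrals of
# width(x) * {1, x, x^2}. This never touches the closed forms under test.

# width of the load-bearing material at axis position x (absolute coords)
oracle_width <- function(shape, a, b, k, centroid_x) {
  switch(shape,
    "porous-disc" = function(x) {
      d2 <- a^2 - (x - centroid_x)^2
      ifelse(d2 > 0, 2 * k * sqrt(d2), 0)
    },
    "rectangle" = function(x) {
      ifelse(abs(x - centroid_x) <= a / 2, b, 0)
    },
    "semi-ellipse" = function(x) {
      # lobe extends toward -x; flat edge sits at centroid + 4a/(3*pi)
      xf <- centroid_x + 4 * a / (3 * pi)
      t <- (xf - x) / a
      ifelse(t >= 0 & t <= 1, 2 * b * sqrt(pmax(0, 1 - t^2)), 0)
    },
    stop("unknown shape")
  )
}

oracle_support <- function(shape, a, b, centroid_x) {
  switch(shape,
    "porous-disc" = centroid_x + c(-a, a),
    "rectangle" = centroid_x + c(-a / 2, a / 2),
    "semi-ellipse" = {
      xf <- centroid_x + 4 * a / (3 * pi)
      c(xf - a, xf)
    }
  )
}

# area, first moment about x = 0, second moment about `about_x`, by midpoint rule
oracle_region_props <- function(shape, a, b = NA, k = NA, centroid_x = 0,
                                about_x = 0, n = 40000) {
  wfun <- oracle_width(shape, a, b, k, centroid_x)
  sup <- oracle_support(shape, a, b, centroid_x)
  h <- diff(sup) / n
  x <- seq(sup[1] + h / 2, sup[2] - h / 2, length.out = n)
  wdt <- wfun(x)
  list(
    area = sum(wdt) * h,
    first = sum(wdt * x) * h,
    second = sum(wdt * (x - about_x)^2) * h
  )
}

# modulus-weighted neutral axis and second moment of a composite section table
oracle_section_props <- function(section, n = 40000) {
  per <- lapply(seq_len(nrow(section)), function(i) {
    oracle_region_props(section$shape[i], section$a[i], section$b[i],
                        section$solid_fraction[i], section$centroid_x[i],
                        about_x = 0, n = n)
  })
  w <- section$weight
  area <- sum(w * vapply(per, `[[`, 1, "area"))
  first <- sum(w * vapply(per, `[[`, 1, "first"))
  delta <- first / area
  second0 <- sum(w * vapply(per, `[[`, 1, "second"))
  # shift from axis 0 to axis delta
  list(delta = delta, area = area, I = second0 - area * delta^2)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of the group
# assignments of the pooled ranks (tie-free data only).
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(length(pooled), nx)
  u_all <- apply(sets, 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# random valid morphology, kept away from degenerate corners
random_morph <- function() {
  morph_params(
    L = stats::runif(1, 5000, 20000),
    w = stats::runif(1, 30, 120),
    r = stats::runif(1, 15, 80),
    c = stats::runif(1, 8, 35),
    k = stats::runif(1, 0.1, 0.9),
    ell = stats::runif(1, 100, 500)
  )
}
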