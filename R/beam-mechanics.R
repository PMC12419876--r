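#' Pull scenario
#'
#' Describes one pull on a seed: the direction, the angle `theta1` (degrees)
#' between the applied force and the seed's original axis, and the axis angle
#' `theta2` (degrees) at the moment of abscission. Video observation gives
#' `theta2` of about 35 degrees for negative pulls (toward the scape) and 15
#' degrees for positive pulls (toward the apex); straight pulls use 0. The
#' seed always abscises at `|theta2| <= |theta1|`.
#'
#' @param direction `"straight"`, `"positive"` or `"negative"`.
#' @param theta1 Applied-force angle to the original seed axis, degrees.
#' @param theta2 Seed-axis angle at abscission, degrees. Defaults to 0 / 15 /
#'   35 for straight / positive / negative.
#' @return An object of class `pull_scenario`.
#' @examples
#' pull_scenario("negative")
#' pull_scenario("positive", theta1 = 90, theta2 = 15)
#' @export
pull_scenario <- function(direction = c("straight", "positive", "negative"),
                          theta1 = if (direction == "straight") 0 else 90,
                          theta2 = switch(direction, straight = 0,
                                          positive = 15, negative = 35)) {
  direction <- match.arg(direction)
  if (!is.finite(theta1) || !is.finite(theta2)) {
    abort("Angles must be finite.")
  }
  if (abs(theta2) > abs(theta1)) {
    abort("Abscission requires |theta2| <= |theta1|.",
          class = "abscissr_invalid_scenario")
  }
  structure(list(direction = direction, theta1 = theta1, theta2 = theta2),
            class = "pull_scenario")
}

#' @export
print.pull_scenario <- function(x, ...) {
  cat(sprintf("<pull_scenario> %s: theta1 = %g deg, theta2 = %g deg\n",
              x$direction, x$theta1, x$theta2))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

# bending angle |theta1| - |theta2|, radians
delta_theta <- function(scen) {
  d <- abs(scen$theta1) - abs(scen$theta2)
  if (d < 0) {
    abort("Moment arm undefined for |theta1| < |theta2|.",
          class = "abscissr_invalid_scenario")
  }
  deg2rad(d)
}

#' Neutral axis of a composite section
#'
#' Signed offset of the modulus-weighted centroid of the engaged section along
#' the bending axis: `sum(w_i A_i x_i) / sum(w_i A_i)`. For the pedicle alone
#' the offset is zero; engaged base tissue pulls the neutral axis toward the
#' compression side.
#'
#' @param section A composite section from [engaged_section()] (or any valid
#'   region table).
#' @return Signed offset, um (positive = toward the capitulum apex).
#' @examples
#' neutral_axis_offset(engaged_section(morph_params(), "negative", beta = 25))
#' @export
neutral_axis_offset <- function(section) {
  a <- region_area(section)
  wa <- section$weight * a
  total <- sum(wa)
  if (!is.finite(total) || total <= 0) {
    abort("Section has zero weighted area.",
          class = "abscissr_invalid_geometry")
  }
  sum(wa * section$centroid_x) / total
}

#' Second moment of area of a composite section
#'
#' Modulus-weighted second moment about a given axis position, via the
#' parallel-axis theorem:
#' `sum(w_i * (I_self_i + A_i * (x_i - about_x)^2))`. By default the moment is
#' taken about the section's neutral axis, where it is minimal.
#'
#' @inheritParams neutral_axis_offset
#' @param about_x Axis position along the bending axis, um. Defaults to the
#'   neutral axis.
#' @return Second moment of area, um^4.
#' @examples
#' sec <- engaged_section(morph_params(), "negative", beta = 25)
#' section_moment(sec)
#' @export
section_moment <- function(section, about_x = neutral_axis_offset(section)) {
  a <- region_area(section)
  i0 <- region_self_moment(section)
  sum(section$weight * (i0 + a * (section$centroid_x - about_x)^2))
}

#' Distance from the neutral axis to the tension edge of the pedicle
#'
#' A pull bends the seed like a cantilever: the pedicle edge opposite the pull
#' direction goes into tension, and that is where fracture starts. The
#' outer-fibre distance is `y_max = c + |delta|` for angled pulls (the neutral
#' axis shifts toward the compression side by `delta`, see
#' [neutral_axis_offset()]) and `c` for a straight pull. The bending model is
#' only trusted while the neutral axis stays inside the pedicle, i.e.
#' `c <= y_max <= 2c`; outside that range a validity flag is raised by
#' [validity_check()] rather than an error.
#'
#' @inheritParams neutral_axis_offset
#' @param params The [morph_params()] the section was built from.
#' @return `y_max`, um.
#' @examples
#' p <- morph_params()
#' y_max_of(engaged_section(p, "negative", beta = 25), p)
#' @export
y_max_of <- function(section, params) {
  stopifnot(inherits(params, "morph_params"))
  if (section_direction(section) == "straight") {
    return(params$c)
  }
  params$c + abs(neutral_axis_offset(section))
}

#' Moment arm of the applied force
#'
#' Length of the lever between the point of force application (top of the
#' achene/beak lever, at `L + ell` from the pedicle base) and the pedicle
#' base, projected perpendicular to the force:
#' `p = (L + ell) * sin(|theta1| - |theta2|)`. In the long-lever regime
#' (`L >> ell`) this reduces to the approximation `p ~ L sin(|theta1| - |theta2|)`.
#'
#' @param params A [morph_params()] object.
#' @param scen A [pull_scenario()].
#' @return Moment arm `p`, um.
#' @examples
#' moment_arm(morph_params(), pull_scenario("positive"))
#' @export
moment_arm <- function(params, scen) {
  stopifnot(inherits(params, "morph_params"), inherits(scen, "pull_scenario"))
  (params$L + params$ell) * sin(delta_theta(scen))
}

#' Tension and bending stress at the tension edge of the pedicle
#'
#' An angled pull loads the pedicle with both a tension component (the force
#' projected on the pedicle axis) and a bending moment. The outer-fibre
#' stresses are `sigma_t = F cos(|theta1| - |theta2|) / A` with
#' `A = k pi c^2`, and `sigma_b = F p y_max / I`.
#'
#' @param F Applied force, mN.
#' @param params A [morph_params()] object.
#' @param section The engaged composite section for the scenario's direction.
#' @param scen A [pull_scenario()].
#' @return A tibble with columns `sigma_t` and `sigma_b`, mN/um^2.
#' @examples
#' p <- morph_params()
#' s <- pull_scenario("negative")
#' stress_components(1, p, engaged_section(p, "negative", beta = 25), s)
#' @export
stress_components <- function(F, params, section, scen) {
  if (!is.finite(F) || F <= 0) abort("`F` must be positive.")
  A <- params$k * pi * params$c^2
  dth <- delta_theta(scen)
  y <- y_max_of(section, params)
  I <- section_moment(section)
  p <- moment_arm(params, scen)
  tibble(sigma_t = F * cos(dth) / A, sigma_b = F * p * y / I)
}

#' Validity conditions of the bending approximation
#'
#' Four named flags delimit where the model (and in particular the pure-
#' bending approximation of [force_ratio_approx()]) is trusted: a long lever
#' `L/ell >= 20`; substantial angle change `theta1/theta2 >= 3/2`; a bending
#' angle of at least 45 degrees (`|theta1| - |theta2| >= pi/4`), so the
#' tension contribution is negligible; and a neutral axis inside the pedicle,
#' `c <= y_max <= 2c`.
#'
#' @inheritParams moment_arm
#' @param y_max Outer-fibre distance, um (from [y_max_of()]).
#' @return A named logical vector with elements `long_lever`, `angle_ratio`,
#'   `bending_angle`, `y_max_in_pedicle`.
#' @examples
#' p <- morph_params()
#' validity_check(p, pull_scenario("negative"), y_max = 25)
#' @export
validity_check <- function(params, scen, y_max) {
  th1 <- abs(scen$theta1)
  th2 <- abs(scen$theta2)
  c(
    long_lever = params$L / params$ell >= 20,
    angle_ratio = if (th2 == 0) th1 > 0 else th1 / th2 >= 1.5,
    bending_angle = deg2rad(th1 - th2) >= pi / 4,
    y_max_in_pedicle = y_max >= params$c && y_max <= 2 * params$c
  )
}

ratio_result <- function(scen, ratio, y_max, I, p, A, flags, method) {
  tibble(
    direction = scen$direction, theta1 = scen$theta1, theta2 = scen$theta2,
    ratio = ratio, y_max_um = y_max, I_um4 = I, p_um = p, A_um2 = A,
    long_lever = flags[["long_lever"]],
    angle_ratio = flags[["angle_ratio"]],
    bending_angle = flags[["bending_angle"]],
    y_max_in_pedicle = flags[["y_max_in_pedicle"]],
    valid = all(flags), method = method
  )
}

#' Directional abscission force ratio (full stress balance)
#'
#' Ratio of the abscission force for an angled pull to the straight-pull
#' force, `Fa/Fas`. At abscission the combined outer-fibre stress reaches the
#' pedicle breaking stress: `sigma_t + sigma_b = sigma_break`, and a straight
#' pull gives `sigma_break = Fas / A`, so the breaking stress cancels and
#'
#' `Fa/Fas = 1 / (cos(|theta1| - |theta2|) + A * y_max * p / I)`.
#'
#' The engaged section -- hence `y_max` and `I` -- depends on the pull
#' direction, which is what makes abscission directional.
#'
#' @inheritParams moment_arm
#' @param beta Stiffness ratio Ep/Eb (>= 1); defaults to `params$beta`.
#' @param halfangle If `TRUE`, use `cos((|theta1| - |theta2|)/2)` in the
#'   denominator instead of the full bending angle. The full-angle form (the
#'   default) is the one consistent with projecting the applied force on the
#'   pedicle axis and with the pure-bending approximation; the half-angle
#'   variant is kept because the stress-balance relation admits that reading.
#' @return A one-row tibble: `direction`, `theta1`, `theta2`, `ratio`,
#'   `y_max_um`, `I_um4`, `p_um`, `A_um2`, the four validity flags of
#'   [validity_check()], `valid` (all flags), `method`.
#' @examples
#' force_ratio_full(morph_params(), pull_scenario("negative"), beta = 25)
#' @export
force_ratio_full <- function(params, scen, beta = params$beta,
                             halfangle = FALSE) {
  stopifnot(inherits(params, "morph_params"), inherits(scen, "pull_scenario"))
  section <- engaged_section(params, scen$direction, beta = beta)
  A <- params$k * pi * params$c^2
  y <- y_max_of(section, params)
  I <- section_moment(section)
  p <- moment_arm(params, scen)
  dth <- delta_theta(scen)
  cos_term <- if (halfangle) cos(dth / 2) else cos(dth)
  ratio <- 1 / (cos_term + A * y * p / I)
  flags <- validity_check(params, scen, y)
  ratio_result(scen, ratio, y, I, p, A, flags, method = "full")
}

#' Directional abscission force ratio (pure-bending approximation)
#'
#' In the validity regime of [validity_check()] the tension term is
#' negligible and the moment arm is approximately `L sin(|theta1| - |theta2|)`,
#' giving the closed form
#'
#' `Fa/Fas = I / (k pi c^2 * y_max * L * sin(|theta1| - |theta2|))`.
#'
#' This expression is dimensionless in length: rescaling every length
#' uniformly leaves it unchanged. The returned flags record whether the
#' stated regime actually holds for the inputs.
#'
#' @inheritParams force_ratio_full
#' @return Same shape as [force_ratio_full()], with `method = "approx"` and
#'   `p_um = L * sin(|theta1| - |theta2|)`.
#' @examples
#' force_ratio_approx(morph_params(), pull_scenario("positive"), beta = 25)
#' @export
force_ratio_approx <- function(params, scen, beta = params$beta) {
  stopifnot(inherits(params, "morph_params"), inherits(scen, "pull_scenario"))
  dth <- delta_theta(scen)
  if (sin(dth) == 0) {
    abort("Pure-bending ratio undefined at |theta1| == |theta2|.",
          class = "abscissr_undefined_ratio")
  }
  section <- engaged_section(params, scen$direction, beta = beta)
  A <- params$k * pi * params$c^2
  y <- y_max_of(section, params)
  I <- section_moment(section)
  p <- params$L * sin(dth)
  ratio <- I / (A * y * p)
  flags <- validity_check(params, scen, y)
  ratio_result(scen, ratio, y, I, p, A, flags, method = "approx")
}
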