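#' Primitive cross-section regions
#'
#' The pedicle--attachment-site bending unit is assembled from three primitive
#' planar shapes, each described by one row of a region table:
#'
#' * `"porous-disc"`: the pedicle, radius `a = c` with solid fraction
#'   `solid_fraction = k`. Only the fraction `k` of the disc carries load, so
#'   its area is `k * pi * c^2` and its own second moment `k * pi * c^4 / 4`.
#' * `"rectangle"`: a block of base tissue with extent `a` along the bending
#'   axis and width `b`; area `a * b`, own second moment `b * a^3 / 12`.
#' * `"semi-ellipse"`: the scape-side horseshoe lobe with bending-axis
#'   semi-axis `a` and lateral semi-axis `b` (flat edge perpendicular to the
#'   bending axis); area `pi * a * b / 2`, own second moment about its
#'   centroid `a^3 * b * (pi/8 - 8/(9*pi))`.
#'
#' `centroid_x` is the signed offset of the region centroid along the bending
#' axis (`+x` points toward the capitulum apex, i.e. the positive pull
#' direction) and `weight` is the modulus weight of the transformed-section
#' method: 1 for pedicle material, `1/beta` for the softer base tissue.
#'
#' @param shape One of `"porous-disc"`, `"rectangle"`, `"semi-ellipse"`.
#' @param a,b Shape dimensions, um (see above; `b` unused for the disc).
#' @param solid_fraction Load-bearing fraction in (0, 1]; only for the disc.
#' @param centroid_x Signed centroid offset along the bending axis, um.
#' @param weight Modulus weight in (0, 1].
#' @return A one-row tibble with columns `shape`, `a`, `b`, `solid_fraction`,
#'   `centroid_x`, `weight`.
#' @examples
#' section_region("porous-disc", a = 18.6, solid_fraction = 0.33)
#' @export
section_region <- function(shape, a, b = NA_real_, solid_fraction = NA_real_,
                           centroid_x = 0, weight = 1) {
  shape <- match.arg(shape, c("porous-disc", "rectangle", "semi-ellipse"))
  region <- tibble(shape = shape, a = a, b = b,
                   solid_fraction = solid_fraction,
                   centroid_x = centroid_x, weight = weight)
  validate_regions(region)
  region
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  needed <- c("shape", "a", "b", "solid_fraction", "centroid_x", "weight")
  if (!all(needed %in% names(regions))) {
    abort(paste0("Region table must have columns: ",
                 paste(needed, collapse = ", "), "."))
  }
  bad_shape <- setdiff(regions$shape,
                       c("porous-disc", "rectangle", "semi-ellipse"))
  if (length(bad_shape) > 0) {
    abort(paste0("Unknown region shape: ", paste(bad_shape, collapse = ", ")),
          class = "abscissr_invalid_geometry")
  }
  if (any(!is.finite(regions$a)) || any(regions$a <= 0)) {
    abort("Region dimension `a` must be finite and positive.",
          class = "abscissr_invalid_geometry")
  }
  needs_b <- regions$shape != "porous-disc"
  if (any(needs_b & (!is.finite(regions$b) | regions$b <= 0))) {
    abort("Region dimension `b` must be finite and positive.",
          class = "abscissr_invalid_geometry")
  }
  is_disc <- regions$shape == "porous-disc"
  k <- regions$solid_fraction[is_disc]
  if (any(!is.finite(k) | k <= 0 | k > 1)) {
    abort("Disc `solid_fraction` must lie in (0, 1].",
          class = "abscissr_invalid_geometry")
  }
  if (any(!is.finite(regions$weight)) || any(regions$weight <= 0) ||
      any(regions$weight > 1)) {
    abort("Region `weight` must lie in (0, 1].",
          class = "abscissr_invalid_geometry")
  }
  invisible(regions)
}

#' Area and own second moment of section regions
#'
#' `region_area()` returns the geometric (for the porous disc: load-bearing)
#' area of each region; `region_self_moment()` returns each region's second
#' moment of area about its own centroid, for bending about the lateral axis.
#' Neither applies the modulus `weight` -- weighting is done where regions are
#' combined ([neutral_axis_offset()], [section_moment()]).
#'
#' @param regions A region table as built by [section_region()] or
#'   [engaged_section()] (one or more rows).
#' @return A numeric vector, um^2 for areas and um^4 for moments, one element
#'   per region row.
#' @examples
#' ped <- section_region("porous-disc", a = 18.6, solid_fraction = 0.33)
#' region_area(ped)        # k * pi * c^2
#' region_self_moment(ped) # k * pi * c^4 / 4
#' @export
region_area <- function(regions) {
  validate_regions(regions)
  dplyr::case_when(
    regions$shape == "porous-disc" ~ regions$solid_fraction * pi * regions$a^2,
    regions$shape == "rectangle"   ~ regions$a * regions$b,
    regions$shape == "semi-ellipse" ~ pi * regions$a * regions$b / 2
  )
}

#' @rdname region_area
#' @export
region_self_moment <- function(regions) {
  validate_regions(regions)
  dplyr::case_when(
    regions$shape == "porous-disc" ~
      regions$solid_fraction * pi * regions$a^4 / 4,
    regions$shape == "rectangle" ~ regions$b * regions$a^3 / 12,
    regions$shape == "semi-ellipse" ~
      regions$a^3 * regions$b * (pi / 8 - 8 / (9 * pi))
  )
}

#' Composite bending section engaged by a pull direction
#'
#' Builds the transformed (modulus-weighted) cross-section that bends as one
#' unit when a seed is pulled in a given direction. Only base tissue on the
#' compression side of the bend joins the section, because the achene merely
#' rests against the attachment site and cannot transmit tension across the
#' contact:
#'
#' * `"straight"`: the pedicle disc alone -- a straight pull engages no base
#'   tissue.
#' * `"positive"` (toward the capitulum apex): pedicle plus the two apex-side
#'   half-rectangles of the horseshoe arms, each `c x w` with centroid at
#'   `x = +c/2`.
#' * `"negative"` (toward the scape): pedicle plus the two scape-side
#'   half-rectangles (centroid `x = -c/2`) plus the scape-side semi-elliptical
#'   lobe (semi-axes `r` along `-x` and `c + w` laterally, flat edge at
#'   `x = -c`, centroid at `x = -c - 4r/(3*pi)`).
#'
#' Base regions carry modulus weight `1/beta`; the pedicle carries weight 1.
#'
#' @param params A [morph_params()] object.
#' @param direction `"straight"`, `"positive"` or `"negative"`.
#' @param beta Stiffness ratio Ep/Eb (>= 1). Defaults to `params$beta`;
#'   required (directly or via `params`) except for `"straight"`.
#' @return A tibble of regions (class `composite_section`) with attributes
#'   `direction` and `beta`.
#' @examples
#' engaged_section(morph_params(), "negative", beta = 25)
#' @export
engaged_section <- function(params, direction = c("straight", "positive", "negative"),
                            beta = params$beta) {
  stopifnot(inherits(params, "morph_params"))
  direction <- match.arg(direction)
  pedicle <- section_region("porous-disc", a = params$c,
                            solid_fraction = params$k,
                            centroid_x = 0, weight = 1)
  if (direction == "straight") {
    regions <- pedicle
    beta <- NA_real_
  } else {
    if (is.null(beta) || !is.finite(beta) || beta < 1) {
      abort("`beta` >= 1 is required for angled-pull sections.",
            class = "abscissr_invalid_geometry")
    }
    side <- if (direction == "positive") +1 else -1
    arm <- section_region("rectangle", a = params$c, b = params$w,
                          centroid_x = side * params$c / 2, weight = 1 / beta)
    regions <- dplyr::bind_rows(pedicle, arm, arm)
    if (direction == "negative") {
      lobe <- section_region(
        "semi-ellipse", a = params$r, b = params$c + params$w,
        centroid_x = -params$c - 4 * params$r / (3 * pi),
        weight = 1 / beta
      )
      regions <- dplyr::bind_rows(regions, lobe)
    }
  }
  structure(regions,
            direction = direction, beta = beta,
            class = c("composite_section", class(regions)))
}

section_direction <- function(section) attr(section, "direction")
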