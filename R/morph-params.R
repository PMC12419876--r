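#' Morphological parameters of the seed-attachment unit
#'
#' Bundles the measured morphology of a dandelion seed unit and its
#' receptacle attachment: the lever formed by achene plus beak (length `L`),
#' the raised attachment-site base (width `w`, radius `r`), and the porous
#' pedicle that actually breaks (radius `c`, solid fraction `k`, length
#' `ell`). Defaults are the study-population means; all lengths are in
#' micrometres.
#'
#' @param L Seed length (centre of pappus to achene tip), um.
#' @param w Base width (thickest lateral extent of the attachment site), um.
#' @param r Base radius (pedicle to scape-side edge of the attachment zone), um.
#' @param c Pedicle radius, um.
#' @param k Pedicle solid fraction in (0, 1]: the load-bearing share of the
#'   pedicle cross-section.
#' @param ell Pedicle length, um. Not reported with the other morphology
#'   measurements; the 200 um default keeps the long-lever regime
#'   (`L/ell >= 20`) comfortably satisfied and is configurable.
#' @param beta Optional stiffness ratio `Ep/Eb` (pedicle to base elastic
#'   modulus), must be >= 1 when supplied. Most functions take `beta` as an
#'   explicit argument; a value stored here acts as their default.
#' @param sigma_break Optional pedicle breaking stress, mN/um^2. It cancels in
#'   every force ratio and is carried only for completeness.
#'
#' @return An object of class `morph_params`: a named list with the fields
#'   above.
#' @examples
#' p <- morph_params()
#' p$c
#' morph_params(c = 25, r = 50, w = 80)
#' @export
morph_params <- function(L = 12400, w = 64, r = 39, c = 18.6, k = 0.33,
                         ell = 200, beta = NULL, sigma_break = NULL) {
  lens <- c(L = L, w = w, r = r, c = c, ell = ell)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("All lengths (L, w, r, c, ell) must be finite and strictly positive.",
          class = "abscissr_invalid_geometry")
  }
  if (!is.finite(k) || k <= 0 || k > 1) {
    abort("Solid fraction `k` must lie in (0, 1].",
          class = "abscissr_invalid_geometry")
  }
  if (!is.null(beta)) {
    if (!is.finite(beta) || beta < 1) {
      abort("Stiffness ratio `beta` = Ep/Eb must be >= 1.",
            class = "abscissr_invalid_geometry")
    }
  }
  if (!is.null(sigma_break) && (!is.finite(sigma_break) || sigma_break <= 0)) {
    abort("`sigma_break` must be positive when supplied.")
  }
  structure(
    list(L = L, w = w, r = r, c = c, k = k, ell = ell,
         beta = beta, sigma_break = sigma_break),
    class = "morph_params"
  )
}

#' @export
print.morph_params <- function(x, ...) {
  cat("<morph_params>\n")
  cat(sprintf("  L = %g um, w = %g um, r = %g um, c = %g um\n",
              x$L, x$w, x$r, x$c))
  cat(sprintf("  k = %g, ell = %g um", x$k, x$ell))
  if (!is.null(x$beta)) cat(sprintf(", beta = %g", x$beta))
  cat("\n")
  invisible(x)
}

#' Convert between morphology parameters and a flat configuration mapping
#'
#' `as_morph_params()` builds a [morph_params()] object from a flat named list
#' (as read from YAML/JSON config) with keys `L_um`, `w_um`, `r_um`, `c_um`,
#' `k`, `ell_um` and optionally `beta`; `morph_config()` is the inverse.
#'
#' @param config Named list with the keys above; missing keys fall back to the
#'   defaults of [morph_params()].
#' @return `as_morph_params()`: a `morph_params` object. `morph_config()`: a
#'   named list of plain numbers.
#' @examples
#' cfg <- morph_config(morph_params(c = 20))
#' as_morph_params(cfg)
#' @export
as_morph_params <- function(config) {
  stopifnot(is.list(config))
  d <- formals(morph_params)
  pick <- function(key, default) {
    if (!is.null(config[[key]])) as.numeric(config[[key]]) else default
  }
  morph_params(
    L = pick("L_um", d$L), w = pick("w_um", d$w), r = pick("r_um", d$r),
    c = pick("c_um", d$c), k = pick("k", d$k), ell = pick("ell_um", d$ell),
    beta = if (!is.null(config$beta)) as.numeric(config$beta) else NULL
  )
}

#' @rdname as_morph_params
#' @param params A `morph_params` object.
#' @export
morph_config <- function(params) {
  stopifnot(inherits(params, "morph_params"))
  out <- list(L_um = params$L, w_um = params$w, r_um = params$r,
              c_um = params$c, k = params$k, ell_um = params$ell)
  if (!is.null(params$beta)) out$beta <- params$beta
  out
}

#' Reference morphology of the dandelion seed unit
#'
#' Population summary of the measured morphological parameters: mean,
#' bootstrapped standard error of the mean, and population standard deviation,
#' with sample sizes. These drive [sample_morphology()] and the error
#' propagation in [propagate_errors()].
#'
#' @return A tibble with columns `parameter`, `mean`, `se`, `sd`, `n`, `unit`.
#' @examples
#' dandelion_morphology()
#' @export
dandelion_morphology <- function() {
  tibble(
    parameter = c("L", "w", "r", "c", "k"),
    mean = c(12400, 64, 39, 18.6, 0.33),
    se   = c(100, 2, 2, 0.95, 0.05),
    sd   = c(1000, 16, 10, 5, 0.1),
    n    = c(304L, 228L, 104L, 115L, 10L),
    unit = c("um", "um", "um", "um", "1")
  )
}
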